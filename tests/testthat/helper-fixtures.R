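# Shared in-code fixtures for the test suite.

# a small, fast simulation: 7 planted archetypes of 60 genes each
small_sim_config <- function(seed = 1L, n_genes = 800L, n_per_pattern = 60L) {
  pats <- default_planted_patterns()
  pats <- lapply(pats, function(p) { p$n_genes <- n_per_pattern; p })
  sim_config(n_genes = n_genes, planted_patterns = pats,
             n_terms = 60L, term_size_range = c(5L, 15L), seed = seed)
}

# hand-built contrast result with given calls
make_contrast <- function(gene_id, call, log2fc = 2 * call,
                          reference = "A", test = "B") {
  res <- data.frame(gene_id = gene_id, base_mean = 100,
                    log2fc = log2fc,
                    p = ifelse(call == 0L, 0.5, 1e-6),
                    padj = ifelse(call == 0L, 0.9, 1e-5),
                    call = as.integer(call), converged = TRUE,
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- c(reference = reference, test = test)
  res
}

# tiny count matrix with dimnames
toy_counts <- function(values, n_genes, n_samples,
                       genes = paste0("g", seq_len(n_genes)),
                       samps = paste0("s", seq_len(n_samples))) {
  m <- matrix(as.integer(values), nrow = n_genes, ncol = n_samples,
              dimnames = list(genes, samps))
  m
}

two_group_samples <- function(n_per_group, labels = c("A", "B")) {
  data.frame(
    sample_id = paste0(rep(labels, each = n_per_group), "_",
                       seq_len(n_per_group)),
    treatment = rep(labels, each = n_per_group),
    replicate = rep(seq_len(n_per_group), times = length(labels)),
    stringsAsFactors = FALSE)
}
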