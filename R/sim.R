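#' Default planted response-pattern archetypes
#'
#' Seven non-null pattern codes mirroring the archetypes seen in potato
#' leaves under potato tuber moth herbivory: genes responding only to
#' wounding (+1,0,0); only to insect-derived cues, up or down (0,+1,0) /
#' (0,-1,0); only to orally-secreted-bacteria cues (0,0,+1) / (0,0,-1); and
#' genes responding to both cue classes with opposite signs (0,+1,+1) /
#' (0,-1,-1). Each archetype plants 400 genes with |log2FC| drawn from
#' [2, 4].
#'
#' @return A list of planted-pattern specs, each with `code` (integer
#'   3-vector in \{-1,0,1\}), `n_genes`, and `lfc_range`.
#' @export
default_planted_patterns <- function() {
  codes <- list(c(1L, 0L, 0L),
                c(0L, 1L, 0L), c(0L, -1L, 0L),
                c(0L, 0L, 1L), c(0L, 0L, -1L),
                c(0L, 1L, 1L), c(0L, -1L, -1L))
  lapply(codes, function(cd) list(code = cd, n_genes = 400L,
                                  lfc_range = c(2, 4)))
}

#' Configuration for the synthetic herbivory experiment
#'
#' Describes a five-treatment design (undamaged control; wounding W_W;
#' wounding plus antibiotic-treated oral secretion W_ABOS; wounding plus
#' oral secretion W_OS, i.e. simulated herbivory; actual herbivory) with
#' negative-binomial gene counts. Planted log2-fold-change patterns are
#' inherited cumulatively along the stimulus chain
#' control -> W_W -> W_ABOS -> W_OS, and the actual-herbivory group mirrors
#' the full W_OS effect scaled by `attenuation` (default 0.74, a realistic
#' damping of insect feeding relative to its simulation).
#'
#' @param n_genes Number of genes (default 5000).
#' @param treatments Ordered treatment labels; the middle three form the
#'   cumulative chain.
#' @param replicates_per_treatment Biological replicates per treatment
#'   (default 4; the field norm is 3-5).
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   baseline gene abundances (meanlog / sdlog).
#' @param dispersion_a0,dispersion_a1 Gene dispersion trend
#'   phi = a0 + a1 / mu.
#' @param library_size_cv Coefficient of variation of log-normal library-size
#'   factors.
#' @param planted_baseline_min Lower truncation (mean counts) of the baseline
#'   abundance of planted responsive genes (default 250). Response modules
#'   are, by construction, genes that remain detectable in every contrast
#'   even after strong knockdown; planting effects on near-silent genes would
#'   emulate dropout, not response.
#' @param planted_patterns List of planted-pattern specs (see
#'   [default_planted_patterns()]); `list()` plants nothing (null model).
#' @param attenuation Scaling of the cumulative W_OS effect in the
#'   actual-herbivory group.
#' @param n_terms Number of synthetic GO terms.
#' @param term_size_range Integer (min, max) genes per term.
#' @param enriched_term_fraction Fraction of terms planted as
#'   module-enriched.
#' @param seed Integer seed controlling every stochastic draw.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000L,
                       treatments = c("control", "W_W", "W_ABOS", "W_OS",
                                      "herbivory"),
                       replicates_per_treatment = 4L,
                       baseline_log_mean = 4.5,
                       baseline_log_sd = 1.2,
                       dispersion_a0 = 0.01,
                       dispersion_a1 = 2,
                       library_size_cv = 0.2,
                       planted_baseline_min = 250,
                       planted_patterns = default_planted_patterns(),
                       attenuation = 0.74,
                       n_terms = 200L,
                       term_size_range = c(10L, 50L),
                       enriched_term_fraction = 0.3,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), treatments = treatments,
              replicates_per_treatment = as.integer(replicates_per_treatment),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion_a0 = dispersion_a0, dispersion_a1 = dispersion_a1,
              library_size_cv = library_size_cv,
              planted_baseline_min = planted_baseline_min,
              planted_patterns = planted_patterns,
              attenuation = attenuation,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              enriched_term_fraction = enriched_term_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes <= 0L) stop("n_genes must be positive")
  if (cfg$replicates_per_treatment < 2L) stop("need >= 2 replicates")
  if (length(cfg$treatments) < 4L || anyDuplicated(cfg$treatments))
    stop("treatments must be >= 4 distinct labels (chain + control)")
  if (cfg$dispersion_a0 <= 0 || cfg$dispersion_a1 <= 0)
    stop("dispersion parameters must be positive")
  n_planted <- sum(vapply(cfg$planted_patterns,
                          function(p) as.integer(p$n_genes), integer(1)))
  if (n_planted > cfg$n_genes)
    stop("planted pattern gene counts (", n_planted,
         ") exceed n_genes (", cfg$n_genes, ")")
  for (p in cfg$planted_patterns) {
    if (length(p$code) != 3L || !all(p$code %in% c(-1L, 0L, 1L)))
      stop("pattern codes must be length-3 vectors over {-1, 0, 1}")
    if (all(p$code == 0L)) stop("planted codes must be non-null")
    if (any(p$lfc_range <= 0)) stop("lfc_range must be positive magnitudes")
  }
  if (cfg$term_size_range[2L] > cfg$n_genes)
    stop("term size exceeds n_genes")
  invisible(cfg)
}

#' Simulate the five-treatment herbivory count experiment
#'
#' Draws NB(mean = library_factor x baseline x 2^(cumulative planted log2FC),
#' dispersion phi_g = a0 + a1/baseline_g) counts for every gene and sample.
#' A planted code (d1, d2, d3) contributes d1*|fc1| to W_W and, cumulatively,
#' d2*|fc2| on top in W_ABOS and d3*|fc3| on top in W_OS; actual herbivory
#' receives `attenuation` times the full W_OS cumulative effect. The same
#' config (including seed) always reproduces the outputs exactly.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (integer matrix), `samples`
#'   (metadata data.frame), `lengths` (named vector), `annotation` (term ->
#'   genes list), and `truth` (a `sim_truth` record; see Details).
#'   `truth$gene_pattern` maps gene id to its code string, `truth$gene_log2fc`
#'   is the n_genes x 3 matrix of true contrast effects, and
#'   `truth$enriched_terms` maps module code strings to planted term ids.
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  reps <- config$replicates_per_treatment
  trts <- config$treatments
  gene_ids <- sprintf("g%05d", seq_len(G))

  # true contrast effects (log2) per gene
  fc <- matrix(0, nrow = G, ncol = 3L,
               dimnames = list(gene_ids, c("fc1", "fc2", "fc3")))
  codes <- matrix(0L, nrow = G, ncol = 3L, dimnames = list(gene_ids, NULL))
  at <- 0L
  for (p in config$planted_patterns) {
    idx <- at + seq_len(p$n_genes)
    at <- at + p$n_genes
    for (k in 1:3) {
      if (p$code[k] != 0L) {
        fc[idx, k] <- p$code[k] *
          stats::runif(p$n_genes, p$lfc_range[1L], p$lfc_range[2L])
      }
    }
    codes[idx, ] <- matrix(p$code, nrow = p$n_genes, ncol = 3L, byrow = TRUE)
  }

  baseline <- stats::rlnorm(G, meanlog = config$baseline_log_mean,
                            sdlog = config$baseline_log_sd)
  if (at > 0L && config$planted_baseline_min > 0) {
    # planted genes: same log-normal, truncated below (inverse-CDF sampling)
    f_min <- stats::plnorm(config$planted_baseline_min,
                           config$baseline_log_mean, config$baseline_log_sd)
    u <- stats::runif(at, f_min, 1)
    baseline[seq_len(at)] <- stats::qlnorm(u, config$baseline_log_mean,
                                           config$baseline_log_sd)
  }
  phi <- config$dispersion_a0 + config$dispersion_a1 / baseline
  lengths <- ceiling(stats::runif(G, 300, 5000))
  names(lengths) <- gene_ids

  # cumulative log2 shift per treatment; chain = treatments 2..4
  cum <- cbind(0,
               fc[, 1L],
               fc[, 1L] + fc[, 2L],
               rowSums(fc))
  shift <- cbind(cum, config$attenuation * cum[, 4L])[, seq_along(trts),
                                                     drop = FALSE]
  colnames(shift) <- trts

  n_samp <- length(trts) * reps
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  libf <- stats::rlnorm(n_samp, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  samples <- data.frame(
    sample_id = paste0(rep(trts, each = reps), "_", seq_len(reps)),
    treatment = rep(trts, each = reps),
    replicate = rep(seq_len(reps), times = length(trts)),
    stringsAsFactors = FALSE)

  counts <- matrix(0L, nrow = G, ncol = n_samp,
                   dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(n_samp)) {
    mu <- libf[j] * baseline * 2^shift[, samples$treatment[j]]
    counts[, j] <- stats::rnbinom(G, mu = mu, size = 1 / phi)
  }
  storage.mode(counts) <- "integer"

  truth <- list(
    gene_pattern = stats::setNames(apply(codes, 1L, code_to_string), gene_ids),
    gene_log2fc = fc,
    enriched_terms = list())
  class(truth) <- "sim_truth"

  ann <- simulate_annotation(config, truth)
  truth$enriched_terms <- attr(ann, "enriched_terms")
  attr(ann, "enriched_terms") <- NULL

  list(counts = counts, samples = samples, lengths = lengths,
       annotation = ann, truth = truth)
}

#' Simulate a gene-to-term annotation with planted enrichment
#'
#' Emits `n_terms` terms with sizes uniform in `term_size_range`. A fraction
#' `enriched_term_fraction` of terms is planted as enriched: each such term
#' is assigned to one planted module (round robin) and draws 80% (>= 60%) of
#' its genes from that module's gene set, the rest from the background; all
#' other terms sample genes uniformly. The planted term -> module map is
#' attached as attribute `enriched_terms` (module code string -> term ids).
#'
#' @param config A [sim_config()].
#' @param truth A `sim_truth` with populated `gene_pattern`.
#' @return Named list term id -> gene ids, with the `enriched_terms`
#'   attribute.
#' @export
simulate_annotation <- function(config, truth) {
  gene_ids <- names(truth$gene_pattern)
  if (length(gene_ids) == 0L) stop("truth has no genes")
  module_codes <- unique(truth$gene_pattern[truth$gene_pattern !=
                                              code_to_string(c(0L, 0L, 0L))])
  n_enriched <- if (length(module_codes) > 0L)
    round(config$enriched_term_fraction * config$n_terms) else 0L
  sizes <- sample(seq(config$term_size_range[1L], config$term_size_range[2L]),
                  config$n_terms, replace = TRUE)
  term_ids <- sprintf("T%04d", seq_len(config$n_terms))
  ann <- vector("list", config$n_terms)
  names(ann) <- term_ids
  enriched <- stats::setNames(vector("list", length(module_codes)),
                              module_codes)
  for (i in seq_len(config$n_terms)) {
    if (i <= n_enriched) {
      code <- module_codes[1L + (i - 1L) %% length(module_codes)]
      pool <- gene_ids[truth$gene_pattern == code]
      n_in <- min(length(pool), ceiling(0.8 * sizes[i]))
      memb <- c(sample(pool, n_in),
                sample(setdiff(gene_ids, pool), sizes[i] - n_in))
      enriched[[code]] <- c(enriched[[code]], term_ids[i])
    } else {
      memb <- sample(gene_ids, sizes[i])
    }
    ann[[i]] <- sort(memb)
  }
  attr(ann, "enriched_terms") <- enriched
  ann
}

#' Write a simulated experiment to a directory
#'
#' Emits counts, sample table, gene lengths and annotation as TSV, and the
#' ground truth as JSON.
#'
#' @param sim Result of [simulate_experiment()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(outdir, "counts.tsv"))
  write_samples(sim$samples, file.path(outdir, "samples.tsv"))
  write_lengths(sim$lengths, file.path(outdir, "gene_lengths.tsv"))
  write_annotation(sim$annotation, file.path(outdir, "annotation.tsv"))
  truth <- sim$truth
  jsonlite::write_json(
    list(gene_pattern = as.list(truth$gene_pattern),
         gene_log2fc = as.data.frame(truth$gene_log2fc),
         enriched_terms = truth$enriched_terms),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
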