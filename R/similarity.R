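#' Signed DEG vector of a term under one contrast
#'
#' For each gene of the term (in the tested universe, fixed order), the entry
#' is the trichotomous DEG call of that gene in the contrast (+1 induced,
#' -1 suppressed, 0 non-significant); genes absent from the contrast get 0.
#'
#' @param term_genes Character vector of the term's genes.
#' @param contrast A contrast result (each treatment vs the common undamaged
#'   control) from [nb_wald_test()].
#' @return Named integer vector over `term_genes`.
#' @export
deg_vector <- function(term_genes, contrast) {
  if (length(term_genes) == 0L) stop("term has no genes in the universe")
  calls <- contrast$call[match(term_genes, contrast$gene_id)]
  calls[is.na(calls)] <- 0L
  stats::setNames(as.integer(calls), term_genes)
}

#' Cosine similarity between two signed DEG vectors
#'
#' s = sum(x_g y_g) / (||x|| ||y||). When either vector has zero norm (no
#' DEG at all in that treatment) the similarity is undefined and `NA` is
#' returned rather than 0: "no response" is a different state from
#' "orthogonal response".
#'
#' @param x,y Equal-length trichotomous vectors with matching gene order.
#' @return A number in \[-1, 1\], or `NA_real_` when undefined.
#' @export
cosine_similarity <- function(x, y) {
  if (length(x) != length(y)) stop("vector length mismatch")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

#' Per-term inductive similarity between two treatments
#'
#' Builds the signed DEG vector of every term under each contrast and
#' returns the cosine similarity plus DEG counts per treatment.
#'
#' @param ann Annotation list (term id -> gene ids).
#' @param cA,cB Contrast results of the two treatments, each vs the common
#'   control.
#' @param terms Term ids to evaluate (default: all of `ann`).
#' @return A data.frame (`term_id`, `n_genes`, `nA_deg`, `nB_deg`,
#'   `similarity`), `similarity` `NA` where undefined.
#' @export
go_similarity <- function(ann, cA, cB, terms = names(ann)) {
  do.call(rbind, lapply(terms, function(tid) {
    genes <- ann[[tid]]
    x <- deg_vector(genes, cA)
    y <- deg_vector(genes, cB)
    data.frame(term_id = tid, n_genes = length(genes),
               nA_deg = sum(x != 0L), nB_deg = sum(y != 0L),
               similarity = cosine_similarity(x, y),
               stringsAsFactors = FALSE)
  }))
}

#' Global fold-change regression between two treatments
#'
#' Ordinary least squares of treatment A's per-gene log2 fold change on
#' treatment B's, over their shared tested genes; if the two treatments
#' provoke identical responses all genes fall on y = x.
#'
#' @param cA,cB Contrast results (each treatment vs the common control).
#' @return A list with `slope`, `intercept`, `r_squared`, `p` (two-sided
#'   slope test) and `n_genes`.
#' @export
global_fc_regression <- function(cA, cB) {
  shared <- intersect(cA$gene_id, cB$gene_id)
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  y <- cA$log2fc[match(shared, cA$gene_id)]
  x <- cB$log2fc[match(shared, cB$gene_id)]
  if (stats::var(x) == 0) stop("degenerate regressor: all log2fc equal")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2L, 4L],
       n_genes = length(shared))
}
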