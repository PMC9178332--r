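#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: per sample, the median ratio of its counts to
#' the gene-wise geometric mean, over genes expressed in every sample.
#'
#' @param m Count matrix.
#' @return Named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(m) {
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no gene is expressed in every sample")
  sf <- apply(m[use, , drop = FALSE], 2L, function(cnt) {
    exp(stats::median(log(cnt) - log_gm[use]))
  })
  sf
}

#' Filter genes by minimum mean read count
#'
#' Keeps genes whose mean raw count across the supplied samples is at least
#' `min_mean` (default 10). Applied per contrast: pass the columns of the two
#' compared treatments.
#'
#' @param m Count matrix (already subset to the samples of interest).
#' @param min_mean Minimum mean count.
#' @return Filtered count matrix, gene order preserved.
#' @export
filter_min_count <- function(m, min_mean = 10) {
  stopifnot(min_mean >= 0)
  m[rowMeans(m) >= min_mean, , drop = FALSE]
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Method-of-moments on size-factor-normalised counts: for each gene the
#' within-group pooled variance s2 and grand mean xbar give the raw estimate
#' phi_hat = max(0, (s2 - xbar) / xbar^2), which is then shrunk toward a
#' fitted mean-dispersion trend phi(mu) = a0 + a1/mu with weight
#' `shrink_weight` (0 = raw, 1 = trend only). Dispersions are floored at
#' 1e-8.
#'
#' @param m Count matrix.
#' @param groups Factor/character of group membership, one entry per column
#'   of `m`; every group needs >= 2 replicates.
#' @param sf Optional size factors (computed from `m` if missing).
#' @param shrink_weight Weight of the fitted trend (default 0.5).
#' @return Numeric vector of dispersions, one per gene; the fitted trend
#'   coefficients are attached as attribute `trend`.
#' @export
estimate_dispersions <- function(m, groups, sf = NULL, shrink_weight = 0.5) {
  groups <- as.character(groups)
  if (length(groups) != ncol(m)) stop("groups must match matrix columns")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 replicates")
  if (is.null(sf)) sf <- size_factors(m)
  q <- sweep(m, 2L, sf, "/")

  grp <- split(seq_len(ncol(m)), groups)
  ssq <- 0
  df <- 0
  means <- matrix(0, nrow = nrow(m), ncol = length(grp))
  for (i in seq_along(grp)) {
    cols <- grp[[i]]
    gm <- rowMeans(q[, cols, drop = FALSE])
    means[, i] <- gm
    ssq <- ssq + rowSums((q[, cols, drop = FALSE] - gm)^2)
    df <- df + length(cols) - 1L
  }
  s2 <- ssq / df
  xbar <- rowMeans(means)
  raw <- pmax(0, (s2 - xbar) / xbar^2)
  raw[!is.finite(raw)] <- 0

  # trend phi(mu) = a0 + a1/mu, fitted on genes with informative raw estimates
  use <- raw > 0 & xbar > 0
  if (sum(use) >= 10L) {
    fit <- stats::lm(raw[use] ~ I(1 / xbar[use]))
    a0 <- max(unname(stats::coef(fit)[1L]), 1e-4)
    a1 <- max(unname(stats::coef(fit)[2L]), 0)
  } else {
    a0 <- max(stats::median(raw), 1e-4)
    a1 <- 0
  }
  trend <- a0 + a1 / pmax(xbar, 1e-8)
  phi <- pmax((1 - shrink_weight) * raw + shrink_weight * trend, 1e-8)
  attr(phi, "trend") <- c(a0 = a0, a1 = a1)
  names(phi) <- rownames(m)
  phi
}

# Vectorised IRLS fit of the two-group NB log-link model with offsets.
# Returns per-gene coefficient (log fold change, natural log), its standard
# error, and a convergence flag.
nb_irls_two_group <- function(y, x, offset, phi, max_iter = 50L,
                              tol = 1e-8) {
  G <- nrow(y)
  S <- ncol(y)
  off <- matrix(offset, nrow = G, ncol = S, byrow = TRUE)
  xm <- matrix(x, nrow = G, ncol = S, byrow = TRUE)
  q <- y / exp(off)
  m0 <- rowSums(q * (1 - xm)) / sum(1 - x)
  m1 <- rowSums(q * xm) / sum(x)
  b0 <- log(pmax(m0, 1e-8))
  b1 <- log(pmax(m1, 1e-8)) - b0
  conv <- rep(FALSE, G)
  se <- rep(NA_real_, G)
  for (it in seq_len(max_iter)) {
    eta <- off + b0 + b1 * xm
    eta <- pmin(pmax(eta, -50), 50)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - off) + (y - mu) / mu
    sw <- rowSums(w)
    swx <- rowSums(w * xm)
    swz <- rowSums(w * z)
    swxz <- rowSums(w * xm * z)
    det <- sw * swx - swx^2  # x binary: sum w x^2 = sum w x
    det <- pmax(det, 1e-12)
    nb1 <- (sw * swxz - swx * swz) / det
    nb0 <- (swz - swx * nb1) / sw
    delta <- pmax(abs(nb0 - b0), abs(nb1 - b1))
    # keep coefficients finite when a group is all zeros (MLE diverges)
    b0 <- pmin(pmax(nb0, -30), 30)
    b1 <- pmin(pmax(nb1, -30), 30)
    conv <- conv | (delta < tol)
    if (all(delta < tol)) break
  }
  # final weights for the Wald standard error
  eta <- pmin(pmax(off + b0 + b1 * xm, -50), 50)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  sw <- rowSums(w)
  swx <- rowSums(w * xm)
  det <- pmax(sw * swx - swx^2, 1e-12)
  se <- sqrt(sw / det)
  list(beta = b1, se = se, converged = conv & is.finite(b1) & is.finite(se))
}

#' Negative-binomial Wald test for one treatment contrast
#'
#' Self-contained two-group differential-expression test: median-of-ratios
#' size factors as offsets, trended moment dispersions
#' ([estimate_dispersions()]), per-gene NB log-link IRLS fit, and a Wald
#' statistic on the group coefficient with a two-sided normal p-value.
#' Genes whose mean raw count over the two groups is below `min_mean` are
#' removed before testing; p-values are BH-adjusted over the tested genes and
#' each gene receives a trichotomous call: +1 if log2fc > `lfc` and
#' padj < `alpha`, -1 if log2fc < -`lfc` and padj < `alpha`, else 0.
#'
#' @param m Count matrix covering at least the two treatments.
#' @param samples Sample table (`sample_id`, `treatment`, `replicate`).
#' @param reference,test Treatment labels; log2fc is test relative to
#'   reference.
#' @param min_mean Mean-count filter (default 10).
#' @param lfc Absolute log2 fold-change threshold for a DEG call
#'   (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param shrink_weight Dispersion trend shrinkage weight.
#' @return A data.frame (`gene_id`, `base_mean`, `log2fc`, `p`, `padj`,
#'   `call`, `converged`) with the contrast stored in attribute `contrast`.
#' @export
nb_wald_test <- function(m, samples, reference, test, min_mean = 10,
                         lfc = 1.5, alpha = 0.05, shrink_weight = 0.5) {
  for (lab in c(reference, test)) {
    if (sum(samples$treatment == lab) < 2L)
      stop("treatment '", lab, "' needs >= 2 replicates")
  }
  keep <- samples$treatment %in% c(reference, test)
  sub_samples <- samples[keep, , drop = FALSE]
  sub <- m[, sub_samples$sample_id, drop = FALSE]
  sub <- filter_min_count(sub, min_mean)
  if (nrow(sub) == 0L) stop("no gene passes the mean-count filter")

  x <- as.numeric(sub_samples$treatment == test)
  sf <- size_factors(sub)
  phi <- estimate_dispersions(sub, sub_samples$treatment, sf = sf,
                              shrink_weight = shrink_weight)
  fit <- nb_irls_two_group(sub, x, log(sf), phi)

  log2fc <- fit$beta / log(2)
  zstat <- fit$beta / fit$se
  p <- 2 * stats::pnorm(-abs(zstat))
  bad <- !fit$converged | !is.finite(p)
  p[bad] <- 1
  log2fc[bad & !is.finite(log2fc)] <- 0
  padj <- benjamini_hochberg(p)
  call <- integer(nrow(sub))
  call[log2fc > lfc & padj < alpha] <- 1L
  call[log2fc < -lfc & padj < alpha] <- -1L
  call[bad] <- 0L

  res <- data.frame(gene_id = rownames(sub),
                    base_mean = rowMeans(sweep(sub, 2L, sf, "/")),
                    log2fc = log2fc, p = p, padj = padj, call = call,
                    converged = fit$converged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "contrast") <- c(reference = reference, test = test)
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' padj of the i-th smallest p is min over j >= i of min(1, m * p_(j) / j);
#' the original order is restored.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  padj_sorted <- pmin(1, m * p[o] / seq_len(m))
  padj_sorted <- rev(cummin(rev(padj_sorted)))
  out <- numeric(m)
  out[o] <- padj_sorted
  out
}

#' PCA of a scaled and centred expression matrix
#'
#' Drops constant-variance genes, centres and unit-variance scales each gene,
#' and projects samples onto principal components of the sample covariance.
#'
#' @param e Expression matrix (genes x samples), e.g. filtered TPM.
#' @return A list with `scores` (samples x components), `variance_fraction`
#'   (per-component explained-variance fractions), and `n_genes_used`.
#' @export
pca_projection <- function(e) {
  if (ncol(e) < 2L) stop("PCA needs >= 2 samples")
  v <- apply(e, 1L, stats::var)
  keep <- is.finite(v) & v > 0
  if (sum(keep) < 2L) stop("fewer than 2 non-constant genes")
  pr <- stats::prcomp(t(e[keep, , drop = FALSE]), center = TRUE,
                      scale. = TRUE)
  frac <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x, variance_fraction = frac, n_genes_used = sum(keep))
}

#' Flag replicate outliers by average-linkage clustering distances
#'
#' Computes Euclidean distances between samples over all genes and an
#' average-linkage dendrogram (returned for inspection). Within each
#' treatment, a replicate is flagged when its mean distance to the other
#' same-treatment replicates exceeds `c_mult` times the median of those mean
#' distances across the treatment's replicates. Treatments with fewer than 3
#' replicates are skipped with a warning.
#'
#' @param e Expression matrix (genes x samples).
#' @param samples Sample table.
#' @param c_mult Flagging multiplier (default 2).
#' @return A list with `flagged` (character vector of sample ids) and `hclust`
#'   (the average-linkage tree over all samples).
#' @export
detect_outliers <- function(e, samples, c_mult = 2) {
  if (ncol(e) < 3L) stop("need >= 3 samples")
  d <- as.matrix(stats::dist(t(e)))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  flagged <- character(0)
  for (trt in unique(samples$treatment)) {
    ids <- samples$sample_id[samples$treatment == trt]
    if (length(ids) < 3L) {
      warning("treatment '", trt, "' has < 3 replicates; outlier check skipped")
      next
    }
    sub <- d[ids, ids, drop = FALSE]
    mean_d <- rowSums(sub) / (length(ids) - 1L)
    med <- stats::median(mean_d)
    flagged <- c(flagged, ids[mean_d > c_mult * med])
  }
  list(flagged = flagged, hclust = hc)
}

#' Relative distance plasticity index between two treatment groups
#'
#' For every (control sample i, treatment sample j) pair, RDPI_ij is the mean
#' over genes g with x_gi + x_gj > 0 of |x_gj - x_gi| / (x_gj + x_gi); genes
#' with both values zero are skipped. One value per pair, each in \[0, 1\];
#' the set of pairwise values represents the inducibility of the treatment.
#'
#' @param e Non-negative expression matrix (e.g. filtered TPM).
#' @param samples Sample table.
#' @param control,treatment Treatment labels.
#' @return A data.frame (`control_sample`, `treatment_sample`, `rdpi`) with
#'   the treatment label in attribute `treatment`.
#' @export
rdpi <- function(e, samples, control, treatment) {
  ci <- samples$sample_id[samples$treatment == control]
  ti <- samples$sample_id[samples$treatment == treatment]
  if (length(ci) == 0L || length(ti) == 0L)
    stop("both groups must be non-empty")
  if (any(e < 0)) stop("expression values must be non-negative")
  out <- expand.grid(control_sample = ci, treatment_sample = ti,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rdpi <- mapply(function(i, j) {
    xi <- e[, i]
    xj <- e[, j]
    s <- xi + xj
    use <- s > 0
    if (!any(use)) stop("no expressed gene for pair ", i, " / ", j)
    mean(abs(xj[use] - xi[use]) / s[use])
  }, out$control_sample, out$treatment_sample)
  attr(out, "treatment") <- treatment
  out
}
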