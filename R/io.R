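#' Read a gene x sample count matrix from TSV
#'
#' Expects a single header row of sample identifiers and gene identifiers in
#' the first column. All cells must be non-negative integers.
#'
#' @param path Path to a tab-separated file.
#' @return An integer matrix (genes in rows, samples in columns) with gene
#'   and sample identifiers as dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count file needs a gene-id column plus >= 1 sample")
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix to TSV
#'
#' @param m Count matrix as returned by [read_counts()].
#' @param path Output path.
#' @export
write_counts <- function(m, path) {
  validate_counts(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a count matrix
#'
#' Checks integrality, non-negativity and identifier uniqueness; errors name
#' the offending gene/sample.
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @return The matrix, invisibly.
#' @export
validate_counts <- function(m) {
  if (!is.matrix(m)) stop("counts must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("counts must carry gene and sample identifiers as dimnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene id: ", rownames(m)[duplicated(rownames(m))][1L])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1L])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid count at gene '", rownames(m)[bad[1L, 1L]],
         "', sample '", colnames(m)[bad[1L, 2L]],
         "': ", m[bad[1L, , drop = FALSE]])
  }
  invisible(m)
}

#' Read / write the sample metadata table
#'
#' Columns: `sample_id`, `treatment`, `replicate` (tab-separated, one header
#' row).
#'
#' @param path File path.
#' @return A data.frame with character `sample_id`/`treatment` and integer
#'   `replicate`.
#' @export
read_samples <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "treatment", "replicate")
  if (!all(need %in% names(df)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$treatment <- as.character(df$treatment)
  df$replicate <- as.integer(df$replicate)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample table")
  df
}

#' @rdname read_samples
#' @param samples Sample table data.frame.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write gene lengths
#'
#' Two-column table `gene_id`, `length` (bases, positive integers).
#'
#' @param path File path.
#' @return Named numeric vector of lengths.
#' @export
read_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("gene length table needs two columns")
  len <- as.numeric(df[[2L]])
  names(len) <- as.character(df[[1L]])
  if (any(!is.finite(len) | len <= 0))
    stop("non-positive gene length for: ",
         names(len)[which(!is.finite(len) | len <= 0)][1L])
  len
}

#' @rdname read_lengths
#' @param lengths Named vector of gene lengths.
#' @export
write_lengths <- function(lengths, path) {
  utils::write.table(
    data.frame(gene_id = names(lengths), length = as.integer(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene-to-term annotation
#'
#' Two-column table `gene_id`, `term_id`; a gene may belong to many terms.
#' In memory the annotation is a named list: term id -> character vector of
#' gene ids.
#'
#' @param path File path.
#' @return Named list mapping term ids to gene-id vectors.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("annotation table needs two columns")
  ann <- split(as.character(df[[1L]]), as.character(df[[2L]]))
  lapply(ann, unique)
}

#' @rdname read_annotation
#' @param ann Annotation list (term id -> gene ids).
#' @export
write_annotation <- function(ann, path) {
  df <- data.frame(
    gene_id = unlist(ann, use.names = FALSE),
    term_id = rep(names(ann), lengths(ann)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to transcripts per million (TPM)
#'
#' TPM_gs = 1e6 * (c_gs / L_g) / sum_h (c_hs / L_h): counts are first divided
#' by gene length (length-normalised rates), then each sample column is
#' rescaled to sum to one million.
#'
#' @param m Count matrix (genes x samples).
#' @param lengths Named vector of gene lengths covering every gene in `m`.
#' @return Numeric matrix of TPM values, same dimnames as `m`; every column
#'   sums to 1e6.
#' @export
compute_tpm <- function(m, lengths) {
  missing <- setdiff(rownames(m), names(lengths))
  if (length(missing) > 0L)
    stop("no length for gene(s): ", paste(utils::head(missing, 3), collapse = ", "))
  L <- lengths[rownames(m)]
  rate <- m / L
  denom <- colSums(rate)
  if (any(denom == 0))
    stop("sample with all-zero counts: ", colnames(m)[which(denom == 0)][1L])
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Filter genes of low expression
#'
#' Removes genes whose mean TPM across all samples falls below `threshold`
#' (the per-sample alternative requires the gene to reach the threshold in at
#' least one sample). Gene order is preserved.
#'
#' @param e TPM expression matrix.
#' @param threshold Minimum TPM (default 1).
#' @param per_sample If `TRUE`, keep genes with max TPM >= threshold instead
#'   of mean TPM >= threshold.
#' @return The filtered expression matrix.
#' @export
filter_low_tpm <- function(e, threshold = 1, per_sample = FALSE) {
  stopifnot(threshold >= 0)
  stat <- if (per_sample) apply(e, 1L, max) else rowMeans(e)
  e[stat >= threshold, , drop = FALSE]
}
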