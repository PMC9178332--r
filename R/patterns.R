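#' Convert a trichotomous pattern code to / from its string form
#'
#' Codes are ordered triples over \{-1, 0, +1\}, one digit per cumulative
#' contrast; the string form joins the digits with "/" (e.g. "1/0/-1").
#'
#' @param code Integer vector of length 3 over \{-1, 0, 1\}.
#' @return `code_to_string`: a character scalar. `string_to_code`: an
#'   integer 3-vector.
#' @export
code_to_string <- function(code) paste(as.integer(code), collapse = "/")

#' @rdname code_to_string
#' @param s Code string such as "0/1/-1".
#' @export
string_to_code <- function(s) as.integer(strsplit(s, "/", fixed = TRUE)[[1L]])

#' The 27-row pattern index table
#'
#' Enumerates all 3^3 trichotomous codes. Index 1 is the null code (0,0,0);
#' the remaining codes are ranked base-3 with digit order (d1, d2, d3) and
#' digit values mapped 0 -> 0, +1 -> 1, -1 -> 2, so the table is a fixed,
#' reproducible labelling of pattern space.
#'
#' @return A data.frame with `pattern_index`, `code`, `d1`, `d2`, `d3`.
#' @export
pattern_index_table <- function() {
  digit_rank <- function(d) ifelse(d == 0L, 0L, ifelse(d == 1L, 1L, 2L))
  grid <- expand.grid(d3 = c(-1L, 0L, 1L), d2 = c(-1L, 0L, 1L),
                      d1 = c(-1L, 0L, 1L))[, 3:1]
  rank <- 9L * digit_rank(grid$d1) + 3L * digit_rank(grid$d2) +
    digit_rank(grid$d3)
  grid <- grid[order(rank), , drop = FALSE]
  data.frame(pattern_index = seq_len(27L),
             code = apply(grid, 1L, code_to_string),
             d1 = grid$d1, d2 = grid$d2, d3 = grid$d3,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes into 27 expression patterns from three cumulative contrasts
#'
#' Each gene tested in all three contrasts receives the code
#' (call1, call2, call3). Genes missing from any contrast (e.g. removed by
#' the mean-count filter there) are excluded from the pattern universe and
#' reported in the `untested` attribute: a trichotomous code requires all
#' three tests.
#'
#' @param r1,r2,r3 Contrast results from [nb_wald_test()] in cumulative
#'   order (control vs wounding; wounding vs wounding+sterile-secretion;
#'   that vs wounding+full-secretion).
#' @return A data.frame (`gene_id`, `d1`, `d2`, `d3`, `code`,
#'   `pattern_index`) with attributes `untested` (gene ids) and
#'   `index_table`.
#' @export
classify_patterns <- function(r1, r2, r3) {
  universe <- Reduce(intersect, list(r1$gene_id, r2$gene_id, r3$gene_id))
  if (length(universe) == 0L)
    stop("empty intersection of tested gene universes")
  all_genes <- unique(c(r1$gene_id, r2$gene_id, r3$gene_id))
  calls <- cbind(
    d1 = r1$call[match(universe, r1$gene_id)],
    d2 = r2$call[match(universe, r2$gene_id)],
    d3 = r3$call[match(universe, r3$gene_id)])
  code <- apply(calls, 1L, code_to_string)
  tab <- pattern_index_table()
  pa <- data.frame(gene_id = universe, calls, code = code,
                   pattern_index = tab$pattern_index[match(code, tab$code)],
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(pa, "untested") <- setdiff(all_genes, universe)
  attr(pa, "index_table") <- tab
  pa
}

#' Extract gene modules from a pattern assignment
#'
#' One module per non-null code whose gene count reaches `min_size`
#' (inclusive); the null code (0,0,0) is never a module. Modules are ordered
#' by size descending (ties broken by code string) and labelled M1, M2, ...
#'
#' @param pa Pattern assignment from [classify_patterns()].
#' @param min_size Minimal module size (default 300).
#' @return A list of modules, each a list with `module_id`, `code`, `genes`,
#'   `size`.
#' @export
extract_modules <- function(pa, min_size = 300) {
  stopifnot(min_size >= 1)
  null_code <- code_to_string(c(0L, 0L, 0L))
  counts <- table(pa$code[pa$code != null_code])
  keep <- names(counts)[counts >= min_size]
  keep <- keep[order(-counts[keep], keep)]
  mods <- lapply(seq_along(keep), function(i) {
    genes <- sort(pa$gene_id[pa$code == keep[i]])
    list(module_id = paste0("M", i), code = keep[i], genes = genes,
         size = length(genes))
  })
  mods
}

#' Summarise a pattern assignment and its modules
#'
#' Reports total genes, the null-pattern (pattern 1) count and percentage,
#' the responsive count (total minus pattern 1), per-module sizes, and the
#' module coverage percentage = sum(module sizes) / responsive * 100.
#' Percentages are rounded to 2 decimals. With zero responsive genes the
#' coverage is `NA` (undefined).
#'
#' @param pa Pattern assignment, or `NULL` when using `counts` directly.
#' @param modules Module list from [extract_modules()], or `NULL`.
#' @param counts Optional list bypassing `pa`/`modules` with elements
#'   `total`, `pattern1`, `module_sizes` (and optionally `responsive`,
#'   defaulting to `total - pattern1`) — useful to summarise published
#'   tallies.
#' @return A list with `total`, `pattern1`, `pattern1_pct`, `responsive`,
#'   `module_sizes`, `coverage_pct`.
#' @export
pattern_summary <- function(pa = NULL, modules = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (is.null(pa) || nrow(pa) == 0L) stop("empty pattern assignment")
    null_code <- code_to_string(c(0L, 0L, 0L))
    total <- nrow(pa)
    pattern1 <- sum(pa$code == null_code)
    sizes <- vapply(modules, function(m) m$size, numeric(1))
    if (length(sizes) > 0L)
      names(sizes) <- vapply(modules, function(m) m$module_id, character(1))
    responsive <- total - pattern1
  } else {
    total <- counts$total
    pattern1 <- counts$pattern1
    sizes <- counts$module_sizes
    responsive <- if (!is.null(counts$responsive)) counts$responsive
                  else total - pattern1
  }
  list(total = total,
       pattern1 = pattern1,
       pattern1_pct = round(100 * pattern1 / total, 2),
       responsive = responsive,
       module_sizes = sizes,
       coverage_pct = if (responsive > 0)
         round(100 * sum(sizes) / responsive, 2) else NA_real_)
}
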