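#' Taxa-by-sample count table with a two-condition design
#'
#' Bundles a non-negative integer count matrix (rows = taxa, columns =
#' samples) with a binary condition label per sample. This is the input
#' container consumed by [draw_compositions()], [run_da()] and the
#' benchmarking harness.
#'
#' @param counts Non-negative integer matrix, taxa in rows and samples in
#'   columns. Row and column names are used as taxon and sample identifiers;
#'   defaults are generated when absent.
#' @param condition Binary (0/1) vector, one entry per sample. Condition 1 is
#'   the "treatment" group in all fold-change contrasts.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix), `condition` (integer vector named by sample), `taxa`
#'   and `samples` (character vectors).
#' @examples
#' m <- matrix(c(10L, 5L, 0L, 7L), 2, 2,
#'             dimnames = list(c("taxA", "taxB"), c("s1", "s2")))
#' ct <- count_table(m, condition = c(0, 1))
#' @export
count_table <- function(counts, condition) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("`counts` must have at least one taxon and one sample", call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts))
    stop("`counts` must be numeric with no missing values", call. = FALSE)
  if (any(counts < 0))
    stop("`counts` contains negative values", call. = FALSE)
  if (any(counts != round(counts)))
    stop("`counts` contains non-integer values", call. = FALSE)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("taxon_%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  condition <- .assert_condition(condition, ncol(counts))
  names(condition) <- colnames(counts)
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts, condition = condition,
         taxa = rownames(counts), samples = colnames(counts)),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples (", sum(x$condition == 0), " vs ", sum(x$condition == 1),
      ")\n", sep = "")
  invisible(x)
}

# Accept either a count_table or a bare matrix (+ explicit condition).
.as_count_matrix <- function(counts) {
  if (inherits(counts, "count_table")) counts$counts
  else if (is.matrix(counts)) counts
  else stop("`counts` must be a count_table or a matrix", call. = FALSE)
}

.resolve_condition <- function(counts, condition) {
  if (is.null(condition)) {
    if (inherits(counts, "count_table")) counts$condition
    else stop("`condition` is required when `counts` is a bare matrix",
              call. = FALSE)
  } else .assert_condition(condition, ncol(.as_count_matrix(counts)))
}
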