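# Readers/writers for the plain-text formats: TSV/CSV count matrices,
# metadata, load tables, result tables, and run manifests.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_delim <- function(path, what) {
  if (!file.exists(path))
    stop("cannot open ", what, " file: ", path, call. = FALSE)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = .delim_for(path),
               comment.char = "#", check.names = FALSE,
               stringsAsFactors = FALSE, quote = "\""),
    error = function(e) stop("malformed ", what, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) == 0L)
    stop("empty ", what, " file: ", path, call. = FALSE)
  df
}

#' Read a taxa-by-sample count matrix
#'
#' Expects TSV (or CSV, chosen by file extension) with taxon identifiers in
#' the first column and one column per sample. Lines starting with `#` are
#' ignored and CRLF line endings are accepted. Duplicate identifiers and
#' negative or non-integer cells are rejected with their coordinates.
#'
#' @param path Path to the file.
#' @return Integer matrix with taxon rownames and sample colnames. Combine
#'   with a metadata file via [count_table()] for the engine.
#' @export
read_count_table <- function(path) {
  df <- .read_delim(path, "count table")
  if (ncol(df) < 2L)
    stop("count table needs a taxon column plus at least one sample: ",
         path, call. = FALSE)
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa))
    stop("duplicate taxon identifiers in ", path, ": ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "),
         call. = FALSE)
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric cells in count table ", path, call. = FALSE)
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid count (negative, missing or non-integer) at taxon '",
         taxa[bad[1, 1]], "', sample '", samples[bad[1, 2]], "' in ",
         path, call. = FALSE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(taxa, samples)
  m
}

#' Write a count table to TSV/CSV
#'
#' @param counts A [count_table()] or integer matrix.
#' @param path Output path; `.csv` extension selects comma separation.
#' @export
write_count_table <- function(counts, path) {
  m <- .as_count_matrix(counts)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = .delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample_id, condition)
#'
#' @param path TSV/CSV with columns `sample_id` and `condition` (0/1).
#' @return Integer 0/1 vector named by sample.
#' @export
read_metadata <- function(path) {
  df <- .read_delim(path, "metadata")
  if (!all(c("sample_id", "condition") %in% colnames(df)))
    stop("metadata must have columns sample_id and condition: ", path,
         call. = FALSE)
  cond <- .assert_condition(df$condition)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ", path, call. = FALSE)
  names(cond) <- as.character(df$sample_id)
  cond
}

#' Write sample metadata for a count table
#'
#' @param counts A [count_table()].
#' @param path Output path.
#' @export
write_metadata <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  write.table(data.frame(sample_id = counts$samples,
                         condition = counts$condition),
              path, sep = .delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read per-sample microbial loads
#'
#' Reads a table with a `sample_id` column and a value column, converting
#' from the declared input scale to the requested internal scale. The
#' engine works in log2 loads; prediction evaluation works in log10.
#'
#' @param path TSV/CSV file.
#' @param scale Scale of the stored values: `"linear"`, `"log10"` or
#'   `"log2"`. Non-positive linear values are rejected.
#' @param output Internal scale to convert to (`"log2"` or `"log10"`).
#' @param column Name of the value column; defaults to the second column.
#' @param samples Optional character vector; when given, every sample must
#'   be present (missing ones are reported) and the result is returned in
#'   this order.
#' @return Named numeric vector of loads on the `output` scale.
#' @export
read_loads <- function(path, scale = c("linear", "log10", "log2"),
                       output = c("log2", "log10"), column = NULL,
                       samples = NULL) {
  scale <- match.arg(scale)
  output <- match.arg(output)
  df <- .read_delim(path, "loads")
  if (!"sample_id" %in% colnames(df))
    stop("loads file must have a sample_id column: ", path, call. = FALSE)
  if (is.null(column)) column <- setdiff(colnames(df), "sample_id")[1]
  if (is.na(column) || !column %in% colnames(df))
    stop("value column '", column, "' not found in ", path, call. = FALSE)
  v <- df[[column]]
  if (!is.numeric(v) || anyNA(v))
    stop("non-numeric or missing load values in ", path, call. = FALSE)
  log2v <- switch(scale,
    linear = {
      if (any(v <= 0))
        stop("non-positive linear load for sample(s): ",
             paste(df$sample_id[v <= 0], collapse = ", "),
             " (log undefined)", call. = FALSE)
      log2(v)
    },
    log10 = v * log2(10),
    log2 = v)
  out <- if (output == "log2") log2v else log2v / log2(10)
  names(out) <- as.character(df$sample_id)
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(out))
    if (length(missing))
      stop("loads missing for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    out <- out[samples]
  }
  out
}

#' Write a differential-abundance result table
#'
#' @param res A `da_result`.
#' @param path Output TSV/CSV path.
#' @export
write_da_result <- function(res, path) {
  stopifnot(inherits(res, "da_result") || is.data.frame(res))
  df <- as.data.frame(res)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  write.table(df, path, sep = .delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a differential-abundance result table for scoring
#'
#' Accepts the package's own output or any external method's results given
#' as a table with columns `taxon`, `direction` (`+`/`-`/`0`) and `p_adj`;
#' significance is recomputed as `p_adj < alpha`.
#'
#' @param path TSV/CSV file.
#' @param alpha Significance level.
#' @return A `da_result`-style data.frame usable by
#'   [score_against_truth()].
#' @export
read_da_result <- function(path, alpha = 0.05) {
  df <- .read_delim(path, "results")
  need <- c("taxon", "direction", "p_adj")
  if (!all(need %in% colnames(df)))
    stop("results file must have columns taxon, direction, p_adj: ", path,
         call. = FALSE)
  if (!all(df$direction %in% c("+", "-", "0")))
    stop("direction must be one of +/-/0 in ", path, call. = FALSE)
  df$p_adj <- as.numeric(df$p_adj)
  if (anyNA(df$p_adj) || any(df$p_adj < 0 | df$p_adj > 1))
    stop("p_adj must lie in [0, 1] in ", path, call. = FALSE)
  df$significant <- df$p_adj < alpha
  class(df) <- c("da_result", "data.frame")
  df
}

#' Write a reproducibility manifest
#'
#' Records the package version, the resolved parameters of a run and md5
#' checksums of its input files, sufficient to re-run the command exactly.
#'
#' @param path Output JSON path.
#' @param command Name of the command or function being recorded.
#' @param params Named list of resolved parameters (seeds included).
#' @param inputs Character vector of input file paths to checksum.
#' @export
write_manifest <- function(path, command, params = list(),
                           inputs = character()) {
  checksums <- if (length(inputs))
    as.list(tools::md5sum(inputs)) else list()
  manifest <- list(package = "ssrv",
                   version = as.character(packageVersion("ssrv")),
                   command = command,
                   parameters = params,
                   input_md5 = checksums)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
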