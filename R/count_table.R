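#' Construct a miRNA count table
#'
#' Container for a feature-by-sample matrix of miRNA-seq read counts, the
#' starting point of the haemolysis assessment pipeline. Rows are mature
#' miRNAs, columns are samples.
#'
#' @param counts Numeric matrix with unique rownames (miRNA names) and unique
#'   colnames (sample ids). Raw tables must be non-negative counts;
#'   pre-normalised tables are interpreted as log2-scale expression values
#'   and bypass library-size normalisation downstream.
#' @param is_prenormalised Logical; `TRUE` declares the values already
#'   normalised on the log2 scale (see Details).
#'
#' @details When `is_prenormalised = TRUE` the values are taken to be
#'   log2-scale expression (e.g. log2-CPM produced elsewhere) and the QC,
#'   filtering and TMM stages are skipped by [assess_haemolysis()]. Raw
#'   tables with non-integer values are accepted with a warning, since some
#'   quantifiers emit fractional counts.
#'
#' @return An object of class `count_table`: a list with elements `counts`
#'   (the matrix) and `is_prenormalised`.
#' @seealso [read_counts()], [assess_haemolysis()]
#' @export
count_table <- function(counts, is_prenormalised = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table needs at least 1 feature and 1 sample", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table requires feature rownames and sample colnames", call. = FALSE)
  if (anyNA(counts))
    stop("count table contains missing values", call. = FALSE)
  if (any(counts < 0))
    stop("negative values in count table", call. = FALSE)
  dup <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup))
    stop("duplicate feature names: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  dup <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup))
    stop("duplicate sample ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  if (!isTRUE(is_prenormalised) && any(counts != round(counts)))
    warning("raw count table contains non-integer values; treating them as counts",
            call. = FALSE)
  structure(list(counts = counts, is_prenormalised = isTRUE(is_prenormalised)),
            class = "count_table")
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d miRNAs x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (x$is_prenormalised) " (pre-normalised, log2 scale)" else ""))
  cat("samples:", paste(utils::head(colnames(x$counts), 6), collapse = ", "),
      if (ncol(x$counts) > 6) "..." else "", "\n")
  invisible(x)
}

#' Feature and sample names of a count table
#' @param x A `count_table`.
#' @return Character vector of miRNA names or sample ids.
#' @export
features <- function(x) rownames(x$counts)

#' @rdname features
#' @export
samples <- function(x) colnames(x$counts)

subset_ct <- function(x, rows = NULL, cols = NULL) {
  m <- x$counts
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  count_table_unchecked(m, x$is_prenormalised)
}

# internal fast path: invariants already hold on a subset
count_table_unchecked <- function(m, pre) {
  structure(list(counts = m, is_prenormalised = pre), class = "count_table")
}

sniff_delimiter <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a miRNA count table from delimited text
#'
#' Reads a TSV or CSV table whose first column holds mature miRNA names and
#' whose header row holds sample ids.
#'
#' @param path Path to the file.
#' @param delimiter `"auto"` (default; sniffs the first line for a tab,
#'   otherwise comma), `"\t"` or `","`.
#' @param prenormalised Logical; declare the table pre-normalised (log2
#'   scale). Default `FALSE` (raw counts).
#' @param transpose Logical; set `TRUE` when the file is oriented
#'   samples-by-miRNAs. Default is the conventional miRNAs-by-samples.
#' @return A [count_table()].
#' @export
read_counts <- function(path, delimiter = "auto", prenormalised = FALSE,
                        transpose = FALSE) {
  if (!file.exists(path))
    stop("counts file not found: ", path, call. = FALSE)
  sep <- if (identical(delimiter, "auto")) sniff_delimiter(path) else delimiter
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          quote = "\"", comment.char = "", row.names = NULL,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("counts file must have a name column plus at least one sample column",
         call. = FALSE)
  feat <- as.character(df[[1L]])
  dup <- unique(feat[duplicated(feat)])
  if (length(dup))
    stop("duplicate feature names in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  vals <- df[-1L]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
         paste(utils::head(names(vals)[bad], 5), collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- feat
  if (transpose) m <- t(m)
  count_table(m, is_prenormalised = prenormalised)
}

#' Validate mature miRNA names against the miRBase pattern
#'
#' Checks each name against the mature human miRBase convention,
#' `hsa-miR-106b-3p` / `hsa-let-7a` style: the `hsa-miR-` or `hsa-let-` stem
#' (case sensitive), a family number with optional letter suffix, an
#' optional numeric duplicate suffix, and an optional `-5p`/`-3p` arm.
#'
#' Names failing the pattern are not dropped by the pipeline: they stay in
#' the background set (they can never match the signature set), and
#' [assess_haemolysis()] logs a warning.
#'
#' @param names Non-empty character vector.
#' @return A list of class `mirna_name_report` with elements `valid`
#'   (character) and `invalid` (data.frame with columns `name`, `reason`).
#' @export
validate_mirna_names <- function(names) {
  if (length(names) == 0L)
    stop("no names supplied", call. = FALSE)
  pattern <- "^hsa-(miR|let)-[0-9]+[a-z]*(-[0-9]+[a-z]*)?(-[35]p)?$"
  ok <- grepl(pattern, names)
  reason <- character(sum(!ok))
  if (any(!ok)) {
    bad <- names[!ok]
    reason <- ifelse(grepl(pattern, tolower(sub("^HSA", "hsa", bad)), ignore.case = TRUE),
                     "case mismatch in miRBase stem",
                     "does not match mature miRBase pattern")
  }
  structure(list(valid = names[ok],
                 invalid = data.frame(name = names[!ok], reason = reason,
                                      stringsAsFactors = FALSE)),
            class = "mirna_name_report")
}

#' Write and re-read haemolysis assessment results
#'
#' Serialises an assessment table to CSV with columns `sample_id`,
#' `haemolysis_metric`, `threshold` and `result` (`Clear`/`Caution`).
#' Metrics are written with full double precision (well beyond 6 significant
#' digits) so that `read_results(write_results(x))` reproduces the values
#' exactly as serialised.
#'
#' @param assessments Data frame as returned by [assess_haemolysis()]; must
#'   contain the four columns above and at least one row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(assessments, path) {
  if (!is.data.frame(assessments) || nrow(assessments) == 0L)
    stop("no assessments to write", call. = FALSE)
  need <- c("sample_id", "haemolysis_metric", "threshold", "result")
  miss <- setdiff(need, names(assessments))
  if (length(miss))
    stop("assessments missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  # shortest decimal form that still round-trips the double bit-exactly
  fmt_exact <- function(x) {
    s <- sprintf("%.15g", x)
    bad <- as.numeric(s) != x
    s[bad] <- sprintf("%.17g", x[bad])
    s
  }
  out <- data.frame(
    sample_id = as.character(assessments$sample_id),
    haemolysis_metric = fmt_exact(assessments$haemolysis_metric),
    threshold = fmt_exact(assessments$threshold),
    result = as.character(assessments$result),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write results to ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  if (!file.exists(path))
    stop("results file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$haemolysis_metric <- as.numeric(df$haemolysis_metric)
  df$threshold <- as.numeric(df$threshold)
  df
}
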