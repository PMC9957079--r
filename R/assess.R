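with_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)),
    warning = function(w) {
      warning(sprintf("[%s] %s", stage, conditionMessage(w)), call. = FALSE)
      invokeRestart("muffleWarning")
    })
}

#' Assess samples for haemolysis
#'
#' Runs the full pipeline on a count table: depth QC, low-expression
#' filtering, TMM normalisation, log2-CPM, signature/background
#' partitioning, the per-sample haemolysis metric, and Clear/Caution
#' classification. Each stage's errors are tagged with the stage name.
#'
#' For a raw table the stages run in the order QC, expression filter, TMM,
#' log2-CPM. A table declared pre-normalised is interpreted directly as
#' log2-scale expression and skips QC, filtering and normalisation. A
#' single-sample table skips TMM (undefined without a second library) with
#' a factor of 1 and a warning.
#'
#' Because the metric takes geometric means of log2-CPM values, any
#' feature with a non-positive value in any retained sample is dropped from
#' both sets before partitioning (a uniform positivity guard; the count is
#' logged). Feature names failing the miRBase pattern are kept in the
#' background with a warning.
#'
#' @param counts A [count_table()].
#' @param signature A [signature_set()] (or character vector of miRNA
#'   names). Required: the pipeline never assumes a signature implicitly.
#' @param config A [run_config()].
#' @return Data frame of class `haemolysis_assessment` with one row per
#'   retained sample and columns `sample_id`, `haemolysis_metric`,
#'   `threshold`, `result`, `p1`, `p2`, `n`. Attributes: `partition`,
#'   `expression` (the log2-CPM matrix), `removed_samples`,
#'   `removed_features`, `n_positivity_dropped`, `norm_factors`, `config`.
#' @examples
#' sim <- simulate_study(simulation_config(seed = 7), default_signature())
#' res <- assess_haemolysis(sim$table, sim$signature_used)
#' table(res$result)
#' @export
assess_haemolysis <- function(counts, signature, config = run_config()) {
  stopifnot(inherits(counts, "count_table"), inherits(config, "run_config"))
  if (missing(signature) || is.null(signature))
    stop("an explicit signature set is required (see default_signature())",
         call. = FALSE)

  rep_names <- validate_mirna_names(rownames(counts$counts))
  if (nrow(rep_names$invalid))
    warning(nrow(rep_names$invalid),
            " feature name(s) do not match the mature miRBase pattern; ",
            "they are retained in the background set", call. = FALSE)

  removed_samples <- character()
  removed_features <- character()

  if (counts$is_prenormalised) {
    expr <- counts$counts
    factors <- NULL
  } else {
    qc <- with_stage("qc", qc_filter_samples(counts, min_reads = config$min_reads))
    removed_samples <- qc$removed
    if (length(removed_samples))
      message("qc: removed ", length(removed_samples), " sample(s) with < ",
              format(config$min_reads, big.mark = ",", scientific = FALSE), " reads: ",
              paste(removed_samples, collapse = ", "))
    kept <- qc$counts

    n_min <- config$min_samples
    if (is.null(n_min)) n_min <- ncol(kept$counts)
    filt <- with_stage("expression-filter",
                       filter_low_expression(kept, min_cpm = config$min_cpm,
                                             min_samples = n_min))
    removed_features <- attr(filt, "removed_features")
    message("expression-filter: removed ", length(removed_features),
            " miRNA(s) below ", config$min_cpm, " CPM in more than ",
            ncol(filt$counts) - n_min, " sample(s)")

    if (ncol(filt$counts) == 1L) {
      warning("single sample: TMM normalisation skipped, factor set to 1",
              call. = FALSE)
      factors <- NULL
    } else {
      factors <- with_stage("tmm",
                            tmm_factors(filt, logratio_trim = config$logratio_trim,
                                        abundance_trim = config$abundance_trim,
                                        weighted = config$weighted))
    }
    expr <- with_stage("log2cpm",
                       log2_cpm(filt, factors = factors,
                                prior_count = config$prior_count))
  }

  # positivity guard: Eq-style geometric means need strictly positive values
  pos <- apply(expr > 0, 1, all)
  n_dropped_pos <- sum(!pos)
  if (n_dropped_pos) {
    message("positivity-guard: dropped ", n_dropped_pos,
            " miRNA(s) with non-positive log2-CPM in at least one sample")
    expr <- expr[pos, , drop = FALSE]
  }
  if (nrow(expr) < 2L)
    stop("[positivity-guard] fewer than 2 miRNAs with all-positive log2-CPM",
         call. = FALSE)

  part <- with_stage("partition",
                     build_partition(rownames(expr), signature,
                                     exclusions = config$exclusions))
  if (nrow(part$excluded))
    message("partition: excluded ", nrow(part$excluded),
            " miRNA(s) from both sets: ",
            paste(part$excluded$name, collapse = ", "))

  ids <- colnames(expr)
  metric <- vapply(ids, function(s)
    with_stage("metric",
               haemolysis_metric(expr, part, s, mode = config$metric_mode)),
    numeric(1))
  result <- with_stage("classify",
                       classify_haemolysis(metric, threshold = config$threshold))

  out <- data.frame(
    sample_id = ids,
    haemolysis_metric = unname(metric),
    threshold = config$threshold,
    result = result,
    p1 = length(part$signature_ids),
    p2 = length(part$background_ids),
    n = length(ids),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("haemolysis_assessment", "data.frame")
  attr(out, "partition") <- part
  attr(out, "expression") <- expr
  attr(out, "removed_samples") <- removed_samples
  attr(out, "removed_features") <- removed_features
  attr(out, "n_positivity_dropped") <- n_dropped_pos
  attr(out, "norm_factors") <- factors
  attr(out, "config") <- config
  out
}

#' @export
print.haemolysis_assessment <- function(x, ...) {
  cat(sprintf("Haemolysis assessment: %d sample(s), p1 = %d signature / p2 = %d background miRNAs\n",
              nrow(x), x$p1[1], x$p2[1]))
  cat(sprintf("threshold %.3g: %d Caution, %d Clear\n\n", x$threshold[1],
              sum(x$result == "Caution"), sum(x$result == "Clear")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
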