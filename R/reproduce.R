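#' Published public-data reproduction targets
#'
#' Registry of the four public GEO plasma miRNA-seq datasets used to
#' demonstrate the method, with the published sample counts, Caution
#' counts, and the dataset-specific exclusion lists (miRNAs reported or
#' found differentially abundant in each study's biology, removed from
#' both signature and background sets).
#'
#' @return Named list; each element has `total_samples`, `caution`, and
#'   `exclusions`.
#' @export
reproduction_targets <- function() {
  list(
    GSE153813 = list(total_samples = 9L, caution = 3L, exclusions = character()),
    GSE105052 = list(total_samples = 42L, caution = 3L, exclusions = c(
      "hsa-miR-128-3p", "hsa-miR-625-3p", "hsa-miR-130b-5p",
      "hsa-miR-151a-5p", "hsa-miR-330-3p", "hsa-miR-323a-3p",
      "hsa-miR-142-3p")),
    GSE151341 = list(total_samples = 91L, caution = 4L, exclusions = c(
      "hsa-miR-335-3p", "hsa-miR-199a-5p", "hsa-miR-671-3p",
      "hsa-miR-1260b", "hsa-miR-191-3p", "hsa-miR-191-5p",
      "hsa-miR-335-5p", "hsa-miR-543")),
    GSE118038 = list(total_samples = 70L, caution = 32L, exclusions = c(
      "hsa-miR-4732-3p", "hsa-let-7a", "hsa-miR-26b-5p", "hsa-miR-98-5p",
      "hsa-miR-30c-5p", "hsa-miR-21-5p", "hsa-miR-191-5p"))
  )
}

#' Reproduce a published public-data assessment
#'
#' Runs the assessment on a user-supplied counts table for one of the four
#' registered GEO datasets, applying that dataset's published exclusion
#' list, under both metric conventions and a small grid of
#' expression-filter settings (the originally used cutoff and
#' smallest-group size are not published, so sensitivity across settings
#' is reported rather than a single answer asserted).
#'
#' The counts table is not downloaded automatically; obtain it from GEO
#' and pass its path. The file's sample count is validated against the
#' published total before running.
#'
#' @param dataset One of `names(reproduction_targets())`.
#' @param counts_path Path to the dataset's miRNA counts table (TSV/CSV,
#'   miRNAs in rows).
#' @param signature A [signature_set()]; defaults to [default_signature()].
#' @param min_cpm_grid CPM cutoffs to sweep; default `c(0.5, 1, 2)`.
#' @param min_samples_grid Smallest-group sizes to sweep; default `NULL`
#'   sweeps roughly 10%, 25% and 50% of the samples.
#' @param modes Metric conventions to sweep.
#' @return Data frame with one row per (mode, min_cpm, min_samples)
#'   combination: samples assessed, Caution count, the published Caution
#'   count, and whether they agree.
#' @export
reproduce_dataset <- function(dataset, counts_path,
                              signature = default_signature(),
                              min_cpm_grid = c(0.5, 1, 2),
                              min_samples_grid = NULL,
                              modes = c("geomean_log2", "mean_log2")) {
  reg <- reproduction_targets()
  if (!dataset %in% names(reg))
    stop("unknown dataset '", dataset, "'; valid ids: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  tgt <- reg[[dataset]]
  ct <- read_counts(counts_path)
  if (ncol(ct$counts) != tgt$total_samples)
    stop(dataset, " should have ", tgt$total_samples, " samples; file has ",
         ncol(ct$counts), call. = FALSE)
  if (is.null(min_samples_grid))
    min_samples_grid <- unique(pmax(1L, floor(tgt$total_samples * c(0.1, 0.25, 0.5))))
  grid <- expand.grid(mode = modes, min_cpm = min_cpm_grid,
                      min_samples = min_samples_grid,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- run_config(min_cpm = grid$min_cpm[i],
                      min_samples = grid$min_samples[i],
                      metric_mode = grid$mode[i],
                      exclusions = tgt$exclusions)
    res <- tryCatch(
      suppressMessages(suppressWarnings(assess_haemolysis(ct, signature, cfg))),
      error = function(e) NULL)
    data.frame(
      dataset = dataset, mode = grid$mode[i], min_cpm = grid$min_cpm[i],
      min_samples = grid$min_samples[i],
      n_assessed = if (is.null(res)) NA_integer_ else nrow(res),
      n_caution = if (is.null(res)) NA_integer_ else sum(res$result == "Caution"),
      published_caution = tgt$caution,
      agrees = if (is.null(res)) FALSE else
        sum(res$result == "Caution") == tgt$caution,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
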