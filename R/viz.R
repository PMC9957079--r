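col_clear <- "#2166AC"
col_caution <- "#B2182B"

#' Signature vs background density plot for one sample
#'
#' Overlays kernel-density estimates of the signature and background
#' log2-CPM distributions for a single sample, annotated with the sample's
#' haemolysis metric. In a haemolysed sample the signature curve sits
#' visibly to the right of the background.
#'
#' @param expr A log2-CPM matrix (see [log2_cpm()]).
#' @param partition A [build_partition()] result.
#' @param sample_id Sample to plot.
#' @param mode Metric mode for the annotation, see [haemolysis_metric()].
#' @param file Optional output path (`.png`, `.pdf` or `.svg`); when given,
#'   the figure is written there.
#' @return The ggplot object, invisibly when `file` is given.
#' @export
density_plot <- function(expr, partition, sample_id,
                         mode = c("geomean_log2", "mean_log2"), file = NULL) {
  mode <- match.arg(mode)
  if (!sample_id %in% colnames(expr))
    stop("unknown sample: ", sample_id, call. = FALSE)
  metric <- haemolysis_metric(expr, partition, sample_id, mode = mode)
  z <- expr[, sample_id]
  df <- data.frame(
    log2cpm = c(z[partition$signature_ids], z[partition$background_ids]),
    set = rep(c("signature", "background"),
              c(length(partition$signature_ids), length(partition$background_ids)))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$log2cpm, colour = .data$set)) +
    ggplot2::geom_density(linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(signature = col_caution,
                                            background = col_clear)) +
    ggplot2::labs(
      title = sample_id,
      subtitle = sprintf("haemolysis metric = %.3f", metric),
      x = "log2 CPM", y = "density", colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Read a reference barcode file
#'
#' A reference barcode holds haemolysis-metric values from a previously
#' validated experiment in which haemolysis was also measured by the qPCR
#' delta-Cq (miR-23a-3p minus miR-451a) assay; each value is labelled
#' `Haemolysed` (delta-Cq > 7) or `Clear` (delta-Cq < 7). Expected CSV
#' columns: `metric`, `dcq_label`.
#'
#' @param path CSV path.
#' @return Data frame of class `reference_barcode`.
#' @export
read_reference_barcode <- function(path) {
  if (!file.exists(path))
    stop("reference file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_barcode(df)
}

#' @rdname read_reference_barcode
#' @param df Data frame with numeric `metric` and `dcq_label` in
#'   `{Haemolysed, Clear}`.
#' @export
reference_barcode <- function(df) {
  if (!all(c("metric", "dcq_label") %in% names(df)))
    stop("reference barcode needs columns 'metric' and 'dcq_label'", call. = FALSE)
  if (!all(df$dcq_label %in% c("Haemolysed", "Clear")))
    stop("dcq_label must be 'Haemolysed' or 'Clear'", call. = FALSE)
  if (!is.numeric(df$metric) || anyNA(df$metric))
    stop("reference metric values must be numeric and complete", call. = FALSE)
  structure(df, class = c("reference_barcode", "data.frame"))
}

#' Generate a synthetic reference barcode
#'
#' Builds a clearly synthetic stand-in for a validated reference
#' experiment by simulating clean and contaminated plasma libraries,
#' assessing them, and labelling each by its ground truth (contaminated =
#' `Haemolysed`, clean = `Clear`). It is NOT the original validation data
#' and is intended only to demonstrate the barcode overlay.
#'
#' @param signature A [signature_set()].
#' @param n_haemolysed,n_clear Sample counts; defaults 12 and 24.
#' @param seed Integer seed.
#' @return A [reference_barcode()] with a `source` attribute marking it
#'   synthetic.
#' @export
synthetic_reference_barcode <- function(signature, n_haemolysed = 12,
                                        n_clear = 24, seed = 1) {
  cfg <- simulation_config(n_clean = n_clear, n_contaminated = n_haemolysed,
                           library_size_range = c(1.2e6, 5e6), seed = seed)
  sim <- simulate_study(cfg, signature)
  res <- suppressMessages(suppressWarnings(
    assess_haemolysis(sim$table, signature,
                      config = run_config(min_samples = n_clear))))
  lab <- sim$truth$status[match(res$sample_id, sim$truth$sample_id)]
  out <- reference_barcode(data.frame(
    metric = res$haemolysis_metric,
    dcq_label = ifelse(lab == "contaminated", "Haemolysed", "Clear"),
    stringsAsFactors = FALSE
  ))
  attr(out, "source") <- "synthetic simulation (not validated experimental data)"
  out
}

#' Histogram of haemolysis metrics with optional reference barcode
#'
#' Plots the assessed samples' metric values coloured by their
#' Clear/Caution label, with a vertical line at the decision threshold.
#' When a reference barcode is supplied, two rug rows appear beneath the
#' histogram: the upper row shows reference values whose delta-Cq label is
#' Haemolysed (red), the lower row those labelled Clear (blue). Reference
#' delta-Cq concordance may be affected by cohort characteristics (e.g.
#' pregnancy status in the original validation cohort), so the barcode is a
#' general comparison, not a calibration.
#'
#' @param assessments Assessment data frame from [assess_haemolysis()].
#' @param reference Optional [reference_barcode()].
#' @param threshold Decision threshold drawn as a vertical line.
#' @param binwidth Histogram bin width in metric units; default 0.25.
#' @param file Optional output figure path.
#' @return The ggplot object, invisibly when `file` is given.
#' @export
metric_histogram <- function(assessments, reference = NULL, threshold = 1.9,
                             binwidth = 0.25, file = NULL) {
  if (!is.data.frame(assessments) || nrow(assessments) == 0L)
    stop("no assessments to plot", call. = FALSE)
  df <- as.data.frame(assessments)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$haemolysis_metric,
                                        fill = .data$result)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, colour = "white") +
    ggplot2::scale_fill_manual(values = c(Clear = col_clear, Caution = col_caution)) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "haemolysis metric", y = "samples", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "reference_barcode"))
    ymax <- max(graphics::hist(df$haemolysis_metric,
                               breaks = seq(floor(min(df$haemolysis_metric) / binwidth) * binwidth,
                                            max(df$haemolysis_metric) + binwidth, by = binwidth),
                               plot = FALSE)$counts)
    rows <- data.frame(
      metric = reference$metric,
      y = ifelse(reference$dcq_label == "Haemolysed", -0.06, -0.14) * ymax,
      dcq_label = reference$dcq_label
    )
    p <- p +
      ggplot2::geom_point(data = rows,
                          ggplot2::aes(x = .data$metric, y = .data$y,
                                       colour = .data$dcq_label),
                          shape = "|", size = 4, inherit.aes = FALSE) +
      ggplot2::scale_colour_manual(values = c(Haemolysed = col_caution,
                                              Clear = col_clear)) +
      ggplot2::labs(colour = "reference (dCq)")
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 7, height = 4.5, dpi = 150)
    return(invisible(p))
  }
  p
}
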