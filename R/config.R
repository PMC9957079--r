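#' Pipeline configuration
#'
#' Collects every tunable knob of the assessment pipeline with the
#' recommended defaults: depth QC at 1,000,000 reads, CPM >= 1 in at least
#' `min_samples` samples for the expression filter, doubly-trimmed weighted
#' TMM (trims 0.30/0.05), prior count 2 for log2-CPM, and the decision
#' threshold 1.9.
#'
#' @param min_reads Depth QC cutoff (strict `<` removal); default 1e6.
#' @param min_cpm Expression-filter CPM cutoff; default 1.
#' @param min_samples Number of samples that must reach `min_cpm`; set this
#'   to the size of the smallest group of interest. `NULL` (default) uses
#'   all samples retained after QC, the most conservative choice.
#' @param logratio_trim,abundance_trim,weighted TMM parameters, see
#'   [tmm_factors()].
#' @param prior_count log2-CPM prior, see [log2_cpm()].
#' @param threshold Decision threshold; default 1.9.
#' @param metric_mode `"geomean_log2"` or `"mean_log2"`, see
#'   [haemolysis_metric()].
#' @param exclusions Character vector of miRNAs excluded from both
#'   signature and background sets.
#' @param signature_file Optional path to a signature list (for the CLI and
#'   manifests; `assess_haemolysis()` takes the set itself).
#' @param seed Integer seed (used by the simulator only; assessment is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(min_reads = 1e6, min_cpm = 1, min_samples = NULL,
                       logratio_trim = 0.30, abundance_trim = 0.05,
                       weighted = TRUE, prior_count = 2, threshold = 1.9,
                       metric_mode = c("geomean_log2", "mean_log2"),
                       exclusions = character(), signature_file = NULL,
                       seed = NULL) {
  metric_mode <- match.arg(metric_mode)
  stopifnot(min_reads >= 0, min_cpm >= 0, prior_count >= 0,
            logratio_trim >= 0, logratio_trim < 0.5,
            abundance_trim >= 0, abundance_trim < 0.5)
  structure(list(
    min_reads = min_reads, min_cpm = min_cpm, min_samples = min_samples,
    logratio_trim = logratio_trim, abundance_trim = abundance_trim,
    weighted = weighted, prior_count = prior_count, threshold = threshold,
    metric_mode = metric_mode, exclusions = as.character(exclusions),
    signature_file = signature_file, seed = seed
  ), class = "run_config")
}

#' Serialise a run configuration to YAML
#'
#' `read_run_config(write_run_config(cfg, path))` round-trips unchanged.
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `path` invisibly; for the reader, a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$exclusions)) raw$exclusions <- character()
  do.call(run_config, raw)
}

#' Write a provenance manifest for a run
#'
#' Records package version, the full configuration, and MD5 checksums of
#' the input files, so a results table can be traced back to its inputs.
#'
#' @param path Output YAML path.
#' @param config A [run_config()].
#' @param inputs Character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character()) {
  stopifnot(inherits(config, "run_config"))
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  yaml::write_yaml(list(
    package = "haemoQC",
    version = as.character(utils::packageVersion("haemoQC")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    input_md5 = sums
  ), path)
  invisible(path)
}
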