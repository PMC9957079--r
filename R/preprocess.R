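#' Per-sample library sizes
#'
#' Column sums of the raw count table: the total mapped miRNA reads per
#' sample, used both for the sequencing-depth QC rule and as the basis of
#' the CPM transform.
#'
#' @param x A [count_table()].
#' @return Named numeric vector, one entry per sample.
#' @export
library_sizes <- function(x) {
  stopifnot(inherits(x, "count_table"))
  colSums(x$counts)
}

#' Remove poorly sequenced samples
#'
#' Samples with fewer than `min_reads` total miRNA reads are considered too
#' shallow for a reliable assessment and are dropped. The rule is a strict
#' inequality: a sample with exactly `min_reads` reads is retained.
#'
#' @param x A raw [count_table()].
#' @param min_reads Minimum total read count; default 1,000,000.
#' @return List with `counts` (the filtered `count_table`) and `removed`
#'   (character vector of dropped sample ids).
#' @export
qc_filter_samples <- function(x, min_reads = 1e6) {
  stopifnot(inherits(x, "count_table"))
  if (x$is_prenormalised)
    stop("sequencing-depth QC applies to raw counts only", call. = FALSE)
  tot <- colSums(x$counts)
  drop <- tot < min_reads
  if (all(drop))
    stop("no samples pass QC: all library sizes < ", format(min_reads, big.mark = ",", scientific = FALSE),
         call. = FALSE)
  list(counts = subset_ct(x, cols = !drop), removed = colnames(x$counts)[drop])
}

#' Filter low-expression miRNAs
#'
#' Retains miRNAs with raw CPM of at least `min_cpm` in at least
#' `min_samples` samples. `min_samples` should be set to the number of
#' samples in the smallest group of interest, so that a miRNA expressed in
#' only one biological group is not discarded. CPM here is computed on raw
#' library sizes, before normalisation.
#'
#' @param x A raw [count_table()].
#' @param min_cpm CPM cutoff (default 1).
#' @param min_samples Number of samples that must reach `min_cpm`.
#' @return The filtered `count_table`, with dropped feature names in
#'   attribute `removed_features`. Feature order is preserved.
#' @export
filter_low_expression <- function(x, min_cpm = 1, min_samples) {
  stopifnot(inherits(x, "count_table"))
  n <- ncol(x$counts)
  if (min_samples < 1 || min_samples > n)
    stop("'min_samples' must be between 1 and the number of samples (", n, ")",
         call. = FALSE)
  cpm_raw <- sweep(x$counts, 2, colSums(x$counts) / 1e6, "/")
  keep <- rowSums(cpm_raw >= min_cpm) >= min_samples
  if (!any(keep))
    stop("no miRNAs pass the low-expression filter (CPM >= ", min_cpm,
         " in >= ", min_samples, " samples)", call. = FALSE)
  out <- subset_ct(x, rows = keep)
  attr(out, "removed_features") <- rownames(x$counts)[!keep]
  out
}

# Reference sample for TMM: the sample whose 75th-percentile count
# proportion is closest to the mean of those percentiles across samples;
# ties broken by lowest sample index.
tmm_reference <- function(counts, lib) {
  q75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  which.min(abs(q75 - mean(q75)))
}

#' TMM normalisation factors
#'
#' Between-sample scaling factors by the trimmed mean of M-values: log2
#' expression ratios against a reference sample are doubly trimmed (by
#' M-value and by average abundance) and averaged with inverse-variance
#' weights; the factor is 2 to that mean. Factors are rescaled to have
#' geometric mean 1, so the haemolysis metric is invariant to a global
#' rescaling of depth. Computation is delegated to
#' \code{edgeR::calcNormFactors}, with the reference sample fixed to the one
#' whose 75th-percentile CPM is closest to the mean of those percentiles.
#'
#' @param x A raw [count_table()] with at least two samples, each with a
#'   positive total.
#' @param logratio_trim Fraction of M-values trimmed from each tail
#'   (default 0.30).
#' @param abundance_trim Fraction of A-values (average abundance) trimmed
#'   from each tail (default 0.05).
#' @param weighted Use inverse asymptotic-binomial-variance weights
#'   (default `TRUE`).
#' @return Named numeric vector of class `norm_factors` with attribute
#'   `ref_sample` (the reference sample id).
#' @export
tmm_factors <- function(x, logratio_trim = 0.30, abundance_trim = 0.05,
                        weighted = TRUE) {
  stopifnot(inherits(x, "count_table"))
  m <- x$counts
  if (ncol(m) < 2L)
    stop("TMM needs at least 2 samples", call. = FALSE)
  lib <- colSums(m)
  if (any(lib <= 0))
    stop("sample(s) with zero total counts: ",
         paste(colnames(m)[lib <= 0], collapse = ", "), call. = FALSE)
  ref <- tmm_reference(m, lib)
  shared <- colSums(m > 0 & m[, ref] > 0)
  if (any(shared == 0L))
    stop("sample(s) share no positive features with the reference sample '",
         colnames(m)[ref], "': ",
         paste(colnames(m)[shared == 0L], collapse = ", "), call. = FALSE)
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref,
                              logratioTrim = logratio_trim,
                              sumTrim = abundance_trim,
                              doWeighting = weighted)
  names(f) <- colnames(m)
  structure(f, ref_sample = colnames(m)[ref], class = "norm_factors")
}

#' log2 counts-per-million on TMM-adjusted library sizes
#'
#' Computes the prior-damped log2-CPM transform: with effective library
#' size \eqn{L_s} (raw total times TMM factor) and prior count \eqn{p}
#' scaled per sample as \eqn{p_s = p L_s / \bar{L}}, each cell is
#' \deqn{\log_2\left(\frac{c + p_s}{L_s + 2 p_s} \cdot 10^6\right).}
#' The scaled prior keeps every value finite at zero counts. Because the
#' haemolysis metric takes geometric means of these values, non-positive
#' entries (possible for zero counts in libraries much deeper than average)
#' are counted and reported in attribute `n_nonpositive`;
#' [assess_haemolysis()] excludes such features from both signature and
#' background sets.
#'
#' @param x A raw [count_table()].
#' @param factors Optional [tmm_factors()] aligned to the samples; `NULL`
#'   uses factors of 1 (no between-sample normalisation).
#' @param prior_count Prior count, >= 0; default 2.
#' @return Feature-by-sample numeric matrix of class `log2cpm`, with
#'   attributes `prior_count`, `effective_lib_sizes` and `n_nonpositive`.
#' @export
log2_cpm <- function(x, factors = NULL, prior_count = 2) {
  stopifnot(inherits(x, "count_table"))
  if (x$is_prenormalised)
    stop("table is declared pre-normalised; its values are already log2 scale",
         call. = FALSE)
  if (prior_count < 0)
    stop("'prior_count' must be >= 0", call. = FALSE)
  lib <- colSums(x$counts)
  if (is.null(factors)) {
    f <- rep(1, ncol(x$counts))
  } else {
    if (length(factors) != ncol(x$counts))
      stop("normalisation factors not aligned to samples", call. = FALSE)
    f <- as.numeric(factors)
  }
  eff <- lib * f
  if (any(eff <= 0))
    stop("non-positive effective library size for sample(s): ",
         paste(colnames(x$counts)[eff <= 0], collapse = ", "), call. = FALSE)
  z <- edgeR::cpm(x$counts, lib.size = eff, log = TRUE,
                  prior.count = prior_count)
  dimnames(z) <- dimnames(x$counts)
  structure(z, prior_count = prior_count, effective_lib_sizes = eff,
            n_nonpositive = sum(z <= 0), class = c("log2cpm", "matrix", "array"))
}
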