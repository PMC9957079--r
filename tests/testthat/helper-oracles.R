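# Independent brute-force oracles. These share no code with the package:
# every step (reference choice, M/A values, trimming, weighting, the prior
# convention) is written out explicitly.

# Trimmed mean of M-values, spelled out.
brute_tmm <- function(counts, logratio_trim = 0.30, abundance_trim = 0.05,
                      weighted = TRUE) {
  lib <- colSums(counts)
  q75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    obs <- counts[, s]; refc <- counts[, ref]
    keep <- obs > 0 & refc > 0
    o <- obs[keep]; r <- refc[keep]
    M <- log2((o / lib[s]) / (r / lib[ref]))
    A <- 0.5 * (log2(o / lib[s]) + log2(r / lib[ref]))
    if (max(abs(M)) < 1e-6) { f[s] <- 1; next }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n - floor(n * logratio_trim)
    loA <- floor(n * abundance_trim) + 1; hiA <- n - floor(n * abundance_trim)
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (weighted) {
      w <- 1 / ((lib[s] - o) / (lib[s] * o) + (lib[ref] - r) / (lib[ref] * r))
      f[s] <- 2^(sum((M * w)[keep2]) / sum(w[keep2]))
    } else {
      f[s] <- 2^mean(M[keep2])
    }
  }
  f / exp(mean(log(f)))
}

# Prior-damped log2-CPM, cell by cell.
brute_log2cpm <- function(counts, eff_lib, prior = 2) {
  ps <- prior * eff_lib / mean(eff_lib)
  out <- counts
  for (j in seq_len(ncol(counts)))
    for (i in seq_len(nrow(counts)))
      out[i, j] <- log2((counts[i, j] + ps[j]) / (eff_lib[j] + 2 * ps[j]) * 1e6)
  out
}

# Direct product-then-root geometric mean and metric.
brute_geomean <- function(v) prod(v)^(1 / length(v))

brute_metric <- function(z, sig, bg) {
  brute_geomean(z[sig]) - brute_geomean(z[bg])
}
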