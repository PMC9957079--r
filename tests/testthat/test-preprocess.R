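test_that("depth QC removes strictly-below-1M samples and keeps the boundary", {
  m <- matrix(0, nrow = 2, ncol = 3,
              dimnames = list(c("hsa-miR-451a", "hsa-miR-16-5p"),
                              c("low", "edge", "deep")))
  m[1, ] <- c(999999 - 10, 1e6 - 10, 2e6 - 10)
  m[2, ] <- 10
  ct <- count_table(m)
  out <- qc_filter_samples(ct)
  expect_equal(out$removed, "low")
  expect_equal(samples(out$counts), c("edge", "deep"))

  # all deep: identity
  deep <- count_table(m[, "deep", drop = FALSE] + 0)
  out2 <- qc_filter_samples(deep)
  expect_length(out2$removed, 0)
  expect_identical(out2$counts$counts, deep$counts)

  # all shallow: error
  shallow <- count_table(m[, "low", drop = FALSE] + 0)
  expect_error(qc_filter_samples(shallow), "no samples pass QC")
})

test_that("depth QC agrees with brute-force column sums on random tables", {
  set.seed(21)
  for (i in 1:5) {
    ct <- toy_counts(nf = 40, ns = 5, seed = i, libsize = 1.1e6)
    out <- qc_filter_samples(ct, min_reads = 1e6)
    keep_oracle <- colnames(ct$counts)[colSums(ct$counts) >= 1e6]
    expect_identical(samples(out$counts), keep_oracle)
    expect_setequal(c(samples(out$counts), out$removed), samples(ct))
  }
})

test_that("low-expression filter counts qualifying samples per feature", {
  m <- rbind(
    keep = c(1.2, 0, 3.1),   # CPM given 1M libraries
    drop = c(0, 0, 0),
    also = c(5, 5, 5)
  )
  m <- round(m)  # counts in a 1M library equal CPM
  # build 1M-total libraries by padding with a filler feature
  filler <- 1e6 - colSums(m)
  m2 <- rbind(m, filler = filler)
  rownames(m2) <- c("hsa-miR-1-5p", "hsa-miR-2-5p", "hsa-miR-3-5p", "hsa-miR-4-5p")
  colnames(m2) <- c("A", "B", "C")
  ct <- count_table(m2)
  out <- filter_low_expression(ct, min_cpm = 1, min_samples = 2)
  expect_true("hsa-miR-1-5p" %in% features(out))   # >=1 CPM in 2 samples
  expect_false("hsa-miR-2-5p" %in% features(out))  # all-zero
  expect_equal(attr(out, "removed_features"), "hsa-miR-2-5p")

  expect_error(filter_low_expression(ct, min_samples = 9), "between 1")
})

test_that("low-expression filter matches a brute-force per-feature count", {
  for (i in 1:5) {
    ct <- toy_counts(nf = 60, ns = 6, seed = 30 + i)
    out <- filter_low_expression(ct, min_cpm = 1, min_samples = 3)
    cpm <- sweep(ct$counts, 2, colSums(ct$counts) / 1e6, "/")
    keep_oracle <- apply(cpm, 1, function(r) sum(r >= 1) >= 3)
    expect_identical(features(out), names(keep_oracle)[keep_oracle])
  }
})

test_that("TMM factors are 1 for identical and depth-scaled columns", {
  ct <- toy_counts(nf = 50, ns = 1, seed = 5)
  m <- cbind(A = ct$counts[, 1], B = ct$counts[, 1])
  rownames(m) <- features(ct)
  f <- tmm_factors(count_table(m))
  expect_equal(unname(as.numeric(f)), c(1, 1), tolerance = 1e-12)

  m2 <- cbind(A = ct$counts[, 1], B = 2 * ct$counts[, 1])
  f2 <- tmm_factors(count_table(m2))
  expect_equal(unname(as.numeric(f2)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches the brute-force oracle on composition-shifted data", {
  set.seed(77)
  for (i in 1:20) {
    m <- matrix(rnbinom(50 * 5, mu = exp(runif(250, 1, 8)), size = 5), 50, 5)
    dimnames(m) <- list(sprintf("hsa-miR-%d-5p", 1:50), sprintf("S%d", 1:5))
    m <- m + 1L  # guarantee shared positive features
    f <- tmm_factors(count_table(m))
    expect_equal(unname(as.numeric(f)), brute_tmm(m), tolerance = 1e-10)
    expect_equal(exp(mean(log(as.numeric(f)))), 1, tolerance = 1e-12)
  }
  # unweighted variant agrees with its oracle too
  m <- matrix(rnbinom(300, mu = 200, size = 3), 60, 5) + 1L
  dimnames(m) <- list(sprintf("hsa-miR-%d-3p", 1:60), sprintf("S%d", 1:5))
  f <- tmm_factors(count_table(m), weighted = FALSE)
  expect_equal(unname(as.numeric(f)), brute_tmm(m, weighted = FALSE),
               tolerance = 1e-10)
})

test_that("TMM preconditions are enforced with named samples", {
  ct <- toy_counts(ns = 1)
  expect_error(tmm_factors(ct), "at least 2 samples")

  m <- matrix(c(5, 0, 0, 0, 9, 8), nrow = 3,
              dimnames = list(c("hsa-miR-1-5p", "hsa-miR-2-5p", "hsa-miR-3-5p"),
                              c("A", "B")))
  expect_error(suppressWarnings(tmm_factors(count_table(m))),
               "share no positive features")
})

test_that("unweighted TMM is invariant to scaling one sample's counts", {
  # scaling a library changes counts and library size proportionally, so
  # M-values on proportions are unchanged; with uniform weights the factor
  # absorbs the scalar exactly
  ct <- toy_counts(nf = 80, ns = 4, seed = 9)
  f0 <- as.numeric(tmm_factors(ct, weighted = FALSE))
  m <- ct$counts
  m[, 2] <- m[, 2] * 3
  f1 <- as.numeric(tmm_factors(count_table(m), weighted = FALSE))
  eff0 <- colSums(ct$counts) * f0
  eff1 <- colSums(m) * f1
  corr <- (eff1 / eff0) / (eff1[1] / eff0[1])  # relative effective-lib change
  expect_equal(unname(corr[2]), 3, tolerance = 1e-8)
})

test_that("permuting samples permutes TMM factors identically", {
  ct <- toy_counts(nf = 70, ns = 5, seed = 13)
  f <- as.numeric(tmm_factors(ct))
  perm <- c(3, 1, 5, 2, 4)
  ctp <- count_table(ct$counts[, perm])
  fp <- as.numeric(tmm_factors(ctp))
  expect_equal(fp, f[perm], tolerance = 1e-12)
})

test_that("log2-CPM matches the cell-wise prior-damped formula", {
  ct <- toy_counts(nf = 40, ns = 4, seed = 17)
  f <- tmm_factors(ct)
  z <- log2_cpm(ct, f, prior_count = 2)
  eff <- colSums(ct$counts) * as.numeric(f)
  expect_equal(as.numeric(z), as.numeric(brute_log2cpm(ct$counts, eff, 2)),
               tolerance = 1e-10)
})

test_that("log2-CPM edge behaviour: exact value at prior 0, finite zeros, monotone", {
  m <- matrix(c(100, 1e6 - 100), 2, 1,
              dimnames = list(c("hsa-miR-1-5p", "hsa-miR-2-5p"), "A"))
  ct <- count_table(m)
  z0 <- log2_cpm(ct, prior_count = 0)
  expect_equal(z0["hsa-miR-1-5p", "A"], log2(100), tolerance = 1e-12)

  m2 <- rbind(m, "hsa-miR-3-5p" = c(0))
  z <- log2_cpm(count_table(m2), prior_count = 2)
  expect_true(all(is.finite(z)))
  expect_gt(z["hsa-miR-3-5p", "A"], 0)  # 1M library, default prior

  # strictly increasing in the count, all else fixed
  counts <- c(0, 1, 5, 50, 500)
  zz <- vapply(counts, function(c0) {
    mm <- matrix(c(c0, 1e6 - c0), 2, 1,
                 dimnames = list(c("hsa-miR-1-5p", "hsa-miR-2-5p"), "A"))
    log2_cpm(count_table(mm))["hsa-miR-1-5p", "A"]
  }, numeric(1))
  expect_true(all(diff(zz) > 0))
})
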