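sig5 <- sprintf("hsa-miR-%d-5p", 1:5)
bg10 <- sprintf("hsa-miR-%d-3p", 101:110)

make_part <- function(sig = sig5, bg = bg10)
  build_partition(c(sig, bg), signature_set(sig))

test_that("partitions follow set algebra, with exclusions dropped from both sets", {
  feats <- c(sig5, bg10)
  p <- build_partition(feats, signature_set(sig5))
  expect_setequal(p$signature_ids, sig5)
  expect_setequal(p$background_ids, bg10)

  p2 <- build_partition(feats, signature_set(sig5), exclusions = sig5[1])
  expect_equal(length(p2$signature_ids), 4)
  expect_false(sig5[1] %in% p2$signature_ids)
  expect_false(sig5[1] %in% p2$background_ids)

  p3 <- build_partition(feats, signature_set(sig5), exclusions = bg10[1])
  expect_false(bg10[1] %in% p3$background_ids)

  # members absent from the data are warned about
  expect_warning(
    build_partition(bg10, signature_set(c(sig5, bg10[1]))),
    "absent")
  expect_error(suppressWarnings(build_partition(bg10, signature_set(sig5))),
               "empty reduced signature")
  expect_error(build_partition(sig5, signature_set(sig5)), "background")
})

test_that("random partitions equal brute-force set operations", {
  set.seed(42)
  pool <- sprintf("hsa-miR-%d-5p", 1:200)
  for (i in 1:20) {
    feats <- sample(pool, 80)
    sig <- sample(pool, 15)
    excl <- sample(pool, 5)
    ok <- length(setdiff(intersect(sig, feats), excl)) > 0 &&
      length(setdiff(feats, union(sig, excl))) > 0
    if (!ok) next
    p <- suppressWarnings(build_partition(feats, signature_set(sig), excl))
    expect_setequal(p$signature_ids, setdiff(intersect(sig, feats), excl))
    expect_setequal(p$background_ids, setdiff(feats, union(sig, excl)))
    expect_length(intersect(p$signature_ids, p$background_ids), 0)
    expect_setequal(union(union(p$signature_ids, p$background_ids),
                          intersect(excl, feats)), feats)
  }
})

test_that("geometric mean: constants, [2,8], random agreement, positivity errors", {
  expect_equal(geometric_mean(rep(3.7, 5)), 3.7, tolerance = 1e-14)
  expect_equal(geometric_mean(c(2, 8)), 4, tolerance = 1e-14)
  set.seed(8)
  for (i in 1:10) {
    v <- runif(50, 0.1, 20)
    expect_equal(geometric_mean(v), brute_geomean(v),
                 tolerance = 1e-12 * brute_geomean(v))
  }
  expect_error(geometric_mean(c(1, 0)), "positive")
  expect_error(geometric_mean(c(1, -2)), "positive")
  expect_error(geometric_mean(numeric()), "empty")
})

test_that("the metric is the difference of geometric means of log2-CPM", {
  part <- make_part()
  # constants: signature all g, background all b -> g - b exactly
  z <- fake_expr(list(A = stats::setNames(c(rep(6, 5), rep(2.5, 10)),
                                          c(sig5, bg10))))
  expect_equal(haemolysis_metric(z, part, "A"), 6 - 2.5, tolerance = 1e-14)

  # identical value multisets -> 0 (need equal-size sets)
  partEq <- build_partition(c(sig5, bg10[1:5]), signature_set(sig5))
  zz <- fake_expr(list(A = stats::setNames(c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1),
                                           c(sig5, bg10[1:5]))))
  expect_equal(haemolysis_metric(zz, partEq, "A"), 0, tolerance = 1e-14)

  # random: matches the hand-rolled product/root/difference oracle
  set.seed(10)
  for (i in 1:10) {
    sig <- sprintf("hsa-miR-%d-5p", 1:6)
    bg <- sprintf("hsa-miR-%d-3p", 101:120)
    v <- stats::setNames(runif(26, 0.5, 15), c(sig, bg))
    z <- fake_expr(list(S = v))
    p <- build_partition(c(sig, bg), signature_set(sig))
    want <- brute_metric(v, sig, bg)
    expect_equal(haemolysis_metric(z, p, "S"), want,
                 tolerance = 1e-12 * max(1, abs(want)))
  }
})

test_that("mean_log2 mode computes arithmetic means of log2 values", {
  part <- make_part()
  v <- stats::setNames(runif(15, 1, 12), c(sig5, bg10))
  z <- fake_expr(list(A = v))
  expect_equal(haemolysis_metric(z, part, "A", mode = "mean_log2"),
               mean(v[sig5]) - mean(v[bg10]), tolerance = 1e-14)
})

test_that("metric errors: unknown sample, non-positive expression", {
  part <- make_part()
  v <- stats::setNames(runif(15, 1, 12), c(sig5, bg10))
  z <- fake_expr(list(A = v))
  expect_error(haemolysis_metric(z, part, "nope"), "unknown sample")
  v2 <- v; v2[1] <- -0.2
  expect_error(haemolysis_metric(fake_expr(list(A = v2)), part, "A"),
               "non-positive")
})

test_that("metric is monotone in signature and background values", {
  part <- make_part()
  set.seed(3)
  v <- stats::setNames(runif(15, 2, 10), c(sig5, bg10))
  base <- haemolysis_metric(fake_expr(list(A = v)), part, "A")
  up_sig <- v; up_sig[sig5] <- up_sig[sig5] + 0.5
  expect_gt(haemolysis_metric(fake_expr(list(A = up_sig)), part, "A"), base)
  up_bg <- v; up_bg[bg10] <- up_bg[bg10] + 0.5
  expect_lt(haemolysis_metric(fake_expr(list(A = up_bg)), part, "A"), base)
})

test_that("feature order never changes the metric", {
  part <- make_part()
  set.seed(5)
  v <- stats::setNames(runif(15, 1, 10), c(sig5, bg10))
  z1 <- fake_expr(list(A = v))
  z2 <- fake_expr(list(A = v[sample(names(v))]))
  expect_equal(haemolysis_metric(z1, part, "A"),
               haemolysis_metric(z2, part, "A"), tolerance = 1e-14)
})

test_that("classification boundary is closed on the Caution side", {
  expect_equal(classify_haemolysis(1.9), "Caution")
  expect_equal(classify_haemolysis(1.8999), "Clear")
  expect_equal(classify_haemolysis(-0.4), "Clear")
  expect_equal(classify_haemolysis(c(0, 2, 1.9)), c("Clear", "Caution", "Caution"))
  expect_error(classify_haemolysis(NaN), "non-finite")
  # label flips exactly when the metric crosses the threshold from below
  eps <- 1e-9
  expect_equal(classify_haemolysis(1.9 - eps), "Clear")
  expect_equal(classify_haemolysis(1.9 + eps), "Caution")
})
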