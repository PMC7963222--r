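test_that("ROI extraction preserves order, counts and grid checks", {
  v <- array(seq_len(4 * 3 * 2), c(4, 3, 2))
  roi <- array(FALSE, c(4, 3, 2)); roi[c(1, 5, 9)] <- TRUE
  s <- extract_roi(v, roi, roi_id = "r1", class = "WM", contrast = "FA")
  expect_equal(s$values, c(1, 5, 9))
  expect_equal(s$n, 3L)
  one <- array(FALSE, c(4, 3, 2)); one[2, 2, 1] <- TRUE
  expect_equal(extract_roi(v, one)$n, 1L)
  cst <- extract_roi(array(2.5, c(4, 3, 2)), roi)
  expect_true(all(cst$values == 2.5))
  expect_error(extract_roi(v, array(TRUE, c(4, 4, 2))), "grid")
  expect_error(extract_roi(v, array(FALSE, c(4, 3, 2))), "empty")
})

test_that("intensity normalisation divides by the reference mean", {
  s <- as_roi_sample(c(1, 2, 3), contrast = "T1w")
  ref <- as_roi_sample(c(1.5, 2.5), roi_id = "wm_ref", contrast = "T1w")
  n <- normalize_intensity(s, ref)
  expect_equal(n$values, c(1, 2, 3) / 2)
  expect_true(n$normalized)
  expect_equal(n$reference_id, "wm_ref")
  # normalised by itself: mean exactly 1
  self <- normalize_intensity(s, s)
  expect_equal(mean(self$values), 1, tolerance = 1e-15)
  # dimensionless contrasts pass through untouched
  fa <- as_roi_sample(c(0.2, 0.9), contrast = "FA")
  expect_identical(normalize_intensity(fa, ref), fa)
  expect_error(normalize_intensity(s, as_roi_sample(c(-2, 0))), "positive")
})

test_that("distribution averaging weights ROIs equally and normalises", {
  set.seed(14)
  v <- rnorm(400)
  s1 <- as_roi_sample(v)
  d1 <- average_distributions(list(s1), n_bins = 32)
  w <- diff(d1$edges)
  expect_equal(sum(d1$density * w), 1, tolerance = 1e-9)
  expect_true(all(d1$density >= 0))
  expect_true(all(diff(d1$edges) > 0))
  # two ROIs of unequal size but identical value sets match a single ROI
  s2 <- as_roi_sample(rep(v, 3))
  d12 <- average_distributions(list(s1, s2), edges = d1$edges)
  expect_equal(d12$density, d1$density, tolerance = 1e-12)
  expect_equal(d12$n_rois, 2L)
  # two disjoint uniform ROIs average to a bimodal density of equal mass
  u1 <- as_roi_sample(seq(0.005, 0.995, length.out = 200))
  u2 <- as_roi_sample(seq(2.005, 2.995, length.out = 200))
  edges <- seq(0, 3, length.out = 61)
  du <- average_distributions(list(u1, u2), edges = edges)
  wq <- diff(edges)
  lower <- sum((du$density * wq)[edges[-1] <= 1])
  upper <- sum((du$density * wq)[edges[-61] >= 2])
  expect_equal(lower, 0.5, tolerance = 1e-9)
  expect_equal(upper, 0.5, tolerance = 1e-9)
  # degenerate input falls back to a flagged single bin
  be <- common_bin_edges(list(as_roi_sample(rep(1, 10))))
  expect_true(be$degenerate)
  expect_length(be$edges, 2L)
})

test_that("ROC thresholds separate distributions with correct polarity", {
  edges <- seq(0, 1, length.out = 65)
  mk <- function(lo, hi, contrast = "X") {
    d <- as.numeric(edges[-1] > lo & edges[-65] < hi)
    structure(list(edges = edges, density = d / sum(d * diff(edges)),
                   n_rois = 1L, contrast = contrast, class = "c",
                   degenerate = FALSE), class = "avg_distribution")
  }
  # fully separated: AUC 1, threshold strictly between the supports
  th <- roc_threshold(mk(0, 0.4), mk(0.6, 1))
  expect_equal(th$auc, 1, tolerance = 1e-12)
  expect_gt(th$threshold, 0.4 - 1e-9)
  expect_lt(th$threshold, 0.6 + 1e-9)
  expect_equal(th$polarity, "high")
  # identical distributions: AUC 1/2
  expect_equal(roc_threshold(mk(0.2, 0.8), mk(0.2, 0.8))$auc, 0.5,
               tolerance = 1e-12)
  # flipped contrast (FLAIR-like): polarity low, AUC still above 1/2
  th2 <- roc_threshold(mk(0.6, 1), mk(0, 0.4))
  expect_equal(th2$polarity, "low")
  expect_equal(th2$auc, 1, tolerance = 1e-12)
  expect_error(roc_threshold(mk(0, 0.4),
                             structure(list(edges = edges + 1,
                                            density = mk(0, 0.4)$density,
                                            contrast = "X"),
                                       class = "avg_distribution")),
               "edges")
})

test_that("binned ROC matches the Gaussian closed form and brute force", {
  edges <- seq(-1.5, 2.5, length.out = 257)
  mid <- (edges[-1] + edges[-257]) / 2
  w <- diff(edges)
  gauss_dist <- function(m) {
    d <- dnorm(mid, m, 0.5)
    structure(list(edges = edges, density = d / sum(d * w), n_rois = 1L,
                   contrast = "X", class = "c", degenerate = FALSE),
              class = "avg_distribution")
  }
  dc <- gauss_dist(0); dw <- gauss_dist(1)
  th <- roc_threshold(dc, dw)
  expect_lt(abs(th$auc - pnorm(1 / (0.5 * sqrt(2)))), 0.01)
  # exhaustive brute-force sweep over every bin edge
  mc <- dc$density * w; mw <- dw$density * w
  J <- vapply(seq_along(edges), function(k) {
    above_w <- if (k <= 256) sum(mw[k:256]) else 0
    above_c <- if (k <= 256) sum(mc[k:256]) else 0
    above_w - above_c
  }, numeric(1))
  expect_equal(th$threshold, edges[which.max(J)])
  expect_equal(th$youden, max(J), tolerance = 1e-12)
  # AUC also agrees with the exhaustive pairwise-comparison estimator
  pairwise <- sum(outer(mw, mc) * outer(mid, mid, `>`)) +
    0.5 * sum(mw * mc)
  expect_lt(abs(th$auc - pairwise), 1 / 256)
})

test_that("white-matter percentages follow the tie and polarity rules", {
  th <- structure(list(contrast = "X", threshold = 0.5, polarity = "high",
                       auc = 1, youden = 1), class = "threshold_result")
  expect_equal(classify_wm_percent(c(0.6, 0.9, 2), th)$wm_percent, 100)
  expect_equal(classify_wm_percent(c(0.1, 0.4), th)$wm_percent, 0)
  # a value exactly at the threshold counts as cortex-like
  expect_equal(classify_wm_percent(c(0.5, 0.6), th)$wm_percent, 50)
  thl <- th; thl$polarity <- "low"
  expect_equal(classify_wm_percent(c(0.4, 0.6), thl)$wm_percent, 50)
  expect_error(classify_wm_percent(numeric(0), th), "empty")
  # invariance under a joint strictly monotone transform
  set.seed(3)
  v <- rnorm(200)
  f <- function(x) x^3 + 2 * x
  th2 <- th; th2$threshold <- f(0.5)
  expect_equal(classify_wm_percent(v, th)$wm_percent,
               classify_wm_percent(f(v), th2)$wm_percent)
})
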