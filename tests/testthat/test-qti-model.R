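protocol <- default_protocol(1)
design <- qti_design(protocol)

test_that("signal prediction matches its closed-form limits", {
  # mono-exponential limit: C = 0, isotropic mean tensor
  th <- c(log(2), voigt6(0.8 * diag(3)), rep(0, 21))
  s <- qti_predict(th, protocol)
  expect_equal(s, 2 * exp(-protocol$b * 0.8), tolerance = 1e-12)
  # b = 0 gives S0 for arbitrary parameters
  set.seed(2)
  th2 <- rand_theta()
  expect_equal(qti_predict(th2, protocol)[protocol$b == 0],
               rep(exp(th2[1]), sum(protocol$b == 0)), tolerance = 1e-12)
  # single Gaussian tensor under linear encoding: direct contraction oracle
  D <- axisym_tensor(2.2, 0.2, c(0, 1, 1) / sqrt(2))
  th3 <- c(0, voigt6(D), rep(0, 21))
  s3 <- qti_predict(th3, protocol)
  oracle <- vapply(protocol$btensors, function(bt)
    exp(-sum(bt$matrix * D)), numeric(1))
  expect_equal(s3, oracle, tolerance = 1e-12)
})

test_that("noiseless fits recover the identifiable projection and metrics", {
  set.seed(31)
  for (i in 1:40) {
    td <- rand_mixture()
    mom <- td_moments(td)
    th <- c(log(runif(1, 0.5, 2)), mom$d6, mom$c21)
    f <- qti_fit(qti_predict(th, protocol, design), protocol,
                 design = design)
    expect_true(f$valid)
    expect_equal(f$rank, 23L)
    est <- c(f$log_s0, f$d6, f$c21)
    proj <- qti_identifiable(th, protocol)
    expect_lt(max(abs(est - proj)) / max(abs(proj)), 1e-8)
    # mean tensor and S0 are fully identifiable
    expect_lt(max(abs(est[1:7] - th[1:7])) / max(abs(th[1:7])), 1e-8)
    # every scalar metric is exact although 5 of the 21 covariance
    # components are invisible to linear + spherical encoding
    mt <- unlist(qti_metrics(list(d6 = mom$d6, c21 = mom$c21)))
    me <- unlist(qti_metrics(f))
    expect_equal(me[1:7], mt[1:7], tolerance = 1e-8)
  }
})

test_that("degenerate inputs yield flagged, not thrown, fits", {
  # constant signals: zero diffusivity and covariance
  f <- qti_fit(rep(1.7, 58), protocol, design = design)
  expect_true(f$valid)
  expect_equal(exp(f$log_s0), 1.7, tolerance = 1e-10)
  expect_lt(max(abs(f$d6)), 1e-10)
  expect_lt(max(abs(f$c21)), 1e-10)
  # fewer than 28 usable measurements
  s <- qti_predict(c(0, voigt6(diag(3) * 0.7), rep(0, 21)), protocol)
  s[1:40] <- -1
  f2 <- qti_fit(s, protocol, design = design)
  expect_false(f2$valid)
  # rank-deficient (linear-only) protocol: invalid, no exception
  lp <- build_protocol(data.frame(shape = "linear",
                                  b = c(0.5, 1, 1.5, 2), n = c(8, 8, 8, 8)),
                       n_b0 = 2, for_fitting = FALSE)
  f3 <- qti_fit(td_signal(dispersed_distribution(2, 0.3, "crossing"), lp),
                lp)
  expect_false(f3$valid)
  expect_lt(f3$rank, 23L)
  expect_error(qti_fit(rep(1, 10), protocol), "length")
})

test_that("scalar metrics match closed-form single-voxel limits", {
  stick <- qti_metrics(list(d6 = voigt6(diag(c(1, 0, 0))), c21 = rep(0, 21)))
  expect_equal(stick$fa, 1, tolerance = 1e-10)
  expect_equal(stick$md, 1 / 3, tolerance = 1e-10)
  expect_equal(stick$mk_a, 2.4, tolerance = 1e-10)    # (6/5) V_l / MD^2
  expect_equal(stick$mk_i, 0, tolerance = 1e-10)
  iso <- qti_metrics(list(d6 = voigt6(0.7 * diag(3)), c21 = rep(0, 21)))
  expect_equal(iso$fa, 0, tolerance = 1e-12)
  expect_equal(iso$mk_a, 0, tolerance = 1e-12)
  expect_equal(iso$mk_i, 0, tolerance = 1e-12)
  cross <- td_metrics(dispersed_distribution(1, 0, "crossing"))
  expect_equal(cross$fa, sqrt(0.5), tolerance = 1e-10)
  expect_equal(cross$mk_a, 2.4, tolerance = 1e-10)
  # MD <= 0 marks the voxel undefined
  bad <- qti_metrics(list(d6 = rep(0, 6), c21 = rep(0, 21)))
  expect_true(all(is.na(unlist(bad))))
})

test_that("shear projection equals the eigenvalue variance of a tensor", {
  # (D (x) D) :: E_shear must reproduce the direct eigenvalue variance
  set.seed(8)
  for (i in 1:20) {
    D <- crossprod(matrix(rnorm(9), 3))
    m <- qti_metrics(list(d6 = voigt6(D), c21 = rep(0, 21)))
    lam <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(m$v_lambda, mean((lam - mean(lam))^2), tolerance = 1e-10)
    expect_equal(m$mk_t, m$mk_i + m$mk_a, tolerance = 1e-12)
  }
})

test_that("MK_A is invariant to orientation dispersion while FA collapses", {
  fas <- mkas <- numeric(3)
  modes <- c("coherent", "crossing", "uniform")
  for (j in seq_along(modes)) {
    m <- td_metrics(dispersed_distribution(2.2, 0.2, modes[j]))
    fas[j] <- m$fa; mkas[j] <- m$mk_a
  }
  expect_lt(max(mkas) - min(mkas), 1e-10)
  expect_true(all(diff(fas) < 0))
  # stick mixtures reach the closed-form FA values
  stick_fas <- vapply(modes, function(md)
    td_metrics(dispersed_distribution(1, 0, md))$fa, numeric(1))
  expect_equal(unname(stick_fas[1:2]), c(1, sqrt(0.5)), tolerance = 1e-10)
  expect_lt(stick_fas[3], 0.3)
})

test_that("cumulant truncation bias in MK_A shrinks monotonically with b", {
  td <- dispersed_distribution(2.2, 0.2, "crossing")
  truth <- td_metrics(td)$mk_a
  bias <- vapply(c(2.0, 1.0, 0.5), function(bm) {
    sh <- data.frame(shape = c(rep("linear", 4), rep("spherical", 4)),
                     b = bm * c(0.05, 0.35, 0.7, 1, 0.05, 0.35, 0.7, 1),
                     n = c(6, 6, 10, 16, 3, 3, 6, 6))
    pp <- build_protocol(sh, n_b0 = 2, seed = 3)
    abs(qti_metrics(qti_fit(td_signal(td, pp), pp))$mk_a - truth)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("volume fits reproduce per-voxel truth and isolate bad voxels", {
  dm <- c(5L, 4L, 3L)
  tds <- list(dispersed_distribution(2.2, 0.2, "coherent"),
              dispersed_distribution(1.2, 0.7, "uniform"),
              dispersed_distribution(3, 3, "coherent"))
  cls <- array(rep(1:3, length.out = prod(dm)), dm)
  # cumulant-form signals: the fit then reproduces the ground-truth moment
  # metrics to numerical precision (exact-mixture signals instead carry the
  # truncation bias covered elsewhere)
  sig <- t(vapply(tds, function(td) {
    mom <- td_moments(td)
    qti_predict(c(0, mom$d6, mom$c21), protocol)
  }, numeric(58)))
  M <- matrix(0, prod(dm), 58L)
  for (k in 1:3) M[cls == k, ] <- matrix(sig[k, ], sum(cls == k), 58,
                                         byrow = TRUE)
  data <- array(M, c(dm, 58L))
  # poison one voxel with non-positive signals
  data[2, 2, 2, 1:35] <- 0
  fit <- qti_fit_volume(data, protocol, mask = array(TRUE, dm))
  expect_false(fit$valid[2, 2, 2])
  expect_true(all(fit$valid[-match(2 + 5 * 1 + 20 * 1, seq_len(prod(dm)))]))
  gt_mka <- vapply(tds, function(td) td_metrics(td)$mk_a, numeric(1))
  gt_fa <- vapply(tds, function(td) td_metrics(td)$fa, numeric(1))
  for (k in 1:3) {
    ok <- cls == k & fit$valid
    expect_lt(max(abs(fit$mk_a[ok] - gt_mka[k])), 1e-6)
    expect_lt(max(abs(fit$fa[ok] - gt_fa[k])), 1e-6)
  }
  # all-zero mask: empty outputs, no failure
  empty <- qti_fit_volume(data, protocol, mask = array(FALSE, dm))
  expect_length(empty$voxels, 0L)
  expect_true(all(is.na(empty$md)))
  # grid mismatch
  expect_error(qti_fit_volume(data, protocol,
                              mask = array(TRUE, c(4, 4, 3))), "grid")
})

test_that("tensor distributions validate and expose exact moments", {
  expect_error(tensor_distribution(c(1, -1), list(diag(3), diag(3))),
               "non-negative")
  expect_error(tensor_distribution(1, list(diag(c(1, 1, -1)))),
               "semidefinite")
  set.seed(12)
  td <- rand_mixture()
  mom <- td_moments(td)
  # brute-force moment oracle over components
  d_direct <- Reduce(`+`, Map(function(w, D) w * D, td$weights, td$tensors))
  expect_equal(voigt6_inv(mom$d6), d_direct, tolerance = 1e-12)
  C_direct <- Reduce(`+`, Map(function(w, D) {
    v <- voigt6(D); w * tcrossprod(v)
  }, td$weights, td$tensors)) - tcrossprod(mom$d6)
  expect_equal(voigt21_inv(mom$c21), C_direct, tolerance = 1e-12)
  # signal equals the weighted sum of component mono-exponentials
  s <- td_signal(td, protocol, s0 = 1.4)
  oracle <- 1.4 * vapply(protocol$btensors, function(bt)
    sum(td$weights * vapply(td$tensors, function(D)
      exp(-sum(bt$matrix * D)), numeric(1))), numeric(1))
  expect_equal(s, oracle, tolerance = 1e-12)
})

test_that("adding isotropic spread raises V_I by the requested amount", {
  td <- dispersed_distribution(2.2, 0.2, "crossing")
  v0 <- td_metrics(td)$v_i
  td2 <- with_md_spread(td, 0.05)
  expect_equal(td_metrics(td2)$v_i - v0, 0.05, tolerance = 1e-10)
  expect_equal(td_metrics(td2)$md, td_metrics(td)$md, tolerance = 1e-12)
})
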