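spec <- small_spec(seed = 7, lesions = list("PH", "SH"))
lm <- build_labelmap(spec)
micro <- assign_microstructure(lm, spec)

test_that("label maps are deterministic and geometrically consistent", {
  lm2 <- build_labelmap(small_spec(seed = 7, lesions = list("PH", "SH")))
  expect_identical(lm$labels, lm2$labels)
  expect_setequal(lm$lesion_types, c("PH", "SH"))
  labs <- sort(unique(as.vector(lm$labels)))
  expect_true(all(c(0:4, 11, 12) %in% labs))
  # every ROI is non-empty and the reference avoids the lesions
  expect_true(all(vapply(lm$rois, sum, numeric(1)) > 0))
  expect_equal(sum(lm$rois$reference & lm$rois$lesion_SH), 0L)
  # periventricular nodules touch the ventricular CSF (6-adjacency)
  csf <- lm$labels == 1L
  touch <- array(FALSE, dim(csf))
  for (ax in 1:3) for (s in c(-1L, 1L))
    touch <- touch | qtimcd:::.shift3(csf, ax, s)
  expect_gt(sum(touch & lm$rois$lesion_PH), 0L)
})

test_that("the designed white-matter-like lesion fraction is exact", {
  n_sh <- sum(lm$rois$lesion_SH)
  f_wm <- spec$lesions[[2]]$f_wm
  expect_equal(sum(micro$wm_like$SH), round(f_wm * n_sh))
  expect_true(all(micro$wm_like$SH[!lm$rois$lesion_SH] == FALSE))
  # WM-like lesion voxels carry the coherent-WM distribution, the rest the
  # cortex distribution
  wm_cls <- match("wm_coherent", micro$class_names)
  ctx_cls <- match("cortex", micro$class_names)
  expect_true(all(micro$class_map[micro$wm_like$SH] == wm_cls))
  rest <- lm$rois$lesion_SH & !micro$wm_like$SH
  expect_true(all(micro$class_map[rest] == ctx_cls))
})

test_that("an empty lesion list produces a normal-brain phantom", {
  lm0 <- build_labelmap(small_spec(seed = 7, lesions = list()))
  expect_length(lm0$lesion_types, 0L)
  expect_true(all(lm0$labels <= 4L))
})

test_that("ground-truth metric volumes equal the distribution moments", {
  for (k in seq_along(micro$classes)) {
    m <- td_metrics(micro$classes[[k]])
    idx <- micro$class_map == k
    if (!any(idx)) next
    expect_lt(max(abs(micro$gt$mk_a[idx] - m$mk_a)), 1e-10)
    expect_lt(max(abs(micro$gt$fa[idx] - m$fa)), 1e-10)
    expect_lt(max(abs(micro$gt$md[idx] - m$md)), 1e-10)
  }
  # contrast ordering built into the tissue table
  wm <- td_metrics(micro$classes$wm_coherent)
  wx <- td_metrics(micro$classes$wm_crossing)
  ctx <- td_metrics(micro$classes$cortex)
  csf <- td_metrics(micro$classes$csf)
  expect_gt(wm$mk_a, ctx$mk_a)
  expect_equal(wx$mk_a, wm$mk_a, tolerance = 1e-12)
  expect_lt(wx$fa, wm$fa)
  expect_equal(csf$fa, 0, tolerance = 1e-12)
  expect_equal(csf$mk_a, 0, tolerance = 1e-12)
})

test_that("simulated dMRI is seed-reproducible with exact noiseless limit", {
  p <- default_protocol(7)
  d1 <- generate_dwi(micro, p, snr = 30, seed = 5)
  d2 <- generate_dwi(micro, p, snr = 30, seed = 5)
  expect_identical(d1, d2)
  d3 <- generate_dwi(micro, p, snr = 30, seed = 6)
  expect_false(identical(d1, d3))
  # noiseless data equal the per-class mixture signals exactly
  d0 <- generate_dwi(micro, p, snr = 30, seed = 5, noise = "none")
  wm_idx <- which(micro$class_map == match("wm_coherent",
                                           micro$class_names))[1]
  arr <- matrix(d0, prod(dim(micro$class_map)), length(p$btensors))
  expect_equal(arr[wm_idx, ],
               td_signal(micro$classes$wm_coherent, p), tolerance = 1e-12)
  expect_error(generate_dwi(micro, p, snr = -1, seed = 1), "snr > 0")
})

test_that("b0 noise follows the closed-form Rician mean", {
  p <- build_protocol(data.frame(shape = c("linear", "spherical"),
                                 b = c(1, 1), n = c(1, 1)),
                      n_b0 = 40, seed = 1)
  d <- generate_dwi(micro, p, snr = 10, seed = 9)
  wm_idx <- micro$class_map == match("wm_coherent", micro$class_names)
  b0 <- d[, , , p$b == 0][rep(wm_idx, sum(p$b == 0))]
  expect_equal(mean(b0), rice_mean(1, 1 / 10), tolerance = 0.01)
})

test_that("pseudo-structural contrasts encode the myelin dissociation", {
  st <- generate_structural(lm, spec, seed = 3)
  ctx <- lm$labels == 2L; wm <- lm$labels == 3L
  les <- lm$rois$lesion_SH
  ts <- spec$tissues
  # lesions always cortex-like in structural intensity
  expect_lt(abs(mean(st$t1w[les]) - mean(st$t1w[ctx])), ts$cortex$t1w_sd)
  expect_gt(mean(st$t1w[wm]), mean(st$t1w[ctx]))
  expect_lt(mean(st$flair[wm]), mean(st$flair[ctx]))
  # T1w/FLAIR ratio contrast is maximal in the highest-myelin tissue
  # (white matter); ratio of ROI means, robust to near-zero FLAIR noise
  rom <- function(m) mean(st$t1w[m]) / mean(st$flair[m])
  means <- c(csf = rom(lm$labels == 1L), cortex = rom(ctx), wm = rom(wm),
             dgm = rom(lm$labels == 4L))
  expect_equal(names(which.max(means)), "wm")
  st2 <- generate_structural(lm, spec, seed = 3)
  expect_identical(st$t1w, st2$t1w)
})

test_that("full phantoms assemble reproducibly from spec and seed", {
  ph1 <- build_phantom(small_spec(seed = 3), noise = "rician")
  ph2 <- build_phantom(small_spec(seed = 3), noise = "rician")
  expect_identical(ph1$dwi, ph2$dwi)
  expect_identical(ph1$t1w, ph2$t1w)
  expect_equal(dim(ph1$dwi)[4], length(ph1$protocol$btensors))
  expect_error(phantom_spec(lesions = list("SH", "SH")), "one lesion")
  expect_error(lesion_spec("SH", f_wm = 1.2), "0, 1")
})
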