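#' Default tissue parameter table for the digital MCD phantom
#'
#' Per-label microstructure and pseudo-structural parameters: component
#' diffusivities (um^2/ms), orientation-dispersion mode, added isotropic
#' variance, a myelin surrogate in `[0, 1]`, and pseudo-T1w / pseudo-FLAIR
#' intensity means and SDs (arbitrary units).  Values are plausible
#' adult-brain defaults chosen to give the normal cortex/white-matter
#' contrast ordering of all four contrasts: pseudo-T1w increases and
#' pseudo-FLAIR decreases with the myelin surrogate, white matter carries
#' high microscopic anisotropy (coherent or crossing), cortex and deep gray
#' matter carry low microscopic anisotropy with uniform dispersion, and CSF
#' is fast isotropic.
#'
#' @return named list of per-tissue parameter lists.
#' @export
default_tissue_table <- function() {
  list(
    csf = list(axial = 3.0, radial = 3.0, mode = "coherent", v_iso = 0,
               myelin = 0.02, t1w_mean = 0.20, t1w_sd = 0.03,
               flair_mean = 0.10, flair_sd = 0.03),
    cortex = list(axial = 1.2, radial = 0.7, mode = "uniform", v_iso = 0,
                  myelin = 0.30, t1w_mean = 0.55, t1w_sd = 0.03,
                  flair_mean = 0.75, flair_sd = 0.04),
    wm = list(axial = 2.2, radial = 0.2, mode = "coherent", v_iso = 0,
              myelin = 0.85, t1w_mean = 0.95, t1w_sd = 0.03,
              flair_mean = 0.45, flair_sd = 0.03),
    deep_gm = list(axial = 1.4, radial = 0.65, mode = "uniform", v_iso = 0,
                   myelin = 0.40, t1w_mean = 0.62, t1w_sd = 0.03,
                   flair_mean = 0.68, flair_sd = 0.04))
}

#' Lesion specification for the digital MCD phantom
#'
#' Procedural, coarse lesion geometries mirroring the four MCD types:
#' periventricular heterotopia (`PH`, a nodule on the ventricular border),
#' subcortical heterotopia (`SH`, a patch within deep white matter), focal
#' cortical dysplasia (`FCD`, a wedge blurring the gray-white boundary) and
#' polymicrogyria (`PMG`, a ribbon along the inner cortical surface).
#' Lesion voxels always receive cortex-like structural intensity; a designed
#' fraction `f_wm` of them receives white-matter-like microstructure (high
#' microscopic anisotropy), assigned to the voxels deepest from the cortex.
#' The `f_wm` defaults per type follow the relative per-type heterogeneity
#' the method is meant to expose (low in PH, substantial in SH/FCD/PMG).
#'
#' @param type one of `"PH"`, `"SH"`, `"FCD"`, `"PMG"`.
#' @param f_wm designed white-matter-like voxel fraction in `[0, 1]`.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(type = c("PH", "SH", "FCD", "PMG"), f_wm = NULL) {
  type <- match.arg(type)
  if (is.null(f_wm))
    f_wm <- c(PH = 0.13, SH = 0.40, FCD = 0.29, PMG = 0.44)[[type]]
  if (f_wm < 0 || f_wm > 1) stop("f_wm must lie in [0, 1]")
  structure(list(type = type, f_wm = f_wm), class = "lesion_spec")
}

#' Digital MCD phantom specification
#'
#' Fixes the grid, voxel size, tissue table, lesion list, SNR at b = 0 and
#' the master seed; all phantom randomness is deterministic given the spec.
#'
#' @param dim grid dimensions (3 integers).
#' @param voxel voxel size in mm (default 2 x 2 x 4).
#' @param lesions list of [lesion_spec()] objects (or type strings); at most
#'   one lesion per type.
#' @param tissues tissue table, see [default_tissue_table()].
#' @param snr signal-to-noise ratio at b = 0 in normal white matter.
#' @param seed master seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(40L, 40L, 20L), voxel = c(2, 2, 4),
                         lesions = list("PH", "SH", "FCD", "PMG"),
                         tissues = default_tissue_table(),
                         snr = 30, seed = 1L) {
  stopifnot(length(dim) == 3L, all(dim >= 8), length(voxel) == 3L,
            all(voxel > 0), snr > 0)
  lesions <- lapply(lesions, function(l)
    if (inherits(l, "lesion_spec")) l else lesion_spec(l))
  types <- vapply(lesions, `[[`, character(1), "type")
  if (anyDuplicated(types)) stop("at most one lesion per type")
  stopifnot(all(c("csf", "cortex", "wm", "deep_gm") %in% names(tissues)))
  structure(list(dim = as.integer(dim), voxel = voxel, lesions = lesions,
                 tissues = tissues, snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

# label codes
PHANTOM_LABELS <- c(background = 0L, csf = 1L, cortex = 2L, wm = 3L,
                    deep_gm = 4L)
.lesion_label <- function(i) 10L + i

# normalised voxel-centre coordinates in [-1, 1]^3
.ph_coords <- function(dm) {
  ax <- function(n) if (n > 1) (2 * seq_len(n) - n - 1) / (n - 1) else 0
  list(x = array(rep(ax(dm[1]), times = dm[2] * dm[3]), dm),
       y = array(rep(rep(ax(dm[2]), each = dm[1]), times = dm[3]), dm),
       z = array(rep(ax(dm[3]), each = dm[1] * dm[2]), dm))
}

.in_ellipsoid <- function(co, centre, semi) {
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

# cone of half-angle acos(cmin) around direction d, radial band (r0, r1]
# (band measured on the brain-scaled radius r, cone on true angles)
.in_wedge <- function(co, r, d, cmin, r0, r1) {
  d <- d / sqrt(sum(d^2))
  rr <- sqrt(co$x^2 + co$y^2 + co$z^2)
  ip <- (co$x * d[1] + co$y * d[2] + co$z * d[3]) / pmax(rr, 1e-9)
  ip > cmin & r > r0 & r <= r1
}

#' Build the phantom label map and its regions of interest
#'
#' Deterministic geometry: an ellipsoidal brain with a cortical shell, two
#' lateral ventricles (CSF), deep gray nuclei and white matter, plus the
#' requested lesions in the right (`x > 0`) hemisphere.  Emits, per lesion,
#' the lesion ROI, a contralateral normal-cortex ROI, an adjacent
#' normal-white-matter ROI, and one shared anterior deep-white-matter
#' reference ROI (anterior corona radiata stand-in).
#'
#' @param spec a [phantom_spec()].
#' @return list with `labels` (3-D integer array), `label_table`, `rois`
#'   (named list of logical arrays: `lesion_<type>`, `cortex_<type>`,
#'   `wm_<type>`, `reference`), and `lesion_types`.
#' @export
build_labelmap <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$dim
  co <- .ph_coords(dm)
  r <- sqrt((co$x / 0.92)^2 + (co$y / 0.92)^2 + (co$z / 0.92)^2)
  brain <- r <= 1
  labels <- array(PHANTOM_LABELS[["background"]], dm)
  labels[brain] <- PHANTOM_LABELS[["wm"]]
  labels[brain & r > 0.78] <- PHANTOM_LABELS[["cortex"]]
  csf <- (.in_ellipsoid(co, c(0.18, -0.05, 0), c(0.10, 0.28, 0.22)) |
            .in_ellipsoid(co, c(-0.18, -0.05, 0), c(0.10, 0.28, 0.22))) &
    labels == PHANTOM_LABELS[["wm"]]
  labels[csf] <- PHANTOM_LABELS[["csf"]]
  dgm <- (.in_ellipsoid(co, c(0.45, 0.12, 0), c(0.09, 0.13, 0.15)) |
            .in_ellipsoid(co, c(-0.45, 0.12, 0), c(0.09, 0.13, 0.15))) &
    labels == PHANTOM_LABELS[["wm"]]
  labels[dgm] <- PHANTOM_LABELS[["deep_gm"]]

  wm_lab <- PHANTOM_LABELS[["wm"]]
  lesion_masks <- list()
  for (les in spec$lesions) {
    m <- switch(les$type,
      PH = .in_ellipsoid(co, c(0.31, -0.20, 0), c(0.13, 0.13, 0.20)) &
        labels == wm_lab,
      SH = .in_ellipsoid(co, c(0.44, 0.32, 0.05), c(0.19, 0.16, 0.34)) &
        labels == wm_lab,
      FCD = .in_wedge(co, r, c(0.55, -0.75, 0.35), 0.85, 0.70, 0.84) &
        co$x > 0 & labels %in% c(wm_lab, PHANTOM_LABELS[["cortex"]]),
      PMG = .in_wedge(co, r, c(0.15, 0.95, 0), 0.85, 0.72, 0.82) &
        co$x > 0 & labels %in% c(wm_lab, PHANTOM_LABELS[["cortex"]]))
    if (!any(m)) stop("lesion ", les$type, " does not fit inside the grid")
    lesion_masks[[les$type]] <- m
  }
  if (length(lesion_masks) > 1L) {
    tot <- Reduce(`+`, lesion_masks)
    if (any(tot > 1)) stop("overlapping lesion specifications")
  }
  for (i in seq_along(lesion_masks))
    labels[lesion_masks[[i]]] <- .lesion_label(i)

  cortex <- labels == PHANTOM_LABELS[["cortex"]]
  rois <- list()
  for (i in seq_along(lesion_masks)) {
    type <- names(lesion_masks)[i]
    m <- lesion_masks[[i]]
    rois[[paste0("lesion_", type)]] <- m
    # contralateral normal cortex: nearest cortex voxels to the mirrored
    # lesion centroid
    idx <- which(m)
    cx <- c(mean(co$x[idx]), mean(co$y[idx]), mean(co$z[idx]))
    mcx <- c(-cx[1], cx[2], cx[3])
    cidx <- which(cortex & co$x < 0)
    d2 <- (co$x[cidx] - mcx[1])^2 + (co$y[cidx] - mcx[2])^2 +
      (co$z[cidx] - mcx[3])^2
    take <- cidx[order(d2)][seq_len(min(length(cidx),
                                        max(80L, min(sum(m), 200L))))]
    rc <- array(FALSE, dm); rc[take] <- TRUE
    rois[[paste0("cortex_", type)]] <- rc
    # adjacent normal-appearing white matter: dilated lesion shell in WM
    shell <- .dilate_box(m, 2L) & labels == wm_lab
    if (sum(shell) < 30L) shell <- .dilate_box(m, 3L) & labels == wm_lab
    rois[[paste0("wm_", type)]] <- shell
  }
  ref <- labels == wm_lab & co$y > 0.30 & r < 0.68 &
    abs(co$x) > 0.05 & abs(co$x) < 0.55
  if (length(lesion_masks))
    for (m in lesion_masks) ref <- ref & !.dilate_box(m, 2L)
  rois[["reference"]] <- ref
  list(labels = labels, label_table = PHANTOM_LABELS, rois = rois,
       lesion_types = names(lesion_masks))
}

# Chebyshev (box) dilation of a logical 3-D mask by k voxels
.dilate_box <- function(mask, k) {
  dm <- dim(mask)
  out <- mask
  for (ax in 1:3) {
    acc <- out
    for (s in seq_len(k)) {
      lo <- .shift3(out, ax, s)
      hi <- .shift3(out, ax, -s)
      acc <- acc | lo | hi
    }
    out <- acc
  }
  out
}

# shift a 3-D array along axis `ax` by `s` voxels, zero/FALSE fill
.shift3 <- function(a, ax, s) {
  dm <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dm)
  n <- dm[ax]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  ix <- function(which) switch(ax, list(which, TRUE, TRUE),
                               list(TRUE, which, TRUE),
                               list(TRUE, TRUE, which))
  do.call(`[<-`, c(list(out), ix(dst),
                   list(do.call(`[`, c(list(a), ix(src), list(drop = FALSE))))))
}

#' Assign ground-truth microstructure to a phantom label map
#'
#' Every tissue class receives a [tensor_distribution()]: white matter a
#' coherent high-anisotropy mixture (crossing in the posterior region),
#' cortex and deep gray matter low-anisotropy mixtures with uniform
#' dispersion, CSF a fast isotropic tensor.  Lesion voxels keep cortex-like
#' structural intensity but a designed fraction `f_wm` (deepest voxels,
#' exact count `round(f_wm * n)`) is given the white-matter-like
#' distribution — the dissociation between myelin-driven structural contrast
#' and axon-driven microscopic anisotropy.
#'
#' @param labelmap result of [build_labelmap()].
#' @param spec the [phantom_spec()].
#' @return list with `class_map` (3-D integer array, 0 = background),
#'   `classes` (list of `tensor_distribution`), `class_names`,
#'   `wm_like` (named per-lesion logical arrays of WM-like voxels), and
#'   ground-truth metric volumes `gt` (`md`, `fa`, `mk_a`, `mk_i`, `ufa`).
#' @export
assign_microstructure <- function(labelmap, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- labelmap$labels
  dm <- dim(labels)
  ts <- spec$tissues
  mk_td <- function(p, direction = c(1, 0, 0)) {
    td <- dispersed_distribution(p$axial, p$radial, p$mode, direction)
    if (p$v_iso > 0) td <- with_md_spread(td, p$v_iso)
    td
  }
  classes <- list(
    csf = mk_td(ts$csf),
    cortex = mk_td(ts$cortex),
    wm_coherent = mk_td(ts$wm, direction = c(1, 0, 0)),
    wm_crossing = {
      p <- ts$wm
      td <- dispersed_distribution(p$axial, p$radial, "crossing",
                                   direction = c(1, 0, 0))
      if (p$v_iso > 0) td <- with_md_spread(td, p$v_iso)
      td
    },
    deep_gm = mk_td(ts$deep_gm))
  cls <- array(0L, dm)
  cid <- function(nm) match(nm, names(classes))
  co <- .ph_coords(dm)
  cls[labels == PHANTOM_LABELS[["csf"]]] <- cid("csf")
  cls[labels == PHANTOM_LABELS[["cortex"]]] <- cid("cortex")
  cls[labels == PHANTOM_LABELS[["deep_gm"]]] <- cid("deep_gm")
  wm <- labels == PHANTOM_LABELS[["wm"]]
  cls[wm] <- cid("wm_coherent")
  cls[wm & co$y < -0.45] <- cid("wm_crossing")

  # lesions: cortex-like microstructure except for the designed fraction,
  # assigned to the voxels farthest from the cortical shell
  cortex_idx <- which(labels == PHANTOM_LABELS[["cortex"]])
  cc <- cbind(co$x[cortex_idx], co$y[cortex_idx], co$z[cortex_idx])
  wm_like <- list()
  for (i in seq_along(labelmap$lesion_types)) {
    type <- labelmap$lesion_types[i]
    f_wm <- spec$lesions[[which(vapply(spec$lesions, `[[`, character(1),
                                       "type") == type)]]$f_wm
    lidx <- which(labels == .lesion_label(i))
    cls[lidx] <- cid("cortex")
    n_wm <- round(f_wm * length(lidx))
    wl <- array(FALSE, dm)
    if (n_wm > 0) {
      lp <- cbind(co$x[lidx], co$y[lidx], co$z[lidx])
      dmin <- vapply(seq_along(lidx), function(j)
        min((cc[, 1] - lp[j, 1])^2 + (cc[, 2] - lp[j, 2])^2 +
              (cc[, 3] - lp[j, 3])^2), numeric(1))
      deep <- lidx[order(-dmin, lidx)][seq_len(n_wm)]
      cls[deep] <- cid("wm_coherent")
      wl[deep] <- TRUE
    }
    wm_like[[type]] <- wl
  }

  mets <- lapply(classes, td_metrics)
  gt_map <- function(field) {
    a <- array(NA_real_, dm)
    for (k in seq_along(classes))
      a[cls == k] <- mets[[k]][[field]]
    a
  }
  list(class_map = cls, classes = classes, class_names = names(classes),
       wm_like = wm_like,
       gt = list(md = gt_map("md"), fa = gt_map("fa"),
                 mk_a = gt_map("mk_a"), mk_i = gt_map("mk_i"),
                 ufa = gt_map("ufa")))
}

#' Simulate tensor-valued dMRI signals for a phantom
#'
#' Per voxel the exact multi-Gaussian mixture signal
#' `s(B) = sum_k w_k exp(-B : D_k)` (not its cumulant truncation) with
#' S0 = 1 in all tissue, plus Rician noise: the magnitude of
#' `(s + e1, e2)` with `e ~ N(0, S0_WM / SNR)`.  Deterministic given
#' `seed`.
#'
#' @param micro result of [assign_microstructure()].
#' @param protocol a `qti_protocol`.
#' @param snr SNR at b = 0 relative to the white-matter S0 (= 1).
#' @param seed integer seed.
#' @param noise `"rician"` (default), `"gaussian"` (analytic checks) or
#'   `"none"`.
#' @return 4-D array `(x, y, z, volume)`.
#' @export
generate_dwi <- function(micro, protocol, snr = 30, seed = 1L,
                         noise = c("rician", "gaussian", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(protocol, "qti_protocol"), snr > 0)
  dm <- dim(micro$class_map)
  nvol <- length(protocol$btensors)
  sig <- t(vapply(micro$classes, td_signal, numeric(nvol),
                  protocol = protocol))                     # ncls x N
  M <- matrix(0, prod(dm), nvol)
  for (k in seq_along(micro$classes)) {
    idx <- which(micro$class_map == k)
    if (length(idx))
      M[idx, ] <- matrix(sig[k, ], length(idx), nvol, byrow = TRUE)
  }
  if (noise != "none") {
    sigma <- 1 / snr
    M <- with_seed(seed, {
      e1 <- matrix(stats::rnorm(length(M), sd = sigma), nrow(M))
      if (noise == "rician") {
        e2 <- matrix(stats::rnorm(length(M), sd = sigma), nrow(M))
        sqrt((M + e1)^2 + e2^2)
      } else M + e1
    })
  }
  array(M, c(dm, nvol))
}

#' Simulate pseudo-structural contrasts for a phantom
#'
#' Pseudo-T1w intensity increases and pseudo-FLAIR intensity decreases with
#' the tissue table's myelin surrogate; lesion voxels always receive the
#' cortex-level intensity regardless of their microstructure assignment
#' (low-myelin cortical tissue looks cortex-like on structural MRI even
#' where its axon content is white-matter-like).  Gaussian intensity noise,
#' seeded.
#'
#' @param labelmap result of [build_labelmap()].
#' @param spec the [phantom_spec()].
#' @param seed integer seed.
#' @return list with 3-D arrays `t1w` and `flair`.
#' @export
generate_structural <- function(labelmap, spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- labelmap$labels
  dm <- dim(labels)
  ts <- spec$tissues
  t1 <- array(0, dm); fl <- array(0, dm)
  put <- function(mask, p, img, which) {
    n <- sum(mask)
    if (!n) return(img)
    img[mask] <- stats::rnorm(n, p[[paste0(which, "_mean")]],
                              p[[paste0(which, "_sd")]])
    img
  }
  with_seed(seed, {
    for (nm in c("csf", "cortex", "wm", "deep_gm")) {
      m <- labels == PHANTOM_LABELS[[nm]]
      t1 <- put(m, ts[[nm]], t1, "t1w")
      fl <- put(m, ts[[nm]], fl, "flair")
    }
    for (i in seq_along(labelmap$lesion_types)) {
      m <- labels == .lesion_label(i)
      t1 <- put(m, ts$cortex, t1, "t1w")     # cortex-like, always
      fl <- put(m, ts$cortex, fl, "flair")
    }
  })
  list(t1w = t1, flair = fl)
}

#' Build a complete digital MCD phantom
#'
#' Runs [build_labelmap()], [assign_microstructure()], [generate_dwi()] and
#' [generate_structural()] under the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param protocol a `qti_protocol`; default [default_protocol()] seeded
#'   from the spec.
#' @param noise noise model passed to [generate_dwi()].
#' @return object of class `mcd_phantom`: `spec`, `protocol`, `labels`,
#'   `label_table`, `rois`, `lesion_types`, `micro`, `gt`, `dwi`, `t1w`,
#'   `flair`.
#' @export
build_phantom <- function(spec = phantom_spec(),
                          protocol = default_protocol(spec$seed),
                          noise = "rician") {
  lm <- build_labelmap(spec)
  micro <- assign_microstructure(lm, spec)
  dwi <- generate_dwi(micro, protocol, snr = spec$snr, seed = spec$seed,
                      noise = noise)
  st <- generate_structural(lm, spec, seed = spec$seed + 1L)
  structure(c(lm, list(spec = spec, protocol = protocol, micro = micro,
                       gt = micro$gt, dwi = dwi, t1w = st$t1w,
                       flair = st$flair)),
            class = "mcd_phantom")
}
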