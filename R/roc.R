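#' Extract per-voxel ROI intensities from a volume
#'
#' @param volume 3-D numeric array.
#' @param roi logical mask on the same grid.
#' @param roi_id identifier string.
#' @param class tissue class of the ROI (`"PH"`, `"SH"`, `"FCD"`, `"PMG"`,
#'   `"cortex"`, `"WM"`, ...).
#' @param contrast contrast name (`"T1w"`, `"FLAIR"`, `"FA"`, `"MKA"`, ...).
#' @return object of class `roi_sample`: `values` (in mask order), `n`,
#'   `roi_id`, `class`, `contrast`, `normalized`, `reference_id`.
#' @export
extract_roi <- function(volume, roi, roi_id = "roi", class = NA_character_,
                        contrast = NA_character_) {
  if (is.null(dim(volume)) || length(dim(volume)) != 3L)
    stop("volume must be a 3-D array")
  roi <- as.logical(roi)
  if (length(roi) != length(volume))
    stop("roi mask does not match the volume grid")
  dim(roi) <- dim(volume)
  if (!any(roi)) stop("empty ROI mask")
  v <- volume[roi]
  if (any(!is.finite(v)))
    stop("ROI '", roi_id, "' contains non-finite values; exclude invalid ",
         "voxels first")
  structure(list(values = v, n = length(v), roi_id = roi_id, class = class,
                 contrast = contrast, normalized = FALSE,
                 reference_id = NA_character_),
            class = "roi_sample")
}

#' Normalise ROI intensities by a reference ROI mean
#'
#' Structural (T1w / FLAIR) intensities are in arbitrary units and are
#' divided by the mean intensity of a reference ROI from the same subject;
#' dimensionless contrasts (FA, MK_A) pass through unchanged.
#'
#' @param sample a `roi_sample`.
#' @param reference a `roi_sample` from the reference region (same
#'   contrast).
#' @param passthrough contrasts returned unchanged (dimensionless maps).
#' @return normalised `roi_sample`.
#' @export
normalize_intensity <- function(sample, reference,
                                passthrough = c("FA", "MKA")) {
  stopifnot(inherits(sample, "roi_sample"))
  if (!is.na(sample$contrast) && sample$contrast %in% passthrough)
    return(sample)
  stopifnot(inherits(reference, "roi_sample"))
  m <- mean(reference$values)
  if (!is.finite(m) || m <= 0)
    stop("reference ROI mean must be positive")
  sample$values <- sample$values / m
  sample$normalized <- TRUE
  sample$reference_id <- reference$roi_id
  sample
}

#' Common histogram bin edges across ROI samples
#'
#' Edges span the pooled 1st-99th percentile of the values of every sample
#' supplied (all classes of one contrast), so that class distributions and
#' ROC thresholds share one binning.  A degenerate range (all values equal)
#' falls back to a single bin and is flagged.
#'
#' @param samples list of `roi_sample` (or numeric vectors).
#' @param n_bins number of bins.
#' @param probs pooled quantile range.
#' @return list with `edges` (strictly increasing) and `degenerate`.
#' @export
common_bin_edges <- function(samples, n_bins = 64L, probs = c(0.01, 0.99)) {
  vals <- unlist(lapply(samples, function(s)
    if (inherits(s, "roi_sample")) s$values else s), use.names = FALSE)
  stopifnot(length(vals) > 0L, all(is.finite(vals)))
  q <- stats::quantile(vals, probs, names = FALSE, type = 7)
  if (diff(q) <= 0) {
    w <- max(abs(q[1]), 1) * 1e-6
    return(list(edges = c(q[1] - w, q[1] + w), degenerate = TRUE))
  }
  list(edges = seq(q[1], q[2], length.out = n_bins + 1L), degenerate = FALSE)
}

#' Average normalised intensity distribution over ROIs
#'
#' Each ROI contributes its own normalised histogram density on the common
#' edges (values clamped into the edge bins); densities are then averaged
#' with equal ROI weight — not voxel-pooled, so large ROIs do not dominate —
#' and renormalised to integrate to 1.
#'
#' @param samples list of `roi_sample` of one contrast and class.
#' @param edges common bin edges from [common_bin_edges()]; computed from
#'   `samples` alone if missing.
#' @param n_bins used only when `edges` is missing.
#' @return object of class `avg_distribution`: `edges`, `density`,
#'   `n_rois`, `contrast`, `class`, `degenerate`.
#' @export
average_distributions <- function(samples, edges = NULL, n_bins = 64L) {
  if (inherits(samples, "roi_sample")) samples <- list(samples)
  stopifnot(length(samples) >= 1L)
  contrast <- samples[[1]]$contrast
  cls <- samples[[1]]$class
  degenerate <- FALSE
  if (is.null(edges)) {
    be <- common_bin_edges(samples, n_bins = n_bins)
    edges <- be$edges
    degenerate <- be$degenerate
  }
  nb <- length(edges) - 1L
  widths <- diff(edges)
  dens <- vapply(samples, function(s) {
    v <- pmin(pmax(s$values, edges[1]), edges[nb + 1L])
    ct <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nb),
                   nbins = nb)
    ct / (sum(ct) * widths)
  }, numeric(nb))
  d <- rowMeans(matrix(dens, nrow = nb))
  d <- d / sum(d * widths)
  structure(list(edges = edges, density = d, n_rois = length(samples),
                 contrast = contrast, class = cls, degenerate = degenerate),
            class = "avg_distribution")
}

#' ROC threshold between cortex and white matter distributions
#'
#' Sweeps every bin edge of the averaged class distributions as a candidate
#' threshold, with white matter as the positive class.  Polarity is
#' auto-resolved so that the AUC is at least 0.5 (white matter high for
#' T1w/FA/MK_A-like contrasts, low for FLAIR-like ones); the optimal
#' threshold maximises the Youden index J = sensitivity + specificity - 1,
#' and the AUC is computed by trapezoidal integration of the swept curve.
#'
#' @param dist_cortex,dist_wm `avg_distribution` objects on identical bin
#'   edges.
#' @return object of class `threshold_result`: `contrast`, `threshold`,
#'   `polarity` (`"high"` = white-matter-like above the threshold), `auc`,
#'   `youden`.
#' @export
roc_threshold <- function(dist_cortex, dist_wm) {
  stopifnot(inherits(dist_cortex, "avg_distribution"),
            inherits(dist_wm, "avg_distribution"))
  e <- dist_cortex$edges
  if (length(e) != length(dist_wm$edges) ||
      max(abs(e - dist_wm$edges)) > 1e-12 * max(abs(e), 1))
    stop("distributions do not share bin edges")
  w <- diff(e)
  mass_c <- dist_cortex$density * w
  mass_w <- dist_wm$density * w
  mass_c <- mass_c / sum(mass_c)
  mass_w <- mass_w / sum(mass_w)
  sweep1 <- function(high) {
    # mass on the WM side of each candidate edge
    if (high) {
      tpr <- rev(cumsum(rev(c(mass_w, 0))))
      fpr <- rev(cumsum(rev(c(mass_c, 0))))
    } else {
      tpr <- cumsum(c(0, mass_w))
      fpr <- cumsum(c(0, mass_c))
    }
    o <- order(fpr, tpr)
    auc <- sum(diff(fpr[o]) * (tpr[o][-1] + tpr[o][-length(o)]) / 2)
    list(tpr = tpr, fpr = fpr, auc = auc)
  }
  hi <- sweep1(TRUE)
  polarity <- if (hi$auc >= 0.5) "high" else "low"
  sw <- if (polarity == "high") hi else sweep1(FALSE)
  j <- sw$tpr - sw$fpr
  k <- which.max(j)                      # first maximiser: deterministic
  structure(list(contrast = dist_cortex$contrast, threshold = e[k],
                 polarity = polarity, auc = sw$auc, youden = j[k]),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "threshold_result [%s]: tau = %.4g (WM %s), AUC = %.3f, J = %.3f\n",
    x$contrast, x$threshold, x$polarity, x$auc, x$youden))
  invisible(x)
}

#' Classify ROI voxels as white-matter-like and report the percentage
#'
#' A voxel is white-matter-like iff it lies strictly on the white-matter
#' side of the threshold (ties count as cortex-like).
#'
#' @param sample a `roi_sample` (normalised consistently with the
#'   threshold's training distributions) or a numeric vector.
#' @param threshold a `threshold_result`.
#' @return list with `wm_percent` (in 0-100), `wm_like` (per-voxel
#'   logical), `n`.
#' @export
classify_wm_percent <- function(sample, threshold) {
  stopifnot(inherits(threshold, "threshold_result"))
  v <- if (inherits(sample, "roi_sample")) sample$values else sample
  if (length(v) == 0L) stop("empty sample")
  wm <- if (threshold$polarity == "high") v > threshold$threshold
        else v < threshold$threshold
  list(wm_percent = 100 * mean(wm), wm_like = wm, n = length(v))
}
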