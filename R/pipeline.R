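#' ROI extraction, thresholding and lesion classification for a phantom
#'
#' The statistical back end applied to a phantom and its fitted metric
#' maps: CSF-contaminated voxels are removed from every ROI using the
#' fitted MD; T1w intensities are normalised to the adjacent
#' normal-white-matter ROI, FLAIR intensities to the anterior
#' deep-white-matter reference ROI, FA and MK_A pass through; per-contrast
#' averaged distributions of normal cortex and normal white matter (equal
#' ROI weight) feed an ROC sweep whose Youden-optimal threshold classifies
#' every lesion voxel as cortex-like or white-matter-like.
#'
#' @param phantom an `mcd_phantom`.
#' @param fit result of [qti_fit_volume()] on the (smoothed) phantom dMRI.
#' @param md_csf_threshold MD threshold for CSF exclusion (um^2/ms).
#' @param n_bins histogram bins per contrast.
#' @return list with `report` (a `lesion_report`), `thresholds` (named
#'   `threshold_result` list per contrast), `distributions` (per contrast:
#'   cortex / wm `avg_distribution`), and `exclusions` (CSF-removed voxel
#'   counts per ROI).
#' @export
classify_phantom <- function(phantom, fit, md_csf_threshold = 1.5,
                             n_bins = 64L) {
  stopifnot(inherits(phantom, "mcd_phantom"))
  volumes <- list(T1w = phantom$t1w, FLAIR = phantom$flair,
                  FA = fit$fa, MKA = fit$mk_a)
  contrasts <- names(volumes)
  md <- fit$md
  types <- phantom$lesion_types
  if (length(types) == 0L) stop("phantom has no lesions to classify")

  excl <- list()
  clean <- list()
  for (nm in names(phantom$rois)) {
    ex <- exclude_csf_voxels(phantom$rois[[nm]], md,
                             md_threshold = md_csf_threshold)
    excl[[nm]] <- ex$n_removed
    clean[[nm]] <- if (ex$empty) NULL else ex$roi
  }
  if (is.null(clean$reference)) stop("reference ROI empty after exclusion")

  grab <- function(ct, roi_name, class) {
    extract_roi(volumes[[ct]], clean[[roi_name]], roi_id = roi_name,
                class = class, contrast = ct)
  }
  ref_of <- function(ct, type) {
    # T1w referenced to the adjacent normal WM; FLAIR to the anterior
    # reference region; FA / MK_A dimensionless
    switch(ct, T1w = grab(ct, paste0("wm_", type), "WM"),
           FLAIR = grab(ct, "reference", "WM"), NULL)
  }
  norm_grab <- function(ct, roi_name, class, type) {
    s <- grab(ct, roi_name, class)
    r <- ref_of(ct, type)
    if (is.null(r)) s else normalize_intensity(s, r)
  }

  thresholds <- list()
  dists <- list()
  for (ct in contrasts) {
    cortex_samples <- list(); wm_samples <- list()
    for (type in types) {
      cn <- paste0("cortex_", type); wn <- paste0("wm_", type)
      if (is.null(clean[[cn]]) || is.null(clean[[wn]])) next
      cortex_samples[[type]] <- norm_grab(ct, cn, "cortex", type)
      wm_samples[[type]] <- norm_grab(ct, wn, "WM", type)
    }
    if (!length(cortex_samples))
      stop("no usable normal-tissue ROIs for contrast ", ct)
    be <- common_bin_edges(c(cortex_samples, wm_samples), n_bins = n_bins)
    dc <- average_distributions(cortex_samples, edges = be$edges)
    dc$class <- "cortex"
    dw <- average_distributions(wm_samples, edges = be$edges)
    dw$class <- "WM"
    thresholds[[ct]] <- roc_threshold(dc, dw)
    dists[[ct]] <- list(cortex = dc, wm = dw)
  }

  rows <- list()
  for (type in types) {
    ln <- paste0("lesion_", type)
    if (is.null(clean[[ln]])) next
    for (ct in contrasts) {
      s <- norm_grab(ct, ln, type, type)
      cl <- classify_wm_percent(s, thresholds[[ct]])
      rows[[length(rows) + 1L]] <-
        data.frame(lesion_id = ln, type = type, n_voxels = cl$n,
                   contrast = ct, wm_percent = cl$wm_percent,
                   stringsAsFactors = FALSE)
    }
  }
  list(report = lesion_report(do.call(rbind, rows)),
       thresholds = thresholds, distributions = dists, exclusions = excl)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full phantom-to-report pipeline
#'
#' simulate -> smooth -> fit -> extract/normalise -> threshold -> classify
#' -> report, writing every artifact (NIfTI volumes, b-tensor sidecar, TSV
#' tables and a plain-text manifest) under `config$output_dir`.  Reruns
#' with the same configuration are bit-identical for the simulation and
#' deterministic for every later stage.
#'
#' @param config a `run_config` (see [default_run_config()]) or the path of
#'   a YAML config file.
#' @return (invisibly) list with `phantom`, `fit`, `classification`,
#'   `report` and `paths`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$protocol) || is.null(config$protocol$shells))
    stop("config validation: missing protocol specification")
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  vox <- config$phantom$voxel
  p <- file.path

  protocol <- .stage("protocol", build_protocol(config$protocol$shells,
                                                n_b0 = config$protocol$n_b0,
                                                seed = config$seed))
  spec <- .stage("phantom_spec", phantom_spec(
    dim = config$phantom$dim, voxel = vox,
    lesions = lapply(names(config$phantom$lesions), function(t)
      lesion_spec(t, f_wm = config$phantom$lesions[[t]])),
    snr = config$phantom$snr, seed = config$seed))
  phantom <- .stage("simulate", build_phantom(spec, protocol))

  .stage("write_phantom", {
    write_nifti(phantom$dwi, p(out, "dwi.nii.gz"), voxel = vox)
    write_btensor_sidecar(protocol, p(out, "dwi.btens"))
    write_nifti(phantom$t1w, p(out, "t1w.nii.gz"), voxel = vox)
    write_nifti(phantom$flair, p(out, "flair.nii.gz"), voxel = vox)
    write_nifti(phantom$labels, p(out, "labels.nii.gz"), voxel = vox)
    for (nm in names(phantom$rois))
      write_nifti(phantom$rois[[nm]], p(out, paste0("roi_", nm, ".nii.gz")),
                  voxel = vox)
    for (nm in names(phantom$gt))
      write_nifti(phantom$gt[[nm]], p(out, paste0("gt_", nm, ".nii.gz")),
                  voxel = vox)
  })

  smoothed <- .stage("smooth", gaussian_smooth(
    phantom$dwi, voxel_size = vox,
    sigma_factor = config$preprocessing$sigma_factor))
  fit <- .stage("fit", qti_fit_volume(smoothed, protocol,
                                      mask = phantom$labels > 0))
  .stage("write_maps", {
    for (nm in c("md", "fa", "mk_i", "mk_a", "mk_t", "ufa", "s0"))
      write_nifti(fit[[nm]], p(out, paste0(nm, ".nii.gz")), voxel = vox)
    write_nifti(fit$valid, p(out, "valid.nii.gz"), voxel = vox)
  })

  cls <- .stage("classify", classify_phantom(
    phantom, fit, md_csf_threshold = config$preprocessing$md_csf_threshold,
    n_bins = config$classification$n_bins))

  .stage("report", {
    write_report(cls$report, p(out, "lesion_report.tsv"))
    th <- do.call(rbind, lapply(cls$thresholds, function(t)
      data.frame(contrast = t$contrast, threshold = t$threshold,
                 polarity = t$polarity, auc = t$auc, youden = t$youden)))
    utils::write.table(th, p(out, "thresholds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest(p(out, "manifest.txt"), config,
                   extra = list(n_volumes = length(protocol$btensors)))
    write_run_config(config, p(out, "config.yaml"))
  })

  invisible(list(phantom = phantom, fit = fit, classification = cls,
                 report = cls$report, paths = out))
}
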