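#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return list with `data` (numeric array), `affine` (4x4 matrix), `voxel`
#'   (voxel dimensions in mm for the spatial axes).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("malformed NIfTI file '", path, "': ",
                         conditionMessage(e)))
  nd <- length(dim(img))
  list(data = array(as.numeric(img), dim(img)),
       affine = structure(RNifti::xform(img), class = NULL),
       voxel = RNifti::pixdim(img)[seq_len(min(nd, 3L))])
}

#' Write a NIfTI volume (float32 on disk)
#'
#' @param data 3-D or 4-D numeric array (logical masks are written as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel voxel dimensions in mm (spatial axes).
#' @param affine optional 4x4 affine; default diagonal from `voxel`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel = c(1, 1, 1), affine = NULL) {
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (is.null(affine)) {
    affine <- diag(c(-voxel[1], voxel[2], voxel[3], 1))  # RAS-ish default
    affine[1:3, 4] <- -affine[cbind(1:3, 1:3)] * (dim(data)[1:3] - 1) / 2
  }
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  pd <- c(voxel, rep(1, max(nd - 3L, 0L)))[seq_len(nd)]
  RNifti::pixdim(img) <- pd
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

# flatten a nested config list to "a.b.c: value" yaml-compatible structure
.known_config_keys <- c("protocol", "phantom", "preprocessing",
                        "classification", "seed", "output_dir")

#' Default end-to-end run configuration
#'
#' @param seed master seed; every stochastic stage derives its stream from
#'   it.
#' @param output_dir artifact directory.
#' @return a `run_config` list: `protocol` (`shells` data frame, `n_b0`),
#'   `phantom` (`dim`, `voxel`, `snr`, `lesions` with per-type `f_wm`),
#'   `preprocessing` (`sigma_factor`, `md_csf_threshold`), `classification`
#'   (`n_bins`), `seed`, `output_dir`.
#' @export
default_run_config <- function(seed = 1L, output_dir = "results/pipeline") {
  structure(list(
    protocol = list(
      shells = data.frame(
        shape = c(rep("linear", 4), rep("spherical", 4)),
        b = c(0.1, 0.7, 1.4, 2.0, 0.1, 0.7, 1.4, 2.0),
        n = c(6, 6, 10, 16, 3, 3, 6, 6)),
      n_b0 = 2L),
    phantom = list(dim = c(40L, 40L, 20L), voxel = c(2, 2, 4), snr = 30,
                   lesions = list(PH = 0.13, SH = 0.40, FCD = 0.29,
                                  PMG = 0.44)),
    preprocessing = list(sigma_factor = 0.42, md_csf_threshold = 1.5),
    classification = list(n_bins = 64L),
    seed = as.integer(seed),
    output_dir = output_dir), class = "run_config")
}

#' Read / write a run configuration (plain-text YAML)
#'
#' The file round-trips losslessly; unknown top-level keys are rejected.
#'
#' @param path config file path.
#' @return `read_run_config`: a `run_config`; `write_run_config`: `path`
#'   invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .known_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(c("protocol", "phantom", "seed"), names(raw))
  if (length(missing))
    stop("config lacks required keys: ", paste(missing, collapse = ", "))
  cfg <- default_run_config(seed = raw$seed)
  cfg$protocol$shells <- as.data.frame(
    lapply(raw$protocol$shells, unlist), stringsAsFactors = FALSE)
  cfg$protocol$n_b0 <- as.integer(raw$protocol$n_b0)
  for (k in intersect(names(raw$phantom), names(cfg$phantom)))
    cfg$phantom[[k]] <- raw$phantom[[k]]
  cfg$phantom$dim <- as.integer(unlist(cfg$phantom$dim))
  cfg$phantom$voxel <- as.numeric(unlist(cfg$phantom$voxel))
  for (k in intersect(names(raw$preprocessing), names(cfg$preprocessing)))
    cfg$preprocessing[[k]] <- raw$preprocessing[[k]]
  for (k in intersect(names(raw$classification), names(cfg$classification)))
    cfg$classification[[k]] <- raw$classification[[k]]
  if (!is.null(raw$output_dir)) cfg$output_dir <- raw$output_dir
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$protocol$shells <- as.list(out$protocol$shells)
  yaml::write_yaml(out, path)
  invisible(path)
}

# plain-text key = value manifest recording how artifacts were produced
write_manifest <- function(path, config, extra = list()) {
  kv <- c(
    package_version = as.character(utils::packageVersion("qtimcd")),
    seed = config$seed,
    snr = config$phantom$snr,
    grid = paste(config$phantom$dim, collapse = "x"),
    voxel_mm = paste(config$phantom$voxel, collapse = "x"),
    sigma_factor = config$preprocessing$sigma_factor,
    md_csf_threshold = config$preprocessing$md_csf_threshold,
    n_bins = config$classification$n_bins,
    lesions = paste(sprintf("%s:%.3g", names(config$phantom$lesions),
                            unlist(config$phantom$lesions)),
                    collapse = ","),
    unlist(extra))
  writeLines(paste(names(kv), "=", kv), path)
  invisible(path)
}
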