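#' Axially symmetric diffusion tensor
#'
#' `radial * I + (axial - radial) * n %o% n`, diffusivities in um^2/ms.
#'
#' @param axial,radial axial and radial diffusivities (um^2/ms).
#' @param direction symmetry-axis 3-vector (normalised internally).
#' @return symmetric 3x3 matrix.
#' @export
axisym_tensor <- function(axial, radial, direction = c(0, 0, 1)) {
  n <- direction / sqrt(sum(direction^2))
  radial * diag(3) + (axial - radial) * tcrossprod(n)
}

#' Ground-truth mixture of Gaussian diffusion tensors
#'
#' A voxel's microenvironments are represented as a weighted mixture of
#' Gaussian components, each a symmetric positive semidefinite diffusion
#' tensor.  This is the distribution whose first two moments the QTI model
#' estimates.
#'
#' @param weights non-negative weights; normalised to sum to 1.
#' @param tensors list of symmetric PSD 3x3 matrices (um^2/ms).
#' @return object of class `tensor_distribution` with `weights` and
#'   `tensors`.
#' @export
tensor_distribution <- function(weights, tensors) {
  if (length(weights) != length(tensors) || length(weights) == 0L)
    stop("weights and tensors must be non-empty and of equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  for (D in tensors) {
    .check_symmetric(D, 3L, what = "component tensor")
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("component tensors must be positive semidefinite")
  }
  structure(list(weights = weights / s, tensors = tensors),
            class = "tensor_distribution")
}

#' Exact first two moments of a tensor distribution
#'
#' @param td a `tensor_distribution`.
#' @return list with `d6` (Voigt 6-vector of the mean tensor) and `c21`
#'   (Voigt 21-vector of the covariance `<D (x) D> - <D> (x) <D>`).
#' @export
td_moments <- function(td) {
  stopifnot(inherits(td, "tensor_distribution"))
  V <- vapply(td$tensors, voigt6, numeric(6))      # 6 x K
  w <- td$weights
  d6 <- as.vector(V %*% w)
  M66 <- (V * rep(w, each = 6)) %*% t(V)
  C66 <- M66 - tcrossprod(d6)
  list(d6 = d6, c21 = voigt21((C66 + t(C66)) / 2))
}

#' Ground-truth scalar metrics of a tensor distribution
#'
#' [qti_metrics()] applied to the exact moments from [td_moments()].
#'
#' @param td a `tensor_distribution`.
#' @return named metric list (see [qti_metrics()]).
#' @export
td_metrics <- function(td) qti_metrics(td_moments(td))

#' Exact multi-Gaussian signal of a tensor distribution
#'
#' `s(B) = S0 * sum_k w_k exp(-B : D_k)` — the full mixture signal, not its
#' cumulant truncation, so fitting these signals with the QTI model exposes
#' the model's truncation bias at finite b.
#'
#' @param td a `tensor_distribution`.
#' @param protocol a `qti_protocol`.
#' @param s0 non-diffusion-weighted signal.
#' @return numeric signal vector, one value per volume.
#' @export
td_signal <- function(td, protocol, s0 = 1) {
  stopifnot(inherits(td, "tensor_distribution"),
            inherits(protocol, "qti_protocol"))
  V <- vapply(td$tensors, voigt6, numeric(6))      # 6 x K
  B6 <- t(vapply(protocol$btensors, function(bt) voigt6(bt$matrix),
                 numeric(6)))                      # N x 6
  s0 * as.vector(exp(-B6 %*% V) %*% td$weights)
}

#' Mixture of identical axisymmetric components at a chosen dispersion
#'
#' All components share the same eigenvalues (hence the same microscopic
#' anisotropy and MK_A) but differ in orientation: `"coherent"` (single
#' orientation), `"crossing"` (two equal-weight perpendicular orientations)
#' or `"uniform"` (a deterministic, approximately uniform set of
#' orientations, collapsing FA towards zero).
#'
#' @param axial,radial component diffusivities (um^2/ms).
#' @param mode dispersion mode.
#' @param direction principal orientation for `"coherent"`, and the first of
#'   the two orientations for `"crossing"` (the second is a perpendicular
#'   axis).
#' @param n_uniform number of orientations for `"uniform"`.
#' @return a `tensor_distribution`.
#' @export
dispersed_distribution <- function(axial, radial,
                                   mode = c("coherent", "crossing",
                                            "uniform"),
                                   direction = c(1, 0, 0),
                                   n_uniform = 60L) {
  mode <- match.arg(mode)
  n1 <- direction / sqrt(sum(direction^2))
  if (mode == "coherent") {
    tensor_distribution(1, list(axisym_tensor(axial, radial, n1)))
  } else if (mode == "crossing") {
    # any unit vector perpendicular to n1
    ref <- if (abs(n1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n2 <- ref - sum(ref * n1) * n1
    n2 <- n2 / sqrt(sum(n2^2))
    tensor_distribution(c(0.5, 0.5),
                        list(axisym_tensor(axial, radial, n1),
                             axisym_tensor(axial, radial, n2)))
  } else {
    dirs <- uniform_directions(n_uniform, seed = 101L)
    tensor_distribution(rep(1 / n_uniform, n_uniform),
                        lapply(seq_len(n_uniform), function(i)
                          axisym_tensor(axial, radial, dirs[i, ])))
  }
}

#' Add isotropic (bulk) variance to a tensor distribution
#'
#' Splits every component into a pair scaled by `1 +/- delta` so that the
#' variance of the components' mean diffusivities increases by `v_iso`
#' (um^4/ms^2) while the mean tensor is unchanged.
#'
#' @param td a `tensor_distribution`.
#' @param v_iso target added bulk variance V_I (um^4/ms^2).
#' @return a `tensor_distribution` with twice the number of components.
#' @export
with_md_spread <- function(td, v_iso) {
  stopifnot(inherits(td, "tensor_distribution"), v_iso >= 0)
  if (v_iso == 0) return(td)
  md <- vapply(td$tensors, function(D) sum(diag(D)) / 3, numeric(1))
  mdbar <- sum(td$weights * md)
  delta <- sqrt(v_iso) / mdbar
  tensors <- c(lapply(td$tensors, function(D) (1 + delta) * D),
               lapply(td$tensors, function(D) (1 - delta) * D))
  tensor_distribution(rep(td$weights / 2, 2), tensors)
}
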