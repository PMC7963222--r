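#' Predict tensor-valued dMRI signals from QTI cumulant parameters
#'
#' The cumulant (QTI) signal model over b-tensors B:
#' `log s = log S0 - B : <D> + 0.5 * (B x B) :: C`,
#' evaluated through the Voigt dot products of the protocol's design matrix.
#'
#' @param theta either a 28-vector `c(log_s0, d6, c21)` or a list/`qti_fit`
#'   with elements `log_s0`, `d6` (Voigt 6-vector of the mean tensor,
#'   um^2/ms) and `c21` (Voigt 21-vector of the covariance, um^4/ms^2).
#' @param protocol a `qti_protocol`.
#' @param design optional precomputed [qti_design()] matrix.
#' @return numeric signal vector, one value per volume.
#' @export
qti_predict <- function(theta, protocol, design = NULL) {
  th <- as_theta28(theta)
  X <- if (is.null(design)) qti_design(protocol) else design
  as.vector(exp(X %*% th))
}

as_theta28 <- function(theta) {
  if (is.numeric(theta) && length(theta) == 28L) return(as.numeric(theta))
  if (is.list(theta) && all(c("log_s0", "d6", "c21") %in% names(theta)))
    return(c(theta$log_s0, theta$d6, theta$c21))
  stop("theta must be a 28-vector or a list with log_s0, d6, c21")
}

# orthonormal basis of the design's row space (the identifiable parameter
# subspace).  Row weighting cannot change this space, so one basis serves
# both WLS passes and every voxel of a volume.
design_rowspace <- function(X, tol = 1e-8) {
  sv <- svd(X)
  r <- sum(sv$d > tol * sv$d[1])
  list(V = sv$v[, seq_len(r), drop = FALSE], rank = r)
}

#' Identifiable projection of a 28-parameter vector under a protocol
#'
#' Projects `theta = c(log_s0, d6, c21)` onto the row space of the
#' protocol's design matrix — the subspace that the acquisition can
#' determine.  Linear plus spherical encoding spans 23 of the 28 cumulant
#' parameters (the totally symmetric quartic part of C plus its isotropic
#' `I (x) I` component); the remaining 5 covariance components are invisible
#' to such data and are reported as zero by [qti_fit()].
#'
#' @param theta 28-vector or list with `log_s0`, `d6`, `c21`.
#' @param protocol a `qti_protocol`.
#' @return projected 28-vector.
#' @export
qti_identifiable <- function(theta, protocol) {
  th <- as_theta28(theta)
  B <- design_rowspace(qti_design(protocol))
  as.vector(B$V %*% crossprod(B$V, th))
}

#' Fit the QTI cumulant model to one voxel's signals
#'
#' Two-pass weighted least squares on the log signals: an ordinary
#' least-squares pass followed by a pass weighted by the squared pass-1
#' predicted signals.  This is the standard heteroscedasticity correction
#' for log-transformed magnitude data, whose log-domain noise variance
#' scales as 1/signal^2.  No positivity constraints are imposed; raw
#' estimates are retained.
#'
#' The solution is the minimum-norm WLS estimate, computed on the design's
#' row space.  With linear plus spherical encoding (the supported b-tensor
#' shapes) that space has dimension 23: `log S0`, the full mean tensor, and
#' 16 of the 21 covariance components — including every combination entering
#' the scalar metrics, which are therefore estimated without bias from the
#' restriction.  The 5 unidentifiable covariance components are returned as
#' zero.
#'
#' Non-positive or non-finite signals are dropped before fitting; the voxel
#' is marked invalid if fewer than 28 usable measurements remain, if the
#' design row space has dimension below `min_rank`, or if the weighted
#' normal equations are ill-conditioned (condition number above
#' `cond_limit`).  Invalid fits are returned (not raised) so that volume
#' fits continue.
#'
#' @param signals numeric vector of measured signals, one per volume.
#' @param protocol a `qti_protocol`.
#' @param design optional precomputed [qti_design()] matrix.
#' @param min_rank minimum acceptable design rank (23 = the identifiable
#'   dimension of linear + spherical protocols; a linear-only protocol
#'   reaches only 22 and is rejected).
#' @param cond_limit condition-number threshold for flagging ill-posed fits.
#' @return object of class `qti_fit`: `log_s0`, `d6`, `c21`,
#'   `residual_variance` (weighted, log domain), `condition_number`,
#'   `rank`, `n_used`, `valid`.
#' @export
qti_fit <- function(signals, protocol, design = NULL, min_rank = 23L,
                    cond_limit = 1e8) {
  X <- if (is.null(design)) qti_design(protocol) else design
  if (length(signals) != nrow(X))
    stop("signal length does not match protocol length")
  use <- is.finite(signals) & signals > 0
  bad <- structure(list(log_s0 = NA_real_, d6 = rep(NA_real_, 6),
                        c21 = rep(NA_real_, 21), residual_variance = NA_real_,
                        condition_number = NA_real_, rank = NA_integer_,
                        n_used = sum(use), valid = FALSE),
                   class = "qti_fit")
  if (sum(use) < 28L) return(bad)
  Xu <- X[use, , drop = FALSE]
  B <- design_rowspace(Xu)
  bad$rank <- B$rank
  if (B$rank < min_rank) return(bad)
  Z <- Xu %*% B$V
  ls <- log(signals[use])
  alpha1 <- qr.coef(qr(Z), ls)
  w <- exp(2 * as.vector(Z %*% alpha1))       # squared predicted signals
  A <- crossprod(Z, Z * w)
  cond <- sqrt(max(kappa(A, exact = FALSE), 1))
  bad$condition_number <- cond
  alpha <- tryCatch(solve(A, crossprod(Z, w * ls)), error = function(e) NULL)
  if (is.null(alpha) || cond > cond_limit) return(bad)
  theta <- as.vector(B$V %*% alpha)
  r <- ls - as.vector(Z %*% alpha)
  structure(list(log_s0 = theta[1], d6 = theta[2:7], c21 = theta[8:28],
                 residual_variance = sum(w * r^2) /
                   max(sum(use) - B$rank, 1L),
                 condition_number = cond, rank = B$rank, n_used = sum(use),
                 valid = TRUE),
            class = "qti_fit")
}

#' @export
print.qti_fit <- function(x, ...) {
  cat(sprintf("qti_fit: valid = %s, n_used = %d, cond = %.3g\n",
              x$valid, x$n_used, x$condition_number))
  if (x$valid) {
    m <- qti_metrics(x)
    cat(sprintf("  S0 = %.4g, MD = %.4g um^2/ms, FA = %.3f, MK_A = %.3f\n",
                exp(x$log_s0), m$md, m$fa, m$mk_a))
  }
  invisible(x)
}

# vectorised metric engine: theta columns -> metric rows.
# Mandel bookkeeping used below (ordering fixed in voigt21):
#   tr(C66)            = sum c21[1:6]
#   sum(C66[1:3,1:3])  = c1+c2+c3 + sqrt2*(c7+c8+c12)   (= I (x) I : C * 1)
.metrics_from_theta <- function(Theta) {
  d <- Theta[2:7, , drop = FALSE]
  c21 <- Theta[8:28, , drop = FALSE]
  trD <- d[1, ] + d[2, ] + d[3, ]
  md <- trD / 3
  d2 <- colSums(d^2)                          # <D> : <D>
  v_lambda_mean_tensor <- pmax(d2 / 3 - md^2, 0)
  # eigenvalue variance at machine precision relative to MD^2 is zero
  # (keeps FA of exactly isotropic tensors at 0 after the sqrt)
  v_lambda_mean_tensor[v_lambda_mean_tensor < 1e-12 * md^2] <- 0
  trC <- colSums(c21[1:6, , drop = FALSE])
  # off-diagonal xx-yy, xx-zz, yy-zz entries sit at 21-vector slots 7, 8, 12
  sumC33 <- c21[1, ] + c21[2, ] + c21[3, ] +
    sqrt(2) * (c21[7, ] + c21[8, ] + c21[12, ])
  v_i <- sumC33 / 9
  # <V_lambda> = M :: E_shear, M = C + <D> (x) <D>
  v_lambda <- (trC + d2) / 3 - (sumC33 + trD^2) / 9
  md2 <- md^2
  ok <- is.finite(md) & md > 0
  fa <- ifelse(ok, sqrt(1.5 * v_lambda_mean_tensor /
                          (v_lambda_mean_tensor + md2)), NA_real_)
  mk_i <- ifelse(ok, 3 * v_i / md2, NA_real_)
  mk_a <- ifelse(ok, 1.2 * v_lambda / md2, NA_real_)
  ufa_den <- v_lambda + v_i + md2
  ufa_q <- pmax(pmin(1.5 * v_lambda / ufa_den, 1), 0)
  ufa <- ifelse(ok & ufa_den > 0 & v_lambda >= 0, sqrt(ufa_q), NA_real_)
  rbind(md = ifelse(ok, md, NA_real_),
        fa = pmin(fa, 1),
        v_i = ifelse(ok, v_i, NA_real_),
        v_lambda = ifelse(ok, v_lambda, NA_real_),
        mk_i = mk_i, mk_a = mk_a, mk_t = mk_i + mk_a, ufa = ufa)
}

#' Scalar metrics of a QTI fit
#'
#' From the fitted mean tensor `<D>` and covariance `C` (equivalently, the
#' first two moments of the voxel's diffusion tensor distribution):
#' \itemize{
#'   \item `md`: mean diffusivity `tr(<D>)/3` (um^2/ms);
#'   \item `fa`: fractional anisotropy of the mean tensor;
#'   \item `v_i`: bulk (isotropic) variance `C :: E_bulk` (um^4/ms^2);
#'   \item `v_lambda`: mean component eigenvalue variance
#'         `<V_lambda> = (C + <D> (x) <D>) :: E_shear`;
#'   \item `mk_i = 3 V_I / MD^2`, `mk_a = (6/5) <V_lambda> / MD^2`,
#'         `mk_t = mk_i + mk_a`;
#'   \item `ufa`: microscopic FA,
#'         `sqrt(1.5 <V_lambda> / (<V_lambda> + V_I + MD^2))`.
#' }
#' `E_bulk = (1/9) I (x) I` and `E_shear = (1/3) I4sym - E_bulk`;
#' with the Mandel convention both contractions are plain dot products, and
#' `(D (x) D) :: E_shear` equals the eigenvalue variance of `D`.
#'
#' MK_A isolates microscopic anisotropy: it depends only on the components'
#' eigenvalue variances, not on their orientations, whereas FA collapses
#' under orientation dispersion.
#'
#' @param fit a `qti_fit`, or a list with `d6` and `c21` (ground-truth
#'   moments; `log_s0` not needed).
#' @return named list of metrics (all `NA` for invalid fits or `md <= 0`,
#'   the undefined marker).
#' @export
#' @examples
#' stick <- list(d6 = voigt6(diag(c(1, 0, 0))), c21 = rep(0, 21))
#' m <- qti_metrics(stick)
#' c(m$fa, m$mk_a)   # 1, 2.4
qti_metrics <- function(fit) {
  if (inherits(fit, "qti_fit") && !fit$valid)
    return(.na_metrics())
  d6 <- fit$d6
  c21 <- if (is.null(fit$c21)) rep(0, 21) else fit$c21
  th <- matrix(c(0, d6, c21), ncol = 1)
  m <- .metrics_from_theta(th)
  out <- as.list(m[, 1])
  if (!is.finite(out$md)) return(.na_metrics())
  out
}

.na_metrics <- function() {
  stats::setNames(as.list(rep(NA_real_, 8)),
                  c("md", "fa", "v_i", "v_lambda", "mk_i", "mk_a", "mk_t",
                    "ufa"))
}

#' Voxel-by-voxel QTI fit of a 4-D volume
#'
#' Applies [qti_fit()] and [qti_metrics()] to every voxel inside `mask`.
#' The first (ordinary least squares) pass is computed for all voxels in one
#' matrix solve; the reweighted pass is solved per voxel.
#'
#' @param data 4-D numeric array `(x, y, z, volume)`.
#' @param protocol a `qti_protocol` matching the 4th dimension.
#' @param mask logical/0-1 3-D array on the same grid; default: voxels with
#'   positive mean signal.
#' @param min_rank,cond_limit validity thresholds, see [qti_fit()].
#' @return list with 3-D arrays `md`, `fa`, `mk_i`, `mk_a`, `mk_t`, `ufa`,
#'   `v_i`, `v_lambda`, `s0`, logical `valid`, plus the 28 x n_voxel
#'   parameter matrix `theta` and the voxel index vector `voxels`.
#' @export
qti_fit_volume <- function(data, protocol, mask = NULL, min_rank = 23L,
                           cond_limit = 1e8) {
  dm <- dim(data)
  if (length(dm) != 4L)
    stop("data must be a 4-D array")
  if (dm[4] != length(protocol$btensors))
    stop("protocol length does not match the 4th data dimension")
  X <- qti_design(protocol)
  if (is.null(mask)) {
    mask <- apply(data, 1:3, function(v) mean(v) > 0)
  }
  if (!all(dim(mask) == dm[1:3]))
    stop("mask grid does not match data grid")
  vox <- which(as.logical(mask))
  nv <- length(vox)
  S <- matrix(data, prod(dm[1:3]), dm[4])[vox, , drop = FALSE]  # nv x N
  theta <- matrix(NA_real_, 28L, nv)
  valid <- rep(FALSE, nv)
  B <- design_rowspace(X)
  if (nv > 0L && B$rank >= min_rank) {
    Z <- X %*% B$V
    allpos <- rowSums(!(is.finite(S) & S > 0)) == 0L
    # pass 1 for all clean voxels at once
    if (any(allpos)) {
      L <- t(log(S[allpos, , drop = FALSE]))                    # N x nv'
      A1 <- qr(Z)
      P <- exp(Z %*% qr.coef(A1, L))                            # predicted
      idx <- which(allpos)
      for (j in seq_along(idx)) {
        w <- P[, j]^2
        A <- crossprod(Z, Z * w)
        al <- tryCatch(solve(A, crossprod(Z, w * L[, j])),
                       error = function(e) NULL)
        if (is.null(al)) next
        if (sqrt(max(kappa(A, exact = FALSE), 1)) > cond_limit) next
        theta[, idx[j]] <- B$V %*% al
        valid[idx[j]] <- TRUE
      }
    }
    # voxels with dropped measurements go through the scalar path
    for (j in which(!allpos)) {
      f <- qti_fit(S[j, ], protocol, design = X, min_rank = min_rank,
                   cond_limit = cond_limit)
      if (f$valid) {
        theta[, j] <- c(f$log_s0, f$d6, f$c21)
        valid[j] <- TRUE
      }
    }
  }
  M <- matrix(NA_real_, 8L, nv)
  if (any(valid))
    M[, valid] <- .metrics_from_theta(theta[, valid, drop = FALSE])
  blank <- function() array(NA_real_, dm[1:3])
  put <- function(vals) { a <- blank(); a[vox] <- vals; a }
  out <- list(md = put(M[1, ]), fa = put(M[2, ]), v_i = put(M[3, ]),
              v_lambda = put(M[4, ]), mk_i = put(M[5, ]), mk_a = put(M[6, ]),
              mk_t = put(M[7, ]), ufa = put(M[8, ]),
              s0 = put(exp(theta[1, ])),
              valid = array(FALSE, dm[1:3]),
              theta = theta, voxels = vox)
  out$valid[vox] <- valid
  out
}
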