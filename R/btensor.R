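#' Construct a diffusion-encoding b-tensor
#'
#' Tensor-valued diffusion encoding is described by a symmetric positive
#' semidefinite 3x3 b-tensor whose trace is the conventional b-value.  Two
#' shapes are supported: `"linear"` (rank-1, conventional directional
#' encoding, `b * n %o% n`) and `"spherical"` (isotropic encoding,
#' `(b/3) * diag(3)`).  Units are ms/um^2 for b throughout.
#'
#' @param shape `"linear"` or `"spherical"`.
#' @param b b-value (trace of the tensor), ms/um^2, non-negative.
#' @param orientation unit 3-vector; required for linear encodings with
#'   `b > 0`, ignored for spherical ones.
#' @return an object of class `btensor`: list with elements `matrix`
#'   (3x3), `shape`, `b` and `orientation` (`NULL` for spherical).
#' @export
#' @examples
#' make_btensor("linear", 1, c(0, 0, 1))$matrix    # diag(0, 0, 1)
#' make_btensor("spherical", 2.0)$matrix           # (2/3) * diag(3)
make_btensor <- function(shape = c("linear", "spherical"), b,
                         orientation = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b < 0)
    stop("b must be a single non-negative finite number (ms/um^2)")
  if (shape == "linear") {
    if (b > 0) {
      if (is.null(orientation) || length(orientation) != 3L)
        stop("linear b-tensors require a 3-vector orientation")
      nrm <- sqrt(sum(orientation^2))
      if (nrm < 1e-12)
        stop("orientation must have non-zero norm")
      if (abs(nrm - 1) > 1e-6)
        stop("orientation must have unit norm")
      n <- orientation / nrm
    } else {
      n <- if (is.null(orientation)) c(0, 0, 1) else orientation
    }
    M <- b * tcrossprod(n)
  } else {
    n <- NULL
    M <- (b / 3) * diag(3)
  }
  structure(list(matrix = M, shape = shape, b = b, orientation = n),
            class = "btensor")
}

#' Approximately uniform unit directions on the sphere
#'
#' Antipodally symmetric electrostatic-repulsion layout: points are drawn at
#' random (deterministically for a given seed) and relaxed under a Coulomb
#' repulsion that includes each point's antipode, which spreads diffusion
#' directions evenly over the half-sphere.
#'
#' @param n number of directions.
#' @param seed integer seed; the layout is deterministic given `seed`.
#' @param n_iter relaxation iterations.
#' @return `n` x 3 matrix of unit row vectors.
#' @export
uniform_directions <- function(n, seed = 1L, n_iter = 250L) {
  stopifnot(n >= 1)
  x <- with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
  x <- x / sqrt(rowSums(x^2))
  if (n == 1L) return(x)
  for (it in seq_len(n_iter)) {
    f <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- rep(x[i, ], each = n - 1L) - x[-i, , drop = FALSE]
      d2 <- rep(x[i, ], each = n - 1L) + x[-i, , drop = FALSE]
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-3)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-3)
      fi <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
      fi <- fi - sum(fi * x[i, ]) * x[i, ]   # tangent component only
      f[i, ] <- fi
    }
    # annealed, capped step keeps the dynamics stable near antipodes
    eta <- 0.1 * 0.99^it
    nrm <- sqrt(rowSums(f^2))
    step <- f * pmin(eta, 0.1 / pmax(nrm, 1e-12))
    x <- x + step
    x <- x / sqrt(rowSums(x^2))
  }
  x
}

#' Build a tensor-valued acquisition protocol
#'
#' Assembles an ordered list of b-tensors (one per acquired volume): `n_b0`
#' b = 0 measurements first, then the shells in the given order.  Linear
#' shells get a seeded, approximately uniform direction set; spherical shells
#' are repeated isotropic encodings.
#'
#' @param shells data frame (or list coercible to one) with columns `shape`
#'   (`"linear"`/`"spherical"`), `b` (ms/um^2) and `n` (directions or
#'   repeats).
#' @param n_b0 number of b = 0 volumes.
#' @param seed integer seed fixing the direction sets.
#' @param for_fitting when `TRUE` (default) require at least one linear and
#'   one spherical shell with `b > 0`, without which the 28-parameter QTI
#'   model is not identifiable.
#' @return object of class `qti_protocol`: list with `btensors` (list of
#'   [make_btensor()] objects), `b`, `shape`, `n_b0`, `b_max`.
#' @export
#' @examples
#' p <- build_protocol(data.frame(shape = c("linear", "spherical"),
#'                                b = c(1, 1), n = c(6, 3)), n_b0 = 2)
#' length(p$btensors)  # 11
build_protocol <- function(shells, n_b0 = 0L, seed = 1L, for_fitting = TRUE) {
  shells <- as.data.frame(shells, stringsAsFactors = FALSE)
  if (nrow(shells) == 0L)
    stop("empty shell specification")
  stopifnot(all(c("shape", "b", "n") %in% names(shells)))
  if (for_fitting) {
    nz <- shells$b > 0
    if (!any(nz & shells$shape == "linear") ||
        !any(nz & shells$shape == "spherical"))
      stop("a protocol intended for QTI fitting needs both a linear and a ",
           "spherical shell with b > 0")
  }
  bts <- vector("list", 0L)
  if (n_b0 > 0)
    bts <- replicate(n_b0, make_btensor("spherical", 0), simplify = FALSE)
  for (k in seq_len(nrow(shells))) {
    sh <- shells$shape[k]; b <- shells$b[k]; n <- shells$n[k]
    if (sh == "linear") {
      dirs <- uniform_directions(n, seed = seed + k)
      for (i in seq_len(n))
        bts[[length(bts) + 1L]] <- make_btensor("linear", b, dirs[i, ])
    } else {
      for (i in seq_len(n))
        bts[[length(bts) + 1L]] <- make_btensor("spherical", b)
    }
  }
  b <- vapply(bts, `[[`, numeric(1), "b")
  structure(list(btensors = bts,
                 b = b,
                 shape = vapply(bts, `[[`, character(1), "shape"),
                 n_b0 = as.integer(n_b0),
                 b_max = max(b)),
            class = "qti_protocol")
}

#' @export
print.qti_protocol <- function(x, ...) {
  cat(sprintf("qti_protocol: %d volumes (%d b=0), b_max = %.3g ms/um^2\n",
              length(x$btensors), x$n_b0, x$b_max))
  tab <- table(shape = x$shape, b = signif(x$b, 3))
  print(tab)
  invisible(x)
}

#' Default 58-volume acquisition protocol
#'
#' Linear shells at b = 0.1, 0.7, 1.4, 2.0 ms/um^2 with 6, 6, 10 and 16
#' directions, spherical shells at the same b-values with 3, 3, 6 and 6
#' repeats, plus two b = 0 volumes (58 volumes in total; QTI design matrix
#' of full column rank 28).
#'
#' @param seed integer seed for the direction sets.
#' @return a `qti_protocol`.
#' @export
default_protocol <- function(seed = 1L) {
  shells <- data.frame(
    shape = c(rep("linear", 4), rep("spherical", 4)),
    b = c(0.1, 0.7, 1.4, 2.0, 0.1, 0.7, 1.4, 2.0),
    n = c(6, 6, 10, 16, 3, 3, 6, 6))
  build_protocol(shells, n_b0 = 2L, seed = seed)
}

#' QTI design matrix of a protocol
#'
#' One row per volume: `[1, -voigt6(B), 0.5 * voigt21(voigt6(B) %o% voigt6(B))]`,
#' so that the cumulant model's log-signal is the row's dot product with the
#' 28-parameter vector `(log S0, <D>, C)`.
#'
#' @param protocol a `qti_protocol`.
#' @return numeric matrix, `n_volumes` x 28.
#' @export
qti_design <- function(protocol) {
  stopifnot(inherits(protocol, "qti_protocol"))
  t(vapply(protocol$btensors, function(bt) {
    b6 <- voigt6(bt$matrix)
    c(1, -b6, 0.5 * voigt21(tcrossprod(b6)))
  }, numeric(28)))
}

#' Write / read the plain-text b-tensor sidecar
#'
#' One line per volume with the nine row-major entries of the 3x3 b-tensor in
#' ms/um^2, whitespace separated; lines starting with `#` are comments.  The
#' line order must match the 4-D volume order.
#'
#' @param protocol a `qti_protocol`.
#' @param path file path.
#' @return `write_btensor_sidecar` returns `path` invisibly;
#'   `read_btensor_sidecar` returns a `qti_protocol` (shapes recovered from
#'   the tensor rank structure).
#' @export
write_btensor_sidecar <- function(protocol, path) {
  stopifnot(inherits(protocol, "qti_protocol"))
  lines <- c("# b-tensor sidecar: 9 row-major entries per volume, ms/um^2",
             vapply(protocol$btensors, function(bt)
               paste(format(as.vector(t(bt$matrix)), digits = 17),
                     collapse = " "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_btensor_sidecar
#' @export
read_btensor_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("sidecar contains no b-tensor lines: ", path)
  bts <- lapply(lines, function(ln) {
    v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(v) != 9L || anyNA(v))
      stop("malformed sidecar line in ", path)
    M <- matrix(v, 3, 3, byrow = TRUE)
    .check_symmetric(M, 3L, tol = 1e-8, what = "sidecar b-tensor")
    M <- (M + t(M)) / 2
    b <- sum(diag(M))
    if (b < 1e-12) return(make_btensor("spherical", 0))
    ev <- eigen(M, symmetric = TRUE)
    lam <- ev$values
    if (max(abs(M - (b / 3) * diag(3))) <= 1e-6 * max(b, 1))
      make_btensor("spherical", b)
    else if (lam[2] <= 1e-6 * lam[1])
      make_btensor("linear", b, ev$vectors[, 1])
    else
      stop("b-tensor in ", path, " is neither linear nor spherical")
  })
  b <- vapply(bts, `[[`, numeric(1), "b")
  structure(list(btensors = bts, b = b,
                 shape = vapply(bts, `[[`, character(1), "shape"),
                 n_b0 = sum(b < 1e-12), b_max = max(b)),
            class = "qti_protocol")
}

#' Read a legacy bval/bvec pair as a linear-only protocol
#'
#' For conventional (linear-encoding-only) data: FSL-style `bval` (one row of
#' b-values, s/mm^2 or ms/um^2) and `bvec` (three rows of direction cosines).
#' b-values larger than 50 are assumed to be s/mm^2 and divided by 1000.
#' The result is not identifiable for QTI fitting on its own
#' (`for_fitting = FALSE` semantics).
#'
#' @param bval_path,bvec_path file paths.
#' @return a `qti_protocol` containing only linear / b = 0 encodings.
#' @export
read_bvalbvec <- function(bval_path, bvec_path) {
  bv <- scan(bval_path, quiet = TRUE)
  g <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(g) != length(bv))
    stop("bval/bvec volume counts disagree")
  if (max(bv) > 50) bv <- bv / 1000
  bts <- lapply(seq_along(bv), function(i) {
    if (bv[i] < 1e-12) make_btensor("spherical", 0)
    else make_btensor("linear", bv[i], g[, i] / sqrt(sum(g[, i]^2)))
  })
  structure(list(btensors = bts, b = bv,
                 shape = vapply(bts, `[[`, character(1), "shape"),
                 n_b0 = sum(bv < 1e-12), b_max = max(bv)),
            class = "qti_protocol")
}
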