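# shared fixtures: everything is generated in code, no data files

# random symmetric 3x3 matrix (not necessarily PSD)
rand_sym3 <- function() {
  A <- matrix(rnorm(9), 3)
  (A + t(A)) / 2
}

# random brain-plausible mixture of axisymmetric diffusion tensors
rand_mixture <- function(k_range = 2:4) {
  K <- sample(k_range, 1)
  tensor_distribution(runif(K, 0.5, 1), replicate(K, {
    ax <- runif(1, 0.5, 2.8)
    rad <- runif(1, 0.1, ax)
    n <- rnorm(3)
    axisym_tensor(ax, rad, n / sqrt(sum(n^2)))
  }, simplify = FALSE))
}

# random physical 28-parameter vector from a mixture's exact moments
rand_theta <- function() {
  mom <- td_moments(rand_mixture())
  c(log(runif(1, 0.5, 2)), mom$d6, mom$c21)
}

# bare roi_sample from a numeric vector
as_roi_sample <- function(values, roi_id = "roi", class = NA_character_,
                          contrast = "X") {
  structure(list(values = values, n = length(values), roi_id = roi_id,
                 class = class, contrast = contrast, normalized = FALSE,
                 reference_id = NA_character_),
            class = "roi_sample")
}

# small phantom spec used by several tests (single SH lesion)
small_spec <- function(seed = 1L, snr = 30, lesions = list("SH")) {
  phantom_spec(dim = c(32L, 32L, 16L), voxel = c(2, 2, 4),
               lesions = lesions, snr = snr, seed = seed)
}

# closed-form mean of a Rician variate with location nu and scale sigma
rice_mean <- function(nu, sigma) {
  x <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) *
    ((1 + x) * besselI(x / 2, 0, expon.scaled = TRUE) +
       x * besselI(x / 2, 1, expon.scaled = TRUE))
}
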