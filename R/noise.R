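#' Mixed Poisson-Gaussian noise parameters
#'
#' Detector model `Y = alpha * Poisson(X / alpha) + N(0, sigma^2)`:
#' shot noise scales with the signal through the sensor/analog gain
#' `alpha`, while readout and dark noise contribute the additive Gaussian
#' term. Under this parameterization `E[Y | X] = X` and
#' `Var[Y | X] = alpha * X + sigma^2`.
#'
#' @param alpha Gain (> 0), in intensity units per photoelectron.
#' @param sigma Standard deviation (>= 0) of the additive Gaussian term.
#' @param seed Integer RNG seed.
#' @param gaussian_only If `TRUE` the Poisson term is skipped and
#'   `Y = X + N(0, sigma^2)`; this replaces the (disallowed) limit
#'   `alpha -> 0`.
#' @return A `noise_params` object.
#' @export
noise_params <- function(alpha = 5, sigma = 40, seed = 1L,
                         gaussian_only = FALSE) {
  if (!gaussian_only && alpha <= 0)
    stop("alpha must be > 0 (use gaussian_only = TRUE for pure Gaussian noise)",
         call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, sigma = sigma, seed = as.integer(seed),
                 gaussian_only = isTRUE(gaussian_only)),
            class = "noise_params")
}

#' Corrupt a clean cube with mixed Poisson-Gaussian noise
#'
#' Applies `Y = alpha * Poisson(X / alpha) + N(0, sigma^2)` independently
#' at every voxel. Negative outputs from the Gaussian term are kept by
#' default (real detector reads dip below baseline); set `clip = TRUE` to
#' clip at zero for display. Negative *clean* values are invalid for the
#' Poisson term unless `clip_input = TRUE` clips them first.
#'
#' @param clean A [hyper_cube] with nonnegative intensities.
#' @param params A [noise_params].
#' @param clip Clip negative outputs at zero? Default `FALSE`.
#' @param clip_input Clip negative clean values at zero before corrupting?
#' @return A noisy [hyper_cube] with the same axis and metadata.
#' @export
corrupt <- function(clean, params, clip = FALSE, clip_input = FALSE) {
  validate_cube(clean)
  stopifnot(inherits(params, "noise_params"))
  x <- clean$data
  if (any(x < 0)) {
    if (clip_input) x[x < 0] <- 0
    else stop("clean cube has negative values (set clip_input = TRUE to clip)",
              call. = FALSE)
  }
  n <- length(x)
  y <- with_seed(params$seed, {
    shot <- if (params$gaussian_only) as.numeric(x)
            else params$alpha * stats::rpois(n, as.numeric(x) / params$alpha)
    read <- if (params$sigma > 0) stats::rnorm(n, 0, params$sigma) else 0
    shot + read
  })
  if (clip) y[y < 0] <- 0
  out <- clean
  out$data <- array(y, dim(x))
  out$provenance <- paste0(clean$provenance, "+noise")
  out
}

#' Recover noise parameters from a clean/noisy pair
#'
#' Empirical validation of the noise model: voxels are binned by clean
#' intensity, the residual variance `Var(Y - X)` is computed per bin, and
#' a least-squares line of variance against mean clean intensity is
#' fitted. Under the model the slope estimates `alpha` and the intercept
#' estimates `sigma^2`.
#'
#' @param clean,noisy Congruent [hyper_cube]s (same dimensions).
#' @param n_bins Number of equal-width intensity bins (default 20).
#' @return A list with `alpha_hat`, `sigma2_hat`, and `bins` (a data frame
#'   of per-bin mean intensity, residual variance and voxel count).
#' @export
estimate_noise_params <- function(clean, noisy, n_bins = 20) {
  validate_cube(clean); validate_cube(noisy)
  if (!identical(dim(clean$data), dim(noisy$data)))
    stop("clean and noisy cubes are not congruent", call. = FALSE)
  x <- as.numeric(clean$data)
  r <- as.numeric(noisy$data) - x
  rng <- range(x)
  if (rng[1] == rng[2]) {
    # single intensity level: can't separate slope from intercept
    stop("fewer than 2 distinct intensity bins; cannot fit the variance line",
         call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  keep <- tabulate(bin, n_bins) >= 2L
  if (sum(keep) < 2L)
    stop("fewer than 2 distinct intensity bins; cannot fit the variance line",
         call. = FALSE)
  mean_x <- tapply(x, bin, mean)
  var_r <- tapply(r, bin, stats::var)
  cnt <- tapply(r, bin, length)
  bins <- data.frame(mean_intensity = as.numeric(mean_x),
                     residual_variance = as.numeric(var_r),
                     n = as.numeric(cnt))
  bins <- bins[bins$n >= 2, , drop = FALSE]
  fit <- stats::lm(residual_variance ~ mean_intensity, data = bins)
  list(alpha_hat = unname(stats::coef(fit)[2]),
       sigma2_hat = unname(stats::coef(fit)[1]),
       bins = bins)
}
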