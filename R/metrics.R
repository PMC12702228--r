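#' Structural similarity index of two band images
#'
#' SSIM with the standard stabilizing constants `C1 = (0.01 R)^2`,
#' `C2 = (0.03 R)^2`. By default local statistics come from a sliding
#' Gaussian window (sigma 1.5, width 7, full windows only) and the local
#' SSIM map is averaged; `window = "global"` uses whole-image moments,
#' which is also the automatic fallback for images smaller than the
#' window. SSIM is symmetric in its two arguments.
#'
#' @param x,y Congruent numeric matrices (one spectral band each).
#' @param R Dynamic range of the data (> 0; 1 for min-max-normalized
#'   cubes).
#' @param window `"gaussian"` (default) or `"global"`.
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, R = 1, window = c("gaussian", "global")) {
  window <- match.arg(window)
  if (!identical(dim(x), dim(y))) stop("shape mismatch in ssim", call. = FALSE)
  if (R <= 0) stop("dynamic range R must be > 0", call. = FALSE)
  C1 <- (0.01 * R)^2
  C2 <- (0.03 * R)^2
  if (window == "global" || any(dim(x) < 7L)) {
    mx <- mean(x); my <- mean(y)
    n <- length(x)
    vx <- sum((x - mx)^2) / n
    vy <- sum((y - my)^2) / n
    cxy <- sum((x - mx) * (y - my)) / n
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  k <- gaussian_kernel1d(7L, 1.5)
  mu_x <- conv2_sep_valid(x, k)
  mu_y <- conv2_sep_valid(y, k)
  xx <- conv2_sep_valid(x * x, k)
  yy <- conv2_sep_valid(y * y, k)
  xy <- conv2_sep_valid(x * y, k)
  vx <- xx - mu_x^2
  vy <- yy - mu_y^2
  cxy <- xy - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * cxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (vx + vy + C2)
  mean(num / den)
}

gaussian_kernel1d <- function(width, sigma) {
  r <- (width - 1L) / 2
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# separable 2D weighted mean, 'valid' mode (full windows only)
conv2_sep_valid <- function(m, k) {
  w <- length(k)
  conv_cols <- function(x) {
    n <- nrow(x) - w + 1L
    out <- matrix(0, n, ncol(x))
    for (t in seq_len(w))
      out <- out + k[t] * x[t:(t + n - 1L), , drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Band-averaged SSIM of two cubes
#'
#' SSIM is computed independently for each spectral channel and the
#' channel values are averaged.
#'
#' @param x,y Congruent 3-d arrays or [hyper_cube]s.
#' @inheritParams ssim
#' @return Mean SSIM over bands.
#' @export
ssim_cube <- function(x, y, R = 1, window = c("gaussian", "global")) {
  window <- match.arg(window)
  xa <- if (inherits(x, "hyper_cube")) x$data else x
  ya <- if (inherits(y, "hyper_cube")) y$data else y
  if (!identical(dim(xa), dim(ya))) stop("shape mismatch in ssim_cube", call. = FALSE)
  mean(vapply(seq_len(dim(xa)[3]), function(b)
    ssim(xa[, , b], ya[, , b], R = R, window = window), 0))
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 log10(R^2 / MSE(x, y))`, with `+Inf` when the inputs are identical.
#'
#' @param x Reference image or volume.
#' @param y Estimate, congruent with `x`.
#' @param R Maximum possible value of the reference (> 0).
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @export
psnr <- function(x, y, R = 1) {
  if (R <= 0) stop("dynamic range R must be > 0", call. = FALSE)
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("shape mismatch in psnr", call. = FALSE)
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(R^2 / m)
}

#' Mean squared error
#'
#' Mean of squared differences over all data points.
#'
#' @param a,b Congruent numeric vectors or arrays.
#' @return Nonnegative scalar.
#' @export
mse <- function(a, b) {
  if (length(a) == 0) stop("empty input to mse", call. = FALSE)
  if (length(a) != length(b)) stop("shape mismatch in mse", call. = FALSE)
  mean((as.numeric(b) - as.numeric(a))^2)
}

#' Spectral signal-to-noise ratio in decibels
#'
#' `10 log10( sum(a^2) / sum((b - a)^2) )`: total signal power of the
#' reference over total residual power of the estimate.
#'
#' @param a Reference spectrum (not identically zero).
#' @param b Estimate, congruent with `a`.
#' @return SNR in dB (`Inf` when `b == a`).
#' @export
snr <- function(a, b) {
  if (length(a) != length(b)) stop("shape mismatch in snr", call. = FALSE)
  sig <- sum(as.numeric(a)^2)
  if (sig == 0) stop("zero reference: signal power undefined", call. = FALSE)
  noise <- sum((as.numeric(b) - as.numeric(a))^2)
  if (noise == 0) return(Inf)
  10 * log10(sig / noise)
}

#' Evaluate reconstructions against references
#'
#' Computes the four quality metrics per sample and their arithmetic
#' means. Spatial metrics (SSIM, PSNR) are computed per spectral band and
#' band-averaged; spectral metrics (MSE, SNR) are computed per pixel
#' spectrum and averaged over pixels.
#'
#' @param pred List of reconstructed cubes ([hyper_cube]s or arrays).
#' @param ref List of reference cubes, same length, congruent.
#' @param R Dynamic range for SSIM/PSNR (default 1, the min-max scale).
#' @param ssim_window Passed to [ssim].
#' @param normalized_inputs Flag recorded in the report stating the
#'   metric-domain convention.
#' @return A `metric_report`: list with `per_sample` (data frame with
#'   columns `ssim`, `psnr_db`, `mse`, `snr_db`), `means`, `n`,
#'   `normalized_inputs`.
#' @export
evaluate_denoising <- function(pred, ref, R = 1,
                               ssim_window = c("gaussian", "global"),
                               normalized_inputs = TRUE) {
  ssim_window <- match.arg(ssim_window)
  if (length(pred) != length(ref))
    stop("pred and ref collections differ in length", call. = FALSE)
  if (length(pred) == 0) stop("empty collection", call. = FALSE)
  rows <- lapply(seq_along(pred), function(i) {
    p <- if (inherits(pred[[i]], "hyper_cube")) pred[[i]]$data else pred[[i]]
    r <- if (inherits(ref[[i]], "hyper_cube")) ref[[i]]$data else ref[[i]]
    if (!identical(dim(p), dim(r)))
      stop(sprintf("sample %d not congruent", i), call. = FALSE)
    B <- dim(p)[3]
    psnr_b <- mean(vapply(seq_len(B), function(b) psnr(r[, , b], p[, , b], R), 0))
    d <- dim(p)
    pm <- matrix(p, d[1] * d[2], d[3])
    rm <- matrix(r, d[1] * d[2], d[3])
    mse_px <- rowMeans((pm - rm)^2)
    sig_px <- rowSums(rm^2)
    noise_px <- rowSums((pm - rm)^2)
    ok <- sig_px > 0
    snr_px <- 10 * log10(sig_px[ok] / pmax(noise_px[ok], .Machine$double.xmin))
    data.frame(ssim = ssim_cube(r, p, R = R, window = ssim_window),
               psnr_db = psnr_b, mse = mean(mse_px), snr_db = mean(snr_px))
  })
  per_sample <- do.call(rbind, rows)
  structure(list(per_sample = per_sample,
                 means = colMeans(per_sample),
                 n = nrow(per_sample),
                 normalized_inputs = isTRUE(normalized_inputs)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Metric report over n = %d samples (%s intensities)\n", x$n,
              if (x$normalized_inputs) "normalized" else "raw"))
  cat(sprintf("  SSIM %.4f   PSNR %.2f dB   MSE %.4g   SNR %.2f dB\n",
              x$means[["ssim"]], x$means[["psnr_db"]],
              x$means[["mse"]], x$means[["snr_db"]]))
  invisible(x)
}
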