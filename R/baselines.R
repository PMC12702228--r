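#' Savitzky-Golay spectral smoothing baseline
#'
#' Least-squares polynomial smoothing applied independently to every
#' pixel's spectrum along the spectral axis; spatial content is
#' untouched. Edges use the polynomial-fit transients of the filter
#' (common spectroscopy practice), so a spectrum that is exactly a
#' polynomial of degree `<= polyorder` is reproduced everywhere.
#'
#' @param cube A [hyper_cube] or 3-d array `[H, W, B]`.
#' @param window Odd window length `<= B`.
#' @param polyorder Polynomial order `< window`.
#' @return Smoothed data of the same type and shape.
#' @export
sg_denoise <- function(cube, window = 5, polyorder = 2) {
  arr <- if (inherits(cube, "hyper_cube")) cube$data else cube
  B <- dim(arr)[3]
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > B) stop("window exceeds the number of bands", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  sm <- t(apply(m, 1, function(s) signal::sgolayfilt(s, p = polyorder, n = window)))
  out <- array(sm, d)
  if (inherits(cube, "hyper_cube")) {
    cube$data <- out
    cube$provenance <- paste0(cube$provenance, "+sg")
    cube
  } else out
}

#' PCA truncation denoising baseline
#'
#' Flattens the cube to a `(H*W) x B` pixels-by-bands matrix, centers the
#' bands, projects onto the top `k` principal components, reconstructs
#' and re-adds the band means. Equivalent to the rank-`k` truncated-SVD
#' reconstruction of the centered matrix; `k` at full rank is the
#' identity.
#'
#' @param cube A [hyper_cube] or 3-d array `[H, W, B]`.
#' @param k Number of components, `1 <= k <= min(H*W, B)`.
#' @return Denoised data of the same type and shape.
#' @export
pca_denoise <- function(cube, k = 5) {
  arr <- if (inherits(cube, "hyper_cube")) cube$data else cube
  d <- dim(arr)
  m <- matrix(arr, d[1] * d[2], d[3])
  if (k < 1 || k > min(dim(m)))
    stop(sprintf("k must lie in [1, %d]", min(dim(m))), call. = FALSE)
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  sv <- svd(mc, nu = k, nv = k)
  rec <- sv$u %*% (diag(sv$d[seq_len(k)], k, k) %*% t(sv$v))
  out <- array(sweep(rec, 2, mu, `+`), d)
  if (inherits(cube, "hyper_cube")) {
    cube$data <- out
    cube$provenance <- paste0(cube$provenance, "+pca")
    cube
  } else out
}
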