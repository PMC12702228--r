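# Independent brute-force oracles and small fixtures shared by the tests.
# The oracles deliberately use naive nested loops / direct formulas so they
# share no code with the implementation paths they check.

# naive zero-padded "same" grouped dilated 3D convolution
oracle_conv3d <- function(x, w, bias, dil = c(1, 1, 1), groups = 1) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[3]; Cin <- d[4]
  wd <- dim(w); kh <- wd[1]; kw <- wd[2]; kb <- wd[3]
  Cing <- wd[4]; Cout <- wd[5]
  cpg <- Cout / groups
  y <- array(0, c(H, W, B, Cout))
  for (co in seq_len(Cout)) {
    g <- (co - 1) %/% cpg
    for (h in seq_len(H)) for (ww in seq_len(W)) for (b in seq_len(B)) {
      acc <- bias[co]
      for (cl in seq_len(Cing)) {
        ci <- g * Cing + cl
        for (ti in seq_len(kh)) for (tj in seq_len(kw)) for (tk in seq_len(kb)) {
          hh <- h + (ti - 1 - kh %/% 2) * dil[1]
          wv <- ww + (tj - 1 - kw %/% 2) * dil[2]
          bb <- b + (tk - 1 - kb %/% 2) * dil[3]
          if (hh >= 1 && hh <= H && wv >= 1 && wv <= W && bb >= 1 && bb <= B)
            acc <- acc + w[ti, tj, tk, cl, co] * x[hh, wv, bb, ci]
        }
      }
      y[h, ww, b, co] <- acc
    }
  }
  y
}

# depthwise-then-pointwise composition via the naive conv
oracle_ds_conv <- function(x, depthwise, pointwise, dil = c(1, 1, 1)) {
  cin <- dim(x)[4]
  mid <- oracle_conv3d(x, depthwise, numeric(cin), dil, groups = cin)
  oracle_conv3d(mid, pointwise, numeric(dim(pointwise)[5]))
}

# whole-image SSIM from first principles (population moments)
oracle_ssim_global <- function(x, y, R = 1) {
  C1 <- (0.01 * R)^2; C2 <- (0.03 * R)^2
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  vx <- sum((x - mx)^2) / n; vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  (2 * mx * my + C1) * (2 * cxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

# Savitzky-Golay coefficients from the least-squares design matrix
oracle_sg_kernel <- function(window, polyorder) {
  half <- (window - 1) / 2
  A <- outer(-half:half, 0:polyorder, `^`)
  (solve(crossprod(A)) %*% t(A))[1, ]
}

# tiny deterministic test cube with distinct float32-exact values
make_test_cube <- function(h = 4, w = 4, b = 8, seed = 1) {
  set.seed(seed)
  hyper_cube(as_float32(array(runif(h * w * b, 0, 100), c(h, w, b))),
             seq(600, 1800, length.out = b),
             pixel_size = 0.5, integration_time = 0.5,
             provenance = "test")
}

tiny_phantom <- function(...) {
  args <- list(...)
  defaults <- list(height = 16, width = 16, n_bands = 32, n_cells = 1,
                   cell_radius_range = c(3, 5))
  do.call(phantom_spec, utils::modifyList(defaults, args))
}
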