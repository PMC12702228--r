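#' Specify the depthwise separable 3D MultiResU-Net
#'
#' Architecture hyperparameters of the spatial-spectral denoiser: a 3D
#' U-Net whose convolutions are depthwise separable, with residual blocks
#' in encoder and decoder and (optionally) a pseudo-3D multi-scale feature
#' fusion module with channel attention on every skip connection.
#'
#' The default fusion inventory carries four spatial branches (two 3x3x1
#' and two 5x5x1 convolutions) and four spectral branches (1x1x3, 1x1x5,
#' 1x1x5 with dilation 5, 1x1x7 with dilation 7), matching the pseudo-3D
#' decomposition of spatial and spectral filtering.
#'
#' @param n_levels Encoder depth (>= 1, default 3); each level halves H, W
#'   and B via 2x2x2 max pooling.
#' @param base_channels Channel width of the first level (default 16).
#'   With fusion enabled it must be divisible by the number of fusion
#'   branches (8) so each branch can carry `C/8` channels.
#' @param channel_growth Per-level width multiplier (default 2).
#' @param use_fusion Enable the multi-scale feature fusion module on the
#'   skip connections (ablation switch, default `TRUE`).
#' @param attention_reduction Squeeze-and-excitation bottleneck ratio
#'   (default 8); channels at every level must be >= this.
#' @param spatial_kernels Integer vector of odd spatial kernel sizes `k`
#'   for the `k x k x 1` fusion branches (default `c(3, 3, 5, 5)`).
#' @param spectral_kernels Two-column matrix (or list of pairs) of odd
#'   spectral kernel sizes and dilations for the `1 x 1 x k` branches
#'   (default `(3,1), (5,1), (5,5), (7,7)`).
#' @param norm_then_act Ordering flag: `TRUE` (default) applies
#'   conv -> batch norm -> PReLU; `FALSE` swaps norm and activation.
#' @param global_residual Learn the correction to the input rather than
#'   the clean signal directly (default `TRUE`): the network output is
#'   added to its input, and the head convolution starts at zero so the
#'   untrained model is exactly the identity. Standard residual-learning
#'   practice for image restoration; it makes short training runs start
#'   from the noisy input's quality instead of from scratch.
#' @return A `network_spec` object.
#' @export
network_spec <- function(n_levels = 3, base_channels = 16, channel_growth = 2,
                         use_fusion = TRUE, attention_reduction = 8,
                         spatial_kernels = c(3, 3, 5, 5),
                         spectral_kernels = cbind(k = c(3, 5, 5, 7),
                                                  dilation = c(1, 1, 5, 7)),
                         norm_then_act = TRUE, global_residual = TRUE) {
  if (n_levels < 1) stop("n_levels must be >= 1", call. = FALSE)
  if (base_channels < 1) stop("base_channels must be >= 1", call. = FALSE)
  if (is.list(spectral_kernels))
    spectral_kernels <- do.call(rbind, spectral_kernels)
  spectral_kernels <- matrix(as.numeric(spectral_kernels), ncol = 2,
                             dimnames = list(NULL, c("k", "dilation")))
  ks <- c(spatial_kernels, spectral_kernels[, "k"])
  if (any(ks %% 2 == 0)) stop("all kernel sizes must be odd", call. = FALSE)
  if (any(spectral_kernels[, "dilation"] < 1))
    stop("dilations must be >= 1", call. = FALSE)
  n_branches <- length(spatial_kernels) + nrow(spectral_kernels)
  if (use_fusion && base_channels %% n_branches != 0)
    stop(sprintf("with fusion enabled base_channels must be divisible by %d",
                 n_branches), call. = FALSE)
  if (use_fusion && base_channels < attention_reduction)
    stop("channels must be >= attention_reduction", call. = FALSE)
  structure(list(n_levels = as.integer(n_levels),
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 use_fusion = isTRUE(use_fusion),
                 attention_reduction = as.integer(attention_reduction),
                 spatial_kernels = as.integer(spatial_kernels),
                 spectral_kernels = spectral_kernels,
                 norm_then_act = isTRUE(norm_then_act),
                 global_residual = isTRUE(global_residual)),
            class = "network_spec")
}

# channel width at level l (level n_levels + 1 is the bottleneck)
level_channels <- function(spec, l) {
  as.integer(round(spec$base_channels * spec$channel_growth^(l - 1)))
}

#' Multi-scale fusion branch inventory
#'
#' Introspection helper: the kernel/dilation inventory of the pseudo-3D
#' multi-scale convolution module, one row per branch.
#'
#' @param spec A [network_spec].
#' @return Data frame with columns `domain` ("spatial"/"spectral"),
#'   `kh`, `kw`, `kb`, `dilation`, and `effective_span` (the dilated
#'   spectral footprint `(k - 1) * d + 1`).
#' @export
fusion_branches <- function(spec = network_spec()) {
  sp <- data.frame(domain = "spatial",
                   kh = spec$spatial_kernels, kw = spec$spatial_kernels,
                   kb = 1L, dilation = 1L)
  st <- data.frame(domain = "spectral", kh = 1L, kw = 1L,
                   kb = as.integer(spec$spectral_kernels[, "k"]),
                   dilation = as.integer(spec$spectral_kernels[, "dilation"]))
  out <- rbind(sp, st)
  out$effective_span <- (pmax(out$kh, out$kb) - 1L) * out$dilation + 1L
  out
}

#' Parameter counts of depthwise separable vs standard 3D convolution
#'
#' Weight counts (excluding biases) for a `k x k x k` convolution mapping
#' `c_in` to `c_out` channels: the separable factorization costs
#' `c_in * k^3 + c_in * c_out` against `c_in * c_out * k^3` for the
#' standard kernel.
#'
#' @param c_in,c_out Channel counts.
#' @param k Kernel size.
#' @return Named vector with elements `separable` and `standard`.
#' @export
ds_conv_param_count <- function(c_in, c_out, k) {
  c(separable = c_in * k^3 + c_in * c_out,
    standard = c_in * c_out * k^3)
}

## ---- parameter initialization ----------------------------------------

init_conv <- function(p, nm, kh, kw, kb, cin_g, cout, bias = TRUE) {
  fan_in <- kh * kw * kb * cin_g
  p[[pname(nm, "w")]] <- array(stats::rnorm(kh * kw * kb * cin_g * cout,
                                            sd = sqrt(2 / fan_in)),
                               c(kh, kw, kb, cin_g, cout))
  p[[pname(nm, "b")]] <- if (bias) numeric(cout) else numeric(cout)
  p
}

init_resblock <- function(p, nm, cin, cout) {
  p <- init_conv(p, pname(nm, "dw"), 3, 3, 3, 1, cin)        # depthwise
  p <- init_conv(p, pname(nm, "pw"), 1, 1, 1, cin, cout)     # pointwise
  p[[pname(nm, "bn.gamma")]] <- rep(1, cout)
  p[[pname(nm, "bn.beta")]] <- numeric(cout)
  p[[pname(nm, "act.a")]] <- rep(0.25, cout)
  if (cin != cout)
    p <- init_conv(p, pname(nm, "proj"), 1, 1, 1, cin, cout)
  p
}

init_fusion <- function(p, nm, C, spec) {
  br <- fusion_branches(spec)
  cb <- C %/% nrow(br)
  for (i in seq_len(nrow(br)))
    p <- init_conv(p, pname(nm, paste0("br", i)),
                   br$kh[i], br$kw[i], br$kb[i], C, cb)
  cr <- max(1L, C %/% spec$attention_reduction)
  p[[pname(nm, "se.w1")]] <- matrix(stats::rnorm(C * cr, sd = sqrt(2 / C)), C, cr)
  p[[pname(nm, "se.b1")]] <- numeric(cr)
  p[[pname(nm, "se.w2")]] <- matrix(stats::rnorm(cr * C, sd = sqrt(2 / cr)), cr, C)
  p[[pname(nm, "se.b2")]] <- numeric(C)
  p
}

#' Initialize network parameters
#'
#' He-style random initialization of every convolution, unit batch-norm
#' scales and PReLU slopes of 0.25, reproducible from `seed`.
#'
#' @param spec A [network_spec].
#' @param seed Integer RNG seed.
#' @return Named list of parameter arrays.
#' @export
init_network <- function(spec, seed = 1L) {
  with_seed(seed, {
    p <- list()
    L <- spec$n_levels
    cin <- 1L
    for (l in seq_len(L)) {
      cl <- level_channels(spec, l)
      p <- init_resblock(p, sprintf("enc%d", l), cin, cl)
      if (spec$use_fusion) p <- init_fusion(p, sprintf("fus%d", l), cl, spec)
      cin <- cl
    }
    cb <- level_channels(spec, L + 1)
    p <- init_resblock(p, "bott", cin, cb)
    for (l in rev(seq_len(L))) {
      cl <- level_channels(spec, l)
      cup <- level_channels(spec, l + 1)
      p <- init_conv(p, sprintf("up%d", l), 1, 1, 1, cup, cl)
      p <- init_resblock(p, sprintf("dec%d", l), 2L * cl, cl)
    }
    p <- init_conv(p, "head", 1, 1, 1, level_channels(spec, 1), 1L)
    if (spec$global_residual) {
      # zero head: the untrained residual model is exactly the identity
      p[["head.w"]][] <- 0
    }
    p
  })
}

#' Count network parameters
#'
#' @param x A parameter list (from [init_network]) or a fitted
#'   `raman_denoiser`.
#' @return Total number of scalar parameters.
#' @export
count_params <- function(x) {
  if (inherits(x, "raman_denoiser")) x <- x$params
  sum(vapply(x, length, 0))
}

## ---- building-block forward/backward ---------------------------------

resblock_fw <- function(p, nm, xs, spec, train, state) {
  cin <- dim(p[[pname(nm, "pw.w")]])[4]
  cout <- dim(p[[pname(nm, "pw.w")]])[5]
  dw <- conv_fw(p, pname(nm, "dw"), xs, groups = cin)
  pw <- conv_fw(p, pname(nm, "pw"), dw$y)
  if (spec$norm_then_act) {
    bn <- bn_fw(p, pname(nm, "bn"), pw$y, train, state); state <- bn$state
    act <- prelu_fw(p, pname(nm, "act"), bn$y)
    t_out <- act$y
  } else {
    act <- prelu_fw(p, pname(nm, "act"), pw$y)
    bn <- bn_fw(p, pname(nm, "bn"), act$y, train, state); state <- bn$state
    t_out <- bn$y
  }
  if (cin == cout) {
    short <- xs
    proj_cache <- NULL
  } else {
    pr <- conv_fw(p, pname(nm, "proj"), xs)
    short <- pr$y
    proj_cache <- pr$cache
  }
  list(y = batch_add(t_out, short),
       cache = list(nm = nm, dw = dw$cache, pw = pw$cache, bn = bn$cache,
                    act = act$cache, proj = proj_cache, identity = cin == cout),
       state = state)
}

resblock_bw <- function(p, gacc, cache, gys, spec) {
  if (spec$norm_then_act) {
    g <- prelu_bw(p, gacc, cache$act, gys)
    g <- bn_bw(p, gacc, cache$bn, g)
  } else {
    g <- bn_bw(p, gacc, cache$bn, gys)
    g <- prelu_bw(p, gacc, cache$act, g)
  }
  g <- conv_bw(p, gacc, cache$pw, g)
  g <- conv_bw(p, gacc, cache$dw, g)
  g_short <- if (cache$identity) gys else conv_bw(p, gacc, cache$proj, gys)
  batch_add(g, g_short)
}

fusion_fw <- function(p, nm, xs, spec) {
  br <- fusion_branches(spec)
  B_ext <- dim(xs[[1]])[3]
  if (B_ext < max(br$kb) || dim(xs[[1]])[1] < max(br$kh))
    stop(sprintf("fusion input extent too small for a %dx%dx%d kernel",
                 max(br$kh), max(br$kh), max(br$kb)), call. = FALSE)
  outs <- vector("list", nrow(br))
  caches <- vector("list", nrow(br))
  for (i in seq_len(nrow(br))) {
    dil <- if (br$domain[i] == "spectral") c(1L, 1L, br$dilation[i])
           else c(br$dilation[i], br$dilation[i], 1L)
    cv <- conv_fw(p, pname(nm, paste0("br", i)), xs, dil = dil)
    outs[[i]] <- cv$y
    caches[[i]] <- cv$cache
  }
  cat_y <- Reduce(batch_concat, outs)
  se <- se_fw(p, pname(nm, "se"), cat_y)
  list(y = se$y,
       cache = list(nm = nm, branches = caches, se = se$cache,
                    widths = vapply(outs, function(o) dim(o[[1]])[4], 0L)))
}

fusion_bw <- function(p, gacc, cache, gys) {
  g <- se_bw(p, gacc, cache$se, gys)
  # un-concatenate into per-branch gradients
  gx_total <- NULL
  offset <- 0L
  for (i in seq_along(cache$branches)) {
    wi <- cache$widths[i]
    gb <- lapply(g, function(gg) gg[, , , offset + seq_len(wi), drop = FALSE])
    offset <- offset + wi
    gxi <- conv_bw(p, gacc, cache$branches[[i]], gb)
    gx_total <- if (is.null(gx_total)) gxi else batch_add(gx_total, gxi)
  }
  gx_total
}

## ---- full network ----------------------------------------------------

forward_network <- function(p, xs, spec, train = FALSE, state = list()) {
  L <- spec$n_levels
  ext <- dim(xs[[1]])[1:3]
  if (any(ext %% 2^L != 0))
    stop(sprintf(
      "input extent %s not divisible by 2^%d; pad to multiples of %d first",
      paste(ext, collapse = "x"), L, 2^L), call. = FALSE)
  caches <- list(enc = vector("list", L), fus = vector("list", L),
                 pool = vector("list", L), up = vector("list", L),
                 upconv = vector("list", L), dec = vector("list", L),
                 skip_ch = integer(L))
  skips <- vector("list", L)
  x <- xs
  for (l in seq_len(L)) {
    rb <- resblock_fw(p, sprintf("enc%d", l), x, spec, train, state)
    state <- rb$state
    caches$enc[[l]] <- rb$cache
    if (spec$use_fusion) {
      fs <- fusion_fw(p, sprintf("fus%d", l), rb$y, spec)
      caches$fus[[l]] <- fs$cache
      skips[[l]] <- fs$y
    } else {
      skips[[l]] <- rb$y
    }
    caches$skip_ch[l] <- dim(skips[[l]][[1]])[4]
    pl <- pool_fw(rb$y)
    caches$pool[[l]] <- pl$cache
    x <- pl$y
  }
  rb <- resblock_fw(p, "bott", x, spec, train, state)
  state <- rb$state
  caches$bott <- rb$cache
  x <- rb$y
  for (l in rev(seq_len(L))) {
    up <- upsample_fw(x)
    caches$up[[l]] <- up$cache
    uc <- conv_fw(p, sprintf("up%d", l), up$y)
    caches$upconv[[l]] <- uc$cache
    x <- batch_concat(skips[[l]], uc$y)
    rb <- resblock_fw(p, sprintf("dec%d", l), x, spec, train, state)
    state <- rb$state
    caches$dec[[l]] <- rb$cache
    x <- rb$y
  }
  hd <- conv_fw(p, "head", x)
  caches$head <- hd$cache
  y <- if (spec$global_residual) batch_add(hd$y, xs) else hd$y
  list(y = y, caches = caches, state = state)
}

backward_network <- function(p, caches, gys, spec) {
  L <- spec$n_levels
  gacc <- new.env(parent = emptyenv())
  g <- conv_bw(p, gacc, caches$head, gys)
  g_skip <- vector("list", L)
  for (l in seq_len(L)) {
    g <- resblock_bw(p, gacc, caches$dec[[l]], g, spec)
    sp <- batch_split(g, caches$skip_ch[l])
    g_skip[[l]] <- sp$first
    g <- conv_bw(p, gacc, caches$upconv[[l]], sp$second)
    g <- upsample_bw(caches$up[[l]], g)
  }
  g <- resblock_bw(p, gacc, caches$bott, g, spec)
  for (l in rev(seq_len(L))) {
    g <- pool_bw(caches$pool[[l]], g)
    gs <- if (spec$use_fusion) fusion_bw(p, gacc, caches$fus[[l]], g_skip[[l]])
          else g_skip[[l]]
    g <- batch_add(g, gs)
    g <- resblock_bw(p, gacc, caches$enc[[l]], g, spec)
  }
  as.list(gacc)
}

## ---- functional op exposure ------------------------------------------

#' Depthwise separable 3D convolution
#'
#' The factorized convolution: a per-channel (depthwise) `k x k x k`
#' filter followed by a `1 x 1 x 1` pointwise channel mixing. Zero-padded
#' "same"; weight count is `C_in * k^3 + C_in * C_out` against
#' `C_in * C_out * k^3` for the standard 3D kernel.
#'
#' @param x Numeric array `[H, W, B, C_in]`.
#' @param depthwise Array `[k, k, k, 1, C_in]` of per-channel kernels.
#' @param pointwise Array `[1, 1, 1, C_in, C_out]` of mixing weights.
#' @param bias_dw,bias_pw Optional bias vectors (default zero).
#' @param dilation Integer length-3 dilation (default 1).
#' @return Array `[H, W, B, C_out]`.
#' @export
ds_conv3d <- function(x, depthwise, pointwise, bias_dw = NULL, bias_pw = NULL,
                      dilation = c(1, 1, 1)) {
  xd <- as.integer(dim(x))
  if (length(xd) != 4L) stop("x must be [H, W, B, C]", call. = FALSE)
  wd <- as.integer(dim(depthwise))
  if (any(wd[1:3] %% 2 == 0)) stop("kernel sizes must be odd", call. = FALSE)
  cin <- xd[4]
  if (wd[4] != 1L || wd[5] != cin)
    stop("depthwise kernels must be [k, k, k, 1, C_in]", call. = FALSE)
  if (is.null(bias_dw)) bias_dw <- numeric(cin)
  pd <- as.integer(dim(pointwise))
  if (is.null(bias_pw)) bias_pw <- numeric(pd[5])
  mid <- conv3d_fw(x, xd, depthwise, wd, bias_dw, as.integer(dilation), cin)
  dim(mid) <- c(xd[1:3], cin)
  out <- conv3d_fw(mid, as.integer(dim(mid)), pointwise, pd, bias_pw,
                   c(1L, 1L, 1L), 1L)
  dim(out) <- c(xd[1:3], pd[5])
  out
}

#' Squeeze-and-excitation channel attention
#'
#' Global average pooling over the spatial-spectral volume, a two-layer
#' bottleneck `C -> C/r -> C` with ReLU then sigmoid, and per-channel
#' rescaling of the input. Attention weights lie strictly in (0, 1).
#'
#' @param x Numeric array `[H, W, B, C]`.
#' @param w1 `C x Cr` matrix, `b1` length-`Cr` bias (squeeze layer).
#' @param w2 `Cr x C` matrix, `b2` length-`C` bias (excite layer).
#' @return List with `y` (reweighted volume) and `weights` (the per-channel
#'   attention vector).
#' @export
channel_attention <- function(x, w1, b1, w2, b2) {
  C <- dim(x)[4]
  if (nrow(w1) != C) stop("w1 must have C rows", call. = FALSE)
  if (C < ncol(w1)) stop("channels must be >= bottleneck width", call. = FALSE)
  z <- chan_stats(x, C)$sum / prod(dim(x)[1:3])
  h <- pmax(drop(crossprod(w1, z)) + b1, 0)
  s <- sigmoid(drop(crossprod(w2, h)) + b2)
  list(y = chan_scale(x, s), weights = s)
}

## ---- padding helpers -------------------------------------------------

# reflect-pad a [H,W,B] or [H,W,B,C] array so each of the first three
# extents is a multiple of m; returns the padded array and the crop index
pad_to_multiple <- function(x, m) {
  d <- dim(x)
  ext <- d[1:3]
  target <- ceiling(ext / m) * m
  pad <- target - ext
  if (all(pad == 0)) return(list(x = x, crop = lapply(ext, seq_len)))
  idx <- lapply(seq_len(3), function(a) {
    n <- ext[a]
    want <- target[a]
    i <- seq_len(n)
    # reflect (without repeating the edge sample) until long enough
    while (length(i) < want) {
      extra <- rev(seq_len(n - 1L))
      i <- c(i, extra[seq_len(min(length(extra), want - length(i)))])
    }
    i[seq_len(want)]
  })
  xp <- if (length(d) == 3L) x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
        else x[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  list(x = xp, crop = lapply(ext, seq_len))
}
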