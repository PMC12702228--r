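# Layer-level forward/backward primitives.
#
# Activations are numeric arrays [H, W, B, C]; a mini-batch is a plain list
# of such arrays (batch norm aggregates statistics across the list).
# Parameters live in a flat named list; gradients are accumulated into an
# environment keyed by the same names. Every layer here has a matching
# _fw/_bw pair; the backward passes are validated against finite
# differences in the test suite.

pname <- function(nm, what) paste0(nm, ".", what)

acc_grad <- function(gacc, name, value) {
  cur <- gacc[[name]]
  gacc[[name]] <- if (is.null(cur)) value else cur + value
  invisible(NULL)
}

# per-channel scale/shift on an [H,W,B,C] array (or V x C matrix view),
# backed by the fused C++ kernel
chan_scale <- function(x, s) {
  C <- dim(x)[length(dim(x))]
  y <- chan_axpb(x, C, s, 0)
  dim(y) <- dim(x)
  y
}

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}
as_vol <- function(m, d) { dim(m) <- d; m }

## ---- convolution -----------------------------------------------------

is_pointwise <- function(wd, groups) all(wd[1:3] == 1L) && groups == 1L

conv_fw <- function(p, nm, xs, dil = c(1L, 1L, 1L), groups = 1L) {
  w <- p[[pname(nm, "w")]]; b <- p[[pname(nm, "b")]]
  wd <- as.integer(dim(w))
  ys <- if (is_pointwise(wd, groups)) {
    wm <- matrix(w, wd[4], wd[5])
    lapply(xs, function(x) {
      ym <- as_mat(x) %*% wm
      as_vol(chan_axpb(ym, wd[5], 1, b), c(dim(x)[1:3], wd[5]))
    })
  } else {
    lapply(xs, function(x) {
      xd <- as.integer(dim(x))
      y <- conv3d_fw(x, xd, w, wd, b, as.integer(dil), as.integer(groups))
      dim(y) <- c(xd[1:3], wd[5])
      y
    })
  }
  list(y = ys, cache = list(nm = nm, x = xs, dil = dil, groups = groups))
}

# the transpose of a zero-padded "same" odd-kernel dilated convolution is
# the same convolution with taps flipped and channel roles swapped
flip_transpose_weights <- function(w, groups) {
  wd <- dim(w)
  kh <- wd[1]; kw <- wd[2]; kb <- wd[3]
  cing <- wd[4]; cout <- wd[5]
  cpg <- cout %/% groups
  wt <- array(0, c(kh, kw, kb, cpg, cing * groups))
  wf <- w[rev(seq_len(kh)), rev(seq_len(kw)), rev(seq_len(kb)), , ,
          drop = FALSE]
  for (g in seq_len(groups) - 1L)
    for (cl in seq_len(cing))
      for (cc in seq_len(cpg))
        wt[, , , cc, g * cing + cl] <- wf[, , , cl, g * cpg + cc]
  wt
}

conv_bw <- function(p, gacc, cache, gys) {
  nm <- cache$nm
  w <- p[[pname(nm, "w")]]
  wd <- as.integer(dim(w))
  groups <- as.integer(cache$groups)
  gxs <- vector("list", length(gys))
  gw <- 0; gb <- 0
  if (is_pointwise(wd, groups)) {
    wm <- matrix(w, wd[4], wd[5])
    for (i in seq_along(gys)) {
      gm <- as_mat(gys[[i]])
      xm <- as_mat(cache$x[[i]])
      gxs[[i]] <- as_vol(tcrossprod(gm, wm), dim(cache$x[[i]]))
      gw <- gw + crossprod(xm, gm)
      gb <- gb + .colSums(gm, nrow(gm), ncol(gm))
    }
  } else {
    wt <- flip_transpose_weights(w, groups)
    wtd <- as.integer(dim(wt))
    for (i in seq_along(gys)) {
      g <- gys[[i]]
      gd <- as.integer(dim(g))
      gx <- conv3d_fw(g, gd, wt, wtd, numeric(wtd[5]),
                      as.integer(cache$dil), groups)
      dim(gx) <- dim(cache$x[[i]])
      gxs[[i]] <- gx
      r <- conv3d_gw(cache$x[[i]], as.integer(dim(cache$x[[i]])), wd, g,
                     as.integer(cache$dil), groups)
      gw <- gw + r$gw
      gb <- gb + r$gb
    }
  }
  acc_grad(gacc, pname(nm, "w"), array(gw, dim(w)))
  acc_grad(gacc, pname(nm, "b"), as.numeric(gb))
  gxs
}

## ---- batch normalization ---------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fw <- function(p, nm, xs, train, state) {
  gamma <- p[[pname(nm, "gamma")]]; beta <- p[[pname(nm, "beta")]]
  C <- length(gamma)
  if (train) {
    N <- sum(vapply(xs, function(x) prod(dim(x)[1:3]), 0))
    st <- lapply(xs, chan_stats, C = C)
    m <- Reduce(`+`, lapply(st, `[[`, "sum")) / N
    v <- pmax(Reduce(`+`, lapply(st, `[[`, "sumsq")) / N - m^2, 0)
    invstd <- 1 / sqrt(v + BN_EPS)
    # xhat = x * invstd - m * invstd ; y = xhat * gamma + beta
    xhat <- lapply(xs, function(x)
      as_vol(chan_axpb(x, C, invstd, -m * invstd), dim(x)))
    ys <- lapply(xhat, function(h)
      as_vol(chan_axpb(h, C, gamma, beta), dim(h)))
    state[[pname(nm, "mean")]] <-
      (1 - BN_MOMENTUM) * (state[[pname(nm, "mean")]] %||% 0) + BN_MOMENTUM * m
    state[[pname(nm, "var")]] <-
      (1 - BN_MOMENTUM) * (state[[pname(nm, "var")]] %||% 1) + BN_MOMENTUM * v
    list(y = ys, cache = list(nm = nm, xhat = xhat, invstd = invstd,
                              gamma = gamma, N = N), state = state)
  } else {
    m <- state[[pname(nm, "mean")]] %||% rep(0, C)
    v <- state[[pname(nm, "var")]] %||% rep(1, C)
    s <- gamma / sqrt(v + BN_EPS)
    ys <- lapply(xs, function(x)
      as_vol(chan_axpb(x, C, s, beta - m * s), dim(x)))
    list(y = ys, cache = NULL, state = state)
  }
}

bn_bw <- function(p, gacc, cache, gys) {
  nm <- cache$nm
  gamma <- cache$gamma
  C <- length(gamma)
  N <- cache$N
  # per-channel reductions over the whole batch
  sum_gy <- Reduce(`+`, lapply(gys, function(g)
    chan_stats(g, C)$sum))
  sum_gy_xhat <- Reduce(`+`, Map(function(g, h) chan_dot(g, h, C),
                                 gys, cache$xhat))
  acc_grad(gacc, pname(nm, "gamma"), sum_gy_xhat)
  acc_grad(gacc, pname(nm, "beta"), sum_gy)
  coef <- gamma * cache$invstd
  # gx = coef * (gy - sum_gy/N - xhat * sum_gy_xhat/N)
  gxs <- Map(function(g, h)
    as_vol(chan_lincomb(g, h, C, coef, -coef * sum_gy_xhat / N,
                        -coef * sum_gy / N), dim(g)),
    gys, cache$xhat)
  gxs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- PReLU -----------------------------------------------------------

prelu_fw <- function(p, nm, xs) {
  a <- p[[pname(nm, "a")]]
  C <- length(a)
  ys <- lapply(xs, function(x) as_vol(prelu_fw_cpp(x, C, a), dim(x)))
  list(y = ys, cache = list(nm = nm, x = xs, a = a))
}

prelu_bw <- function(p, gacc, cache, gys) {
  a <- cache$a
  C <- length(a)
  ga <- 0
  gxs <- Map(function(g, x) {
    r <- prelu_bw_cpp(x, C, a, g)
    ga <<- ga + r$ga
    as_vol(r$gx, dim(g))
  }, gys, cache$x)
  acc_grad(gacc, pname(cache$nm, "a"), ga)
  gxs
}

## ---- pooling / upsampling --------------------------------------------

pool_fw <- function(xs) {
  res <- lapply(xs, function(x) {
    xd <- as.integer(dim(x))
    r <- maxpool2_fw(x, xd)
    dim(r$y) <- c(xd[1:3] %/% 2L, xd[4])
    r
  })
  list(y = lapply(res, `[[`, "y"),
       cache = list(argmax = lapply(res, `[[`, "argmax"),
                    xdim = lapply(xs, dim)))
}

pool_bw <- function(cache, gys) {
  Map(function(g, am, xd) {
    gx <- maxpool2_bw(g, am, as.integer(xd))
    dim(gx) <- xd
    gx
  }, gys, cache$argmax, cache$xdim)
}

upsample_fw <- function(xs) {
  ys <- lapply(xs, function(x) {
    xd <- as.integer(dim(x))
    y <- upsample2_fw(x, xd)
    dim(y) <- c(xd[1:3] * 2L, xd[4])
    y
  })
  list(y = ys, cache = list(xdim = lapply(xs, dim)))
}

upsample_bw <- function(cache, gys) {
  Map(function(g, xd) {
    gx <- upsample2_bw(g, as.integer(xd))
    dim(gx) <- xd
    gx
  }, gys, cache$xdim)
}

## ---- squeeze-and-excitation channel attention ------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

se_fw <- function(p, nm, xs) {
  w1 <- p[[pname(nm, "w1")]]; b1 <- p[[pname(nm, "b1")]]
  w2 <- p[[pname(nm, "w2")]]; b2 <- p[[pname(nm, "b2")]]
  caches <- vector("list", length(xs))
  ys <- vector("list", length(xs))
  for (i in seq_along(xs)) {
    x <- xs[[i]]
    C <- dim(x)[4]
    V <- prod(dim(x)[1:3])
    z <- chan_stats(x, C)$sum / V
    h <- pmax(drop(crossprod(w1, z)) + b1, 0)
    s <- sigmoid(drop(crossprod(w2, h)) + b2)
    ys[[i]] <- chan_scale(x, s)
    caches[[i]] <- list(x = x, z = z, h = h, s = s, V = V)
  }
  list(y = ys, cache = list(nm = nm, per = caches, w1 = w1, w2 = w2))
}

se_bw <- function(p, gacc, cache, gys) {
  nm <- cache$nm
  w1 <- cache$w1; w2 <- cache$w2
  gxs <- vector("list", length(gys))
  gw1 <- 0; gb1 <- 0; gw2 <- 0; gb2 <- 0
  for (i in seq_along(gys)) {
    cc <- cache$per[[i]]
    g <- gys[[i]]
    C <- dim(g)[4]
    gs <- chan_dot(g, cc$x, C)
    dlogit <- gs * cc$s * (1 - cc$s)
    gw2 <- gw2 + outer(cc$h, dlogit)
    gb2 <- gb2 + dlogit
    gh <- drop(w2 %*% dlogit) * (cc$h > 0)
    gw1 <- gw1 + outer(cc$z, gh)
    gb1 <- gb1 + gh
    gz <- drop(w1 %*% gh)
    # gx = gy * s[c] + gz[c] / V  (attention path + pooled path)
    gxs[[i]] <- as_vol(chan_axpb(g, C, cc$s, gz / cc$V), dim(g))
  }
  acc_grad(gacc, pname(nm, "w1"), gw1)
  acc_grad(gacc, pname(nm, "b1"), gb1)
  acc_grad(gacc, pname(nm, "w2"), gw2)
  acc_grad(gacc, pname(nm, "b2"), gb2)
  gxs
}

## ---- batch-list helpers ----------------------------------------------

batch_add <- function(xs, ys) Map(`+`, xs, ys)

batch_concat <- function(xs, ys) {
  Map(function(a, b) {
    d <- dim(a)
    out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
    out[, , , seq_len(d[4])] <- a
    out[, , , d[4] + seq_len(dim(b)[4])] <- b
    out
  }, xs, ys)
}

batch_split <- function(gs, c1) {
  list(first = lapply(gs, function(g) g[, , , seq_len(c1), drop = FALSE]),
       second = lapply(gs, function(g) {
         g[, , , (c1 + 1):dim(g)[4], drop = FALSE]
       }))
}
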