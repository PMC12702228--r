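ns <- asNamespace("raman3d")
forward_network <- get("forward_network", ns)
backward_network <- get("backward_network", ns)
composite_loss_grad <- get("composite_loss_grad", ns)

test_that("depthwise separable convolution matches the naive two-stage oracle", {
  set.seed(4)
  x <- array(rnorm(4 * 4 * 4 * 2), c(4, 4, 4, 2))
  dw <- array(rnorm(3 * 3 * 3 * 1 * 2), c(3, 3, 3, 1, 2))
  pw <- array(rnorm(1 * 1 * 1 * 2 * 3), c(1, 1, 1, 2, 3))
  got <- ds_conv3d(x, dw, pw)
  want <- oracle_ds_conv(x, dw, pw)
  expect_lt(max(abs(got - want)), 1e-5)
})

test_that("centered delta kernels with identity mixing reproduce the input exactly", {
  set.seed(5)
  x <- array(rnorm(5 * 4 * 6 * 3), c(5, 4, 6, 3))
  dw <- array(0, c(3, 3, 3, 1, 3)); for (c in 1:3) dw[2, 2, 2, 1, c] <- 1
  pw <- array(0, c(1, 1, 1, 3, 3)); for (c in 1:3) pw[1, 1, 1, c, c] <- 1
  expect_identical(ds_conv3d(x, dw, pw), x)
})

test_that("separable factorization has the advertised parameter count", {
  counts <- ds_conv_param_count(8, 16, 3)
  expect_equal(unname(counts["separable"]), 8 * 27 + 8 * 16)
  expect_equal(unname(counts["separable"]), 344)
  expect_equal(unname(counts["standard"]), 3456)
})

test_that("dilated convolution agrees with the oracle and spans (k-1)*d+1 samples", {
  set.seed(6)
  x <- array(rnorm(2 * 2 * 50 * 1), c(2, 2, 50, 1))
  w <- array(rnorm(1 * 1 * 7), c(1, 1, 7, 1, 1))
  cf <- get("conv3d_fw", ns)
  got <- cf(x, dim(x), w, dim(w), 0, c(1L, 1L, 7L), 1L)
  dim(got) <- dim(x)
  expect_lt(max(abs(got - oracle_conv3d(x, w, numeric(1), c(1, 1, 7)))), 1e-10)
  # impulse response support equals the effective span
  imp <- array(0, c(1, 1, 101, 1)); imp[1, 1, 51, 1] <- 1
  wones <- array(1, c(1, 1, 7, 1, 1))
  resp <- cf(imp, dim(imp), wones, dim(wones), 0, c(1L, 1L, 7L), 1L)
  nz <- which(resp != 0)
  expect_equal(max(nz) - min(nz) + 1, (7 - 1) * 7 + 1)  # support spans 43 samples
  br <- fusion_branches(network_spec())
  expect_equal(br$effective_span[br$kb == 7 & br$dilation == 7], 43)
})

test_that("the default fusion inventory carries the published kernel list", {
  br <- fusion_branches(network_spec())
  sp <- br[br$domain == "spatial", ]
  expect_equal(sort(sp$kh), c(3, 3, 5, 5))
  expect_true(all(sp$kb == 1))
  st <- br[br$domain == "spectral", ]
  expect_true(all(st$kh == 1))
  expect_equal(unname(split(st$dilation, st$kb)),
               list(1, c(1, 5), 7))   # 1x1x3; 1x1x5 plain and dilated 5; 1x1x7 dilated 7
  expect_equal(nrow(br), 8)
})

test_that("channel attention matches a hand-rolled pool/affine/sigmoid oracle", {
  set.seed(7)
  x <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  w1 <- matrix(rnorm(2), 2, 1); b1 <- 0.3
  w2 <- matrix(rnorm(2), 1, 2); b2 <- c(-0.2, 0.4)
  got <- channel_attention(x, w1, b1, w2, b2)
  z <- c(mean(x[, , , 1]), mean(x[, , , 2]))
  h <- max(sum(w1 * z) + b1, 0)
  s <- 1 / (1 + exp(-(as.numeric(w2) * h + b2)))
  want <- x
  want[, , , 1] <- x[, , , 1] * s[1]
  want[, , , 2] <- x[, , , 2] * s[2]
  expect_lt(max(abs(got$y - want)), 1e-6)
  expect_true(all(got$weights > 0 & got$weights < 1))
  # identical channels receive identical weights
  xx <- x; xx[, , , 2] <- xx[, , , 1]
  ws <- channel_attention(xx, matrix(1, 2, 1), 0, matrix(1, 1, 2), c(0, 0))$weights
  expect_equal(ws[1], ws[2])
})

test_that("residual blocks reduce to the shortcut when the transform is zeroed", {
  spec <- network_spec(n_levels = 1, base_channels = 8, use_fusion = FALSE)
  p <- init_network(spec, seed = 3)
  # zero the encoder transform: output must equal the 1->8 projection
  p[["enc1.pw.w"]][] <- 0; p[["enc1.pw.b"]][] <- 0
  p[["enc1.bn.beta"]][] <- 0
  set.seed(8)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  rb <- get("resblock_fw", ns)(p, "enc1", list(x), spec, TRUE, list())
  proj <- oracle_conv3d(x, p[["enc1.proj.w"]], p[["enc1.proj.b"]])
  expect_lt(max(abs(rb$y[[1]] - proj)), 1e-10)
  # matching channels allocate no projection parameters
  expect_false("bott.proj.w" %in% names(p) &&
                 dim(p[["bott.pw.w"]])[4] == dim(p[["bott.pw.w"]])[5])
  spec2 <- network_spec(n_levels = 1, base_channels = 8,
                        channel_growth = 1, use_fusion = FALSE)
  p2 <- init_network(spec2, seed = 3)
  expect_false("bott.proj.w" %in% names(p2))  # 8 -> 8 bottleneck is identity-shortcut
})

test_that("the network preserves spatial-spectral extent and reports shape errors", {
  spec <- network_spec(n_levels = 2, base_channels = 8)
  p <- init_network(spec, seed = 1)
  x <- array(rnorm(16 * 16 * 32), c(16, 16, 32, 1))
  fw <- forward_network(p, list(x), spec, train = FALSE, state = list())
  expect_identical(dim(fw$y[[1]]), dim(x))
  bad <- array(0, c(15, 16, 32, 1))
  expect_error(forward_network(p, list(bad), spec, FALSE, list()),
               "divisible")
})

test_that("parameter count equals an independent layer-by-layer hand count", {
  spec <- network_spec(n_levels = 2, base_channels = 8, use_fusion = TRUE,
                       attention_reduction = 8)
  p <- init_network(spec, seed = 1)
  resblock <- function(cin, cout) {
    n <- cin * 27 + cin +          # depthwise w + b
      cin * cout + cout +          # pointwise w + b
      2 * cout +                   # batch norm gamma/beta
      cout                         # prelu slopes
    if (cin != cout) n <- n + cin * cout + cout  # projection w + b
    n
  }
  fusion <- function(C) {
    cb <- C / 8
    br <- (9 + 9 + 25 + 25 + 3 + 5 + 5 + 7) * C * cb + 8 * cb  # branch w + b
    cr <- C / 8
    br + C * cr + cr + cr * C + C                              # SE weights
  }
  hand <- resblock(1, 8) + fusion(8) +
    resblock(8, 16) + fusion(16) +
    resblock(16, 32) +
    (32 * 16 + 16) +               # up2 pointwise
    resblock(32, 16) +
    (16 * 8 + 8) +                 # up1 pointwise
    resblock(16, 8) +
    (8 * 1 + 1)                    # head
  expect_equal(count_params(p), hand)
})

test_that("parameter count grows with depth, width and the fusion switch", {
  n <- function(...) count_params(init_network(network_spec(...), seed = 1))
  base <- n(n_levels = 2, base_channels = 8)
  expect_gt(base, n(n_levels = 2, base_channels = 8, use_fusion = FALSE))
  expect_gt(n(n_levels = 3, base_channels = 8), base)
  expect_gt(n(n_levels = 2, base_channels = 16), base)
})

test_that("analytic gradients match finite differences through the whole network", {
  spec <- network_spec(n_levels = 2, base_channels = 8, use_fusion = TRUE)
  p <- init_network(spec, seed = 7)
  set.seed(42)
  xs <- list(array(rnorm(12 * 12 * 16), c(12, 12, 16, 1)))
  ts <- list(array(rnorm(12 * 12 * 16), c(12, 12, 16, 1)))
  lossfun <- function(pp) {
    fw <- forward_network(pp, xs, spec, train = TRUE, state = list())
    composite_loss(fw$y[[1]], ts[[1]])
  }
  fw <- forward_network(p, xs, spec, train = TRUE, state = list())
  gys <- list(composite_loss_grad(fw$y[[1]], ts[[1]]))
  gr <- backward_network(p, fw$caches, gys, spec)
  eps <- 1e-6
  set.seed(9)
  for (nm in sample(names(p), 10)) {
    idx <- sample(length(p[[nm]]), 1)
    p1 <- p; p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2 <- p; p2[[nm]][idx] <- p2[[nm]][idx] - eps
    fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    an <- gr[[nm]][idx]
    expect_lt(abs(fd - an), 1e-4 * max(1, abs(fd)))
  }
})

test_that("one gradient step decreases the loss for a small learning rate", {
  spec <- network_spec(n_levels = 1, base_channels = 8, use_fusion = FALSE)
  ok <- 0
  for (s in 1:5) {
    p <- init_network(spec, seed = s)
    set.seed(100 + s)
    xs <- list(array(rnorm(8 * 8 * 8), c(8, 8, 8, 1)))
    ts <- list(array(rnorm(8 * 8 * 8), c(8, 8, 8, 1)))
    fw <- forward_network(p, xs, spec, train = TRUE, state = list())
    l0 <- composite_loss(fw$y[[1]], ts[[1]])
    gys <- list(composite_loss_grad(fw$y[[1]], ts[[1]]))
    gr <- backward_network(p, fw$caches, gys, spec)
    for (nm in names(p))
      if (!is.null(gr[[nm]])) p[[nm]] <- p[[nm]] - 1e-3 * gr[[nm]]
    fw1 <- forward_network(p, xs, spec, train = TRUE, state = list())
    if (composite_loss(fw1$y[[1]], ts[[1]]) < l0) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("network spec validation rejects malformed configurations", {
  expect_error(network_spec(spatial_kernels = c(3, 4)), "odd")
  expect_error(network_spec(spectral_kernels = cbind(k = 3, dilation = 0)),
               "dilation")
  expect_error(network_spec(base_channels = 12), "divisible")
  expect_error(network_spec(n_levels = 0), "n_levels")
})
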