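test_that("splitting follows the floor/floor/remainder rule", {
  s <- split_dataset(144, c(0.8, 0.1, 0.1), seed = 1)
  expect_length(s$train_idx, 115)
  expect_length(s$val_idx, 14)
  expect_length(s$test_idx, 15)
  s10 <- split_dataset(10, c(0.8, 0.1, 0.1), seed = 2)
  expect_equal(sapply(s10[1:3], length), c(train_idx = 8, val_idx = 1, test_idx = 1))
  expect_error(split_dataset(2, c(0.8, 0.1, 0.1)), "cannot split")
  expect_error(split_dataset(10, c(0.5, 0.5, 0.5)), "summing to 1")
})

test_that("splits are disjoint and exhaustive for random sizes and seeds", {
  set.seed(30)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    s <- split_dataset(n, seed = sample(1e6, 1))
    all_idx <- c(s$train_idx, s$val_idx, s$test_idx)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0)
  }
})

test_that("flips and rotations are involutions that preserve the pairing", {
  set.seed(31)
  x <- array(runif(6 * 6 * 4), c(6, 6, 4))
  tr <- list(flip_h = TRUE, flip_w = FALSE, rot90 = 0L)
  expect_identical(apply_transform(apply_transform(x, tr), tr), x)
  tr2 <- list(flip_h = FALSE, flip_w = TRUE, rot90 = 0L)
  expect_identical(apply_transform(apply_transform(x, tr2), tr2), x)
  r1 <- list(flip_h = FALSE, flip_w = FALSE, rot90 = 1L)
  y <- x
  for (i in 1:4) y <- apply_transform(y, r1)
  expect_identical(y, x)
  # the recorded transform reproduces the augmented clean member exactly
  n <- array(runif(6 * 6 * 4), c(6, 6, 4))
  aug <- augment_pair(n, x, seed = 99)
  expect_identical(aug$clean, apply_transform(x, aug$transform))
  expect_identical(aug$noisy, apply_transform(n, aug$transform))
  # spectra are never permuted: band means move with the spatial transform only
  expect_equal(apply(aug$clean, 3, mean), apply(x, 3, mean))
  expect_error(augment_pair(n, x[, , 1:2]), "congruent")
})

test_that("pair mixing is convex with exact endpoints", {
  set.seed(32)
  a <- list(noisy = array(runif(8), c(2, 2, 2)), clean = array(runif(8), c(2, 2, 2)))
  b <- list(noisy = array(runif(8), c(2, 2, 2)), clean = array(runif(8), c(2, 2, 2)))
  expect_identical(mix_pairs(a, b, 1)$noisy, a$noisy)
  expect_identical(mix_pairs(a, b, 0)$clean, b$clean)
  half <- mix_pairs(a, b, 0.5)
  expect_equal(half$noisy, (a$noisy + b$noisy) / 2)
})

test_that("the composite loss matches its closed form and elementwise oracle", {
  x <- array(runif(24), c(2, 3, 4))
  expect_equal(composite_loss(x, x), 0)
  expect_equal(composite_loss(x + 1, x), 0.1 * 1 + 0.9 * 1)
  set.seed(33)
  a <- array(rnorm(60), c(3, 4, 5)); b <- array(rnorm(60), c(3, 4, 5))
  hand <- 0
  for (i in seq_along(a))
    hand <- hand + 0.1 * abs(a[i] - b[i]) / 60 + 0.9 * (a[i] - b[i])^2 / 60
  expect_lt(abs(composite_loss(a, b) - hand), 1e-7)
  expect_error(composite_loss(a, b, w_l1 = -1), "nonnegative")
  expect_error(composite_loss(a, b[, , 1:2]), "congruent")
  # permutation invariance and quadratic scaling of the MSE term
  perm <- sample(60)
  expect_equal(composite_loss(a, b), composite_loss(a[perm], b[perm]))
  l1 <- mean(abs(a - b)); l2 <- mean((a - b)^2)
  for (f in c(2, 3))
    expect_equal(composite_loss(a, a + f * (b - a)),
                 0.1 * f * l1 + 0.9 * f^2 * l2)
})

test_that("the learning-rate schedule steps at the drop epoch", {
  ctl <- train_control(epochs = 100)
  expect_equal(lr_at_epoch(1, ctl), 0.001)
  expect_equal(lr_at_epoch(59, ctl), 0.001)
  expect_equal(lr_at_epoch(60, ctl), 0.0001)
  expect_equal(lr_at_epoch(100, ctl), 0.0001)
  expect_error(lr_at_epoch(101, ctl), "outside")
  expect_error(train_control(epochs = 10, lr_drop_epoch = 20), "lr_drop_epoch")
})

test_that("training is reproducible, checkpoints serialize, and histories descend", {
  set.seed(34)
  ph <- generate_phantoms(tiny_phantom(), 4, base_seed = 300)
  pairs <- lapply(seq_along(ph), function(i) {
    nz <- min_max_normalize(ph[[i]]$cube)
    no <- corrupt(ph[[i]]$cube, noise_params(alpha = 5, sigma = 40, seed = 70 + i))
    list(clean = nz$cube$data, noisy = apply_scale(no, nz$scale)$data)
  })
  xs <- lapply(pairs, `[[`, "noisy")
  ys <- lapply(pairs, `[[`, "clean")
  spec <- network_spec(n_levels = 2, base_channels = 8)
  ctl <- train_control(epochs = 6, batch_size = 2, lr_drop_epoch = 4, seed = 5)
  m1 <- raman_denoiser(xs[1:3], ys[1:3], spec, ctl,
                       validation = list(x = xs[4], y = ys[4]))
  m2 <- raman_denoiser(xs[1:3], ys[1:3], spec, ctl,
                       validation = list(x = xs[4], y = ys[4]))
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 6)
  expect_equal(m1$history$lr, c(0.001, 0.001, 0.001, 1e-4, 1e-4, 1e-4))

  # checkpoint round-trip gives identical predictions
  path <- tempfile(fileext = ".rds")
  saveRDS(m1, path)
  m3 <- readRDS(path)
  unlink(path)
  expect_identical(predict(m1, xs[[4]]), predict(m3, xs[[4]]))

  # denoising improves over the schedule for most seeds (descent property)
  ok <- 0
  for (s in 1:5) {
    ctl_s <- train_control(epochs = 8, batch_size = 2, lr_drop_epoch = 6, seed = s)
    m <- raman_denoiser(xs[1:3], ys[1:3], spec, ctl_s,
                        validation = list(x = xs[4], y = ys[4]))
    if (tail(m$history$val_loss, 1) < m$history$val_loss[1]) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("training rejects empty and incongruent inputs", {
  spec <- network_spec(n_levels = 1, base_channels = 8, use_fusion = FALSE)
  expect_error(raman_denoiser(list(), list(), spec), "empty")
  a <- array(0, c(8, 8, 8)); b <- array(0, c(8, 8, 4))
  expect_error(raman_denoiser(list(a), list(b), spec), "congruent")
})

test_that("model methods expose coefficients, summary and residuals", {
  set.seed(35)
  x <- list(array(runif(8 * 8 * 8), c(8, 8, 8)))
  spec <- network_spec(n_levels = 1, base_channels = 8, use_fusion = FALSE)
  ctl <- train_control(epochs = 2, lr_drop_epoch = 2, seed = 1,
                       augment = c(flip = FALSE, rotate = FALSE, mix = FALSE))
  m <- raman_denoiser(x, x, spec, ctl)
  expect_equal(count_params(coef(m)), m$n_params)
  sm <- summary(m)
  expect_s3_class(sm, "summary.raman_denoiser")
  expect_true(any(grepl("bottleneck", sm$layers$stage)))
  r <- residuals(m, x, x)
  expect_identical(dim(r[[1]]), dim(x[[1]]))
  expect_output(print(m), "MultiResU-Net")
})
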