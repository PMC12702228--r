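#' Shuffle-and-partition dataset split
#'
#' Indices `1:n` are shuffled with `seed` and partitioned into train /
#' validation / test sets. Sizes follow floor(n * f_train),
#' floor(n * f_val), remainder -> test: the only rounding rule consistent
#' with a 144-image collection splitting as 115 / 14 / 15 at fractions
#' 0.8 / 0.1 / 0.1.
#'
#' @param n Number of items.
#' @param fractions Positive length-3 fractions summing to 1.
#' @param seed Integer RNG seed for the shuffle.
#' @return A `dataset_split`: list with `train_idx`, `val_idx`,
#'   `test_idx`, `fractions`.
#' @export
split_dataset <- function(n, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be 3 nonnegative values summing to 1", call. = FALSE)
  if (n < sum(fractions > 0))
    stop(sprintf("cannot split %d items into %d nonempty subsets",
                 n, sum(fractions > 0)), call. = FALSE)
  n_train <- floor(n * fractions[1])
  n_val <- floor(n * fractions[2])
  n_test <- n - n_train - n_val
  idx <- with_seed(seed, sample.int(n))
  structure(list(train_idx = sort(idx[seq_len(n_train)]),
                 val_idx = sort(idx[n_train + seq_len(n_val)]),
                 test_idx = sort(idx[n_train + n_val + seq_len(n_test)]),
                 fractions = fractions),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Dataset split: %d train / %d val / %d test\n",
              length(x$train_idx), length(x$val_idx), length(x$test_idx)))
  invisible(x)
}

#' Apply a recorded spatial transform to a cube array
#'
#' Flips are axis reversals in H/W; rotations are 90-degree multiples in
#' the H x W plane. The spectral axis is never permuted.
#'
#' @param x 3-d array `[H, W, B]`.
#' @param transform List with logical `flip_h`, `flip_w` and integer
#'   `rot90` (0-3), as recorded by [augment_pair].
#' @return The transformed array.
#' @export
apply_transform <- function(x, transform) {
  if (isTRUE(transform$flip_h)) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
  if (isTRUE(transform$flip_w)) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  k <- (transform$rot90 %||% 0L) %% 4L
  if (k > 0 && dim(x)[1] != dim(x)[2])
    stop("90-degree rotation requires a square field of view", call. = FALSE)
  for (i in seq_len(k)) {
    # counter-clockwise quarter turn in the H x W plane, band by band
    x <- aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
  }
  x
}

#' Randomly augment a noisy/clean training pair
#'
#' Draws one spatial transform (flips, 90-degree rotations) and applies it
#' identically to both members, preserving the pairing. Rotation requires
#' a square H x W field.
#'
#' @param noisy,clean Congruent 3-d arrays `[H, W, B]`.
#' @param flags Named logical vector with elements `flip` and `rotate`.
#' @param seed Integer seed for the transform draw.
#' @return List with `noisy`, `clean` and the recorded `transform`.
#' @export
augment_pair <- function(noisy, clean, flags = c(flip = TRUE, rotate = TRUE),
                         seed = 1L) {
  if (!identical(dim(noisy), dim(clean)))
    stop("noisy and clean members are not congruent", call. = FALSE)
  tr <- with_seed(seed, list(
    flip_h = isTRUE(flags[["flip"]]) && stats::runif(1) < 0.5,
    flip_w = isTRUE(flags[["flip"]]) && stats::runif(1) < 0.5,
    rot90 = if (isTRUE(flags[["rotate"]]) && dim(noisy)[1] == dim(noisy)[2])
      sample(0:3, 1) else 0L))
  list(noisy = apply_transform(noisy, tr),
       clean = apply_transform(clean, tr),
       transform = tr)
}

#' Blend two training pairs (mixup-style)
#'
#' Convex combination `lambda * A + (1 - lambda) * B` applied identically
#' to inputs and targets. With `lambda = 1` returns pair A exactly; with
#' `lambda = 0`, pair B. When `lambda` is `NULL` it is drawn from a
#' symmetric Beta(0.4, 0.4). Experimental; off by default in training.
#'
#' @param pair_a,pair_b Lists with congruent `noisy` and `clean` arrays.
#' @param lambda Mixing weight in `[0, 1]`, or `NULL` to draw one.
#' @return List with blended `noisy`, `clean` and the `lambda` used.
#' @export
mix_pairs <- function(pair_a, pair_b, lambda = NULL) {
  if (!identical(dim(pair_a$noisy), dim(pair_b$noisy)))
    stop("pairs are not congruent", call. = FALSE)
  if (is.null(lambda)) lambda <- stats::rbeta(1, 0.4, 0.4)
  list(noisy = lambda * pair_a$noisy + (1 - lambda) * pair_b$noisy,
       clean = lambda * pair_a$clean + (1 - lambda) * pair_b$clean,
       lambda = lambda)
}

#' Composite L1 + MSE training loss
#'
#' `w_l1 * mean(|pred - target|) + w_mse * mean((pred - target)^2)`, the
#' weighted objective used for training (defaults 0.1 and 0.9).
#'
#' @param pred,target Congruent numeric arrays.
#' @param w_l1,w_mse Nonnegative weights.
#' @return Scalar loss, zero iff `pred == target` (for positive weights).
#' @export
composite_loss <- function(pred, target, w_l1 = 0.1, w_mse = 0.9) {
  if (w_l1 < 0 || w_mse < 0) stop("loss weights must be nonnegative", call. = FALSE)
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("pred and target are not congruent", call. = FALSE)
  r <- pred - target
  w_l1 * mean(abs(r)) + w_mse * mean(r * r)
}

composite_loss_grad <- function(pred, target, w_l1 = 0.1, w_mse = 0.9) {
  r <- pred - target
  (w_l1 * sign(r) + 2 * w_mse * r) / length(r)
}

#' Training hyperparameters
#'
#' Defaults follow the published training recipe: 100 epochs, batch size
#' 2, Adam with learning rate 0.001 dropped to 0.0001 at epoch 60, and a
#' 0.1 L1 + 0.9 MSE composite loss.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param lr_initial,lr_after_drop Learning rates before/after the drop.
#' @param lr_drop_epoch Epoch at which the rate drops (1 <= . <= epochs).
#' @param w_l1,w_mse Loss weights.
#' @param patch Optional `c(h, w, b)` random training crop; `NULL` trains
#'   on whole cubes.
#' @param crops_per_epoch Number of random crops drawn from each cube per
#'   epoch when `patch` is set (default 1); raises the optimizer step
#'   count of short runs without more data.
#' @param seed Integer seed controlling init, shuffling, crops and
#'   augmentation draws.
#' @param augment Named logical vector: `flip`, `rotate`, `mix`.
#' @param deterministic Reproducible mode (default `TRUE`); identical
#'   config and seed give identical training histories.
#' @return A `train_control` object.
#' @export
train_control <- function(epochs = 100, batch_size = 2, lr_initial = 0.001,
                          lr_drop_epoch = 60, lr_after_drop = 0.0001,
                          w_l1 = 0.1, w_mse = 0.9, patch = NULL,
                          crops_per_epoch = 1L, seed = 1L,
                          augment = c(flip = TRUE, rotate = TRUE, mix = FALSE),
                          deterministic = TRUE) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (lr_drop_epoch < 1 || lr_drop_epoch > epochs)
    stop("lr_drop_epoch must lie in [1, epochs]", call. = FALSE)
  if (w_l1 < 0 || w_mse < 0) stop("loss weights must be nonnegative", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_initial = lr_initial, lr_drop_epoch = as.integer(lr_drop_epoch),
                 lr_after_drop = lr_after_drop, w_l1 = w_l1, w_mse = w_mse,
                 patch = patch, crops_per_epoch = as.integer(crops_per_epoch),
                 seed = as.integer(seed), augment = augment,
                 deterministic = isTRUE(deterministic)),
            class = "train_control")
}

#' Learning rate schedule
#'
#' Step schedule: `lr_initial` for epochs before `lr_drop_epoch`,
#' `lr_after_drop` from that epoch on.
#'
#' @param epoch Epoch number in `[1, epochs]`.
#' @param control A [train_control].
#' @return The learning rate for that epoch.
#' @export
lr_at_epoch <- function(epoch, control) {
  if (epoch < 1 || epoch > control$epochs)
    stop(sprintf("epoch %d outside [1, %d]", epoch, control$epochs), call. = FALSE)
  if (epoch < control$lr_drop_epoch) control$lr_initial else control$lr_after_drop
}

## ---- Adam optimizer --------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(params = params, opt = opt)
}

## ---- the fitting function --------------------------------------------

coerce_pair_array <- function(x) {
  if (inherits(x, "hyper_cube")) x <- x$data
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

random_crop_idx <- function(ext, patch) {
  lapply(seq_len(3), function(a) {
    if (is.null(patch) || patch[a] >= ext[a]) seq_len(ext[a])
    else {
      s <- sample.int(ext[a] - patch[a] + 1L, 1L)
      s:(s + patch[a] - 1L)
    }
  })
}

#' Fit the depthwise separable 3D MultiResU-Net denoiser
#'
#' Trains the spatial-spectral denoising network on paired noisy/clean
#' hyperspectral cubes (both on the `[0, 1]` min-max scale) with Adam, a
#' step learning-rate schedule and the composite L1+MSE loss. The
#' checkpoint with the best validation loss is retained as the fitted
#' model.
#'
#' @param x List of noisy cubes ([hyper_cube]s or `[H, W, B]` arrays),
#'   normalized to the unit scale.
#' @param y List of matching clean cubes, same length and dimensions.
#' @param spec A [network_spec]. Cube extents must be divisible by
#'   `2^n_levels` (use [pad_to_multiple], or let [predict.raman_denoiser]
#'   pad at inference).
#' @param control A [train_control].
#' @param validation Optional list with elements `x` and `y` (lists of
#'   cubes) scored each epoch; without it the training loss doubles as the
#'   validation signal.
#' @param verbose Print one line per 10 epochs.
#' @return An object of class `raman_denoiser` with elements `params`
#'   (best-on-validation weights), `bn_state` (batch-norm running
#'   moments), `spec`, `control`, `history` (per-epoch data frame with
#'   `epoch`, `lr`, `train_loss`, `val_loss`), `best_epoch`, `n_params`.
#' @seealso [predict.raman_denoiser], [summary.raman_denoiser]
#' @export
raman_denoiser <- function(x, y, spec = network_spec(),
                           control = train_control(), validation = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(spec, "network_spec"), inherits(control, "train_control"))
  if (length(x) == 0) stop("empty training set", call. = FALSE)
  if (length(x) != length(y))
    stop("x and y must have the same length", call. = FALSE)
  xs <- lapply(x, coerce_pair_array)
  ys <- lapply(y, coerce_pair_array)
  for (i in seq_along(xs))
    if (!identical(dim(xs[[i]]), dim(ys[[i]])))
      stop(sprintf("pair %d is not congruent", i), call. = FALSE)
  vx <- if (!is.null(validation)) lapply(validation$x, coerce_pair_array)
  vy <- if (!is.null(validation)) lapply(validation$y, coerce_pair_array)

  params <- init_network(spec, seed = control$seed)
  opt <- adam_init(params)
  state <- list()
  n <- length(xs)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  best <- list(loss = Inf, params = params, state = state, epoch = 0L)

  run <- function() {
    for (epoch in seq_len(control$epochs)) {
      lr <- lr_at_epoch(epoch, control)
      reps <- if (!is.null(control$patch)) max(1L, control$crops_per_epoch) else 1L
      pool <- rep(seq_len(n), reps)
      ord <- pool[sample.int(length(pool))]
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1, length(ord), by = control$batch_size)) {
        take <- ord[start:min(start + control$batch_size - 1L, length(ord))]
        bx <- vector("list", length(take))
        by <- vector("list", length(take))
        for (j in seq_along(take)) {
          i <- take[j]
          xn <- xs[[i]]; dim(xn) <- dim(xn)[1:3]
          yc <- ys[[i]]; dim(yc) <- dim(yc)[1:3]
          if (isTRUE(control$augment[["flip"]]) || isTRUE(control$augment[["rotate"]])) {
            aug <- augment_pair(xn, yc, flags = c(
              flip = isTRUE(control$augment[["flip"]]),
              rotate = isTRUE(control$augment[["rotate"]])),
              seed = sample.int(.Machine$integer.max, 1))
            xn <- aug$noisy; yc <- aug$clean
          }
          if (!is.null(control$patch)) {
            ci <- random_crop_idx(dim(xn), control$patch)
            xn <- xn[ci[[1]], ci[[2]], ci[[3]], drop = FALSE]
            yc <- yc[ci[[1]], ci[[2]], ci[[3]], drop = FALSE]
          }
          dim(xn) <- c(dim(xn), 1L)
          dim(yc) <- c(dim(yc), 1L)
          bx[[j]] <- xn; by[[j]] <- yc
        }
        if (isTRUE(control$augment[["mix"]]) && length(bx) >= 2) {
          lam <- stats::rbeta(1, 0.4, 0.4)
          mixed <- mix_pairs(list(noisy = bx[[1]], clean = by[[1]]),
                             list(noisy = bx[[2]], clean = by[[2]]), lam)
          bx[[1]] <- mixed$noisy; by[[1]] <- mixed$clean
        }
        fw <- forward_network(params, bx, spec, train = TRUE, state = state)
        state <<- fw$state
        losses <- Map(function(p, t) composite_loss(p, t, control$w_l1, control$w_mse),
                      fw$y, by)
        batch_loss <- mean(unlist(losses))
        if (!is.finite(batch_loss))
          stop(sprintf("NaN loss at epoch %d, batch starting at item %d",
                       epoch, start), call. = FALSE)
        gys <- Map(function(p, t) {
          composite_loss_grad(p, t, control$w_l1, control$w_mse) / length(take)
        }, fw$y, by)
        grads <- backward_network(params, fw$caches, gys, spec)
        st <- adam_step(params, grads, opt, lr)
        params <<- st$params; opt <<- st$opt
        ep_loss <- ep_loss + batch_loss; n_batches <- n_batches + 1L
      }
      train_loss <- ep_loss / n_batches
      val_loss <- if (!is.null(vx)) {
        fw <- forward_network(params, vx, spec, train = FALSE, state = state)
        mean(unlist(Map(function(p, t)
          composite_loss(p, t, control$w_l1, control$w_mse), fw$y, vy)))
      } else train_loss
      history[nrow(history) + 1L, ] <<- list(epoch, lr, train_loss, val_loss)
      if (val_loss < best$loss)
        best <<- list(loss = val_loss, params = params, state = state,
                      epoch = epoch)
      if (verbose && (epoch %% 10L == 0L || epoch == 1L))
        message(sprintf("epoch %3d  lr %.4g  train %.5g  val %.5g",
                        epoch, lr, train_loss, val_loss))
    }
  }
  if (control$deterministic) with_seed(control$seed, run()) else run()

  structure(list(params = best$params, bn_state = best$state,
                 final_params = params, spec = spec, control = control,
                 history = history, best_epoch = best$epoch,
                 n_params = count_params(best$params)),
            class = "raman_denoiser")
}

#' Denoise cubes with a fitted model
#'
#' Runs the network in inference mode (batch-norm running moments). Inputs
#' whose extents are not divisible by `2^n_levels` are reflect-padded and
#' the output is cropped back, so output extent always equals input
#' extent. The model operates on the `[0, 1]` min-max scale; pass
#' normalized data (or a [hyper_cube], whose values are used as-is).
#'
#' @param object A fitted `raman_denoiser`.
#' @param newdata A [hyper_cube], a 3-d array, or a list of either.
#' @param ... Unused.
#' @return Denoised data of the same type and shape as `newdata`.
#' @export
predict.raman_denoiser <- function(object, newdata, ...) {
  single <- inherits(newdata, "hyper_cube") || !is.list(newdata)
  items <- if (single) list(newdata) else newdata
  m <- 2^object$spec$n_levels
  out <- lapply(items, function(it) {
    arr <- if (inherits(it, "hyper_cube")) it$data else it
    d0 <- dim(arr)
    pd <- pad_to_multiple(arr, m)
    xp <- pd$x
    dim(xp) <- c(dim(xp), 1L)
    fw <- forward_network(object$params, list(xp), object$spec,
                          train = FALSE, state = object$bn_state)
    y <- fw$y[[1]][pd$crop[[1]], pd$crop[[2]], pd$crop[[3]], 1]
    dim(y) <- d0
    if (inherits(it, "hyper_cube")) {
      it$data <- y
      it$provenance <- paste0(it$provenance, "+denoised")
      it
    } else y
  })
  if (single) out[[1]] else out
}

#' @export
print.raman_denoiser <- function(x, ...) {
  cat(sprintf("Depthwise separable 3D MultiResU-Net denoiser (%d levels, width %d%s)\n",
              x$spec$n_levels, x$spec$base_channels,
              if (x$spec$use_fusion) ", multi-scale fusion" else ""))
  cat(sprintf("  %d parameters; trained %d epochs, best validation loss %.5g at epoch %d\n",
              x$n_params, nrow(x$history),
              min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
summary.raman_denoiser <- function(object, ...) {
  spec <- object$spec
  L <- spec$n_levels
  rows <- list()
  push <- function(stage, channels, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(stage = stage,
                                             channels = channels, note = note)
  }
  cin <- 1L
  for (l in seq_len(L)) {
    cl <- level_channels(spec, l)
    push(sprintf("encoder %d", l), sprintf("%d -> %d", cin, cl),
         "residual DS-conv block")
    if (spec$use_fusion)
      push(sprintf("fusion %d", l), sprintf("%d -> %d", cl, cl),
           "8-branch pseudo-3D + channel attention")
    cin <- cl
  }
  push("bottleneck", sprintf("%d -> %d", cin, level_channels(spec, L + 1)),
       "residual DS-conv block")
  for (l in rev(seq_len(L)))
    push(sprintf("decoder %d", l),
         sprintf("%d -> %d", 2 * level_channels(spec, l), level_channels(spec, l)),
         "upsample + skip concat + residual block")
  push("head", sprintf("%d -> 1", level_channels(spec, 1)), "pointwise conv")
  out <- list(layers = do.call(rbind, rows), n_params = object$n_params,
              history = object$history, best_epoch = object$best_epoch)
  class(out) <- "summary.raman_denoiser"
  out
}

#' @export
print.summary.raman_denoiser <- function(x, ...) {
  print(x$layers, row.names = FALSE)
  cat(sprintf("\nTotal parameters: %d; best epoch %d (val loss %.5g)\n",
              x$n_params, x$best_epoch, min(x$history$val_loss)))
  invisible(x)
}

#' @export
coef.raman_denoiser <- function(object, ...) object$params

#' @export
plot.raman_denoiser <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "composite loss", log = "y", ...)
  graphics::abline(v = x$control$lr_drop_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Residuals of a fitted denoiser on paired data
#'
#' @param object A fitted `raman_denoiser`.
#' @param x List of noisy cubes/arrays.
#' @param y List of clean references.
#' @param ... Unused.
#' @return List of residual arrays (denoised minus clean).
#' @export
residuals.raman_denoiser <- function(object, x, y, ...) {
  pred <- predict(object, x)
  Map(function(p, t) {
    (if (inherits(p, "hyper_cube")) p$data else p) -
      (if (inherits(t, "hyper_cube")) t$data else t)
  }, pred, y)
}
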