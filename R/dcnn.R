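# Compact fully-convolutional encoder-decoder segmentation network.
#
# Shape: a depthwise-separable inverted-residual encoder (total stride 4),
# a multi-rate dilated (atrous) spatial pyramid pooling block with an
# image-level pooling branch, and a decoder that upsamples and fuses a
# low-level skip feature before the per-pixel softmax classifier. Trained
# with Adam on cross-entropy over augmented patches, keeping the weights
# of the epoch with the smallest validation loss.

#' Network and training configuration
#'
#' The `"desk"` profile (64 x 64 patches, width multiplier 0.25, 5 epochs,
#' 200 augmented samples per epoch) trains in seconds on a CPU and is the
#' default for experiments in this package; the `"full"` profile mirrors a
#' production setting (256 x 256 patches, full width, 50 epochs, 4000
#' augmented samples per epoch, learning rate 0.001, batch 8, dropout 0.5).
#'
#' @param profile Preset, `"desk"` or `"full"`; explicit arguments
#'   override preset values.
#' @param width_multiplier Scales every channel width; parameter count is
#'   monotone in it.
#' @param num_classes `K`, at least 2.
#' @param aspp_rates Dilation rates of the two 3x3 pyramid branches.
#' @param input_size Patch side; must be divisible by 4 (the encoder
#'   stride).
#' @param dropout_rate Dropout before the classifier head, in `[0, 1)`.
#' @param learning_rate,batch_size,epochs,adam_beta1,adam_beta2 Adam
#'   optimizer settings.
#' @param samples_per_epoch Augmented training patches drawn per epoch
#'   (with replacement from the training split).
#' @param augment Apply random geometric augmentation while training.
#' @param seed RNG seed controlling initialization, sampling, augmentation
#'   and dropout.
#' @return A `net_config`.
#' @export
net_config <- function(profile = c("desk", "full"),
                       width_multiplier = NULL, num_classes = 2L,
                       aspp_rates = c(2L, 4L), input_size = NULL,
                       dropout_rate = 0.5, learning_rate = 0.001,
                       batch_size = 8L, epochs = NULL,
                       adam_beta1 = 0.9, adam_beta2 = 0.999,
                       samples_per_epoch = NULL, augment = TRUE,
                       seed = 1L) {
  profile <- match.arg(profile)
  defaults <- if (profile == "desk") {
    list(width_multiplier = 0.25, input_size = 64L, epochs = 5L,
         samples_per_epoch = 200L)
  } else {
    list(width_multiplier = 1, input_size = 256L, epochs = 50L,
         samples_per_epoch = 4000L)
  }
  width_multiplier <- width_multiplier %||% defaults$width_multiplier
  input_size <- input_size %||% defaults$input_size
  epochs <- epochs %||% defaults$epochs
  samples_per_epoch <- samples_per_epoch %||% defaults$samples_per_epoch
  if (num_classes < 2) stop_bagseg("need at least 2 classes", "bagseg_config_error")
  if (input_size %% 4 != 0) {
    stop_bagseg("input_size must be divisible by the encoder stride (4)",
                "bagseg_config_error")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_bagseg("dropout_rate must lie in [0, 1)", "bagseg_config_error")
  }
  if (width_multiplier <= 0) {
    stop_bagseg("width_multiplier must be positive", "bagseg_config_error")
  }
  structure(
    list(width_multiplier = width_multiplier, num_classes = as.integer(num_classes),
         aspp_rates = as.integer(aspp_rates), input_size = as.integer(input_size),
         dropout_rate = dropout_rate, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
         samples_per_epoch = as.integer(samples_per_epoch),
         augment = isTRUE(augment), seed = as.integer(seed)),
    class = "net_config"
  )
}

net_channels <- function(config) {
  m <- config$width_multiplier
  c1 <- max(4L, as.integer(round(16 * m)))
  c2 <- max(8L, as.integer(round(32 * m)))
  list(c1 = c1, e1 = 2L * c1, c2 = c2, e2 = 2L * c2,
       ca = c2, cs = max(4L, as.integer(round(c1 / 2))), cd = c2,
       K = config$num_classes)
}

#' Build an untrained segmentation network
#'
#' @param config A [net_config()].
#' @return A `seg_model`: initialized parameters plus the config. Maps
#'   H x W x 3 inputs (H, W divisible by 4) to H x W x K per-pixel softmax
#'   probabilities.
#' @export
build_model <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  ch <- net_channels(config)
  params <- with_seed(derive_seed(config$seed, "init"), {
    p <- list()
    p$stem.W <- he_init(ch$c1, 27, 27)
    p$stem.b <- numeric(ch$c1)
    p$exp1.W <- he_init(ch$e1, ch$c1, ch$c1);  p$exp1.b <- numeric(ch$e1)
    p$dw1.W  <- he_init(ch$e1, 9, 9);          p$dw1.b  <- numeric(ch$e1)
    p$proj1.W <- he_init(ch$c2, ch$e1, ch$e1); p$proj1.b <- numeric(ch$c2)
    p$exp2.W <- he_init(ch$e2, ch$c2, ch$c2);  p$exp2.b <- numeric(ch$e2)
    p$dw2.W  <- he_init(ch$e2, 9, 9);          p$dw2.b  <- numeric(ch$e2)
    p$proj2.W <- he_init(ch$c2, ch$e2, ch$e2); p$proj2.b <- numeric(ch$c2)
    p$aspp0.W <- he_init(ch$ca, ch$c2, ch$c2); p$aspp0.b <- numeric(ch$ca)
    p$aspp1.W <- he_init(ch$ca, 9 * ch$c2, 9 * ch$c2); p$aspp1.b <- numeric(ch$ca)
    p$aspp2.W <- he_init(ch$ca, 9 * ch$c2, 9 * ch$c2); p$aspp2.b <- numeric(ch$ca)
    p$asppP.W <- he_init(ch$ca, ch$c2, ch$c2); p$asppP.b <- numeric(ch$ca)
    p$fuse.W <- he_init(ch$ca, 4 * ch$ca, 4 * ch$ca); p$fuse.b <- numeric(ch$ca)
    p$skip.W <- he_init(ch$cs, ch$c1, ch$c1);  p$skip.b <- numeric(ch$cs)
    p$dec.W <- he_init(ch$cd, 9 * (ch$ca + ch$cs), 9 * (ch$ca + ch$cs))
    p$dec.b <- numeric(ch$cd)
    p$head.W <- he_init(ch$K, ch$cd, ch$cd);   p$head.b <- numeric(ch$K)
    p
  })
  structure(list(params = params, config = config, channels = ch),
            class = "seg_model")
}

#' Number of trainable parameters of a model
#' @param model A `seg_model` or `trained_estimator`.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

net_forward <- function(params, ch, config, x, training = FALSE) {
  r <- config$aspp_rates
  cache <- list()
  cache$stem <- conv2d_fw(x, params$stem.W, params$stem.b, stride = 2L)
  cache$stem_r <- relu_fw(cache$stem$out)
  low <- cache$stem_r$out

  cache$exp1 <- conv1x1_fw(low, params$exp1.W, params$exp1.b)
  cache$exp1_r <- relu_fw(cache$exp1$out)
  cache$dw1 <- dwconv_fw(cache$exp1_r$out, params$dw1.W, params$dw1.b, stride = 2L)
  cache$dw1_r <- relu_fw(cache$dw1$out)
  cache$proj1 <- conv1x1_fw(cache$dw1_r$out, params$proj1.W, params$proj1.b)
  f2 <- cache$proj1$out

  cache$exp2 <- conv1x1_fw(f2, params$exp2.W, params$exp2.b)
  cache$exp2_r <- relu_fw(cache$exp2$out)
  cache$dw2 <- dwconv_fw(cache$exp2_r$out, params$dw2.W, params$dw2.b, stride = 1L)
  cache$dw2_r <- relu_fw(cache$dw2$out)
  cache$proj2 <- conv1x1_fw(cache$dw2_r$out, params$proj2.W, params$proj2.b)
  f3 <- f2 + cache$proj2$out

  cache$a0 <- conv1x1_fw(f3, params$aspp0.W, params$aspp0.b)
  cache$a0_r <- relu_fw(cache$a0$out)
  cache$a1 <- conv2d_fw(f3, params$aspp1.W, params$aspp1.b,
                        pad = r[1], dilation = r[1])
  cache$a1_r <- relu_fw(cache$a1$out)
  cache$a2 <- conv2d_fw(f3, params$aspp2.W, params$aspp2.b,
                        pad = r[2], dilation = r[2])
  cache$a2_r <- relu_fw(cache$a2$out)
  cache$ap <- gap_fw(f3, params$asppP.W, params$asppP.b)
  cat_aspp <- concat3(cache$a0_r$out, cache$a1_r$out, cache$a2_r$out,
                      cache$ap$out)
  cache$fuse <- conv1x1_fw(cat_aspp, params$fuse.W, params$fuse.b)
  cache$fuse_r <- relu_fw(cache$fuse$out)

  up1 <- upsample2_fw(cache$fuse_r$out)
  cache$skip <- conv1x1_fw(low, params$skip.W, params$skip.b)
  cache$skip_r <- relu_fw(cache$skip$out)
  dcat <- concat3(up1, cache$skip_r$out)
  cache$dec <- conv2d_fw(dcat, params$dec.W, params$dec.b)
  cache$dec_r <- relu_fw(cache$dec$out)
  dec_out <- cache$dec_r$out
  if (training && config$dropout_rate > 0) {
    keep <- 1 - config$dropout_rate
    cache$drop_mask <- array(
      (runif(length(dec_out)) < keep) / keep, dim = dim(dec_out)
    )
    dec_out <- dec_out * cache$drop_mask
  }
  cache$head <- conv1x1_fw(dec_out, params$head.W, params$head.b)
  logits <- upsample2_fw(cache$head$out)
  probs <- softmax3(logits)
  list(probs = probs, logits = logits, cache = cache)
}

net_backward <- function(params, ch, config, fwd, dlogits) {
  cache <- fwd$cache
  g <- list()
  dhead_out <- upsample2_bw(dlogits)
  bw <- conv1x1_bw(dhead_out, params$head.W, cache$head)
  g$head.W <- bw$dW; g$head.b <- bw$db
  ddec <- bw$dx
  if (!is.null(cache$drop_mask)) ddec <- ddec * cache$drop_mask
  ddec <- relu_bw(ddec, cache$dec_r)
  bw <- conv2d_bw(ddec, params$dec.W, cache$dec)
  g$dec.W <- bw$dW; g$dec.b <- bw$db
  ddcat <- bw$dx
  ca <- ch$ca
  dup1 <- ddcat[, , seq_len(ca), drop = FALSE]
  dskip <- ddcat[, , ca + seq_len(ch$cs), drop = FALSE]

  dskip <- relu_bw(dskip, cache$skip_r)
  bw <- conv1x1_bw(dskip, params$skip.W, cache$skip)
  g$skip.W <- bw$dW; g$skip.b <- bw$db
  dlow <- bw$dx

  dfuse <- relu_bw(upsample2_bw(dup1), cache$fuse_r)
  bw <- conv1x1_bw(dfuse, params$fuse.W, cache$fuse)
  g$fuse.W <- bw$dW; g$fuse.b <- bw$db
  dcat_aspp <- bw$dx
  da0 <- relu_bw(dcat_aspp[, , seq_len(ca), drop = FALSE], cache$a0_r)
  da1 <- relu_bw(dcat_aspp[, , ca + seq_len(ca), drop = FALSE], cache$a1_r)
  da2 <- relu_bw(dcat_aspp[, , 2 * ca + seq_len(ca), drop = FALSE], cache$a2_r)
  dap <- dcat_aspp[, , 3 * ca + seq_len(ca), drop = FALSE]

  bw <- conv1x1_bw(da0, params$aspp0.W, cache$a0)
  g$aspp0.W <- bw$dW; g$aspp0.b <- bw$db
  df3 <- bw$dx
  bw <- conv2d_bw(da1, params$aspp1.W, cache$a1)
  g$aspp1.W <- bw$dW; g$aspp1.b <- bw$db
  df3 <- df3 + bw$dx
  bw <- conv2d_bw(da2, params$aspp2.W, cache$a2)
  g$aspp2.W <- bw$dW; g$aspp2.b <- bw$db
  df3 <- df3 + bw$dx
  bw <- gap_bw(dap, params$asppP.W, cache$ap)
  g$asppP.W <- bw$dW; g$asppP.b <- bw$db
  df3 <- df3 + bw$dx

  # residual: f3 = f2 + proj2(...)
  bw <- conv1x1_bw(df3, params$proj2.W, cache$proj2)
  g$proj2.W <- bw$dW; g$proj2.b <- bw$db
  ddw2 <- relu_bw(bw$dx, cache$dw2_r)
  bw <- dwconv_bw(ddw2, params$dw2.W, cache$dw2)
  g$dw2.W <- bw$dW; g$dw2.b <- bw$db
  dexp2 <- relu_bw(bw$dx, cache$exp2_r)
  bw <- conv1x1_bw(dexp2, params$exp2.W, cache$exp2)
  g$exp2.W <- bw$dW; g$exp2.b <- bw$db
  df2 <- df3 + bw$dx

  bw <- conv1x1_bw(df2, params$proj1.W, cache$proj1)
  g$proj1.W <- bw$dW; g$proj1.b <- bw$db
  ddw1 <- relu_bw(bw$dx, cache$dw1_r)
  bw <- dwconv_bw(ddw1, params$dw1.W, cache$dw1)
  g$dw1.W <- bw$dW; g$dw1.b <- bw$db
  dexp1 <- relu_bw(bw$dx, cache$exp1_r)
  bw <- conv1x1_bw(dexp1, params$exp1.W, cache$exp1)
  g$exp1.W <- bw$dW; g$exp1.b <- bw$db
  dlow <- dlow + bw$dx

  dstem <- relu_bw(dlow, cache$stem_r)
  bw <- conv2d_bw(dstem, params$stem.W, cache$stem)
  g$stem.W <- bw$dW; g$stem.b <- bw$db
  g
}

#' One-hot encoding of a label mask
#' @param mask A [label_mask()].
#' @param num_classes `K`; defaults to the mask's class count.
#' @return H x W x K array of 0/1 with per-pixel sum 1.
#' @export
one_hot <- function(mask, num_classes = NULL) {
  K <- num_classes %||% num_classes(mask)
  d <- dim(mask)
  out <- array(0, dim = c(d[1], d[2], K))
  for (k in seq_len(K) - 1L) out[, , k + 1L] <- (unclass(mask) == k) * 1
  out
}

#' Categorical cross-entropy loss
#'
#' For one patch, the loss is the double sum over the `H*W` pixels and `K`
#' classes of `-y * log(p)` (probabilities clamped at 1e-7); for a list of
#' patches, the mean of the per-patch sums.
#'
#' @param prediction H x W x K probability array (a forward-pass output),
#'   or a list of them.
#' @param truth One-hot H x W x K array, a [label_mask()], or a matching
#'   list.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' p <- array(c(0.2, 0.8), dim = c(1, 1, 2))
#' y <- array(c(0, 1), dim = c(1, 1, 2))
#' cross_entropy_loss(p, y)  # -log(0.8)
cross_entropy_loss <- function(prediction, truth) {
  if (is.list(prediction) && !is.array(prediction)) {
    stopifnot(length(prediction) == length(truth))
    return(mean(mapply(cross_entropy_loss, prediction, truth)))
  }
  if (inherits(truth, "label_mask")) truth <- one_hot(truth, dim(prediction)[3])
  if (!identical(dim(prediction), dim(truth))) {
    stop_bagseg("prediction and truth dims differ", "bagseg_shape_error")
  }
  -sum(truth * log(pmax(prediction, 1e-7)))
}

#' Geometric augmentation of an image/mask pair
#'
#' Applies one random affine transform - rotation, shift, shear, zoom, and
#' horizontal/vertical flips - identically to the image and the mask. Both
#' are resampled by nearest neighbor (the mask therefore keeps exact label
#' values) with edge clamping, and the draw is deterministic in `seed`.
#'
#' @param pair A [patch_pair()].
#' @param seed RNG seed for the parameter draw.
#' @param bounds List of transform bounds: `rotation` (degrees), `shift`
#'   (fraction of the side), `shear` (degrees), `zoom` (c(lo, hi)), `flip`
#'   (logical).
#' @param params Optional fixed transform parameters (list with `rotation`,
#'   `shift_r`, `shift_c`, `shear`, `zoom`, `hflip`, `vflip`), bypassing
#'   the random draw.
#' @return A transformed [patch_pair()].
#' @export
augment_pair <- function(pair, seed = 1L,
                         bounds = list(rotation = 30, shift = 0.1,
                                       shear = 10, zoom = c(0.9, 1.1),
                                       flip = TRUE),
                         params = NULL) {
  d <- dim(pair$image)
  if (is.null(params)) {
    params <- with_seed(seed, list(
      rotation = runif(1, -bounds$rotation, bounds$rotation),
      shift_r = runif(1, -bounds$shift, bounds$shift) * d[1],
      shift_c = runif(1, -bounds$shift, bounds$shift) * d[2],
      shear = runif(1, -bounds$shear, bounds$shear),
      zoom = runif(1, bounds$zoom[1], bounds$zoom[2]),
      hflip = isTRUE(bounds$flip) && runif(1) < 0.5,
      vflip = isTRUE(bounds$flip) && runif(1) < 0.5
    ))
  }
  th <- params$rotation * pi / 180
  sh <- tan(params$shear * pi / 180)
  z <- params$zoom
  # forward map: flip -> zoom -> shear -> rotate -> shift, about the center
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
    matrix(c(1, 0, sh, 1), 2, 2) %*%
    diag(c(z, z)) %*%
    diag(c(if (params$vflip) -1 else 1, if (params$hflip) -1 else 1))
  Ainv <- solve(A)
  cr <- (d[1] + 1) / 2; cc <- (d[2] + 1) / 2
  tr <- rep(seq_len(d[1]), times = d[2]) - cr
  tc <- rep(seq_len(d[2]), each = d[1]) - cc
  src_r <- Ainv[1, 1] * (tr - params$shift_r) + Ainv[1, 2] * (tc - params$shift_c) + cr
  src_c <- Ainv[2, 1] * (tr - params$shift_r) + Ainv[2, 2] * (tc - params$shift_c) + cc
  sr <- pmin(pmax(round(src_r), 1L), d[1])
  sc <- pmin(pmax(round(src_c), 1L), d[2])
  lin <- cbind(sr, sc)
  img <- unclass(pair$image)
  new_img <- array(0L, dim = d)
  for (ch in 1:3) {
    plane <- img[, , ch]
    new_img[, , ch] <- matrix(plane[lin], d[1], d[2])
  }
  msk <- unclass(pair$mask)
  new_msk <- matrix(msk[lin], d[1], d[2])
  patch_pair(rgb_image(new_img), label_mask(new_msk, num_classes(pair$mask)),
             source_id = pair$source_id, grid_pos = pair$grid_pos)
}

#' Train one segmentation estimator
#'
#' Runs the configured number of epochs, drawing `samples_per_epoch`
#' augmented patches per epoch from the training split (with replacement),
#' optimizing the cross-entropy loss with Adam, and keeping the weights of
#' the epoch with the smallest validation loss. Fully reproducible in
#' `config$seed`.
#'
#' @param train,val Nonempty lists of [patch_pair()]s.
#' @param config A [net_config()].
#' @return A `trained_estimator` with fields `params` (best weights),
#'   `best_val_loss`, `history` (tibble epoch/train_loss/val_loss),
#'   `config`.
#' @export
train_estimator <- function(train, val, config = net_config()) {
  if (length(train) == 0 || length(val) == 0) {
    stop_bagseg("empty train or validation split", "bagseg_input_error")
  }
  model <- build_model(config)
  ch <- model$channels
  params <- model$params
  state <- adam_init(params)
  history <- vector("list", config$epochs)

  val_x <- lapply(val, function(p) unclass(p$image) / 255)
  val_y <- lapply(val, function(p) one_hot(p$mask, config$num_classes))

  best_val <- Inf
  best_params <- params
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(length(train), config$samples_per_epoch, replace = TRUE)
      train_losses <- numeric(length(idx))
      pos <- 1L
      while (pos <= length(idx)) {
        batch <- idx[pos:min(pos + config$batch_size - 1L, length(idx))]
        grads <- NULL
        for (bi in seq_along(batch)) {
          pair <- train[[batch[bi]]]
          if (config$augment) {
            pair <- augment_pair(
              pair, seed = derive_seed(config$seed,
                                       paste0("aug", epoch, "_", pos, "_", bi)))
          }
          x <- unclass(pair$image) / 255
          y <- one_hot(pair$mask, config$num_classes)
          fwd <- net_forward(params, ch, config, x, training = TRUE)
          n_px <- prod(dim(y)[1:2])
          train_losses[pos + bi - 1L] <-
            -sum(y * log(pmax(fwd$probs, 1e-7)))
          dlogits <- (fwd$probs - y) / n_px
          g <- net_backward(params, ch, config, fwd, dlogits)
          grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
        }
        grads <- lapply(grads, function(x) x / length(batch))
        upd <- adam_step(params, grads, state, config$learning_rate,
                         config$adam_beta1, config$adam_beta2)
        params <- upd$params
        state <- upd$state
        pos <- pos + length(batch)
      }
      val_loss <- mean(vapply(seq_along(val_x), function(i) {
        fwd <- net_forward(params, ch, config, val_x[[i]], training = FALSE)
        -sum(val_y[[i]] * log(pmax(fwd$probs, 1e-7)))
      }, numeric(1)))
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- params
      }
      history[[epoch]] <- tibble(epoch = epoch,
                                 train_loss = mean(train_losses),
                                 val_loss = val_loss)
    }
  })
  structure(
    list(params = best_params, final_params = params, channels = ch,
         config = config, best_val_loss = best_val,
         history = dplyr::bind_rows(history)),
    class = "trained_estimator"
  )
}

#' Predict a patch with a trained estimator
#'
#' One forward pass per patch (patch-to-patch); the mask is the per-pixel
#' argmax of the probability map, ties broken toward the lower class index.
#'
#' @param estimator A [train_estimator()] result (an untrained
#'   [build_model()] network is also accepted, e.g. to inspect the output
#'   normalization of fresh weights).
#' @param patch An [rgb_image()] with sides divisible by 4.
#' @return List with `probs` (H x W x K `prob_map`) and `mask`
#'   ([label_mask()]).
#' @export
predict_patch <- function(estimator, patch) {
  if (!inherits(estimator, c("trained_estimator", "seg_model"))) {
    stop_bagseg("not a trained estimator", "bagseg_state_error")
  }
  d <- dim(patch)
  if (d[1] %% 4 != 0 || d[2] %% 4 != 0) {
    stop_bagseg("patch sides must be divisible by the encoder stride (4)",
                "bagseg_shape_error")
  }
  x <- unclass(patch) / 255
  fwd <- net_forward(estimator$params, estimator$channels, estimator$config,
                     x, training = FALSE)
  probs <- structure(fwd$probs, class = "prob_map")
  list(probs = probs, mask = prob_to_mask(fwd$probs))
}

#' Per-pixel argmax of a probability map
#' @param probs H x W x K array.
#' @return A [label_mask()]; argmax ties go to the lower class index.
#' @export
prob_to_mask <- function(probs) {
  d <- dim(probs)
  m <- matrix(probs, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  label_mask(matrix(lab, d[1], d[2]), d[3])
}

#' @export
print.trained_estimator <- function(x, ...) {
  cat(sprintf("<trained_estimator> %d params, %d epochs, best val loss %.4g\n",
              n_parameters(x), nrow(x$history), x$best_val_loss))
  invisible(x)
}

#' @export
tidy.trained_estimator <- function(x, ...) x$history

#' @export
glance.trained_estimator <- function(x, ...) {
  tibble(n_parameters = n_parameters(x),
         epochs = nrow(x$history),
         best_val_loss = x$best_val_loss,
         final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @export
autoplot.trained_estimator <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy (per-patch sum)",
                  title = "Training history") +
    ggplot2::theme_minimal()
}
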