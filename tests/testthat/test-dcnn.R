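# The convolutional segmentation network: configuration, forward/backward
# contracts, the loss, augmentation, and training behavior.

test_that("net_config validates its ranges and applies profiles", {
  desk <- net_config("desk")
  expect_equal(desk$width_multiplier, 0.25)
  expect_identical(desk$input_size, 64L)
  expect_identical(desk$epochs, 5L)
  full <- net_config("full")
  expect_equal(full$width_multiplier, 1)
  expect_identical(full$input_size, 256L)
  expect_identical(full$epochs, 50L)
  expect_identical(full$samples_per_epoch, 4000L)
  expect_equal(full$learning_rate, 0.001)
  expect_identical(full$batch_size, 8L)
  expect_equal(full$dropout_rate, 0.5)
  expect_equal(full$adam_beta1, 0.9)
  expect_equal(full$adam_beta2, 0.999)

  expect_error(net_config(input_size = 30L), class = "bagseg_config_error")
  expect_error(net_config(dropout_rate = 1.5), class = "bagseg_config_error")
  expect_error(net_config(dropout_rate = -0.1), class = "bagseg_config_error")
  expect_error(net_config(num_classes = 1L), class = "bagseg_config_error")
  expect_error(net_config(width_multiplier = 0), class = "bagseg_config_error")
})

test_that("an untrained model maps any patch to normalized probabilities", {
  model <- build_model(tiny_net_config(seed = 2L))
  img <- with_seed(3L, rgb_image(array(sample(0:255, 16 * 16 * 3, TRUE),
                                       c(16, 16, 3))))
  out <- predict_patch(model, img)
  expect_identical(dim(out$probs), c(16L, 16L, 2L))
  sums <- apply(unclass(out$probs), c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
  expect_true(all(out$probs >= 0))
  expect_identical(dim(out$mask), c(16L, 16L))
  expect_error(predict_patch(model, flat_image(0, 0, 0, 18, 18)),
               class = "bagseg_shape_error")
  expect_error(predict_patch(list(), img), class = "bagseg_state_error")
})

test_that("parameter count is monotone in the width multiplier", {
  n <- vapply(c(0.25, 0.5, 1), function(m) {
    n_parameters(build_model(net_config(width_multiplier = m)))
  }, numeric(1))
  expect_true(all(diff(n) > 0))
})

test_that("model building is deterministic in the seed", {
  p1 <- build_model(tiny_net_config(seed = 5L))$params
  p2 <- build_model(tiny_net_config(seed = 5L))$params
  expect_identical(p1, p2)
  p3 <- build_model(tiny_net_config(seed = 6L))$params
  expect_false(identical(p1$stem.W, p3$stem.W))
})

test_that("cross-entropy matches hand values and the closed form", {
  p <- array(c(0.2, 0.8), dim = c(1, 1, 2))
  y <- array(c(0, 1), dim = c(1, 1, 2))
  expect_equal(cross_entropy_loss(p, y), -log(0.8))

  # perfect prediction: zero loss
  expect_equal(cross_entropy_loss(array(c(0, 1), c(1, 1, 2)), y), 0)

  # uniform prediction over N pixels, K = 2: N * ln 2
  for (n in c(1L, 16L, 64L)) {
    pu <- array(0.5, dim = c(n, n, 2))
    mask <- label_mask(matrix(rep(0:1, length.out = n * n), n, n))
    expect_equal(cross_entropy_loss(pu, mask), n * n * log(2))
  }

  expect_error(cross_entropy_loss(p, array(0, c(2, 1, 2))),
               class = "bagseg_shape_error")
})

test_that("cross-entropy equals a scalar double loop on random maps", {
  set.seed(51)
  for (rep in 1:3) {
    h <- sample(3:6, 1); w <- sample(3:6, 1)
    raw <- array(runif(h * w * 2), c(h, w, 2))
    p <- raw / rep(apply(raw, c(1, 2), sum), times = 2)
    mask <- label_mask(matrix(sample(0:1, h * w, TRUE), h, w))
    y <- one_hot(mask)
    acc <- 0
    for (i in 1:h) for (j in 1:w) for (k in 1:2) {
      acc <- acc - y[i, j, k] * log(max(p[i, j, k], 1e-7))
    }
    expect_equal(cross_entropy_loss(p, mask), acc, tolerance = 1e-9)
  }
})

test_that("a list of patches yields the mean of per-patch sums", {
  p1 <- array(c(0.2, 0.8), c(1, 1, 2)); y1 <- array(c(0, 1), c(1, 1, 2))
  p2 <- array(c(0.5, 0.5), c(1, 1, 2)); y2 <- array(c(1, 0), c(1, 1, 2))
  expect_equal(cross_entropy_loss(list(p1, p2), list(y1, y2)),
               mean(c(-log(0.8), log(2))))
})

test_that("augmentation at identity parameters is the identity", {
  pool <- tiny_pool(1)
  ident <- list(rotation = 0, shift_r = 0, shift_c = 0, shear = 0, zoom = 1,
                hflip = FALSE, vflip = FALSE)
  out <- augment_pair(pool[[1]], params = ident)
  expect_identical(unclass(out$image), unclass(pool[[1]]$image))
  expect_identical(unclass(out$mask), unclass(pool[[1]]$mask))
})

test_that("a pure horizontal flip mirrors image and mask together", {
  pool <- tiny_pool(1)
  flip <- list(rotation = 0, shift_r = 0, shift_c = 0, shear = 0, zoom = 1,
               hflip = TRUE, vflip = FALSE)
  out <- augment_pair(pool[[1]], params = flip)
  expect_identical(unclass(out$image), unclass(pool[[1]]$image)[, 16:1, ])
  expect_identical(matrix(as.integer(out$mask), 16, 16),
                   unclass(pool[[1]]$mask)[, 16:1])
})

test_that("random augmentation keeps labels valid and is seeded", {
  pool <- tiny_pool(2)
  a1 <- augment_pair(pool[[1]], seed = 9L)
  a2 <- augment_pair(pool[[1]], seed = 9L)
  expect_identical(unclass(a1$image), unclass(a2$image))
  expect_identical(unclass(a1$mask), unclass(a2$mask))
  a3 <- augment_pair(pool[[1]], seed = 10L)
  expect_false(identical(unclass(a1$image), unclass(a3$image)))
  expect_true(all(unclass(a1$mask) %in% 0:1))
  expect_identical(dim(a1$image), dim(pool[[1]]$image))
})

test_that("analytic gradients match central finite differences", {
  # Biases are randomized away from 0 so that no pre-activation sits on the
  # ReLU kink, where a subdifferential makes finite differences ill-posed.
  cfg <- net_config(input_size = 8L, width_multiplier = 0.2, seed = 7L,
                    dropout_rate = 0)
  model <- build_model(cfg)
  params <- model$params
  set.seed(71)
  for (nm in names(params)) {
    if (grepl("\\.b$", nm)) {
      params[[nm]] <- params[[nm]] + runif(length(params[[nm]]), -0.05, 0.05)
    }
  }
  ch <- model$channels
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- one_hot(label_mask(matrix(sample(0:1, 64, TRUE), 8, 8)))

  loss_at <- function(p) {
    fwd <- net_forward(p, ch, cfg, x, training = FALSE)
    -sum(y * log(pmax(fwd$probs, 1e-7)))
  }
  fwd <- net_forward(params, ch, cfg, x, training = FALSE)
  grads <- net_backward(params, ch, cfg, fwd, fwd$probs - y)

  eps <- 1e-5
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("d%s[%d]", nm, i))
    }
  }
})

test_that("training reduces the loss from its chance level", {
  pool <- tiny_pool(3, seed = 61L)
  cfg <- tiny_net_config(seed = 11L, epochs = 3L, samples_per_epoch = 48L)
  # an untrained model is near-uniform: per-patch loss close to 256 * ln 2
  fresh <- predict_patch(build_model(cfg), pool[[1]]$image)
  expect_lt(abs(cross_entropy_loss(unclass(fresh$probs), pool[[1]]$mask) -
                  256 * log(2)), 40)
  est <- train_estimator(pool[1:8], pool[9:12], cfg)
  expect_lt(est$history$train_loss[3], est$history$train_loss[1])
  expect_identical(nrow(est$history), 3L)
  expect_equal(est$best_val_loss, min(est$history$val_loss))
})

test_that("training is reproducible in the config seed", {
  pool <- tiny_pool(2, seed = 67L)
  cfg <- tiny_net_config(seed = 13L)
  e1 <- train_estimator(pool[1:6], pool[7:8], cfg)
  e2 <- train_estimator(pool[1:6], pool[7:8], cfg)
  expect_identical(e1$history, e2$history)
  expect_identical(e1$params, e2$params)
  expect_error(train_estimator(list(), pool[1:2], cfg),
               class = "bagseg_input_error")
})

test_that("argmax ties resolve to the lower class index", {
  tie <- array(0.5, dim = c(2, 2, 2))
  expect_true(all(prob_to_mask(tie) == 0L))
  sure <- array(c(0.4, 0.6), dim = c(1, 1, 2))
  expect_identical(as.integer(prob_to_mask(sure)), 1L)
})

test_that("a short training run learns a color-separable scene", {
  scenes <- separable_dataset(8, seed = 73L, height = 32, width = 32)
  pool <- tile_scenes(scenes[1:6], 32)
  test <- tile_scenes(scenes[7:8], 32)
  cfg <- net_config(input_size = 32L, epochs = 5L, samples_per_epoch = 300L,
                    learning_rate = 0.003, seed = 17L)
  est <- train_estimator(pool[1:5], pool[6], cfg)
  rep_t <- evaluate_model(function(p) predict_patch(est, p)$mask, test)
  expect_gt(rep_t$miou, 0.7)
})

test_that("estimator accessors report history and size", {
  pool <- tiny_pool(2, seed = 79L)
  est <- train_estimator(pool[1:6], pool[7:8], tiny_net_config(seed = 19L))
  expect_output(print(est), "trained_estimator")
  expect_identical(tidy(est), est$history)
  g <- glance(est)
  expect_identical(g$epochs, 2L)
  expect_equal(g$best_val_loss, est$best_val_loss)
  expect_s3_class(ggplot2::autoplot(est), "ggplot")
})
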