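# Random-forest pixel classifier on RGB + GLCM texture features.
#
# Each pixel is described by its R, G, B intensities plus five Haralick
# statistics (contrast, dissimilarity, homogeneity, correlation, ASM) of
# the gray-level co-occurrence matrix of its 7x7 neighborhood, with border
# pixels replicated near the edges. Per-pixel R operations define the
# contract; whole-patch featurization runs through a compiled batch path
# that the tests pin against the per-pixel path.

GLCM_OFFSETS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

luma_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Quantize a grayscale plane to a fixed number of levels
#' @param gray Numeric matrix in `[0, 255]`.
#' @param levels Number of gray levels.
#' @return Integer matrix with values in `0 .. levels - 1`.
#' @export
quantize_gray <- function(gray, levels = 8L) {
  q <- floor(gray / 256 * levels)
  q[q >= levels] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}

#' Extract a square window around a pixel, replicating the border
#'
#' @param image An [rgb_image()] (or a plain matrix).
#' @param row,col Center pixel (1-based).
#' @param size Odd window side.
#' @return A window of the same kind as `image`, `size` x `size`;
#'   out-of-bounds positions take the nearest edge value.
#' @export
extract_window <- function(image, row, col, size = 7L) {
  if (size %% 2 == 0) stop_bagseg("window size must be odd", "bagseg_parameter_error")
  d <- dim(image)
  if (row < 1 || row > d[1] || col < 1 || col > d[2]) {
    stop_bagseg("center pixel outside the image", "bagseg_range_error")
  }
  half <- size %/% 2
  rows <- pmin(pmax(row + (-half):half, 1L), d[1])
  cols <- pmin(pmax(col + (-half):half, 1L), d[2])
  if (length(d) == 3) {
    out <- unclass(image)[rows, cols, , drop = FALSE]
    if (inherits(image, "rgb_image")) out <- rgb_image(out)
    out
  } else {
    image[rows, cols, drop = FALSE]
  }
}

#' Gray-level co-occurrence matrix of a quantized window
#'
#' Counts co-occurring level pairs over the given offsets (pairs whose
#' both ends fall inside the window), optionally symmetrized, normalized
#' to sum 1.
#'
#' @param window_gray Integer matrix of quantized levels, all `< levels`.
#' @param levels Number of gray levels.
#' @param offsets List of `(drow, dcol)` integer pairs.
#' @param symmetric Count each pair in both directions.
#' @return A `glcm_matrix`: `levels` x `levels` probability matrix with
#'   attributes `levels`, `offsets`, `symmetric`.
#' @export
compute_glcm <- function(window_gray, levels = 8L, offsets = list(c(0L, 1L)),
                         symmetric = TRUE) {
  if (length(offsets) == 0) stop_bagseg("no offsets given", "bagseg_parameter_error")
  if (any(window_gray >= levels) || any(window_gray < 0)) {
    stop_bagseg("window values must be quantized below `levels`", "bagseg_range_error")
  }
  H <- nrow(window_gray); W <- ncol(window_gray)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- seq_len(H); r1 <- r1[r1 + dr >= 1 & r1 + dr <= H]
    c1 <- seq_len(W); c1 <- c1[c1 + dc >= 1 & c1 + dc <= W]
    if (length(r1) == 0 || length(c1) == 0) next
    a <- window_gray[r1, c1, drop = FALSE]
    b <- window_gray[r1 + dr, c1 + dc, drop = FALSE]
    for (k in seq_along(a)) {
      counts[a[k] + 1L, b[k] + 1L] <- counts[a[k] + 1L, b[k] + 1L] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) {
    stop_bagseg("offsets admit no valid pairs in this window",
                "bagseg_normalization_error")
  }
  structure(counts / total, levels = levels, offsets = offsets,
            symmetric = symmetric, class = c("glcm_matrix", "matrix"))
}

#' Haralick statistics of a normalized GLCM
#'
#' Contrast `sum P (i-j)^2`, dissimilarity `sum P |i-j|`, homogeneity
#' `sum P / (1 + (i-j)^2)`, ASM `sum P^2`, and correlation
#' `sum P (i - mu_i)(j - mu_j) / (sigma_i sigma_j)`, with correlation
#' defined as 1 for a zero-variance (constant) matrix.
#'
#' @param glcm A [compute_glcm()] result (entries summing to 1).
#' @return Named numeric: contrast, dissimilarity, homogeneity,
#'   correlation, asm.
#' @export
glcm_stats <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-6) {
    stop_bagseg("GLCM is not normalized", "bagseg_contract_error")
  }
  L <- nrow(glcm)
  i <- row(glcm) - 1
  j <- col(glcm) - 1
  p <- unclass(glcm)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  var_i <- sum(p * (i - mu_i)^2); var_j <- sum(p * (j - mu_j)^2)
  corr <- if (var_i * var_j > 1e-12) {
    sum(p * (i - mu_i) * (j - mu_j)) / sqrt(var_i * var_j)
  } else {
    1
  }
  c(contrast = sum(p * (i - j)^2),
    dissimilarity = sum(p * abs(i - j)),
    homogeneity = sum(p / (1 + (i - j)^2)),
    correlation = corr,
    asm = sum(p^2))
}

#' Feature vector of one pixel
#'
#' Center-pixel R, G, B plus the five GLCM statistics of the windowed
#' grayscale neighborhood, each statistic averaged over the four
#' distance-1 offsets (0, 45, 90, 135 degrees).
#'
#' @param image An [rgb_image()].
#' @param row,col Pixel (1-based).
#' @param levels Gray levels for quantization.
#' @param window Odd window side.
#' @return Named numeric of length 8:
#'   r, g, b, contrast, dissimilarity, homogeneity, correlation, asm.
#' @export
featurize_pixel <- function(image, row, col, levels = 8L, window = 7L) {
  win <- extract_window(image, row, col, window)
  q <- quantize_gray(luma_gray(win), levels)
  stats <- rowMeans(vapply(
    GLCM_OFFSETS,
    function(off) glcm_stats(compute_glcm(q, levels, list(off))),
    numeric(5)
  ))
  c(r = as.numeric(image[row, col, 1]),
    g = as.numeric(image[row, col, 2]),
    b = as.numeric(image[row, col, 3]),
    stats)
}

#' Feature matrix of every pixel of an image (compiled batch path)
#'
#' @inheritParams featurize_pixel
#' @return Numeric matrix `(H*W)` x 8 (pixels in column-major order),
#'   columns r, g, b, contrast, dissimilarity, homogeneity, correlation,
#'   asm. Identical to calling [featurize_pixel()] at every pixel.
#' @export
featurize_image <- function(image, levels = 8L, window = 7L) {
  q <- quantize_gray(luma_gray(image), levels)
  offs <- do.call(rbind, GLCM_OFFSETS)
  tex <- t(glcm_features_cpp(q, levels, as.integer(window), offs))
  out <- cbind(
    r = as.numeric(image[, , 1]),
    g = as.numeric(image[, , 2]),
    b = as.numeric(image[, , 3]),
    tex
  )
  colnames(out) <- c("r", "g", "b", "contrast", "dissimilarity",
                     "homogeneity", "correlation", "asm")
  out
}

#' Random-forest configuration
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum tree depth; mapped to the forest's
#'   `maxnodes = 2^max_depth` (capped at the training-set size).
#' @param n_pixels_per_image Pixels sampled per image for training.
#' @param seed RNG seed.
#' @return An `rf_config`.
#' @export
rf_config <- function(n_trees = 200L, max_depth = 50L,
                      n_pixels_per_image = 3000L, seed = 1L) {
  stopifnot(is_count(n_trees), n_trees >= 1, is_count(max_depth),
            max_depth >= 1, is_count(n_pixels_per_image),
            n_pixels_per_image >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 n_pixels_per_image = as.integer(n_pixels_per_image),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Sample labeled training pixels from a dataset
#'
#' Draws exactly `n_per_image` distinct pixel positions uniformly (without
#' replacement) from every image, reproducibly in `seed`.
#'
#' @param dataset List of scenes, each with `image` and `mask`.
#' @param n_per_image Pixels per image.
#' @param seed RNG seed.
#' @param features If `FALSE`, skip featurization and return positions and
#'   labels only (useful when only the sampling design is needed).
#' @return A tibble with `n_per_image * length(dataset)` rows: `image_id`,
#'   `row`, `col`, `label`, and (when `features = TRUE`) the 8 feature
#'   columns of [featurize_pixel()].
#' @export
sample_training_pixels <- function(dataset, n_per_image, seed = 1L,
                                   features = TRUE) {
  if (length(dataset) == 0) stop_bagseg("empty dataset", "bagseg_input_error")
  rows <- with_seed(seed, {
    lapply(seq_along(dataset), function(i) {
      d <- dim(dataset[[i]]$image)
      n_px <- d[1] * d[2]
      if (n_per_image > n_px) {
        stop_bagseg("n_per_image exceeds the image area", "bagseg_sampling_error")
      }
      lin <- sample.int(n_px, n_per_image)
      tibble(
        image_id = i,
        row = ((lin - 1L) %% d[1]) + 1L,
        col = ((lin - 1L) %/% d[1]) + 1L,
        lin = lin
      )
    })
  })
  out <- lapply(seq_along(rows), function(i) {
    tab <- rows[[i]]
    tab$label <- as.integer(dataset[[i]]$mask)[tab$lin]
    if (features) {
      feats <- featurize_image(dataset[[i]]$image)[tab$lin, , drop = FALSE]
      tab <- dplyr::bind_cols(tab, as_tibble(feats))
    }
    tab$lin <- NULL
    tab
  })
  dplyr::bind_rows(out)
}

FEATURE_COLS <- c("r", "g", "b", "contrast", "dissimilarity",
                  "homogeneity", "correlation", "asm")

#' Train the random-forest pixel classifier
#'
#' @param rows Tibble from [sample_training_pixels()] (feature columns +
#'   `label`); both classes must be present.
#' @param config An [rf_config()].
#' @return A `pixel_rf` model.
#' @export
train_rf <- function(rows, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  if (!all(FEATURE_COLS %in% names(rows))) {
    stop_bagseg("rows lack the 8 feature columns", "bagseg_input_error")
  }
  if (length(unique(rows$label)) < 2) {
    stop_bagseg("training rows contain a single class", "bagseg_degenerate_training_error")
  }
  x <- as.matrix(rows[, FEATURE_COLS])
  y <- factor(rows$label, levels = sort(unique(rows$label)))
  maxnodes <- min(2^min(config$max_depth, 30), nrow(rows))
  fit <- with_seed(config$seed, {
    randomForest::randomForest(x = x, y = y, ntree = config$n_trees,
                               maxnodes = maxnodes)
  })
  structure(list(forest = fit, config = config,
                 classes = as.integer(levels(y))),
            class = "pixel_rf")
}

#' Predict a whole patch with the pixel classifier
#'
#' Patch-to-pixel: every one of the `H*W` pixels is featurized and
#' classified individually; the realized classification count is recorded
#' on the result as attribute `n_classifications`.
#'
#' @param model A [train_rf()] model.
#' @param patch An [rgb_image()].
#' @return A [label_mask()] of the patch dims, with attribute
#'   `n_classifications = H*W`.
#' @export
predict_patch_rf <- function(model, patch) {
  if (!inherits(model, "pixel_rf")) {
    stop_bagseg("not a trained pixel_rf model", "bagseg_state_error")
  }
  feats <- featurize_image(patch)
  pred <- predict(model$forest, newdata = feats)
  d <- dim(patch)
  mask <- label_mask(matrix(as.integer(as.character(pred)), d[1], d[2]), 2L)
  attr(mask, "n_classifications") <- nrow(feats)
  mask
}

#' @export
print.pixel_rf <- function(x, ...) {
  cat(sprintf("<pixel_rf> %d trees, maxnodes %s, trained on %d pixels\n",
              x$forest$ntree, format(x$forest$forest$nrnodes),
              length(x$forest$y)))
  invisible(x)
}

#' @export
tidy.pixel_rf <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(feature = rownames(imp), importance = as.numeric(imp[, 1]))
}

#' @export
glance.pixel_rf <- function(x, ...) {
  tibble(n_trees = x$forest$ntree,
         n_training_pixels = length(x$forest$y),
         oob_error = x$forest$err.rate[x$forest$ntree, "OOB"])
}
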