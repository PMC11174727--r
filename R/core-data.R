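# Core image containers, file I/O, color conversion, and patch tiling.
#
# Images are plain R arrays with light S3 classes so they print sanely and
# carry their invariants:
#   * rgb_image  - H x W x 3 integer array, channel intensities in [0, 255]
#   * hsv_image  - H x W x 3 double array, hue in degrees [0, 360),
#                  saturation and value in [0, 1]
#   * label_mask - H x W integer matrix of class ids in {0, ..., K-1}

#' Construct an RGB image
#'
#' @param pixels Numeric H x W x 3 array with values in `[0, 255]`.
#' @return An `rgb_image`: an integer array of the same shape.
#' @export
#' @examples
#' img <- rgb_image(array(0L, dim = c(4, 4, 3)))
#' dim(img)
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3) {
    stop_bagseg("`pixels` must be a 3-d array", "bagseg_channel_error")
  }
  d <- dim(pixels)
  if (d[3] != 3) {
    stop_bagseg(
      sprintf("an RGB image needs exactly 3 channels, got %d", d[3]),
      "bagseg_channel_error"
    )
  }
  if (d[1] < 1 || d[2] < 1) stop_bagseg("empty image", "bagseg_size_error")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_bagseg("channel intensities must lie in [0, 255]", "bagseg_range_error")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' Construct a label mask
#'
#' @param labels Integer H x W matrix of class ids.
#' @param num_classes Number of classes `K`; every label must be `< K`.
#' @return A `label_mask` with attribute `num_classes`.
#' @export
label_mask <- function(labels, num_classes = 2L) {
  if (!is.matrix(labels)) stop_bagseg("`labels` must be a matrix", "bagseg_shape_error")
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    stop_bagseg("labels must be nonnegative integers", "bagseg_range_error")
  }
  if (any(labels >= num_classes)) {
    stop_bagseg(
      sprintf("label %d exceeds num_classes = %d", max(labels), num_classes),
      "bagseg_range_error"
    )
  }
  storage.mode(labels) <- "integer"
  structure(labels, num_classes = as.integer(num_classes), class = "label_mask")
}

#' Number of classes carried by a mask
#' @param mask A `label_mask`.
#' @return Integer `K`.
#' @export
num_classes <- function(mask) {
  k <- attr(mask, "num_classes")
  if (is.null(k)) max(mask) + 1L else k
}

#' Read an 8-bit RGB image from disk
#'
#' PNG files are decoded with the png package; JPEG/TIFF are decoded via
#' EBImage when it is installed. The image is returned at its original
#' resolution, no resampling. Inputs that are not 3-channel (grayscale,
#' RGBA) are rejected with an error naming the offending channel count.
#'
#' @param path Path to a PNG/JPEG/TIFF file.
#' @return An [rgb_image()].
#' @export
load_rgb <- function(path) {
  if (!file.exists(path)) {
    stop_bagseg(sprintf("no such file: %s", path), "bagseg_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop_bagseg("EBImage is required to read JPEG/TIFF", "bagseg_io_error")
    }
    img <- EBImage::readImage(path)
    px <- aperm(EBImage::imageData(img), if (length(dim(img)) == 3) c(2, 1, 3) else c(2, 1))
  } else {
    stop_bagseg(sprintf("unsupported image format: .%s", ext), "bagseg_io_error")
  }
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    nchan <- if (length(dim(px)) == 3) dim(px)[3] else 1L
    stop_bagseg(
      sprintf("expected a 3-channel RGB image, got %d channel(s)", nchan),
      "bagseg_channel_error"
    )
  }
  rgb_image(round(px * 255))
}

#' Write an RGB image as PNG
#' @param image An [rgb_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_rgb <- function(image, path) {
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Write / read a label mask as a single-channel 8-bit PNG
#'
#' The stored pixel value equals the label value, so the round trip is
#' bit-exact for any label below 256.
#'
#' @param mask A [label_mask()].
#' @param path File path.
#' @return `save_mask()` returns `path` invisibly; `load_mask()` a mask.
#' @export
save_mask <- function(mask, path) {
  if (max(mask) >= 256) {
    stop_bagseg("labels >= 256 cannot be encoded in an 8-bit PNG",
                "bagseg_encoding_error")
  }
  png::writePNG(unclass(mask) / 255, target = path)
  invisible(path)
}

#' @rdname save_mask
#' @param num_classes Optional class count; defaults to `max(label) + 1`,
#'   floored at 2.
#' @export
load_mask <- function(path, num_classes = NULL) {
  if (!file.exists(path)) {
    stop_bagseg(sprintf("no such file: %s", path), "bagseg_io_error")
  }
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  labels <- round(px * 255)
  if (is.null(num_classes)) num_classes <- max(2L, max(labels) + 1L)
  label_mask(labels, num_classes)
}

#' Convert an RGB image to HSV
#'
#' Standard hexcone transform. Hue is reported in degrees `[0, 360)`,
#' saturation and value in `[0, 1]`. Achromatic pixels (zero saturation)
#' get hue 0 by convention.
#'
#' @param image An [rgb_image()].
#' @return An `hsv_image` array of the same spatial shape.
#' @export
#' @examples
#' px <- array(0L, dim = c(1, 1, 3)); px[1, 1, 1] <- 255L
#' rgb_to_hsv(rgb_image(px))[1, 1, ]  # pure red: hue 0, s 1, v 1
rgb_to_hsv <- function(image) {
  d <- dim(image)
  flat <- matrix(as.numeric(image), ncol = 3)  # columns R, G, B
  hsv <- grDevices::rgb2hsv(t(flat), maxColorValue = 255)
  h <- hsv[1, ] * 360
  h[h >= 360] <- 0
  out <- array(c(h, hsv[2, ], hsv[3, ]), dim = d)
  structure(out, class = "hsv_image")
}

#' A single image/mask tile and its grid position
#'
#' @param image Patch [rgb_image()].
#' @param mask Patch [label_mask()] of identical spatial dims.
#' @param source_id Provenance string for the parent image.
#' @param grid_pos Integer `(row, col)` of the tile, 0-based, origin top-left.
#' @return A `patch_pair`.
#' @export
patch_pair <- function(image, mask, source_id = "image", grid_pos = c(0L, 0L)) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2])) {
    stop_bagseg("patch image and mask dims differ", "bagseg_shape_error")
  }
  structure(
    list(image = image, mask = mask, source_id = source_id,
         grid_pos = as.integer(grid_pos)),
    class = "patch_pair"
  )
}

#' Tile a full-size image into fixed-size patches
#'
#' Lays a top-left-anchored grid of non-overlapping `patch_size` x
#' `patch_size` tiles over the image; leftover right/bottom margins are
#' discarded. A 1064 x 768 image at patch size 256 therefore yields
#' 4 x 3 = 12 patches (a 40-pixel right margin is dropped).
#'
#' @param image An [rgb_image()].
#' @param mask The paired [label_mask()], same dims.
#' @param patch_size Tile side in pixels.
#' @param source_id Provenance string stored on every tile.
#' @return List of [patch_pair()]s, `floor(H/p) * floor(W/p)` of them,
#'   in row-major grid order.
#' @export
crop_to_patches <- function(image, mask, patch_size, source_id = "image") {
  d <- dim(image)
  if (d[1] < patch_size || d[2] < patch_size) {
    stop_bagseg("image smaller than patch_size", "bagseg_size_error")
  }
  if (!identical(d[1:2], dim(mask)[1:2])) {
    stop_bagseg("image and mask dims differ", "bagseg_shape_error")
  }
  n_rows <- d[1] %/% patch_size
  n_cols <- d[2] %/% patch_size
  out <- vector("list", n_rows * n_cols)
  idx <- 1L
  for (gr in seq_len(n_rows) - 1L) {
    for (gc in seq_len(n_cols) - 1L) {
      rs <- gr * patch_size + seq_len(patch_size)
      cs <- gc * patch_size + seq_len(patch_size)
      out[[idx]] <- patch_pair(
        rgb_image(unclass(image)[rs, cs, , drop = FALSE]),
        label_mask(unclass(mask)[rs, cs, drop = FALSE], num_classes(mask)),
        source_id = source_id,
        grid_pos = c(gr, gc)
      )
      idx <- idx + 1L
    }
  }
  out
}

#' Dataset manifest I/O
#'
#' A manifest is a tibble with columns `image`, `mask`, `split`
#' (train/validation/test) and `excluded` (logical; mirrors manual
#' poor-quality patch exclusion).
#'
#' @param manifest Tibble with the columns above.
#' @param path CSV path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the tibble.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("image", "mask", "split") %in% names(manifest)))
  if (!"excluded" %in% names(manifest)) manifest$excluded <- FALSE
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_bagseg(sprintf("no such file: %s", path), "bagseg_io_error")
  }
  out <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!"excluded" %in% names(out)) out$excluded <- FALSE
  out$excluded <- as.logical(out$excluded)
  out
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d>\n", d[1], d[2]))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_mask %d x %d, K = %d>\n", d[1], d[2], num_classes(x)))
  invisible(x)
}
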