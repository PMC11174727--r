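# HSV hue-range thresholding baseline and its SSE grid search.
#
# The hue grid is expressed in half-degree "grid units" (the 0-180 scale
# common to 8-bit HSV encodings): a grid endpoint g corresponds to 2*g
# degrees. A pixel is labeled crop iff its hue in degrees lies in the
# closed interval [2a, 2b].

#' A hue range in grid units
#'
#' @param a,b Lower/upper endpoints in grid units (half-degrees); `a < b`.
#' @return A `hue_range`.
#' @export
hue_range <- function(a, b) {
  if (a >= b) stop_bagseg("hue range needs a < b", "bagseg_range_error")
  structure(list(a = a, b = b), class = "hue_range")
}

#' Segment an image by hue thresholding
#'
#' Labels a pixel crop (1) iff its hue lies within the closed interval
#' spanned by `range` (grid units are doubled to degrees), else background
#' (0).
#'
#' @param image An [rgb_image()].
#' @param range A [hue_range()].
#' @return A [label_mask()].
#' @export
#' @examples
#' px <- array(c(0L, 255L, 0L), dim = c(1, 1, 3))  # pure green, hue 120
#' segment_by_hue(rgb_image(px), hue_range(40, 80))[1, 1]
segment_by_hue <- function(image, range) {
  stopifnot(inherits(range, "hue_range"))
  hsv <- rgb_to_hsv(image)
  hue <- hsv[, , 1]
  lab <- (hue >= 2 * range$a & hue <= 2 * range$b) * 1L
  label_mask(matrix(as.integer(lab), nrow = dim(image)[1]), 2L)
}

#' Sum of squared error between two binary masks
#'
#' For 0/1 masks this is exactly the misclassified-pixel count.
#'
#' @param pred,truth [label_mask()]s of equal dims.
#' @return Nonnegative integer.
#' @export
mask_sse <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop_bagseg("mask dims differ", "bagseg_shape_error")
  }
  sum((as.integer(pred) - as.integer(truth))^2)
}

#' Grid search of the hue range minimizing total SSE
#'
#' Evaluates the total SSE, summed over the search set, of every `(a, b)`
#' combination on the Cartesian grid, and returns the minimizer. Ties are
#' broken toward the tightest band (smallest `b - a`), then the smallest
#' `a`, so the result is deterministic.
#'
#' @param dataset List of scenes/patches, each a list with elements
#'   `image` and `mask` (a [patch_pair()] works as-is).
#' @param a_values,b_values Grid endpoints in grid units. Defaults are the
#'   canonical search grid: `a` in 0..40, `b` in 80..130, both in steps
#'   of 10 (30 combinations).
#' @return A `hue_grid_search` with fields `best` ([hue_range()]) and
#'   `sse_table` (tibble `a`, `b`, `sse`).
#' @export
grid_search_hue <- function(dataset,
                            a_values = seq(0, 40, by = 10),
                            b_values = seq(80, 130, by = 10)) {
  if (length(dataset) == 0) stop_bagseg("empty dataset", "bagseg_input_error")
  if (length(a_values) == 0 || length(b_values) == 0) {
    stop_bagseg("empty grid", "bagseg_input_error")
  }
  hues <- lapply(dataset, function(d) rgb_to_hsv(d$image)[, , 1])
  truths <- lapply(dataset, function(d) as.integer(d$mask))
  grid <- expand.grid(a = a_values, b = b_values)
  grid <- grid[grid$a < grid$b, , drop = FALSE]
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    lo <- 2 * grid$a[i]; hi <- 2 * grid$b[i]
    tot <- 0
    for (j in seq_along(hues)) {
      pred <- (hues[[j]] >= lo & hues[[j]] <= hi) * 1L
      tot <- tot + sum((as.integer(pred) - truths[[j]])^2)
    }
    tot
  }, numeric(1))
  tbl <- tibble(a = grid$a, b = grid$b, sse = sse)
  ord <- order(tbl$sse, tbl$b - tbl$a, tbl$a)
  best <- tbl[ord[1], ]
  structure(
    list(best = hue_range(best$a, best$b), sse_table = tbl),
    class = "hue_grid_search"
  )
}

#' @export
print.hue_grid_search <- function(x, ...) {
  cat(sprintf("<hue_grid_search> best range [%g, %g] grid units (SSE %g) over %d combinations\n",
              x$best$a, x$best$b,
              x$sse_table$sse[x$sse_table$a == x$best$a & x$sse_table$b == x$best$b],
              nrow(x$sse_table)))
  invisible(x)
}

#' @export
tidy.hue_grid_search <- function(x, ...) x$sse_table

#' @export
glance.hue_grid_search <- function(x, ...) {
  tibble(a = x$best$a, b = x$best$b,
         min_sse = min(x$sse_table$sse),
         n_combinations = nrow(x$sse_table))
}

#' @export
autoplot.hue_grid_search <- function(object, ...) {
  ggplot2::ggplot(object$sse_table,
                  ggplot2::aes(x = factor(.data$a), y = factor(.data$b),
                               fill = .data$sse)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = tibble(a = object$best$a, b = object$best$b, sse = NA_real_),
      shape = 4, size = 3, color = "white"
    ) +
    ggplot2::labs(x = "lower endpoint a (grid units)",
                  y = "upper endpoint b (grid units)",
                  fill = "total SSE",
                  title = "Hue-range grid search") +
    ggplot2::theme_minimal()
}
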