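# IoU (Jaccard) evaluation, performance tables, and the labeled-sample-size
# study with Student-t confidence bands.

#' Intersection-over-Union for one class
#'
#' `|pred = c AND truth = c| / |pred = c OR truth = c|`; defined as 1 when
#' the union is empty (the class is absent from both masks and correctly
#' not predicted).
#'
#' @param pred,truth [label_mask()]s of equal dims.
#' @param class_id Class index (0-based).
#' @return Real in `[0, 1]`.
#' @export
iou <- function(pred, truth, class_id) {
  if (!identical(dim(pred), dim(truth))) {
    stop_bagseg("mask dims differ", "bagseg_shape_error")
  }
  p <- unclass(pred) == class_id
  t <- unclass(truth) == class_id
  union <- sum(p | t)
  if (union == 0) return(1)
  sum(p & t) / union
}

#' Per-class IoU report
#'
#' @param pred,truth [label_mask()]s.
#' @param num_classes `K`; defaults to the truth's class count.
#' @return An `iou_report`: per-class IoUs and their arithmetic mean
#'   (mIoU).
#' @export
#' @examples
#' m <- label_mask(matrix(c(0L, 1L, 1L, 0L), 2, 2))
#' miou(m, m)$miou  # 1
miou <- function(pred, truth, num_classes = NULL) {
  K <- num_classes %||% num_classes(truth)
  per_class <- vapply(seq_len(K) - 1L, function(k) iou(pred, truth, k),
                      numeric(1))
  iou_report(per_class)
}

#' @rdname miou
#' @param iou_per_class Numeric vector of per-class IoUs.
#' @export
iou_report <- function(iou_per_class) {
  structure(list(iou_per_class = iou_per_class,
                 miou = mean(iou_per_class)),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("<iou_report> %s | mIoU %.4f\n",
              paste(sprintf("IoU%d %.4f", seq_along(x$iou_per_class) - 1,
                            x$iou_per_class), collapse = " "),
              x$miou))
  invisible(x)
}

#' @export
tidy.iou_report <- function(x, ...) {
  tibble(class = c(seq_along(x$iou_per_class) - 1L, NA_integer_),
         metric = c(sprintf("iou_%d", seq_along(x$iou_per_class) - 1L), "miou"),
         value = c(x$iou_per_class, x$miou))
}

# Micro-averaged report from aligned lists of predictions and truths:
# per-class intersection and union counts pooled over all patches.
evaluate_masks <- function(preds, truths, num_classes = 2L, average = "micro") {
  K <- num_classes
  if (average == "macro") {
    reps <- mapply(function(p, t) miou(p, t, K)$iou_per_class, preds, truths)
    return(iou_report(rowMeans(matrix(reps, nrow = K))))
  }
  inter <- numeric(K); union <- numeric(K)
  for (i in seq_along(preds)) {
    p <- unclass(preds[[i]]); t <- unclass(truths[[i]])
    for (k in seq_len(K) - 1L) {
      pk <- p == k; tk <- t == k
      inter[k + 1] <- inter[k + 1] + sum(pk & tk)
      union[k + 1] <- union[k + 1] + sum(pk | tk)
    }
  }
  iou_report(ifelse(union == 0, 1, inter / union))
}

#' Evaluate a predictor over a test set
#'
#' Accumulates global per-class intersection and union pixel counts over
#' all test patches and forms the IoUs from the pooled counts
#' (micro-averaging; per-patch macro-averaging available as an option).
#'
#' @param predict_fn Function mapping an [rgb_image()] patch to a
#'   [label_mask()].
#' @param testset Nonempty list of [patch_pair()]s.
#' @param num_classes `K`.
#' @param average `"micro"` (pooled counts, default) or `"macro"` (mean of
#'   per-patch reports).
#' @return An [iou_report()].
#' @export
evaluate_model <- function(predict_fn, testset, num_classes = 2L,
                           average = c("micro", "macro")) {
  average <- match.arg(average)
  if (length(testset) == 0) stop_bagseg("empty test set", "bagseg_input_error")
  preds <- lapply(testset, function(p) predict_fn(p$image))
  evaluate_masks(preds, lapply(testset, `[[`, "mask"), num_classes, average)
}

#' Two-sided Student-t band multiplier
#'
#' The factor `t` in the `mean +/- t * sd` confidence band: the two-sided
#' quantile of the Student distribution at `n_repeats - 1` degrees of
#' freedom.
#'
#' @param n_repeats Number of repeats the sd was computed from (>= 2).
#' @param level Band level (default 0.95).
#' @return Positive scalar (e.g. 2.045 for 30 repeats at 95%).
#' @export
t_multiplier <- function(n_repeats, level = 0.95) {
  stopifnot(n_repeats >= 2)
  qt(1 - (1 - level) / 2, df = n_repeats - 1)
}

#' Labeled-sample-size study
#'
#' For each sample size `s` and repeat `r`, draws `s` patches from the
#' pool (seeded), splits them `train_fraction` / the rest for validation,
#' trains one estimator, and evaluates it on the fixed test set. Reports
#' per-size means and standard deviations of IoU0, IoU1 and mIoU together
#' with `mean +/- t * sd` bands at the requested level (`t` from the
#' Student distribution at `n_repeats - 1` degrees of freedom).
#'
#' @param pool List of [patch_pair()]s.
#' @param sizes Increasing sample sizes, each `<= length(pool)`.
#' @param n_repeats Repeats per size (>= 2).
#' @param testset Fixed list of [patch_pair()]s for evaluation.
#' @param base_config [net_config()] for every trained model.
#' @param train_fraction Training share of each drawn sample.
#' @param master_seed Seed all draws and trainings derive from.
#' @param band_level Confidence-band level.
#' @param trainer Function `(train, val, config) -> predict_fn` returning
#'   a patch -> mask predictor; defaults to training a single network via
#'   [train_estimator()]. Injectable for baselines or oracles.
#' @return A `sample_size_curve`: tibble with per-size mean/sd/band
#'   columns; attributes `n_repeats`, `band_level`, `t_multiplier`.
#' @export
sample_size_study <- function(pool, sizes, n_repeats, testset,
                              base_config = net_config(),
                              train_fraction = 0.8, master_seed = 1L,
                              band_level = 0.95, trainer = NULL) {
  if (any(sizes > length(pool))) {
    stop_bagseg("a sample size exceeds the pool", "bagseg_parameter_error")
  }
  if (n_repeats < 2) stop_bagseg("need n_repeats >= 2", "bagseg_parameter_error")
  sizes <- sort(unique(as.integer(sizes)))
  if (is.null(trainer)) {
    trainer <- function(train, val, config) {
      est <- train_estimator(train, val, config)
      function(patch) predict_patch(est, patch)$mask
    }
  }
  tmult <- t_multiplier(n_repeats, band_level)
  rows <- vector("list", length(sizes))
  for (si in seq_along(sizes)) {
    s <- sizes[si]
    reps <- matrix(0, n_repeats, 3)
    for (r in seq_len(n_repeats)) {
      seed_r <- derive_seed(master_seed, paste0("size", s, "rep", r))
      idx <- with_seed(seed_r, sample.int(length(pool), s))
      n_train <- max(1L, min(s - 1L, round(train_fraction * s)))
      cfg <- base_config
      cfg$seed <- derive_seed(seed_r, "fit")
      predict_fn <- trainer(pool[idx[seq_len(n_train)]],
                            pool[idx[-seq_len(n_train)]], cfg)
      rep_t <- evaluate_model(predict_fn, testset)
      reps[r, ] <- c(rep_t$iou_per_class, rep_t$miou)
    }
    mu <- colMeans(reps); sdv <- apply(reps, 2, sd)
    rows[[si]] <- tibble(
      sample_size = s,
      mean_iou_0 = mu[1], mean_iou_1 = mu[2], mean_miou = mu[3],
      sd_iou_0 = sdv[1], sd_iou_1 = sdv[2], sd_miou = sdv[3],
      lower_miou = mu[3] - tmult * sdv[3],
      upper_miou = mu[3] + tmult * sdv[3]
    )
  }
  structure(dplyr::bind_rows(rows),
            n_repeats = n_repeats, band_level = band_level,
            t_multiplier = tmult,
            class = c("sample_size_curve", class(tibble())))
}

#' @export
autoplot.sample_size_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$sample_size, y = .data$mean_miou)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower_miou,
                                      ymax = .data$upper_miou),
                         alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "labeled sample size", y = "test mIoU",
                  title = sprintf("Sample-size curve (mean ± t × sd, %d repeats)",
                                  attr(object, "n_repeats"))) +
    ggplot2::theme_minimal()
}

#' Performance summary table
#'
#' Renders per-model training time, per-patch prediction time, and IoUs in
#' a fixed-width text layout; timings are reported as measured, never
#' asserted.
#'
#' @param rows List of lists (or a tibble) with fields `model`,
#'   `train_time`, `predict_time`, `report` (an [iou_report()]).
#' @return Character vector: one header line plus one line per model (also
#'   carries the underlying tibble as attribute `data`).
#' @export
report_table <- function(rows) {
  if (length(rows) == 0) stop_bagseg("no rows", "bagseg_input_error")
  if (inherits(rows, "data.frame")) {
    rows <- lapply(seq_len(nrow(rows)), function(i) as.list(rows[i, ]))
  }
  tab <- dplyr::bind_rows(lapply(rows, function(r) {
    nm <- r$model
    if (is.null(nm) || !nzchar(nm)) nm <- "—"
    tibble(model = nm,
           t1 = as.character(r$train_time %||% "NA"),
           t2 = as.character(r$predict_time %||% "NA"),
           iou_0 = r$report$iou_per_class[1],
           iou_1 = r$report$iou_per_class[2],
           miou = r$report$miou)
  }))
  widths <- c(max(nchar(c("Model", tab$model))), max(nchar(c("t1", tab$t1))),
              max(nchar(c("t2", tab$t2))), 5, 5, 5)
  fmt <- function(vals) {
    paste(mapply(formatC, vals, width = widths, flag = "-"), collapse = "  ")
  }
  lines <- c(
    fmt(c("Model", "t1", "t2", "IoU0", "IoU1", "mIoU")),
    vapply(seq_len(nrow(tab)), function(i) {
      fmt(c(tab$model[i], tab$t1[i], tab$t2[i],
            sprintf("%.2f", tab$iou_0[i]), sprintf("%.2f", tab$iou_1[i]),
            sprintf("%.2f", tab$miou[i])))
    }, character(1))
  )
  attr(lines, "data") <- tab
  lines
}
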