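# Bagging: many estimators trained on distinct random train/validation
# splits of the same labeled pool, fused by per-pixel majority vote.

#' Bagging specification
#'
#' @param n_estimators Number of ensemble members (>= 1).
#' @param train_fraction Fraction of the pool used for training in each
#'   split (the rest validates); strictly inside (0, 1). The canonical
#'   setting 0.8 splits a 750-patch pool into 600 train / 150 validation.
#' @param split_seed Seed controlling the split family and the derived
#'   per-estimator training seeds.
#' @param estimator_config [net_config()] used for every member.
#' @return A `bag_spec`.
#' @export
bag_spec <- function(n_estimators = 5L, train_fraction = 0.8,
                     split_seed = 1L, estimator_config = net_config()) {
  stopifnot(is_count(n_estimators), n_estimators >= 1)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_bagseg("train_fraction must lie strictly in (0, 1)", "bagseg_split_error")
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 estimator_config = estimator_config),
            class = "bag_spec")
}

#' Draw the family of train/validation splits
#'
#' Each split is an independent random partition of the whole pool at
#' `train_fraction`: train and validation are disjoint and their union is
#' the pool. Reproducible in `split_seed`.
#'
#' @param pool List of [patch_pair()]s (length >= 2).
#' @param spec A [bag_spec()].
#' @return List of `n_estimators` lists, each with `train` and
#'   `validation` elements.
#' @export
make_splits <- function(pool, spec) {
  n <- length(pool)
  if (n < 2) stop_bagseg("pool must hold at least 2 patches", "bagseg_split_error")
  n_train <- round(spec$train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop_bagseg("train_fraction leaves an empty split side", "bagseg_split_error")
  }
  lapply(seq_len(spec$n_estimators), function(e) {
    idx <- with_seed(derive_seed(spec$split_seed, paste0("split", e)),
                     sample.int(n, n_train))
    list(train = pool[idx], validation = pool[-idx])
  })
}

#' Per-pixel majority vote over a stack of masks
#'
#' The winning label at each pixel is the one with the most votes; exact
#' ties go to the lower class index (background for the binary case).
#'
#' @param stack Nonempty list of [label_mask()]s with identical dims.
#' @return A [label_mask()].
#' @export
majority_vote <- function(stack) {
  if (length(stack) == 0) stop_bagseg("empty stack", "bagseg_input_error")
  d <- dim(stack[[1]])
  for (m in stack) {
    if (!identical(dim(m), d)) stop_bagseg("stack dims differ", "bagseg_shape_error")
  }
  K <- max(vapply(stack, num_classes, integer(1)))
  votes <- matrix(0L, d[1] * d[2], K)
  for (m in stack) {
    lab <- as.integer(m)
    for (k in seq_len(K) - 1L) votes[, k + 1L] <- votes[, k + 1L] + (lab == k)
  }
  lab <- max.col(votes, ties.method = "first") - 1L
  label_mask(matrix(lab, d[1], d[2]), K)
}

#' Train a bagged ensemble
#'
#' One estimator per split, each with a distinct derived training seed (so
#' members differ both by data split and by initialization); order matches
#' split order, and members are independent given their seeds, so any
#' scheduling yields identical results.
#'
#' @param pool List of [patch_pair()]s.
#' @param spec A [bag_spec()].
#' @return List of `trained_estimator`s.
#' @export
train_ensemble <- function(pool, spec) {
  splits <- make_splits(pool, spec)
  lapply(seq_along(splits), function(e) {
    cfg <- spec$estimator_config
    cfg$seed <- derive_seed(spec$split_seed, paste0("estimator", e))
    train_estimator(splits[[e]]$train, splits[[e]]$validation, cfg)
  })
}

#' Ensemble prediction of one patch
#'
#' @param estimators Nonempty list of `trained_estimator`s.
#' @param patch An [rgb_image()].
#' @param mode `"vote"` (per-pixel majority over member argmax masks, the
#'   canonical fusion) or `"mean_prob"` (argmax of the averaged
#'   probability maps, provided as an alternative).
#' @return A [label_mask()].
#' @export
ensemble_predict <- function(estimators, patch, mode = c("vote", "mean_prob")) {
  mode <- match.arg(mode)
  if (length(estimators) == 0) stop_bagseg("no estimators", "bagseg_input_error")
  if (mode == "vote") {
    masks <- lapply(estimators, function(e) predict_patch(e, patch)$mask)
    majority_vote(masks)
  } else {
    probs <- lapply(estimators, function(e) unclass(predict_patch(e, patch)$probs))
    prob_to_mask(Reduce(`+`, probs) / length(probs))
  }
}

#' IoU as a function of ensemble size
#'
#' For each count `m`, fuses the first `m` estimators (training order) by
#' majority vote over the test set and records the micro-averaged
#' per-class IoU and mIoU.
#'
#' @param estimators List of `trained_estimator`s.
#' @param testset List of [patch_pair()]s.
#' @param counts Increasing estimator counts, each `<=
#'   length(estimators)`.
#' @return An `estimator_curve`: tibble with columns `n_estimators`,
#'   `iou_0`, `iou_1`, `miou`.
#' @export
estimator_curve <- function(estimators, testset, counts) {
  if (any(counts > length(estimators)) || any(counts < 1)) {
    stop_bagseg("counts must lie in 1..length(estimators)", "bagseg_parameter_error")
  }
  # per-estimator masks computed once, vote tallies grown incrementally
  member_masks <- lapply(estimators, function(e) {
    lapply(testset, function(p) predict_patch(e, p$image)$mask)
  })
  K <- 2L
  counts <- sort(unique(as.integer(counts)))
  tallies <- lapply(testset, function(p) {
    matrix(0L, prod(dim(p$mask)), K)
  })
  rows <- vector("list", length(counts))
  m_done <- 0L
  for (ci in seq_along(counts)) {
    m <- counts[ci]
    while (m_done < m) {
      m_done <- m_done + 1L
      for (t in seq_along(testset)) {
        lab <- as.integer(member_masks[[m_done]][[t]])
        for (k in seq_len(K) - 1L) {
          tallies[[t]][, k + 1L] <- tallies[[t]][, k + 1L] + (lab == k)
        }
      }
    }
    preds <- lapply(seq_along(testset), function(t) {
      d <- dim(testset[[t]]$mask)
      label_mask(matrix(max.col(tallies[[t]], ties.method = "first") - 1L,
                        d[1], d[2]), K)
    })
    rep_t <- evaluate_masks(preds, lapply(testset, `[[`, "mask"))
    rows[[ci]] <- tibble(n_estimators = m, iou_0 = rep_t$iou_per_class[1],
                         iou_1 = rep_t$iou_per_class[2], miou = rep_t$miou)
  }
  structure(dplyr::bind_rows(rows), class = c("estimator_curve", class(tibble())))
}

#' @export
autoplot.estimator_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("iou_0", "iou_1", "miou"),
                              names_to = "metric", values_to = "iou")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_estimators, y = .data$iou,
                                     color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of estimators", y = "IoU",
                  title = "Ensemble-size curve") +
    ggplot2::theme_minimal()
}
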