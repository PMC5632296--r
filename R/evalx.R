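# Accuracy metrics for the two evaluation surfaces: patch classification
# (per-class correct/misclassified counts) and localization (per-cell
# false-positive / false-negative rates within a radius of ground truth).

#' Classification accuracy from per-class counts
#'
#' `100 * sum(correct) / sum(correct + misclassified)` over the selected
#' classes; with a single class this is its per-class accuracy, with all
#' classes the dataset's total/average accuracy.
#'
#' @param counts Tibble with columns `class`, `correct`, `misclassified`.
#' @param classes Optional subset of classes; default all.
#' @return Accuracy in percent (full precision; round to one decimal for
#'   reporting).
#' @export
classification_accuracy <- function(counts, classes = NULL) {
  stopifnot(all(c("class", "correct", "misclassified") %in% names(counts)))
  if (!is.null(classes)) {
    miss <- setdiff(classes, counts$class)
    if (length(miss) > 0L) {
      abort(sprintf("class(es) not in counts: %s", paste(miss, collapse = ", ")))
    }
    counts <- counts[counts$class %in% classes, ]
  }
  total <- sum(counts$correct) + sum(counts$misclassified)
  if (total == 0L) abort("no samples in the selected classes")
  100 * sum(counts$correct) / total
}

#' Confusion counts of a classifier on labelled patches
#'
#' Runs the model over a labelled patch set and tallies correct /
#' misclassified per class (argmax decision).
#'
#' @param model A `tip_classifier`.
#' @param patches Patch tibble with `patch` and `label` columns; patch
#'   sides must match the model input (crop or downscale upstream).
#' @return Tibble `class`, `correct`, `misclassified`.
#' @export
confusion_counts <- function(model, patches) {
  probs <- classify_patches(model, patches)
  pred <- model$class_names[max.col(as.matrix(probs), ties.method = "first")]
  tibble(label = patches$label, pred = pred) |>
    dplyr::group_by(class = .data$label) |>
    dplyr::summarise(
      correct = sum(.data$pred == .data$class),
      misclassified = sum(.data$pred != .data$class),
      .groups = "drop"
    )
}

#' Localization accuracy of a thresholded map against ground truth
#'
#' Every map cell is scored at its image-space centre. A cell is a false
#' positive if it is marked positive yet lies farther than `radius` from
#' every ground-truth feature; it is a false negative if it lies within
#' `radius` of some feature yet is not marked. Both are reported as
#' percentages of all cells, and
#' `feature_accuracy = 100 - FP% - FN%` (the identity holds exactly before
#' rounding). The radius defaults to half the classification window.
#'
#' @param mask Logical matrix from [threshold_map()].
#' @param map The `class_map` the mask came from (supplies geometry).
#' @param truth Ground-truth points: tibble with `x`, `y` in image
#'   coordinates (may have zero rows).
#' @param radius Match radius in pixels.
#' @return One-row tibble: `false_positive_pct`, `false_negative_pct`,
#'   `feature_accuracy_pct`, `radius`, `n_cells`.
#' @export
localization_metrics <- function(mask, map, truth, radius = NULL) {
  radius <- radius %||% (map$window / 2)
  d <- dim(mask)
  ij <- cbind(
    i = rep(seq_len(d[1L]), times = d[2L]),
    j = rep(seq_len(d[2L]), each = d[1L])
  )
  xy <- cell_to_image(map, ij[, 1L], ij[, 2L])
  pts <- as_xy_matrix(truth[, c("x", "y")])
  if (nrow(pts) > 0L) {
    d2min <- rep(Inf, nrow(xy))
    for (t in seq_len(nrow(pts))) {
      d2 <- (xy$x - pts[t, 1L])^2 + (xy$y - pts[t, 2L])^2
      d2min <- pmin(d2min, d2)
    }
    in_radius <- d2min <= radius^2
  } else {
    in_radius <- rep(FALSE, nrow(xy))
  }
  positive <- as.vector(mask)
  n <- length(positive)
  fp <- 100 * sum(positive & !in_radius) / n
  fn <- 100 * sum(in_radius & !positive) / n
  tibble(
    false_positive_pct = fp,
    false_negative_pct = fn,
    feature_accuracy_pct = 100 - fp - fn,
    radius = radius,
    n_cells = n
  )
}

#' Match detected tips to ground truth
#'
#' Greedy radius matching for detector evaluation: each ground-truth tip is
#' recovered if some detection lies within `radius`; each detection not
#' within `radius` of any ground-truth tip is spurious.
#'
#' @param detected,truth Tip-set tibbles (`x`, `y`).
#' @param radius Match radius in pixels (half the window, typically).
#' @return One-row tibble: `n_truth`, `n_detected`, `n_recovered`,
#'   `n_spurious`, `recall_pct`, `spurious_pct` (spurious as a percentage
#'   of the ground-truth count).
#' @export
match_tips <- function(detected, truth, radius) {
  r2 <- radius^2
  n_truth <- nrow(truth)
  n_det <- nrow(detected)
  recovered <- 0L
  if (n_truth > 0L && n_det > 0L) {
    for (t in seq_len(n_truth)) {
      d2 <- (detected$x - truth$x[t])^2 + (detected$y - truth$y[t])^2
      if (any(d2 <= r2)) recovered <- recovered + 1L
    }
  }
  spurious <- 0L
  if (n_det > 0L) {
    for (k in seq_len(n_det)) {
      d2 <- if (n_truth > 0L) {
        (truth$x - detected$x[k])^2 + (truth$y - detected$y[k])^2
      } else Inf
      if (!any(d2 <= r2)) spurious <- spurious + 1L
    }
  }
  tibble(
    n_truth = n_truth, n_detected = n_det, n_recovered = recovered,
    n_spurious = spurious,
    recall_pct = if (n_truth > 0L) 100 * recovered / n_truth else NA_real_,
    spurious_pct = if (n_truth > 0L) 100 * spurious / n_truth else NA_real_
  )
}

#' Reference classification counts shipped with the package
#'
#' Per-class correct/misclassified validation counts for the published
#' full-scale root and shoot classifiers, distributed as plain CSV in
#' `inst/extdata`; used to exercise the accuracy arithmetic.
#'
#' @param domain `"root"` or `"shoot"`.
#' @return Tibble `class`, `correct`, `misclassified`.
#' @export
reference_classification_counts <- function(domain = c("root", "shoot")) {
  domain <- match.arg(domain)
  path <- system.file("extdata", "reference_classification_counts.csv",
                      package = "tipscan", mustWork = TRUE)
  counts <- readr::read_csv(path, show_col_types = FALSE)
  counts[counts$domain == domain, c("class", "correct", "misclassified")]
}

#' Reference localization rates shipped with the package
#'
#' Published per-class false-positive and false-negative percentages of
#' the full-scale sliding-window detectors over their unseen test images.
#'
#' @return Tibble `domain`, `class`, `false_positive_pct`,
#'   `false_negative_pct`.
#' @export
reference_localization_rates <- function() {
  path <- system.file("extdata", "reference_localization_rates.csv",
                      package = "tipscan", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
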