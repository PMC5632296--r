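test_that("published per-class counts reproduce the printed accuracies", {
  root <- reference_classification_counts("root")
  expect_equal(round(classification_accuracy(root), 1), 98.4)
  expect_equal(round(classification_accuracy(root, "root_tip"), 1), 97.5)
  expect_equal(round(classification_accuracy(root, "root_negative"), 1), 98.9)
  shoot <- reference_classification_counts("shoot")
  expect_equal(round(classification_accuracy(shoot), 1), 97.3)
  expect_equal(round(classification_accuracy(shoot, "leaf_tip"), 1), 95.2)
  expect_equal(round(classification_accuracy(shoot, "ear_tip"), 1), 97.9)
  perfect <- tibble::tibble(class = "x", correct = 7, misclassified = 0)
  expect_equal(classification_accuracy(perfect), 100)
  expect_error(classification_accuracy(
    tibble::tibble(class = "x", correct = 0, misclassified = 0)
  ), "no samples")
  expect_error(classification_accuracy(perfect, "unknown"), "unknown")
})

grid_map <- function(n = 25L, stride = 4L, window = 32L) {
  prob <- matrix(0, n, n)
  tipscan:::new_class_map(
    array(c(prob, 1 - prob), dim = c(n, n, 2)),
    c("root_tip", "root_negative"), stride, window, "synthetic",
    c(window + stride * (n - 1L), window + stride * (n - 1L))
  )
}

cells_xy <- function(map) {
  d <- dim(map$grid)
  ij <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  cbind(
    x = map$origin[1] + map$stride * (ij$j - 1),
    y = map$origin[2] + map$stride * (ij$i - 1),
    i = ij$i, j = ij$j
  )
}

test_that("a perfect detector scores 100 with zero FP and FN", {
  map <- grid_map()
  truth <- tibble::tibble(x = 52, y = 52)
  xy <- cells_xy(map)
  mask <- matrix(FALSE, 25, 25)
  inside <- sqrt((xy[, "x"] - 52)^2 + (xy[, "y"] - 52)^2) <= 16
  mask[cbind(xy[inside, "i"], xy[inside, "j"])] <- TRUE
  rep <- localization_metrics(mask, map, truth, radius = 16)
  expect_equal(rep$false_positive_pct, 0)
  expect_equal(rep$false_negative_pct, 0)
  expect_equal(rep$feature_accuracy_pct, 100)
})

test_that("missing all features gives FN equal to the disc-membership count", {
  map <- grid_map()
  truth <- tibble::tibble(x = c(52, 80), y = c(52, 88))
  mask <- matrix(FALSE, 25, 25)
  rep <- localization_metrics(mask, map, truth, radius = 16)
  xy <- cells_xy(map)
  d1 <- sqrt((xy[, "x"] - 52)^2 + (xy[, "y"] - 52)^2)
  d2 <- sqrt((xy[, "x"] - 80)^2 + (xy[, "y"] - 88)^2)
  n_in <- sum(d1 <= 16 | d2 <= 16)
  expect_equal(rep$false_negative_pct, 100 * n_in / 625)
  expect_equal(rep$false_positive_pct, 0)
  expect_equal(rep$feature_accuracy_pct,
               100 - rep$false_positive_pct - rep$false_negative_pct)
})

test_that("one far positive cell contributes exactly one FP cell", {
  map <- grid_map()
  truth <- tibble::tibble(x = 52, y = 52)
  mask <- matrix(FALSE, 25, 25)
  mask[25, 25] <- TRUE # image position (112, 112): far from truth
  rep <- localization_metrics(mask, map, truth, radius = 16)
  xy <- cells_xy(map)
  n_in <- sum(sqrt((xy[, "x"] - 52)^2 + (xy[, "y"] - 52)^2) <= 16)
  expect_equal(rep$false_positive_pct, 100 * 1 / 625)
  expect_equal(rep$false_negative_pct, 100 * n_in / 625)
  # the identity holds exactly, before any rounding
  expect_identical(
    rep$feature_accuracy_pct + rep$false_positive_pct + rep$false_negative_pct,
    100
  )
})

test_that("metrics are invariant to truth ordering and monotone in far positives", {
  map <- grid_map()
  truth <- tibble::tibble(x = c(52, 80, 100), y = c(52, 88, 60))
  mask <- withr::with_seed(5, matrix(runif(625) < 0.1, 25, 25))
  a <- localization_metrics(mask, map, truth, radius = 16)
  b <- localization_metrics(mask, map, truth[c(3, 1, 2), ], radius = 16)
  expect_equal(a, b)
  mask2 <- mask
  mask2[1, 25] <- TRUE # guaranteed far from all truth
  c2 <- localization_metrics(mask2, map, truth, radius = 16)
  expect_gte(c2$false_positive_pct, a$false_positive_pct)
  expect_equal(c2$false_negative_pct, a$false_negative_pct)
})

test_that("empty truth with an empty mask is perfect accuracy", {
  map <- grid_map(10)
  rep <- localization_metrics(matrix(FALSE, 10, 10), map,
                              tibble::tibble(x = double(), y = double()))
  expect_equal(rep$false_positive_pct, 0)
  expect_equal(rep$false_negative_pct, 0)
  expect_equal(rep$feature_accuracy_pct, 100)
  expect_equal(rep$radius, 16)
})

test_that("published localization rates satisfy the accuracy identity", {
  rates <- reference_localization_rates()
  acc <- 100 - rates$false_positive_pct - rates$false_negative_pct
  root <- acc[rates$domain == "root" & rates$class == "root_tip"]
  expect_equal(round(root, 2), 99.85)
  expect_equal(round(acc[rates$class == "leaf_tip"], 2), 99.64)
  expect_equal(round(acc[rates$class == "leaf_base"], 2), 99.68)
})

test_that("tip matching counts recovered and spurious detections", {
  truth <- tibble::tibble(x = c(10, 50), y = c(10, 50))
  det <- tibble::tibble(x = c(12, 90), y = c(9, 90))
  m <- match_tips(det, truth, radius = 16)
  expect_equal(m$n_recovered, 1L)
  expect_equal(m$n_spurious, 1L)
  expect_equal(m$recall_pct, 50)
  expect_equal(m$spurious_pct, 50)
  none <- match_tips(det[0, ], truth, radius = 16)
  expect_equal(none$n_recovered, 0L)
  expect_equal(none$recall_pct, 0)
})
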