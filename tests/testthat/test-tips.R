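test_that("erosion shrinks solid squares as the definition predicts", {
  m <- matrix(FALSE, 11, 11)
  m[3:9, 3:9] <- TRUE # 7x7 solid
  e <- erode_mask(m, 3)
  expect_equal(sum(e), 1L)
  expect_true(e[6, 6])
  m5 <- matrix(TRUE, 5, 5) # fills the mask; border counts as background
  expect_equal(sum(erode_mask(m5, 3)), 0L)
  expect_equal(sum(erode_mask(m5, 2)), 1L)
  # iterations = 0 is the identity
  expect_equal(erode_mask(m, 0), m)
})

test_that("erosion matches the neighbourhood-definition oracle on random masks", {
  for (s in 1:100) {
    mask <- random_mask(15, 18, p = 0.65, seed = s)
    it <- 1L + (s %% 3L)
    expect_identical(erode_mask(mask, it), erode_oracle(mask, it))
  }
})

test_that("component labelling uses 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE # diagonal neighbours: one component
  m[5, 5] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_true(lab[5, 5] != lab[1, 1])
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0L)
})

test_that("labelling and centroids match an independent graph oracle", {
  for (s in 1:40) {
    mask <- erode_oracle(random_mask(20, 20, p = 0.72, seed = 100 + s), 1)
    lab <- label_components(mask)
    idx <- which(mask, arr.ind = TRUE)
    oracle_mem <- components_oracle(mask)
    if (length(oracle_mem) == 0L) {
      expect_equal(max(lab), 0L)
      next
    }
    got_mem <- lab[mask]
    # same partition up to label permutation
    expect_equal(max(got_mem), max(oracle_mem))
    expect_true(all(tapply(oracle_mem, got_mem, function(v) {
      length(unique(v)) == 1L
    })))
    # centroids: per-component coordinate means agree as sets
    got_c <- cbind(tapply(idx[, 1], got_mem, mean),
                   tapply(idx[, 2], got_mem, mean))
    want_c <- cbind(tapply(idx[, 1], oracle_mem, mean),
                    tapply(idx[, 2], oracle_mem, mean))
    ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(unname(ord(got_c)), unname(ord(want_c)), tolerance = 1e-12)
  }
})

make_map_with_mask <- function(prob, stride = 4L, window = 32L) {
  grid <- array(0, dim = c(dim(prob), 2L))
  grid[, , 1] <- prob
  grid[, , 2] <- 1 - prob
  tipscan:::new_class_map(grid, c("root_tip", "root_negative"), stride,
                          window, "synthetic",
                          c(window + stride * (ncol(prob) - 1L),
                            window + stride * (nrow(prob) - 1L)))
}

test_that("well-separated blocks give one tip per block at its centre", {
  prob <- matrix(0, 24, 24)
  prob[3:9, 3:9] <- 1
  prob[14:20, 12:18] <- 1
  map <- make_map_with_mask(prob)
  tips <- extract_tips(map, "root_tip", 0.5, iterations = 3)
  expect_equal(nrow(tips), 2L)
  got <- tips[order(tips$y), ]
  expect_equal(got$x, 16 + 4 * (c(6, 15) - 1))
  expect_equal(got$y, 16 + 4 * (c(6, 17) - 1))
  # 5x5 blocks: symmetric centroids at the block centres too
  prob5 <- matrix(0, 24, 24)
  prob5[3:7, 3:7] <- 1
  prob5[14:18, 12:16] <- 1
  tips5 <- extract_tips(make_map_with_mask(prob5), "root_tip", 0.5,
                        iterations = 3)
  got5 <- tips5[order(tips5$y), ]
  expect_equal(got5$x, 16 + 4 * (c(5, 14) - 1))
  expect_equal(got5$y, 16 + 4 * (c(5, 16) - 1))
  # a lone heat-map cell is an artefact: erased by the third iteration
  lone <- matrix(0, 24, 24)
  lone[12, 12] <- 1
  expect_equal(nrow(extract_tips(make_map_with_mask(lone), "root_tip", 0.5,
                                 iterations = 3)), 0L)
  expect_equal(nrow(extract_tips(make_map_with_mask(lone), "root_tip", 0.5,
                                 iterations = 1)), 1L)
})

test_that("an empty mask yields an empty tip set", {
  map <- make_map_with_mask(matrix(0, 10, 10))
  tips <- extract_tips(map, "root_tip")
  expect_equal(nrow(tips), 0L)
})

test_that("random multi-blob masks give centroids equal to per-label means", {
  for (s in 1:10) {
    prob <- matrix(0, 30, 30)
    prob[random_mask(30, 30, p = 0.4, seed = 200 + s)] <- 1
    map <- make_map_with_mask(prob)
    tips <- extract_tips(map, "root_tip", 0.5, iterations = 1)
    # oracle: render at pixel resolution, erode by definition, label with
    # the independent graph labelling, average member pixel coordinates
    px <- (prob > 0.5)[rep(1:30, each = 4), rep(1:30, each = 4)]
    eroded <- erode_oracle(px, 1)
    mem <- components_oracle(eroded)
    if (length(mem) == 0L) {
      expect_equal(nrow(tips), 0L)
      next
    }
    idx <- which(eroded, arr.ind = TRUE)
    want_x <- sort(16 + as.numeric(tapply(idx[, 2], mem, mean)) - 2.5)
    want_y <- sort(16 + as.numeric(tapply(idx[, 1], mem, mean)) - 2.5)
    expect_equal(nrow(tips), max(mem))
    expect_equal(sort(tips$x), want_x, tolerance = 1e-9)
    expect_equal(sort(tips$y), want_y, tolerance = 1e-9)
  }
})

test_that("erosion cannot create tips from compact isolated regions", {
  # for isolated convex blobs (no bridges for erosion to cut), the tip
  # count is bounded by the component count of the un-eroded mask
  prob <- matrix(0, 30, 30)
  prob[3:9, 3:9] <- 1
  prob[15:22, 14:21] <- 1
  prob[25:28, 4:8] <- 1
  map <- make_map_with_mask(prob)
  n_comp <- max(components_oracle(prob > 0.5))
  for (it in 1:3) {
    expect_lte(nrow(extract_tips(map, "root_tip", 0.5, iterations = it)),
               n_comp)
  }
})

test_that("tip sets round-trip through CSV", {
  tips <- tibble::tibble(
    image_id = c("a", "a", "b"), x = c(1.5, 20, 3), y = c(2, 8.25, 9),
    source = "detector"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_tips(tips, path)
  expect_equal(as.data.frame(read_tips(path)), as.data.frame(tips))
})
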