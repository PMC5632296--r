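make_root_img <- function(ann, h = 160, w = 160, polylines = NULL, seed = 1) {
  r <- withr::with_seed(seed, array(round(runif(h * w * 3, 0, 255)),
                                    dim = c(h, w, 3)))
  annotated_image("img", r, ann, polylines = polylines)
}

test_that("positive patches are centred crops of the storage size", {
  cfg <- dataset_config("root")
  ann <- tibble::tibble(
    feature_class = "root_tip", x = c(60, 80, 100), y = c(50, 90, 120),
    root_length = c(40, 30, 25)
  )
  img <- make_root_img(ann)
  pos <- extract_positive_patches(img, cfg)
  expect_equal(nrow(pos), 3L)
  for (i in 1:3) {
    p <- pos$patch[[i]]
    expect_equal(dim(p), c(42L, 42L, 3L))
    # the annotation pixel sits at the crop's centre index floor(42/2) = 21
    expect_equal(p[22, 22, ], img$raster[ann$y[i] + 1, ann$x[i] + 1, ])
  }
  expect_equal(pos$x, ann$x)
  expect_equal(pos$y, ann$y)
})

test_that("root tips at or below the 16-px length floor are excluded", {
  cfg <- dataset_config("root")
  ann <- tibble::tibble(
    feature_class = "root_tip", x = c(60, 80, 100, 120), y = rep(80, 4),
    root_length = c(10, 16, 16.5, NA)
  )
  pos <- extract_positive_patches(make_root_img(ann), cfg)
  # 10 and exactly 16 are dropped; 16.5 passes; NA (unknown) is kept
  expect_equal(pos$x, c(100, 120))
})

test_that("border crops are completed by edge replication", {
  cfg <- dataset_config("root")
  ann <- tibble::tibble(feature_class = "root_tip", x = 0, y = 0,
                        root_length = 40)
  pos <- extract_positive_patches(make_root_img(ann), cfg)
  expect_equal(dim(pos$patch[[1]]), c(42L, 42L, 3L))
  # replicated rows: everything above/left of the corner repeats pixel (0,0)
  expect_true(all(pos$patch[[1]][1:22, 1, 1] == pos$patch[[1]][22, 1, 1]))
})

test_that("root negatives split half on-root, half random, all outside the exclusion radius", {
  img <- generate_root_image(root_scene_params(seed = 12))
  cfg <- dataset_config("root")
  ann_xy <- cbind(img$annotations$x, img$annotations$y)
  dense <- do.call(rbind, lapply(img$polylines, tipscan:::resample_polyline,
                                 step = 0.25))
  withr::with_seed(1, {
    neg <- mine_negatives_root(img, 10, cfg)
    expect_equal(nrow(neg), 10L)
    expect_true(all(neg$label == "root_negative"))
    # every centre farther than window/2 from every tip annotation
    for (i in seq_len(nrow(neg))) {
      expect_gt(min(sqrt((ann_xy[, 1] - neg$x[i])^2 +
                           (ann_xy[, 2] - neg$y[i])^2)), 16)
    }
    # the first ceiling(n/2) are the on-root half: within the stroke width
    for (i in 1:5) {
      d <- min(sqrt((dense[, 1] - neg$x[i])^2 + (dense[, 2] - neg$y[i])^2))
      expect_lte(d, 2)
    }
  })
})

test_that("on-root mining without polylines is an error", {
  ann <- tibble::tibble(feature_class = "root_tip", x = 60, y = 60,
                        root_length = 40)
  img <- make_root_img(ann)
  expect_error(mine_negatives_root(img, 4, dataset_config("root")),
               "polylines")
})

test_that("negative centres respect the exclusion radius across many draws", {
  img <- generate_root_image(root_scene_params(seed = 13))
  cfg <- dataset_config("root")
  ann_xy <- cbind(img$annotations$x, img$annotations$y)
  for (s in 1:100) {
    neg <- withr::with_seed(s, mine_negatives_root(img, 6, cfg))
    dmin <- vapply(seq_len(nrow(neg)), function(i) {
      min(sqrt((ann_xy[, 1] - neg$x[i])^2 + (ann_xy[, 2] - neg$y[i])^2))
    }, numeric(1))
    expect_true(all(dmin > cfg$exclusion_radius))
  }
})

test_that("a blank image yields no Harris candidates and random shoot negatives", {
  img <- annotated_image("blank", array(128, dim = c(256, 256, 3)))
  expect_equal(nrow(harris_corners(img$raster)), 0L)
  cfg <- dataset_config("shoot")
  neg <- withr::with_seed(2, suppressMessages(
    mine_negatives_shoot(img, 6, cfg)
  ))
  expect_equal(nrow(neg), 6L)
  expect_true(all(neg$label == "shoot_negative"))
})

test_that("Harris candidates coincide with response maxima at rectangle corners", {
  r <- array(0, dim = c(200, 200, 3))
  r[61:141, 51:151, ] <- 255
  cand <- harris_corners(r)
  corners <- rbind(c(50, 60), c(150, 60), c(50, 140), c(150, 140))
  # the four strongest candidates sit at the four rectangle corners
  top <- cand[1:4, ]
  for (k in 1:4) {
    d <- sqrt((top$x - corners[k, 1])^2 + (top$y - corners[k, 2])^2)
    expect_lte(min(d), 3)
  }
  # oracle: recompute the Harris response by direct convolution and check
  # the package's candidate locations are local maxima of it
  gray <- r[, , 1] / 255
  shift <- function(m, dy, dx) {
    H <- nrow(m); W <- ncol(m)
    ys <- pmin(pmax(seq_len(H) + dy, 1), H)
    xs <- pmin(pmax(seq_len(W) + dx, 1), W)
    m[ys, xs]
  }
  ix <- (shift(gray, 0, 1) - shift(gray, 0, -1)) / 2
  iy <- (shift(gray, 1, 0) - shift(gray, -1, 0)) / 2
  g1 <- stats::dnorm(-5:5, sd = 1.5)
  gk <- outer(g1, g1); gk <- gk / sum(gk)
  conv <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (dy in -5:5) for (dx in -5:5) {
      out <- out + gk[dy + 6, dx + 6] * shift(m, dy, dx)
    }
    out
  }
  ixx <- conv(ix * ix); iyy <- conv(iy * iy); ixy <- conv(ix * iy)
  resp <- ixx * iyy - ixy^2 - 0.04 * (ixx + iyy)^2
  strong <- which(resp > 0.5 * max(resp), arr.ind = TRUE)
  oracle_xy <- cbind(x = strong[, 2] - 1, y = strong[, 1] - 1)
  for (k in 1:4) {
    d <- sqrt((oracle_xy[, 1] - top$x[k])^2 + (oracle_xy[, 2] - top$y[k])^2)
    expect_lte(min(d), 2)
  }
})

test_that("shoot negatives avoid annotated features", {
  img <- generate_shoot_image(small_shoot_params(seed = 3))
  cfg <- dataset_config("shoot")
  ann_xy <- cbind(img$annotations$x, img$annotations$y)
  for (s in 1:30) {
    neg <- withr::with_seed(s, suppressMessages(
      mine_negatives_shoot(img, 8, cfg)
    ))
    dmin <- vapply(seq_len(nrow(neg)), function(i) {
      min(sqrt((ann_xy[, 1] - neg$x[i])^2 + (ann_xy[, 2] - neg$y[i])^2))
    }, numeric(1))
    expect_true(all(dmin > cfg$exclusion_radius))
  }
})

test_that("the 80/20 split reproduces the published cardinalities", {
  cfg <- dataset_config("root", rng_seed = 4)
  big <- tibble::tibble(i = seq_len(43641))
  sp <- split_dataset(big, cfg)
  expect_equal(nrow(sp$train), 34912L)
  expect_equal(nrow(sp$val), 8729L)
  sp2 <- split_dataset(tibble::tibble(i = seq_len(62118)), cfg)
  expect_equal(nrow(sp2$train), 49694L)
  expect_equal(nrow(sp2$val), 12424L)
})

test_that("splits are disjoint, exhaustive and reproducible", {
  cfg <- dataset_config("root", rng_seed = 9)
  sp <- split_dataset(tibble::tibble(i = 1:10), cfg)
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$val), 2L)
  expect_length(intersect(sp$train$i, sp$val$i), 0L)
  expect_setequal(c(sp$train$i, sp$val$i), 1:10)
  sp2 <- split_dataset(tibble::tibble(i = 1:10), cfg)
  expect_identical(sp$train$i, sp2$train$i)
  expect_error(split_dataset(tibble::tibble(), cfg), "empty")
})

test_that("mean colour equals the flat per-channel pixel average", {
  grey <- list(array(100, dim = c(4, 4, 3)))
  expect_equal(unname(compute_mean_color(grey)), c(100, 100, 100))
  two <- list(array(0, dim = c(4, 4, 3)), array(200, dim = c(4, 4, 3)))
  expect_equal(unname(compute_mean_color(two)), c(100, 100, 100))
  rnd <- withr::with_seed(8, lapply(1:5, function(i) {
    array(runif(42 * 42 * 3, 0, 255), dim = c(42, 42, 3))
  }))
  oracle <- vapply(1:3, function(ch) {
    mean(unlist(lapply(rnd, function(p) p[, , ch])))
  }, numeric(1))
  expect_equal(unname(compute_mean_color(rnd)), oracle, tolerance = 1e-12)
  expect_error(compute_mean_color(list()), "empty")
})

test_that("root augmentation draws offsets uniformly from the 11x11 grid", {
  cfg <- dataset_config("root")
  # encode the offset in the patch: top-left value reveals (ox, oy)
  coded <- array(0, dim = c(42, 42, 3))
  coded[, , 1] <- outer(0:41, 0:41, function(y, x) y * 42 + x)
  crop0 <- augment_for_training(coded, cfg, offset = c(0, 0))
  expect_equal(crop0, coded[1:32, 1:32, , drop = FALSE])
  counts <- withr::with_seed(10, {
    tab <- matrix(0L, 11, 11)
    for (i in 1:10000) {
      cr <- augment_for_training(coded, cfg)
      v <- cr[1, 1, 1]
      tab[v %/% 42 + 1, v %% 42 + 1] <- tab[v %/% 42 + 1, v %% 42 + 1] + 1L
    }
    tab
  })
  expect_equal(sum(counts), 10000L)
  chi <- stats::chisq.test(as.vector(counts))
  expect_gt(chi$p.value, 0.001)
})

test_that("shoot augmentation is an area-weighted 2x downscale", {
  cfg <- dataset_config("shoot")
  solid <- array(123, dim = c(128, 128, 3))
  down <- augment_for_training(solid, cfg)
  expect_equal(dim(down), c(64L, 64L, 3L))
  expect_true(all(down == 123))
  rnd <- withr::with_seed(3, array(runif(128 * 128 * 3), dim = c(128, 128, 3)))
  down2 <- augment_for_training(rnd, cfg)
  # oracle: mean over each 2x2 block
  for (probe in list(c(1, 1), c(10, 33), c(64, 64))) {
    i <- probe[1]; j <- probe[2]
    expect_equal(down2[i, j, 2],
                 mean(rnd[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), 2]),
                 tolerance = 1e-12)
  }
  expect_error(augment_for_training(solid[1:100, 1:100, ], cfg), "storage_crop")
})

test_that("the assembled dataset keeps the configured class balance", {
  imgs <- lapply(1:2, function(i) {
    generate_root_image(small_root_params(seed = 40 + i))
  })
  cfg <- dataset_config("root", rng_seed = 2)
  ds <- build_patch_dataset(imgs, cfg)
  n_pos <- sum(ds$label == "root_tip")
  n_neg <- sum(ds$label == "root_negative")
  expect_gt(n_pos, 0)
  expect_equal(n_neg, 2L * n_pos)
})
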