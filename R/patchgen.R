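# Building balanced patch-classification datasets from annotated images:
# positives centred on annotations, hard negatives mined on the root system
# (roots) or at Harris corner candidates (shoots), plus truly random
# negatives. Patches are stored larger than the network window (42 px for a
# 32-px window) so a random sub-crop can jitter the feature off-centre
# during training.

#' Dataset construction parameters
#'
#' Defaults follow the published protocol for each domain: a 32-px window
#' stored as 42-px crops with two negatives per positive for roots; a 64-px
#' window stored as 128-px crops (downscaled 2x at training time) with one
#' hard negative per positive plus a 10% top-up of truly random negatives
#' for shoots. Tips whose bearing root is 16 px or shorter are excluded in
#' the root domain to avoid root-hair ambiguity.
#'
#' @param domain `"root"` or `"shoot"`.
#' @param window_size Classifier input side in pixels.
#' @param storage_crop Stored crop side in pixels (`>= window_size`).
#' @param min_root_length Root-length floor in pixels; root tips with
#'   `root_length <= min_root_length` are not used as positives.
#' @param negative_ratio Negatives mined per positive.
#' @param split_fraction Fraction of samples assigned to the training set.
#' @param exclusion_radius Minimum distance (px) from any annotation for a
#'   negative-patch centre; defaults to `window_size / 2`, the same radius
#'   used when scoring localization.
#' @param shoot_random_fraction Fraction of shoot negatives drawn at truly
#'   random positions rather than at Harris candidates.
#' @param rng_seed Seed for the split shuffle and any sampling.
#' @return A `dataset_config` list.
#' @export
dataset_config <- function(domain = c("root", "shoot"),
                           window_size = NULL, storage_crop = NULL,
                           min_root_length = 16,
                           negative_ratio = NULL, split_fraction = 0.8,
                           exclusion_radius = NULL,
                           shoot_random_fraction = 0.1, rng_seed = 1L) {
  domain <- match.arg(domain)
  window_size <- window_size %||% if (domain == "root") 32L else 64L
  storage_crop <- storage_crop %||% if (domain == "root") 42L else 128L
  negative_ratio <- negative_ratio %||% if (domain == "root") 2 else 1
  exclusion_radius <- exclusion_radius %||% (window_size / 2)
  if (storage_crop < window_size) abort("storage_crop must be >= window_size")
  if (split_fraction <= 0 || split_fraction >= 1) {
    abort("split_fraction must be in (0, 1)")
  }
  structure(
    list(
      domain = domain, window_size = as.integer(window_size),
      storage_crop = as.integer(storage_crop),
      min_root_length = min_root_length, negative_ratio = negative_ratio,
      split_fraction = split_fraction, exclusion_radius = exclusion_radius,
      shoot_random_fraction = shoot_random_fraction,
      rng_seed = as.integer(rng_seed)
    ),
    class = "dataset_config"
  )
}

new_patch_tibble <- function(patches, labels, image_id, x, y) {
  tibble(
    patch = patches, label = labels,
    source_image_id = image_id, x = as.numeric(x), y = as.numeric(y)
  )
}

#' Extract positive patches centred on annotations
#'
#' One `storage_crop`-sized patch per qualifying annotation, centred on the
#' annotated pixel. In the root domain, tips whose `root_length` is at or
#' below `min_root_length` are skipped. Crops overhanging the image border
#' are completed by edge replication so every patch is full size.
#'
#' @param img An [annotated_image()].
#' @param cfg A [dataset_config()].
#' @return Tibble with list-column `patch` (arrays `side x side x 3`),
#'   `label`, `source_image_id`, and the crop-centre coordinates `x`, `y`.
#' @export
extract_positive_patches <- function(img, cfg) {
  stopifnot(inherits(img, "annotated_image"), inherits(cfg, "dataset_config"))
  ann <- img$annotations
  if (cfg$domain == "root") {
    keep <- is.na(ann$root_length) | ann$root_length > cfg$min_root_length
    ann <- ann[keep, ]
  }
  if (nrow(ann) == 0L) {
    return(new_patch_tibble(list(), character(), character(), numeric(), numeric()))
  }
  patches <- lapply(seq_len(nrow(ann)), function(i) {
    crop_patch(img$raster, ann$x[i], ann$y[i], cfg$storage_crop)
  })
  new_patch_tibble(patches, ann$feature_class, img$image_id, ann$x, ann$y)
}

negative_label <- function(domain) {
  if (domain == "root") "root_negative" else "shoot_negative"
}

# Rejection-sample candidate centres: keep those farther than the exclusion
# radius from every annotation and inside the canvas.
filter_excluded <- function(cand, ann_xy, radius) {
  if (nrow(cand) == 0L) return(cand)
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    min_dist_to_points(cand[i, 1L], cand[i, 2L], ann_xy) > radius
  }, logical(1L))
  cand[ok, , drop = FALSE]
}

#' Mine negative patches for the root domain
#'
#' Half of the requested negatives (the ceiling) are hard negatives centred
#' on points sampled arc-length-uniformly along the known root polylines;
#' the remainder are drawn at uniform random image positions. Every centre
#' is kept farther than `cfg$exclusion_radius` from every tip annotation.
#' If the image cannot supply `n` valid centres within a bounded number of
#' attempts, fewer are returned with a warning.
#'
#' @param img An [annotated_image()] with polylines.
#' @param n Number of negatives requested.
#' @param cfg A [dataset_config()].
#' @return Patch tibble as in [extract_positive_patches()], labels
#'   `root_negative`.
#' @export
mine_negatives_root <- function(img, n, cfg) {
  stopifnot(inherits(img, "annotated_image"))
  if (n <= 0L) {
    return(new_patch_tibble(list(), character(), character(), numeric(), numeric()))
  }
  if (is.null(img$polylines) || length(img$polylines) == 0L) {
    abort(sprintf("image '%s': on-root negative mining needs polylines", img$image_id))
  }
  d <- dim(img$raster)
  ann_xy <- as_xy_matrix(img$annotations[, c("x", "y")])
  n_on <- ceiling(n / 2)
  n_rand <- floor(n / 2)

  seg_pts <- do.call(rbind, lapply(img$polylines, resample_polyline, step = 1))
  sample_on_root <- function(k) {
    idx <- sample.int(nrow(seg_pts), k, replace = TRUE)
    round(seg_pts[idx, , drop = FALSE])
  }
  sample_random <- function(k) {
    cbind(
      x = sample.int(d[2L], k, replace = TRUE) - 1L,
      y = sample.int(d[1L], k, replace = TRUE) - 1L
    )
  }
  draw <- function(sampler, need) {
    out <- matrix(numeric(0), ncol = 2L)
    attempts <- 0L
    while (nrow(out) < need && attempts < 60L) {
      cand <- filter_excluded(sampler(2L * need), ann_xy, cfg$exclusion_radius)
      out <- rbind(out, cand)
      attempts <- attempts + 1L
    }
    out[seq_len(min(need, nrow(out))), , drop = FALSE]
  }
  on_pts <- draw(sample_on_root, n_on)
  rand_pts <- draw(sample_random, n_rand)
  got <- nrow(on_pts) + nrow(rand_pts)
  if (got < n) {
    warn(sprintf(
      "image '%s': only %d of %d requested negatives could be placed",
      img$image_id, got, n
    ))
  }
  centres <- rbind(on_pts, rand_pts)
  patches <- lapply(seq_len(nrow(centres)), function(i) {
    crop_patch(img$raster, centres[i, 1L], centres[i, 2L], cfg$storage_crop)
  })
  new_patch_tibble(patches, rep(negative_label(cfg$domain), nrow(centres)),
                   img$image_id, centres[, 1L], centres[, 2L])
}

#' Harris corner candidates
#'
#' Standard Harris response: image gradients by central differences, the
#' structure tensor smoothed with a Gaussian window, response
#' `det(M) - k tr(M)^2`, candidates at 8-neighbourhood local maxima above
#' `threshold_rel` times the maximum response.
#'
#' @param raster `c(H, W, 3)` array (converted to grayscale internally) or a
#'   matrix.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param k Harris sensitivity constant.
#' @param threshold_rel Relative response threshold in `(0, 1)`.
#' @return Tibble `x`, `y` (0-based), `response`, ordered by decreasing
#'   response; zero rows when the image has no corners.
#' @export
harris_corners <- function(raster, sigma = 1.5, k = 0.04, threshold_rel = 0.01) {
  gray <- if (length(dim(raster)) == 3L) {
    (raster[, , 1L] + raster[, , 2L] + raster[, , 3L]) / 3
  } else {
    raster
  }
  gray <- gray / 255
  # matrix rows are y, columns are x: a 1x3 kernel differentiates along x
  ix <- EBImage::filter2(gray, matrix(c(-0.5, 0, 0.5), nrow = 1L), boundary = "replicate")
  iy <- EBImage::filter2(gray, matrix(c(-0.5, 0, 0.5), ncol = 1L), boundary = "replicate")
  bsize <- 2L * ceiling(3 * sigma) + 1L
  gk <- EBImage::makeBrush(bsize, shape = "gaussian", sigma = sigma)
  sm <- function(m) EBImage::filter2(m, gk, boundary = "replicate")
  ixx <- sm(ix * ix); iyy <- sm(iy * iy); ixy <- sm(ix * iy)
  resp <- ixx * iyy - ixy^2 - k * (ixx + iyy)^2
  mx <- max(resp)
  # absolute floor: numerically flat images have no corners, only FFT noise
  if (!is.finite(mx) || mx <= 1e-8) {
    return(tibble(x = double(), y = double(), response = double()))
  }
  H <- nrow(resp); W <- ncol(resp)
  is_max <- resp > threshold_rel * mx
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- resp
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- pad[(2:(H + 1L)) + dy, (2:(W + 1L)) + dx]
    is_max <- is_max & resp >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  out <- tibble(
    x = as.numeric(idx[, 2L] - 1L), y = as.numeric(idx[, 1L] - 1L),
    response = resp[idx]
  )
  dplyr::arrange(out, dplyr::desc(.data$response))
}

#' Mine negative patches for the shoot domain
#'
#' Hard negatives are centred on Harris corner candidates (excluding a
#' radius around every annotation) so that clutter and plant material are
#' well represented; a configurable small fraction
#' (`cfg$shoot_random_fraction`) is drawn from truly random positions so
#' plain background is represented too. If fewer valid Harris candidates
#' exist than requested, the deficit falls back to random positions with a
#' message.
#'
#' @inheritParams mine_negatives_root
#' @return Patch tibble with labels `shoot_negative`.
#' @export
mine_negatives_shoot <- function(img, n, cfg) {
  stopifnot(inherits(img, "annotated_image"))
  if (n <= 0L) {
    return(new_patch_tibble(list(), character(), character(), numeric(), numeric()))
  }
  d <- dim(img$raster)
  ann_xy <- as_xy_matrix(img$annotations[, c("x", "y")])
  n_rand <- round(n * cfg$shoot_random_fraction)
  n_hard <- n - n_rand
  cand <- harris_corners(img$raster)
  cand_xy <- filter_excluded(as_xy_matrix(cand[, c("x", "y")]), ann_xy,
                             cfg$exclusion_radius)
  if (nrow(cand_xy) < n_hard) {
    inform(sprintf(
      "image '%s': %d Harris candidates for %d hard negatives; filling with random positions",
      img$image_id, nrow(cand_xy), n_hard
    ))
    n_rand <- n - nrow(cand_xy)
    n_hard <- nrow(cand_xy)
  }
  hard_pts <- if (n_hard > 0L) {
    cand_xy[sample.int(nrow(cand_xy), n_hard), , drop = FALSE]
  } else {
    matrix(numeric(0), ncol = 2L)
  }
  rand_pts <- matrix(numeric(0), ncol = 2L)
  attempts <- 0L
  while (nrow(rand_pts) < n_rand && attempts < 60L) {
    cand_r <- cbind(
      x = sample.int(d[2L], 2L * n_rand, replace = TRUE) - 1L,
      y = sample.int(d[1L], 2L * n_rand, replace = TRUE) - 1L
    )
    rand_pts <- rbind(rand_pts, filter_excluded(cand_r, ann_xy, cfg$exclusion_radius))
    attempts <- attempts + 1L
  }
  rand_pts <- rand_pts[seq_len(min(n_rand, nrow(rand_pts))), , drop = FALSE]
  centres <- rbind(hard_pts, rand_pts)
  patches <- lapply(seq_len(nrow(centres)), function(i) {
    crop_patch(img$raster, centres[i, 1L], centres[i, 2L], cfg$storage_crop)
  })
  new_patch_tibble(patches, rep(negative_label(cfg$domain), nrow(centres)),
                   img$image_id, centres[, 1L], centres[, 2L])
}

#' Split a patch dataset into training and validation sets
#'
#' A seeded random shuffle assigns `floor(split_fraction * N)` samples to
#' the training set and the remainder to validation; the two are disjoint
#' and together exhaust the input.
#'
#' @param samples Tibble (or data frame) of samples, one row each.
#' @param cfg A [dataset_config()] supplying `split_fraction` and `rng_seed`.
#' @return List with elements `train` and `val`.
#' @export
split_dataset <- function(samples, cfg) {
  n <- nrow(samples)
  if (is.null(n) || n == 0L) abort("cannot split an empty sample set")
  n_train <- floor(cfg$split_fraction * n)
  perm <- withr::with_seed(cfg$rng_seed, sample.int(n))
  list(
    train = samples[perm[seq_len(n_train)], , drop = FALSE],
    val = samples[perm[seq.int(n_train + 1L, length.out = n - n_train)], ,
                  drop = FALSE]
  )
}

#' Mean colour of a training set
#'
#' Per-channel mean over every pixel of every training patch; subtracted
#' from inputs before they enter the network so pixel values are centred
#' around zero.
#'
#' @param train Patch tibble (or a list of patch arrays).
#' @return Numeric `c(r, g, b)` on the 0..255 scale.
#' @export
compute_mean_color <- function(train) {
  patches <- if (is.data.frame(train)) train$patch else train
  if (length(patches) == 0L) abort("cannot compute the mean colour of an empty set")
  sums <- c(0, 0, 0)
  npix <- 0
  for (p in patches) {
    sums <- sums + c(sum(p[, , 1L]), sum(p[, , 2L]), sum(p[, , 3L]))
    npix <- npix + prod(dim(p)[1:2])
  }
  stats::setNames(sums / npix, c("r", "g", "b"))
}

#' Reduce a stored patch to the network window
#'
#' Root domain: a uniformly random `window_size` sub-crop of the stored
#' crop (offsets drawn from `0..(storage_crop - window_size)` on each axis)
#' — the training-time jitter augmentation. Shoot domain: deterministic 2x
#' area-weighted downscale (each output pixel the mean of a 2x2 block).
#' Uses the current RNG stream; seed the caller for reproducibility.
#'
#' @param patch Array `storage_crop x storage_crop x 3`.
#' @param cfg A [dataset_config()].
#' @param offset Optional integer `c(ox, oy)` forcing the root crop offset
#'   (mainly for tests); `NULL` draws it at random.
#' @return Array `window_size x window_size x 3`.
#' @export
augment_for_training <- function(patch, cfg, offset = NULL) {
  d <- dim(patch)
  if (d[1L] != cfg$storage_crop || d[2L] != cfg$storage_crop) {
    abort(sprintf(
      "patch side %dx%d does not match storage_crop %d",
      d[1L], d[2L], cfg$storage_crop
    ))
  }
  if (cfg$domain == "root") {
    span <- cfg$storage_crop - cfg$window_size
    if (is.null(offset)) {
      offset <- c(
        sample.int(span + 1L, 1L) - 1L,
        sample.int(span + 1L, 1L) - 1L
      )
    }
    patch[offset[2L] + seq_len(cfg$window_size),
          offset[1L] + seq_len(cfg$window_size), , drop = FALSE]
  } else {
    downscale_2x(patch, cfg$storage_crop %/% cfg$window_size)
  }
}

# Area-weighted integer-factor downscale: each output pixel is the mean of
# an f x f input block.
downscale_2x <- function(patch, f = 2L) {
  d <- dim(patch)
  ho <- d[1L] %/% f; wo <- d[2L] %/% f
  out <- array(0, dim = c(ho, wo, d[3L]))
  for (ch in seq_len(d[3L])) {
    m <- patch[seq_len(ho * f), seq_len(wo * f), ch]
    # average rows then columns in f-blocks
    m <- matrix(colMeans(matrix(m, nrow = f)), nrow = ho, ncol = wo * f,
                byrow = FALSE)
    m2 <- t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = wo, ncol = ho))
    out[, , ch] <- m2
  }
  out
}

#' Build the full patch dataset for a set of images
#'
#' Convenience wrapper: positives from every image, then per image the
#' configured number of negatives (`negative_ratio` x its positive count),
#' mined by the domain's strategy.
#'
#' @param images List of [annotated_image()] records.
#' @param cfg A [dataset_config()].
#' @return Patch tibble combining positives and negatives.
#' @export
build_patch_dataset <- function(images, cfg) {
  withr::with_seed(cfg$rng_seed, {
    parts <- lapply(images, function(img) {
      pos <- extract_positive_patches(img, cfg)
      n_neg <- round(cfg$negative_ratio * nrow(pos))
      neg <- if (cfg$domain == "root") {
        mine_negatives_root(img, n_neg, cfg)
      } else {
        mine_negatives_shoot(img, n_neg, cfg)
      }
      dplyr::bind_rows(pos, neg)
    })
    dplyr::bind_rows(parts)
  })
}
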