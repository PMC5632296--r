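# Synthetic annotated scenes with exact ground truth. Root scenes emulate
# washed seedling root systems photographed against a light pouch: dark,
# slightly curved primaries growing downward from a source point near the
# top, with laterals branching off. Shoot scenes emulate studio turntable
# images: leaf and ear strokes over a cluttered background of bars and blobs.

#' Parameters for a synthetic root scene
#'
#' @param image_width,image_height Canvas size in pixels; at least 4x the
#'   root classification window (128 px).
#' @param n_primary Number of primary roots.
#' @param laterals_per_primary Lateral count per primary: a single count or
#'   an inclusive `c(min, max)` range sampled per primary.
#' @param primary_length,lateral_length Arc-length ranges `c(min, max)` in
#'   pixels from which each root's target length is drawn.
#' @param root_half_width Stroke half-width in pixels.
#' @param curvature Dimensionless heading-jitter scale; 0 gives straight
#'   roots.
#' @param background_noise_sd Gaussian intensity noise of the background,
#'   on the 0..255 scale.
#' @param min_annotated_length Laterals whose drawn arc length is at or
#'   below this floor are drawn but not annotated, mimicking root-hair-like
#'   ambiguity (default 16 px, half the classification window).
#' @param min_tip_separation Target minimum distance (px) between annotated
#'   tips: a root whose tip would land closer than this to an existing tip
#'   is redrawn (bounded retries, so the separation is strongly encouraged
#'   rather than guaranteed). 0 disables the constraint. Use this to build
#'   well-separated-tip scenes for detector evaluation.
#' @param tip_clearance Target minimum distance (px) between a tip and any
#'   *other* root's path: redraws roots whose tip would overlap another
#'   root, or whose path would run over an existing tip (bounded retries).
#'   0 disables it. Occluded tips — tips lying on another root — are
#'   visually ambiguous crossings, so clean evaluation scenes exclude them.
#' @param seed RNG seed; identical parameters and seed reproduce the scene
#'   bit for bit.
#' @return A `root_scene_params` list.
#' @export
root_scene_params <- function(image_width = 256, image_height = 256,
                              n_primary = 5, laterals_per_primary = c(4, 7),
                              primary_length = c(130, 200),
                              lateral_length = c(20, 60),
                              root_half_width = 2, curvature = 0.12,
                              background_noise_sd = 4,
                              min_annotated_length = 16,
                              min_tip_separation = 0, tip_clearance = 0,
                              seed = 1L) {
  p <- list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    n_primary = as.integer(n_primary),
    laterals_per_primary = as.integer(rep(laterals_per_primary, length.out = 2L)),
    primary_length = rep(primary_length, length.out = 2L),
    lateral_length = rep(lateral_length, length.out = 2L),
    root_half_width = root_half_width, curvature = curvature,
    background_noise_sd = background_noise_sd,
    min_annotated_length = min_annotated_length,
    min_tip_separation = min_tip_separation, tip_clearance = tip_clearance,
    seed = as.integer(seed)
  )
  if (p$image_width < 128L || p$image_height < 128L) {
    abort("root scene canvas must be at least 128x128 (4x the 32-px window)")
  }
  if (p$n_primary < 0L || any(p$laterals_per_primary < 0L)) {
    abort("root/lateral counts must be >= 0")
  }
  if (any(p$primary_length <= 0) || any(p$lateral_length <= 0)) {
    abort("root lengths must be > 0")
  }
  structure(p, class = "root_scene_params")
}

#' Parameters for a synthetic shoot scene
#'
#' @param image_width,image_height Canvas size; at least 4x the shoot
#'   classification window (256 px).
#' @param n_leaves,n_ears Number of leaves / ears, each contributing a tip
#'   and a base annotation.
#' @param stroke_half_width Leaf stroke half-width in pixels.
#' @param clutter_density Unannotated distractor objects (bars, blobs) per
#'   megapixel.
#' @param seed RNG seed.
#' @return A `shoot_scene_params` list.
#' @export
shoot_scene_params <- function(image_width = 320, image_height = 320,
                               n_leaves = 4, n_ears = 1,
                               stroke_half_width = 2, clutter_density = 40,
                               seed = 1L) {
  p <- list(
    image_width = as.integer(image_width), image_height = as.integer(image_height),
    n_leaves = as.integer(n_leaves), n_ears = as.integer(n_ears),
    stroke_half_width = stroke_half_width, clutter_density = clutter_density,
    seed = as.integer(seed)
  )
  if (p$image_width < 256L || p$image_height < 256L) {
    abort("shoot scene canvas must be at least 256x256 (4x the 64-px window)")
  }
  if (p$n_leaves < 0L || p$n_ears < 0L || p$clutter_density < 0) {
    abort("counts and clutter_density must be >= 0")
  }
  structure(p, class = "shoot_scene_params")
}

# Resample a polyline at roughly `step`-pixel spacing for stroke stamping.
resample_polyline <- function(pts, step = 0.6) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(pts[1L, , drop = FALSE])
  s <- seq(0, total, by = step)
  cbind(
    x = stats::approx(cum, pts[, 1L], xout = s)$y,
    y = stats::approx(cum, pts[, 2L], xout = s)$y
  )
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2 + 1e-9, , drop = FALSE]
}

# Stamp a soft-edged stroke of the given colour along a polyline.
# Coordinates are 0-based; writes in place semantics via return value.
draw_stroke <- function(raster, pts, half_width, color) {
  d <- dim(raster)
  dense <- resample_polyline(pts)
  stamp <- function(raster, offs, blend) {
    xx <- as.vector(outer(round(dense[, 1L]), offs$dx, "+"))
    yy <- as.vector(outer(round(dense[, 2L]), offs$dy, "+"))
    ok <- xx >= 0 & xx < d[2L] & yy >= 0 & yy < d[1L]
    lin <- unique((xx[ok]) * d[1L] + yy[ok] + 1)
    for (ch in 1:3) {
      li <- lin + (ch - 1L) * d[1L] * d[2L]
      raster[li] <- (1 - blend) * raster[li] + blend * color[ch]
    }
    raster
  }
  raster <- stamp(raster, disc_offsets(half_width + 1), 0.45)
  stamp(raster, disc_offsets(half_width), 1)
}

# Grow a jittered trajectory from (x0, y0) with initial heading `angle`
# (radians, 0 = rightward, pi/2 = downward), mean-reverting to `bias_angle`.
grow_root <- function(x0, y0, angle, target_length, curvature, bias_angle,
                      width, height, step = 3, margin = 3) {
  n_steps <- max(2L, ceiling(target_length / step))
  pts <- matrix(NA_real_, n_steps + 1L, 2L)
  pts[1L, ] <- c(x0, y0)
  a <- angle
  len <- 0
  k <- 1L
  for (i in seq_len(n_steps)) {
    a <- a + stats::rnorm(1L, 0, curvature) + 0.08 * (bias_angle - a)
    nx <- pts[k, 1L] + step * cos(a)
    ny <- pts[k, 2L] + step * sin(a)
    if (nx < margin || nx > width - 1 - margin ||
        ny < margin || ny > height - 1 - margin) break
    k <- k + 1L
    pts[k, ] <- c(nx, ny)
    len <- len + step
    if (len >= target_length) break
  }
  pts[seq_len(k), , drop = FALSE]
}

#' Generate a synthetic annotated root-system image
#'
#' Draws `n_primary` primaries growing downward from a top-centre source
#' point with laterals branching at random arc positions, over a light noisy
#' background. Every drawn root is returned as a polyline; a `root_tip`
#' annotation is recorded at the endpoint of each primary and of each
#' lateral whose drawn arc length exceeds `min_annotated_length` (shorter
#' laterals are drawn unannotated, the deliberate root-hair analogue). The
#' source point is stored as `seed_position`.
#'
#' @param params A [root_scene_params()] object.
#' @return An [annotated_image()] with annotations, polylines and
#'   `seed_position`; deterministic given `params` (including its seed).
#' @export
generate_root_image <- function(params) {
  stopifnot(inherits(params, "root_scene_params"))
  p <- params
  withr::with_seed(p$seed, {
    H <- p$image_height; W <- p$image_width
    raster <- blank_raster(H, W, 0)
    bg <- 225 + matrix(stats::rnorm(H * W, 0, p$background_noise_sd), H, W)
    for (ch in 1:3) raster[, , ch] <- bg
    seed_pos <- c(
      x = W / 2 + stats::runif(1L, -0.08, 0.08) * W,
      y = stats::runif(1L, 4, 10)
    )
    polylines <- list()
    ann <- list()
    tip_xy <- matrix(numeric(0), ncol = 2L)
    dense_all <- matrix(numeric(0), ncol = 2L)
    separated <- function(pts) {
      tip <- pts[nrow(pts), ]
      if (p$min_tip_separation > 0 &&
          min_dist_to_points(tip[1L], tip[2L], tip_xy) < p$min_tip_separation) {
        return(FALSE)
      }
      if (p$tip_clearance > 0) {
        # tip must clear every previously drawn root ...
        if (min_dist_to_points(tip[1L], tip[2L], dense_all) < p$tip_clearance) {
          return(FALSE)
        }
        # ... and the new path must not run over an existing tip
        if (nrow(tip_xy) > 0L) {
          dense <- resample_polyline(pts, step = 1)
          for (t in seq_len(nrow(tip_xy))) {
            if (min(sqrt((dense[, 1L] - tip_xy[t, 1L])^2 +
                           (dense[, 2L] - tip_xy[t, 2L])^2)) < p$tip_clearance) {
              return(FALSE)
            }
          }
        }
      }
      TRUE
    }
    note_drawn <- function(pts) {
      dense_all <<- rbind(dense_all, resample_polyline(pts, step = 2))
    }
    if (p$n_primary > 0L) {
      spread <- seq(-0.45, 0.45, length.out = max(p$n_primary, 2L))[seq_len(p$n_primary)]
      for (i in seq_len(p$n_primary)) {
        for (attempt in 1:40) {
          a0 <- pi / 2 + spread[i] + stats::rnorm(1L, 0, 0.08)
          tlen <- stats::runif(1L, p$primary_length[1L], p$primary_length[2L])
          pts <- grow_root(seed_pos[1L], seed_pos[2L], a0, tlen, p$curvature,
                           pi / 2, W, H)
          if (separated(pts)) break
        }
        col <- 60 + stats::runif(1L, -12, 12)
        raster <- draw_stroke(raster, pts, p$root_half_width, rep(col, 3L))
        polylines[[length(polylines) + 1L]] <- pts
        note_drawn(pts)
        plen <- polyline_length(pts)
        ann[[length(ann) + 1L]] <- tibble(
          feature_class = "root_tip",
          x = round(pts[nrow(pts), 1L]), y = round(pts[nrow(pts), 2L]),
          root_length = plen
        )
        tip_xy <- rbind(tip_xy, pts[nrow(pts), ])
        n_lat <- if (p$laterals_per_primary[1L] == p$laterals_per_primary[2L]) {
          p$laterals_per_primary[1L]
        } else {
          sample(p$laterals_per_primary[1L]:p$laterals_per_primary[2L], 1L)
        }
        if (n_lat > 0L && nrow(pts) > 3L) {
          seg <- sqrt(rowSums(diff(pts)^2))
          cum <- c(0, cumsum(seg))
          for (j in seq_len(n_lat)) {
            for (attempt in 1:40) {
              u <- stats::runif(1L, 0.15, 0.85) * plen
              k <- findInterval(u, cum)
              bx <- pts[k, 1L]; by <- pts[k, 2L]
              local_a <- atan2(pts[k + 1L, 2L] - pts[k, 2L],
                               pts[k + 1L, 1L] - pts[k, 1L])
              side <- sample(c(-1, 1), 1L)
              la <- local_a + side * stats::runif(1L, 0.7, 1.2)
              llen <- stats::runif(1L, p$lateral_length[1L], p$lateral_length[2L])
              lpts <- grow_root(bx, by, la, llen, p$curvature * 1.4,
                                la * 0.3 + (pi / 2) * 0.7, W, H, step = 2.5)
              if (separated(lpts)) break
            }
            lcol <- 70 + stats::runif(1L, -12, 12)
            raster <- draw_stroke(raster, lpts, max(p$root_half_width - 1, 1),
                                  rep(lcol, 3L))
            polylines[[length(polylines) + 1L]] <- lpts
            note_drawn(lpts)
            llen_drawn <- polyline_length(lpts)
            if (llen_drawn > p$min_annotated_length) {
              ann[[length(ann) + 1L]] <- tibble(
                feature_class = "root_tip",
                x = round(lpts[nrow(lpts), 1L]), y = round(lpts[nrow(lpts), 2L]),
                root_length = llen_drawn
              )
              tip_xy <- rbind(tip_xy, lpts[nrow(lpts), ])
            }
          }
        }
      }
    }
    raster <- round(clamp(raster, 0, 255))
    annotated_image(
      image_id = sprintf("root_scene_%010d", p$seed),
      raster = raster,
      annotations = if (length(ann) > 0L) dplyr::bind_rows(ann) else NULL,
      polylines = polylines,
      seed_position = unname(seed_pos)
    )
  })
}

#' Generate a synthetic annotated shoot image
#'
#' Leaves are curved strokes rising from a stem region near the bottom
#' centre (base annotated at the start, tip at the end); ears are thick
#' textured near-vertical strokes with `ear_base`/`ear_tip` annotations.
#' Clutter bars and blobs carry no annotations. Deterministic under the
#' parameter seed.
#'
#' @param params A [shoot_scene_params()] object.
#' @return An [annotated_image()] with the four shoot feature classes.
#' @export
generate_shoot_image <- function(params) {
  stopifnot(inherits(params, "shoot_scene_params"))
  p <- params
  withr::with_seed(p$seed, {
    H <- p$image_height; W <- p$image_width
    raster <- blank_raster(H, W, 0)
    bg <- 190 + matrix(stats::rnorm(H * W, 0, 6), H, W)
    for (ch in 1:3) raster[, , ch] <- bg
    margin <- 6
    n_clutter <- round(p$clutter_density * W * H / 1e6)
    for (i in seq_len(n_clutter)) {
      cx <- stats::runif(1L, margin, W - 1 - margin)
      cy <- stats::runif(1L, margin, H - 1 - margin)
      shade <- stats::runif(1L, 40, 160)
      if (stats::runif(1L) < 0.6) {
        a <- stats::runif(1L, 0, pi)
        len <- stats::runif(1L, 15, 60)
        ex <- clamp(cx + len * cos(a), margin, W - 1 - margin)
        ey <- clamp(cy + len * sin(a), margin, H - 1 - margin)
        raster <- draw_stroke(raster, rbind(c(cx, cy), c(ex, ey)),
                              stats::runif(1L, 1, 3), rep(shade, 3L))
      } else {
        raster <- draw_stroke(raster, rbind(c(cx, cy), c(cx + 0.5, cy)),
                              stats::runif(1L, 2, 6), rep(shade, 3L))
      }
    }
    ann <- list()
    stem_x <- W / 2
    for (i in seq_len(p$n_leaves)) {
      bx <- stem_x + stats::runif(1L, -0.06, 0.06) * W
      by <- stats::runif(1L, 0.7, 0.9) * (H - 1 - margin)
      a0 <- -pi / 2 + stats::runif(1L, -0.9, 0.9)
      tlen <- stats::runif(1L, 0.35, 0.6) * H
      pts <- grow_root(bx, by, a0, tlen, 0.08, a0 + stats::runif(1L, -0.3, 0.3),
                       W, H, step = 3, margin = margin)
      raster <- draw_stroke(raster, pts, p$stroke_half_width,
                            c(55, 110, 55) + stats::runif(1L, -15, 15))
      ann[[length(ann) + 1L]] <- tibble(
        feature_class = c("leaf_base", "leaf_tip"),
        x = round(c(pts[1L, 1L], pts[nrow(pts), 1L])),
        y = round(c(pts[1L, 2L], pts[nrow(pts), 2L])),
        root_length = NA_real_
      )
    }
    for (i in seq_len(p$n_ears)) {
      bx <- stem_x + stats::runif(1L, -0.2, 0.2) * W
      by <- stats::runif(1L, 0.35, 0.55) * H
      a0 <- -pi / 2 + stats::runif(1L, -0.25, 0.25)
      elen <- stats::runif(1L, 0.12, 0.2) * H
      pts <- grow_root(bx, by, a0, elen, 0.04, a0, W, H, step = 3, margin = margin)
      ecol <- c(150, 138, 78) + stats::runif(1L, -12, 12)
      raster <- draw_stroke(raster, pts, p$stroke_half_width * 2.2, ecol)
      dense <- resample_polyline(pts, step = 4)
      for (k in seq_len(nrow(dense))) {
        off <- stats::runif(2L, -2.5, 2.5)
        raster <- draw_stroke(
          raster,
          rbind(dense[k, ] + off, dense[k, ] + off + 0.5),
          p$stroke_half_width * 1.2, ecol * 0.82
        )
      }
      ann[[length(ann) + 1L]] <- tibble(
        feature_class = c("ear_base", "ear_tip"),
        x = round(c(pts[1L, 1L], pts[nrow(pts), 1L])),
        y = round(c(pts[1L, 2L], pts[nrow(pts), 2L])),
        root_length = NA_real_
      )
    }
    raster <- round(clamp(raster, 0, 255))
    annotated_image(
      image_id = sprintf("shoot_scene_%010d", p$seed),
      raster = raster,
      annotations = if (length(ann) > 0L) dplyr::bind_rows(ann) else NULL
    )
  })
}
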