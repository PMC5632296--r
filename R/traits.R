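# Root-system traits computed from detected tip coordinates alone. The
# seed (root-system origin) is estimated as the mid-point of the top edge
# of the bounding box around all tips; strip counts and total length are
# measured from that estimate.

#' Estimate the seed position from a tip set
#'
#' Mid-point of the top of the bounding box surrounding all tips:
#' `x = (min(x) + max(x)) / 2`, `y = min(y)` (y grows downward).
#'
#' @param tips Tip-set tibble (columns `x`, `y`) with at least one row.
#' @return Named numeric `c(x, y)`.
#' @export
estimate_seed_position <- function(tips) {
  if (nrow(tips) == 0L) abort("cannot estimate a seed position from an empty tip set")
  c(x = (min(tips$x) + max(tips$x)) / 2, y = min(tips$y))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Compute the root-trait vector from a tip set
#'
#' All traits derive from the tip coordinates (pixels): the tip count; the
#' convex hull area of the tip centroids; the bounding-box width and depth
#' and their ratio (`NA` at zero depth); mean and population standard
#' deviation of the x and y positions; counts of tips in the 100-, 200-
#' and 300-pixel strips below the seed position; the total-length estimate
#' (sum of tip-to-seed distances); and the centre of mass (reported
#' separately from the means for fidelity to the published trait list,
#' with which it coincides).
#'
#' @param tips Tip-set tibble for a single image (columns `x`, `y`,
#'   optionally `image_id`).
#' @param seed_position Optional `c(x, y)`; estimated via
#'   [estimate_seed_position()] when `NULL`.
#' @param image_id Id for the output row (defaults to the tips' id).
#' @return One-row tibble with the canonical trait columns (see
#'   [write_trait_table()]).
#' @export
compute_traits <- function(tips, seed_position = NULL, image_id = NULL) {
  if (nrow(tips) == 0L) abort("cannot compute traits from an empty tip set")
  image_id <- image_id %||%
    (if ("image_id" %in% names(tips)) tips$image_id[1L] else "image")
  seed <- seed_position %||% estimate_seed_position(tips)
  x <- tips$x
  y <- tips$y
  hull <- grDevices::chull(x, y)
  width <- max(x) - min(x)
  depth <- max(y) - min(y)
  strip_count <- function(k) {
    sum(y > seed[2L] & y <= seed[2L] + k)
  }
  tibble(
    image_id = image_id,
    tip_count = length(x),
    hull_area = shoelace_area(x[hull], y[hull]),
    width = width,
    depth = depth,
    width_depth_ratio = if (depth > 0) width / depth else NA_real_,
    mean_x = mean(x), mean_y = mean(y),
    sd_x = sqrt(mean((x - mean(x))^2)),
    sd_y = sqrt(mean((y - mean(y))^2)),
    top100_count = strip_count(100), top200_count = strip_count(200),
    top300_count = strip_count(300),
    total_length = sum(sqrt((x - seed[1L])^2 + (y - seed[2L])^2)),
    centre_mass_x = mean(x), centre_mass_y = mean(y),
    seed_x = unname(seed[1L]), seed_y = unname(seed[2L])
  )
}

#' Trait table for many images
#'
#' Applies [compute_traits()] per `image_id` group.
#'
#' @param tips Tip-set tibble with an `image_id` column.
#' @param ... Passed on to [compute_traits()].
#' @return Tibble with one trait row per image, in first-appearance order.
#' @export
compute_trait_table <- function(tips, ...) {
  stopifnot("image_id" %in% names(tips))
  ids <- unique(tips$image_id)
  dplyr::bind_rows(lapply(ids, function(id) {
    compute_traits(tips[tips$image_id == id, ], ...)
  }))
}

#' Plot a tip set with its derived geometry
#'
#' Shows tips, the convex hull, the bounding box and the estimated seed
#' position for a single image.
#'
#' @param tips Tip-set tibble for one image.
#' @return A ggplot object.
#' @export
plot_tip_set <- function(tips) {
  seed <- estimate_seed_position(tips)
  hull <- grDevices::chull(tips$x, tips$y)
  hull_df <- tips[c(hull, hull[1L]), ]
  ggplot2::ggplot(tips, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(data = hull_df, fill = "steelblue", alpha = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::annotate("point", x = seed[1L], y = seed[2L], colour = "red",
                      shape = 17, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
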