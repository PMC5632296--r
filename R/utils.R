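#' @importFrom rlang abort warn inform %||% hash .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 pmap imap keep
NULL

# Coordinate convention used throughout the package: x grows rightward,
# y grows downward, both 0-based, integer pixel centres. Rasters are numeric
# arrays dim c(H, W, 3) with values on the 0..255 scale.

#' The closed vocabulary of point-feature classes
#'
#' @return Character vector of the five feature classes the detectors know.
#' @export
feature_classes <- function() {
  c("root_tip", "leaf_tip", "leaf_base", "ear_tip", "ear_base")
}

#' Class vocabularies of the two classifiers
#'
#' Root networks separate `root_tip` from `root_negative`; shoot networks
#' separate the four shoot features from `shoot_negative`.
#'
#' @param domain `"root"` or `"shoot"`.
#' @return Character vector of class names, negatives last.
#' @export
classifier_classes <- function(domain = c("root", "shoot")) {
  domain <- match.arg(domain)
  if (domain == "root") c("root_tip", "root_negative")
  else c("leaf_tip", "leaf_base", "ear_tip", "ear_base", "shoot_negative")
}

blank_raster <- function(height, width, value = 0) {
  array(value, dim = c(height, width, 3L))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

raster_dim <- function(raster) {
  d <- dim(raster)
  list(height = d[1L], width = d[2L])
}

# Crop a square patch of side `side` centred (by the floor(side/2) pixel)
# on 0-based (cx, cy). Out-of-bounds indices are clamped, i.e. edge
# replication, so crops near the border keep full size.
crop_patch <- function(raster, cx, cy, side) {
  d <- dim(raster)
  half <- side %/% 2L
  ys <- clamp(seq.int(cy - half, length.out = side) + 1L, 1L, d[1L])
  xs <- clamp(seq.int(cx - half, length.out = side) + 1L, 1L, d[2L])
  raster[ys, xs, , drop = FALSE]
}

# Arc length of an n x 2 polyline matrix (columns x, y).
polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Minimum Euclidean distance from point (x, y) to a set of points (n x 2).
min_dist_to_points <- function(x, y, pts) {
  if (is.null(pts) || nrow(pts) == 0L) return(Inf)
  sqrt(min((pts[, 1L] - x)^2 + (pts[, 2L] - y)^2))
}

as_xy_matrix <- function(df) {
  if (is.null(df)) return(matrix(numeric(0), ncol = 2L))
  m <- cbind(df[[1L]], df[[2L]])
  colnames(m) <- c("x", "y")
  m
}
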