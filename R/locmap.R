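# Sliding-window localization: the classifier is applied at regular pixel
# intervals (the stride) over the whole image, producing a grid of class
# probabilities — the classification map / heatmap. Windows are fully
# interior (no border padding), so grid cell (i, j) (1-based) represents
# the window centred at image pixel origin + stride * (j - 1, i - 1).

new_class_map <- function(grid, class_names, stride, window, image_id,
                          image_size) {
  structure(
    list(
      grid = grid, class_names = class_names, stride = as.integer(stride),
      window = as.integer(window),
      origin = c(window %/% 2L, window %/% 2L),
      image_id = image_id, image_size = image_size
    ),
    class = "class_map"
  )
}

#' @export
print.class_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<class_map '%s'> %dx%d cells, stride %d, window %d, classes: %s\n",
    x$image_id, d[2L], d[1L], x$stride, x$window,
    paste(x$class_names, collapse = ", ")
  ))
  invisible(x)
}

#' Scan an image with a trained classifier
#'
#' Evaluates the classifier on every `window x window` sub-image whose
#' top-left corner lies on the stride grid, in batches; results are
#' identical to classifying one window at a time. The output grid has
#' `floor((W - window)/stride) + 1` columns and the analogous number of
#' rows.
#'
#' @param model A `tip_classifier`.
#' @param image An [annotated_image()] or a raster array `c(H, W, 3)`.
#' @param stride Pixel interval between window positions (default 4).
#' @param batch_windows Windows evaluated per forward pass.
#' @return A `class_map` object: probability grid
#'   `rows x cols x n_classes` plus the stride/window/origin geometry.
#' @export
scan_image <- function(model, image, stride = 4L, batch_windows = 256L) {
  stopifnot(inherits(model, "tip_classifier"))
  raster <- if (inherits(image, "annotated_image")) image$raster else image
  image_id <- if (inherits(image, "annotated_image")) image$image_id else "image"
  d <- dim(raster)
  H <- d[1L]; W <- d[2L]
  window <- model$spec$input_side
  if (H < window || W < window) {
    abort(sprintf("image %dx%d is smaller than the %d-px window", W, H, window))
  }
  nx <- (W - window) %/% stride + 1L
  ny <- (H - window) %/% stride + 1L
  rows_all <- raster_to_rows(raster)
  rows_all[, 1L] <- (rows_all[, 1L] - model$mean_color[1L]) / 255
  rows_all[, 2L] <- (rows_all[, 2L] - model$mean_color[2L]) / 255
  rows_all[, 3L] <- (rows_all[, 3L] - model$mean_color[3L]) / 255
  # within-window gather offsets in engine row order (y-major, x fastest)
  ridx <- as.vector(t(outer(0:(window - 1L), 0:(window - 1L),
                            function(dy, dx) dy * W + dx))) + 1L
  # top-left corners, grid-row-major (j fastest) to fill the grid in order
  tx <- rep(0:(nx - 1L), times = ny) * stride
  ty <- rep(0:(ny - 1L), each = nx) * stride
  bases <- ty * W + tx
  n_win <- length(bases)
  probs <- matrix(0, n_win, model$spec$n_classes)
  start <- 1L
  while (start <= n_win) {
    b <- min(batch_windows, n_win - start + 1L)
    sel <- start:(start + b - 1L)
    idx <- rep(bases[sel], each = length(ridx)) + rep(ridx, times = b)
    M <- rows_all[idx, , drop = FALSE]
    probs[sel, ] <- net_forward(model$params, model$spec, M, b)$probs
    start <- start + b
  }
  grid <- array(0, dim = c(ny, nx, model$spec$n_classes))
  for (k in seq_len(model$spec$n_classes)) {
    grid[, , k] <- matrix(probs[, k], ny, nx, byrow = TRUE)
  }
  new_class_map(grid, model$class_names, stride, window, image_id, c(W, H))
}

#' Map grid cells to image coordinates
#'
#' The grid-to-image mapping is exactly invertible:
#' `image_xy = origin + stride * (cell - 1)`.
#'
#' @param map A `class_map`.
#' @param i,j 1-based grid row / column indices (vectors allowed).
#' @return Tibble with image-space `x`, `y` (0-based pixels).
#' @export
cell_to_image <- function(map, i, j) {
  tibble(
    x = map$origin[1L] + map$stride * (j - 1),
    y = map$origin[2L] + map$stride * (i - 1)
  )
}

#' @rdname cell_to_image
#' @param x,y Image coordinates lying on the stride grid.
#' @return For `image_to_cell`: tibble with grid indices `i`, `j`.
#' @export
image_to_cell <- function(map, x, y) {
  tibble(
    i = (y - map$origin[2L]) / map$stride + 1,
    j = (x - map$origin[1L]) / map$stride + 1
  )
}

#' Threshold one class of a classification map
#'
#' @param map A `class_map`.
#' @param feature_class One of `map$class_names`.
#' @param threshold Likelihood threshold; cells with probability strictly
#'   above it are marked.
#' @return Logical matrix on the map grid.
#' @export
threshold_map <- function(map, feature_class, threshold = 0.5) {
  k <- match(feature_class, map$class_names)
  if (is.na(k)) {
    abort(sprintf(
      "class '%s' not in the map (classes: %s)",
      feature_class, paste(map$class_names, collapse = ", ")
    ))
  }
  map$grid[, , k] > threshold
}

#' Heatmap overlay of a classification map
#'
#' Renders per-class probabilities as coloured tiles at their image
#' positions, for visual inspection of a scan.
#'
#' @param object A `class_map`.
#' @param classes Classes to show (default: all but negatives).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_map <- function(object, classes = NULL, ...) {
  classes <- classes %||% setdiff(
    object$class_names, c("root_negative", "shoot_negative")
  )
  d <- dim(object$grid)
  df <- tidyr::expand_grid(i = seq_len(d[1L]), j = seq_len(d[2L]))
  df <- dplyr::bind_rows(lapply(classes, function(cl) {
    k <- match(cl, object$class_names)
    dplyr::mutate(df, class = cl,
                  prob = object$grid[cbind(df$i, df$j, k)])
  }))
  xy <- cell_to_image(object, df$i, df$j)
  df$x <- xy$x
  df$y <- xy$y
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$prob)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "probability")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
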