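# From heatmap to coordinates: threshold the map, render it at image
# resolution (each stride-grid cell a stride x stride block), erode with a
# 3x3 structuring element (3 iterations by default) to remove single-cell
# artefacts and split near-touching tips, label the remaining foreground
# by 8-connectivity, and take each component's centroid. Erosion at image
# resolution is what makes 3 iterations a compromise rather than a
# guillotine: a lone heat-map cell (a stride x stride pixel block) is
# gone by the second pass, while any response spanning two or more cells
# survives.

#' Binary erosion with the full 3x3 structuring element
#'
#' Standard morphological erosion applied `iterations` times; a cell
#' survives one iteration iff its full 3x3 neighbourhood is foreground.
#' Outside the mask counts as background, so foreground touching the
#' border is eroded away.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param iterations Number of erosion passes.
#' @return Logical matrix of the same size.
#' @export
erode_mask <- function(mask, iterations = 3L) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (iterations <= 0L) return(m > 0)
  pad <- iterations
  big <- matrix(0, nrow(m) + 2L * pad, ncol(m) + 2L * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  brush <- EBImage::makeBrush(3L, shape = "box")
  for (i in seq_len(iterations)) big <- EBImage::erode(big, brush)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] > 0
}

#' Label connected components (8-connectivity)
#'
#' Breadth-first labelling where diagonal neighbours are connected.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same size: 0 background, 1..n component
#'   labels.
#' @export
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  nbr_off <- c(-1L, 1L, -H, H, -H - 1L, -H + 1L, H - 1L, H + 1L)
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0L) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      qr <- ((q - 1L) %% H) + 1L
      cand <- q + nbr_off
      # drop wrap-arounds across matrix columns
      ok <- rep(TRUE, 8L)
      if (qr == 1L) ok[c(1L, 5L, 7L)] <- FALSE
      if (qr == H) ok[c(2L, 6L, 8L)] <- FALSE
      cand <- cand[ok]
      cand <- cand[cand >= 1L & cand <= H * W]
      cand <- cand[mask[cand] & lab[cand] == 0L]
      if (length(cand) > 0L) {
        lab[cand] <- cur
        queue <- c(queue, cand)
      }
    }
  }
  lab
}

#' Extract tip coordinates from a classification map
#'
#' Thresholds the map, renders the binary heat map at image resolution
#' (each grid cell becomes a `stride x stride` pixel block centred on the
#' cell's image position), erodes it (default 3 iterations of the full
#' 3x3 element — enough to delete single-cell artefacts while preserving
#' any response spanning two or more cells), labels the surviving
#' foreground with 8-connectivity, and reports the unweighted centroid of
#' each component in source-image pixel coordinates.
#'
#' @param map A `class_map` from [scan_image()].
#' @param feature_class Class to extract (default `root_tip`).
#' @param threshold Likelihood threshold.
#' @param iterations Erosion iterations.
#' @param source Provenance tag recorded in the result.
#' @return A tip set: tibble `image_id`, `x`, `y`, `source`; zero rows when
#'   nothing survives.
#' @export
extract_tips <- function(map, feature_class = "root_tip", threshold = 0.5,
                         iterations = 3L, source = "detector") {
  mask <- threshold_map(map, feature_class, threshold)
  stride <- map$stride
  px <- mask[rep(seq_len(nrow(mask)), each = stride),
             rep(seq_len(ncol(mask)), each = stride), drop = FALSE]
  eroded <- erode_mask(px, iterations)
  lab <- label_components(eroded)
  n <- max(lab)
  if (n == 0L) {
    return(tibble(image_id = character(), x = double(), y = double(),
                  source = character()))
  }
  idx <- which(lab > 0L)
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  # pixel row r of the rendered map spans grid row (r-1)/stride + 1; a
  # full cell block has mean pixel index stride*(i-1) + (stride+1)/2, so
  # image_y = origin_y + mean(r) - (stride+1)/2 (and likewise for x)
  cy <- tapply(r, lab[idx], mean)
  cx <- tapply(cc, lab[idx], mean)
  tibble(
    image_id = map$image_id,
    x = map$origin[1L] + as.numeric(cx) - (stride + 1) / 2,
    y = map$origin[2L] + as.numeric(cy) - (stride + 1) / 2,
    source = source
  )
}

#' Ground-truth tip set of an annotated image
#'
#' @param img An [annotated_image()].
#' @param feature_class Class to take (default `root_tip`).
#' @return Tip-set tibble with `source = "ground_truth"`.
#' @export
ground_truth_tips <- function(img, feature_class = "root_tip") {
  ann <- img$annotations[img$annotations$feature_class == feature_class, ]
  tibble(
    image_id = img$image_id, x = ann$x, y = ann$y, source = "ground_truth"
  )
}

#' Write a tip set as CSV
#'
#' @param tips Tip-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tips <- function(tips, path) {
  readr::write_csv(tips[, c("image_id", "x", "y", "source")], path, na = "NA")
  invisible(path)
}

#' Read a tip-set CSV written by [write_tips()]
#'
#' @param path CSV path.
#' @return Tip-set tibble.
#' @export
read_tips <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(image_id = readr::col_character()))
}
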