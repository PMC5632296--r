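#' Construct an annotated image
#'
#' The unit of raw input for the pipeline: an 8-bit RGB raster plus point
#' annotations and, for root scenes, the polylines tracing each drawn root
#' and the seed (source-point) position.
#'
#' @param image_id Unique identifier string.
#' @param raster Numeric array `c(H, W, 3)`, values in `[0, 255]`.
#' @param annotations Tibble with columns `feature_class`, `x`, `y` and
#'   optionally `root_length` (pixels of bearing root, tips only).
#'   Coordinates are 0-based, x rightward, y downward.
#' @param polylines Optional list of two-column (`x`, `y`) matrices or data
#'   frames, one per traced root.
#' @param seed_position Optional length-2 numeric `c(x, y)`: the root-system
#'   source point.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(image_id, raster, annotations = NULL,
                            polylines = NULL, seed_position = NULL) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  if (length(dim(raster)) == 2L) {
    raster <- array(rep(raster, 3L), dim = c(dim(raster), 3L))
  }
  stopifnot(length(dim(raster)) == 3L, dim(raster)[3L] == 3L)
  d <- dim(raster)
  annotations <- normalize_annotations(annotations)
  bad <- annotations$x < 0 | annotations$x >= d[2L] |
    annotations$y < 0 | annotations$y >= d[1L]
  if (any(bad)) {
    abort(sprintf(
      "image '%s': %d annotation(s) fall outside the %dx%d raster",
      image_id, sum(bad), d[2L], d[1L]
    ))
  }
  unknown <- setdiff(unique(annotations$feature_class), feature_classes())
  if (length(unknown) > 0L) {
    abort(sprintf(
      "image '%s': unknown feature class(es): %s",
      image_id, paste(sQuote(unknown), collapse = ", ")
    ))
  }
  if (!is.null(polylines)) {
    polylines <- lapply(polylines, function(p) {
      m <- as_xy_matrix(as.data.frame(p))
      storage.mode(m) <- "double"
      m
    })
  }
  structure(
    list(
      image_id = image_id, raster = raster, annotations = annotations,
      polylines = polylines, seed_position = seed_position
    ),
    class = "annotated_image"
  )
}

normalize_annotations <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    return(tibble(
      feature_class = character(), x = double(), y = double(),
      root_length = double()
    ))
  }
  annotations <- as_tibble(annotations)
  if (!"root_length" %in% names(annotations)) annotations$root_length <- NA_real_
  if (any(!is.na(annotations$root_length) & annotations$root_length < 0)) {
    abort("root_length must be >= 0 where present")
  }
  annotations[, c("feature_class", "x", "y", "root_length")]
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf(
    "<annotated_image '%s'> %dx%d px, %d annotation(s), %d polyline(s)\n",
    x$image_id, d[2L], d[1L], nrow(x$annotations),
    length(x$polylines %||% list())
  ))
  invisible(x)
}

#' Read an image file into a 0..255 RGB array
#'
#' PNG files are read with the png package; JPEG and TIFF fall back to
#' EBImage. Grayscale input is expanded to three identical channels.
#'
#' @param path Image file path.
#' @return Numeric array `c(H, W, 3)` on the 0..255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: '%s'", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    e <- EBImage::readImage(path)
    img <- aperm(array(e, dim = c(dim(e)[1:2], prod(dim(e)[-(1:2)], 1L))),
                 c(2L, 1L, 3L))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3L] == 1L) {
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  }
  img * 255
}

#' Write a 0..255 RGB array as PNG
#'
#' @param raster Numeric array `c(H, W, 3)`, 0..255.
#' @param path Output path, extension `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(raster, path) {
  png::writePNG(clamp(raster, 0, 255) / 255, target = path)
  invisible(path)
}

#' Write a dataset manifest
#'
#' Serializes a list of [annotated_image()] records to a directory: one PNG
#' per image and a single JSON manifest holding, per image, the file name,
#' the point annotations, the root polylines (as coordinate arrays) and the
#' seed position. The JSON file is the dataset's on-disk identity;
#' [read_manifest()] inverts it exactly.
#'
#' @param images List of `annotated_image` objects with unique ids.
#' @param dir Output directory (created if missing).
#' @param name Manifest file name within `dir`.
#' @return Path to the manifest JSON, invisibly.
#' @export
write_manifest <- function(images, dir, name = "manifest.json") {
  ids <- vapply(images, function(im) im$image_id, character(1L))
  if (anyDuplicated(ids)) abort("image_id values must be unique within a manifest")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(images, function(im) {
    file <- paste0(im$image_id, ".png")
    write_image(im$raster, file.path(dir, file))
    list(
      image_id = im$image_id,
      file = file,
      seed_position = im$seed_position,
      annotations = lapply(seq_len(nrow(im$annotations)), function(i) {
        a <- as.list(im$annotations[i, ])
        if (is.na(a$root_length)) a$root_length <- NULL
        a
      }),
      polylines = lapply(im$polylines %||% list(), function(p) {
        lapply(seq_len(nrow(p)), function(i) {
          list(x = unname(p[i, 1L]), y = unname(p[i, 2L]))
        })
      })
    )
  })
  path <- file.path(dir, name)
  jsonlite::write_json(
    list(format = "tipscan-manifest", version = 1L, images = entries),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a dataset manifest
#'
#' Reads either a JSON manifest written by [write_manifest()] or an
#' annotations-only CSV with columns `image_id`, `file`, `feature_class`,
#' `x`, `y` and optionally `root_length` (no polylines). Feature classes
#' outside the closed vocabulary, missing image files and malformed rows are
#' rejected with errors naming the offender.
#'
#' @param path Manifest file (`.json` or `.csv`); image paths are resolved
#'   relative to its directory.
#' @return List of [annotated_image()] records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: '%s'", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    return(read_manifest_csv(path))
  }
  doc <- jsonlite::read_json(path)
  if (is.null(doc$images)) abort(sprintf("'%s' is not a manifest (no 'images' key)", path))
  base <- dirname(path)
  lapply(doc$images, function(e) {
    img_path <- file.path(base, e$file)
    if (!file.exists(img_path)) {
      abort(sprintf("image '%s': referenced file missing: '%s'", e$image_id, img_path))
    }
    ann <- if (length(e$annotations) > 0L) {
      dplyr::bind_rows(lapply(e$annotations, function(a) {
        tibble(
          feature_class = a$feature_class %||% NA_character_,
          x = as.numeric(a$x %||% NA_real_),
          y = as.numeric(a$y %||% NA_real_),
          root_length = as.numeric(a$root_length %||% NA_real_)
        )
      }))
    } else NULL
    poly <- if (length(e$polylines) > 0L) {
      lapply(e$polylines, function(p) {
        m <- do.call(rbind, lapply(p, function(q) c(q$x, q$y)))
        colnames(m) <- c("x", "y")
        m
      })
    } else NULL
    annotated_image(
      image_id = e$image_id, raster = read_image(img_path),
      annotations = ann, polylines = poly,
      seed_position = if (!is.null(e$seed_position)) unlist(e$seed_position)
    )
  })
}

read_manifest_csv <- function(path) {
  rows <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("image_id", "file", "feature_class", "x", "y")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0L) {
    abort(sprintf("CSV manifest lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  bad <- which(!rows$feature_class %in% feature_classes())
  if (length(bad) > 0L) {
    abort(sprintf(
      "row %d: unknown feature class '%s'", bad[1L] + 1L, rows$feature_class[bad[1L]]
    ))
  }
  base <- dirname(path)
  split(rows, factor(rows$image_id, levels = unique(rows$image_id))) |>
    lapply(function(g) {
      annotated_image(
        image_id = g$image_id[1L],
        raster = read_image(file.path(base, g$file[1L])),
        annotations = g[, intersect(names(g), c("feature_class", "x", "y", "root_length"))]
      )
    }) |>
    unname()
}

trait_column_order <- function() {
  c(
    "tip_count", "hull_area", "width", "depth", "width_depth_ratio",
    "mean_x", "mean_y", "sd_x", "sd_y",
    "top100_count", "top200_count", "top300_count",
    "total_length", "centre_mass_x", "centre_mass_y", "seed_x", "seed_y"
  )
}

#' Write a root-trait table as CSV
#'
#' One row per image, `image_id` first, then the traits in their canonical
#' order: tip_count, hull_area, width, depth, width_depth_ratio, mean_x,
#' mean_y, sd_x, sd_y, top100_count, top200_count, top300_count,
#' total_length, centre_mass_x, centre_mass_y, seed_x, seed_y. Undefined
#' values (e.g. the width:depth ratio at zero depth) are written as `NA`;
#' formatting is locale-independent.
#'
#' @param traits Tibble as returned by [compute_traits()] (one or more rows).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  if (is.null(traits) || nrow(traits) == 0L) abort("no trait records to write")
  cols <- c("image_id", trait_column_order())
  miss <- setdiff(cols, names(traits))
  if (length(miss) > 0L) {
    abort(sprintf("trait table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  readr::write_csv(traits[, cols], path, na = "NA")
  invisible(path)
}

#' Read a trait table written by [write_trait_table()]
#'
#' @param path CSV path.
#' @return Tibble with the canonical trait columns.
#' @export
read_trait_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(image_id = readr::col_character()))
}

#' Tolerant RSML reader
#'
#' Extracts root polylines from a Root System Markup Language file; each
#' root's tip is taken as the last polyline point and its length as the
#' polyline arc length. Only geometry is read; scenes, properties and
#' functions are ignored.
#'
#' @param path RSML file path.
#' @param image_id Id for the resulting record (defaults to the file stem).
#' @return A list with `annotations` (tibble of `root_tip` rows) and
#'   `polylines`, ready to combine with a raster via [annotated_image()].
#' @export
read_rsml <- function(path, image_id = NULL) {
  if (!file.exists(path)) abort(sprintf("RSML file not found: '%s'", path))
  doc <- xml2::read_xml(path)
  pls <- xml2::xml_find_all(doc, ".//root/geometry/polyline")
  polylines <- lapply(pls, function(pl) {
    pts <- xml2::xml_find_all(pl, "./point")
    m <- cbind(
      x = as.numeric(xml2::xml_attr(pts, "x")),
      y = as.numeric(xml2::xml_attr(pts, "y"))
    )
    m[stats::complete.cases(m), , drop = FALSE]
  })
  polylines <- polylines[vapply(polylines, nrow, integer(1L)) > 0L]
  ann <- dplyr::bind_rows(lapply(polylines, function(m) {
    tibble(
      feature_class = "root_tip",
      x = unname(m[nrow(m), 1L]), y = unname(m[nrow(m), 2L]),
      root_length = polyline_length(m)
    )
  }))
  list(
    image_id = image_id %||% sub("\\.[^.]*$", "", basename(path)),
    annotations = ann,
    polylines = polylines
  )
}
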