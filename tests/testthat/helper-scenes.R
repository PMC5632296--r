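# Shared fixtures, built in code at test time.

small_root_params <- function(seed = 1L, ...) {
  root_scene_params(
    image_width = 160, image_height = 160, n_primary = 2,
    laterals_per_primary = c(1, 2), primary_length = c(70, 110),
    lateral_length = c(20, 40), seed = seed, ...
  )
}

small_shoot_params <- function(seed = 1L, ...) {
  shoot_scene_params(
    image_width = 256, image_height = 256, n_leaves = 2, n_ears = 1,
    clutter_density = 15, seed = seed, ...
  )
}

# Solid-colour coded patches: a linearly separable toy classification task.
toy_patch_set <- function(n_per_class = 200L, side = 32L, seed = 42L,
                          classes = c("root_tip", "root_negative"),
                          colors = list(c(200, 60, 60), c(60, 60, 200))) {
  withr::with_seed(seed, {
    patches <- list()
    labels <- character()
    for (ci in seq_along(classes)) {
      for (i in seq_len(n_per_class)) {
        patches[[length(patches) + 1L]] <- array(
          rep(colors[[ci]], each = side * side) +
            stats::rnorm(side * side * 3, 0, 5),
          dim = c(side, side, 3L)
        )
        labels <- c(labels, classes[ci])
      }
    }
    tibble::tibble(
      patch = patches, label = labels, source_image_id = "toy",
      x = 0, y = 0
    )
  })
}

# An untrained (randomly initialized) classifier: sufficient for geometry,
# normalization and batching checks that do not need a good detector.
make_untrained_model <- function(filters_base = 2L, seed = 7L) {
  spec <- build_root_network(filters_base = filters_base)
  structure(
    list(
      spec = spec,
      params = tipscan:::init_network_params(spec, seed = seed),
      mean_color = c(r = 120, g = 120, b = 120),
      class_names = spec$class_names,
      config = train_config(),
      history = tibble::tibble(),
      best_val_accuracy = NA_real_, best_iteration = NA_integer_
    ),
    class = "tip_classifier"
  )
}

# Toy-trained model, memoized so several test files can share it.
.toy_model_env <- new.env(parent = emptyenv())
get_toy_model <- function() {
  if (is.null(.toy_model_env$model)) {
    ds <- toy_patch_set(150L)
    cfg <- dataset_config("root", rng_seed = 11L)
    sp <- split_dataset(ds, cfg)
    .toy_model_env$model <- train_network(
      build_root_network(filters_base = 2L), sp$train, sp$val,
      train_config(
        initial_lr = 0.01, max_iterations = 250L, check_interval = 50L,
        batch_size = 32L, rng_seed = 11L
      )
    )
    .toy_model_env$split <- sp
  }
  list(model = .toy_model_env$model, split = .toy_model_env$split)
}

random_mask <- function(h, w, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(h * w) < p, h, w)
}

# Independent erosion oracle: a pixel survives iff its full 3x3
# neighbourhood (background outside the mask) is foreground.
erode_oracle <- function(mask, iterations) {
  m <- mask
  for (it in seq_len(iterations)) {
    H <- nrow(m); W <- ncol(m)
    out <- matrix(FALSE, H, W)
    for (y in seq_len(H)) {
      for (x in seq_len(W)) {
        if (!m[y, x]) next
        ok <- TRUE
        for (dy in -1:1) {
          for (dx in -1:1) {
            yy <- y + dy; xx <- x + dx
            if (yy < 1 || yy > H || xx < 1 || xx > W || !m[yy, xx]) ok <- FALSE
          }
        }
        out[y, x] <- ok
      }
    }
    m <- out
  }
  m
}

# Independent component labelling via igraph: vertices are foreground
# cells, edges join 8-neighbours; returns a membership vector aligned with
# which(mask).
components_oracle <- function(mask) {
  n <- sum(mask)
  if (n == 0L) return(integer(0))
  H <- nrow(mask); W <- ncol(mask)
  id <- matrix(0L, H, W)
  id[mask] <- seq_len(n) # column-major, matching which(mask) order
  edges <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dy <- off[1L]; dx <- off[2L]
    ys <- seq_len(H - dy)
    xs <- if (dx >= 0L) seq_len(W - dx) else seq.int(1L - dx, W)
    a <- id[ys, xs, drop = FALSE]
    b <- id[ys + dy, xs + dx, drop = FALSE]
    sel <- a > 0L & b > 0L
    edges <- c(edges, rbind(a[sel], b[sel]))
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = FALSE)
  unname(igraph::components(g)$membership)
}
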