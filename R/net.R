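#' Define a network architecture
#'
#' Layers are applied in order to a square RGB input of side `input_side`.
#' Supported kinds: `conv3x3` (valid, unpadded), `relu`, `maxpool2x2`,
#' `dropout` (between fully connected layers only), `fully_connected` and a
#' final `softmax`. Convolutions are unpadded so the spatial size shrinks
#' by two per convolution and halves at each pool; the architecture must
#' bring it to exactly 1x1 before the fully connected stack.
#'
#' @param layers List of layer records, e.g. `list(kind = "conv3x3",
#'   filters = 64)`, `list(kind = "fully_connected", units = 64)`,
#'   `list(kind = "dropout", rate = 0.5)`.
#' @param input_side Input image side in pixels.
#' @param class_names Output class vocabulary; the last fully connected
#'   layer must have `length(class_names)` units.
#' @return A `network_spec` object.
#' @export
network_spec <- function(layers, input_side, class_names) {
  s <- as.integer(input_side)
  seen_fc <- FALSE
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$kind == "conv3x3") {
      if (seen_fc) abort("convolutions cannot follow fully connected layers")
      if (s < 3L) abort(sprintf("layer %d: spatial size %d too small for 3x3 conv", li, s))
      s <- s - 2L
    } else if (ly$kind == "maxpool2x2") {
      if (s %% 2L != 0L) {
        abort(sprintf("layer %d: spatial size %d not divisible by 2 for pooling", li, s))
      }
      s <- s %/% 2L
    } else if (ly$kind == "fully_connected") {
      if (s != 1L) {
        abort(sprintf(
          "fully connected layer %d reached at spatial size %dx%d; convolutions must reduce to 1x1 first",
          li, s, s
        ))
      }
      seen_fc <- TRUE
    } else if (ly$kind == "dropout") {
      if (!seen_fc) abort("dropout is only allowed between fully connected layers")
      later <- vapply(layers[seq.int(li + 1L, length.out = length(layers) - li)],
                      function(l) l$kind, character(1L))
      if (!"fully_connected" %in% later) {
        abort("dropout is only allowed between fully connected layers")
      }
    } else if (!ly$kind %in% c("relu", "softmax")) {
      abort(sprintf("unknown layer kind '%s'", ly$kind))
    }
  }
  if (layers[[length(layers)]]$kind != "softmax") {
    abort("the last layer must be softmax")
  }
  fc <- keep(layers, function(l) l$kind == "fully_connected")
  if (length(fc) == 0L || fc[[length(fc)]]$units != length(class_names)) {
    abort("the last fully connected layer must have one unit per class")
  }
  structure(
    list(
      layers = layers, input_side = as.integer(input_side),
      n_classes = length(class_names), class_names = class_names
    ),
    class = "network_spec"
  )
}

#' Spatial shape trace of a network
#'
#' Propagates the input side through every layer: convolutions shrink the
#' side by two (unpadded 3x3 kernels), pooling halves it, everything else
#' leaves it unchanged.
#'
#' @param spec A [network_spec()].
#' @return Tibble with one row per layer: `layer`, `kind`, `size_in`,
#'   `size_out`, `channels_out`.
#' @export
spatial_trace <- function(spec) {
  s <- spec$input_side
  c_out <- 3L
  rows <- lapply(seq_along(spec$layers), function(li) {
    ly <- spec$layers[[li]]
    s_in <- s
    if (ly$kind == "conv3x3") {
      s <<- s - 2L
      c_out <<- ly$filters
    } else if (ly$kind == "maxpool2x2") {
      s <<- s %/% 2L
    } else if (ly$kind == "fully_connected") {
      c_out <<- ly$units
    }
    tibble(layer = li, kind = ly$kind, size_in = s_in, size_out = s,
           channels_out = c_out)
  })
  dplyr::bind_rows(rows)
}

conv_block <- function(filters, n = 2L) {
  unlist(lapply(seq_len(n), function(i) {
    list(list(kind = "conv3x3", filters = filters), list(kind = "relu"))
  }), recursive = FALSE)
}

fc_stack <- function(units, n_classes, dropout_rate = 0.5) {
  out <- list()
  for (u in units) {
    out <- c(out, list(
      list(kind = "fully_connected", units = u),
      list(kind = "relu"),
      list(kind = "dropout", rate = dropout_rate)
    ))
  }
  c(out, list(
    list(kind = "fully_connected", units = n_classes),
    list(kind = "softmax")
  ))
}

#' The root-tip classification network
#'
#' Two groups of two 3x3 convolutions each followed by max pooling, two
#' final convolutions, then three fully connected layers with ReLU and 50%
#' dropout between them, ending in a two-class softmax (`root_tip` vs
#' `root_negative`). Filter counts double after each pool, from
#' `filters_base` up to `4 * filters_base` (64 up to 256 at the default);
#' the unpadded convolutions take the 32x32 input down the trace
#' 32-30-28-14-12-10-5-3-1 so the fully connected stack sees a 1x1 map.
#'
#' @param filters_base First-layer filter count; 64 reproduces the
#'   full-scale design, smaller values give reduced networks for
#'   desk-scale experiments.
#' @param fc_units Widths of the two hidden fully connected layers
#'   (default `c(4, 1) * filters_base`).
#' @param dropout_rate Dropout probability between fully connected layers.
#' @return A [network_spec()] with `input_side = 32`.
#' @export
build_root_network <- function(filters_base = 64L, fc_units = NULL,
                               dropout_rate = 0.5) {
  f <- as.integer(filters_base)
  fc_units <- fc_units %||% c(4L * f, f)
  layers <- c(
    conv_block(f), list(list(kind = "maxpool2x2")),
    conv_block(2L * f), list(list(kind = "maxpool2x2")),
    conv_block(4L * f),
    fc_stack(fc_units, 2L, dropout_rate)
  )
  network_spec(layers, input_side = 32L, class_names = classifier_classes("root"))
}

#' The shoot-feature classification network
#'
#' Three groups of convolutions (2, 3 and 3 layers — the varying counts
#' keep every pre-pool size even) each followed by max pooling, a single
#' final convolution, then three fully connected layers with ReLU and
#' dropout, ending in a five-class softmax. Filters double per group from
#' `filters_base` to `8 * filters_base` (64 up to 512 at the default); the
#' 64x64 input follows the trace 64-62-60-30-28-26-24-12-10-8-6-3-1.
#'
#' @inheritParams build_root_network
#' @param fc_units Widths of the two hidden fully connected layers
#'   (default `c(8, 2) * filters_base`).
#' @return A [network_spec()] with `input_side = 64`.
#' @export
build_shoot_network <- function(filters_base = 64L, fc_units = NULL,
                                dropout_rate = 0.5) {
  f <- as.integer(filters_base)
  fc_units <- fc_units %||% c(8L * f, 2L * f)
  layers <- c(
    conv_block(f, 2L), list(list(kind = "maxpool2x2")),
    conv_block(2L * f, 3L), list(list(kind = "maxpool2x2")),
    conv_block(4L * f, 3L), list(list(kind = "maxpool2x2")),
    conv_block(8L * f, 1L),
    fc_stack(fc_units, 5L, dropout_rate)
  )
  network_spec(layers, input_side = 64L, class_names = classifier_classes("shoot"))
}

#' Training configuration
#'
#' Defaults follow the published full-scale protocol: initial learning rate
#' 0.1 decreased by a factor of 10 every 20,000 iterations, 50% dropout,
#' mean-colour centring, periodic validation with training halted once
#' accuracy reaches a steady state. Momentum SGD (momentum 0.9, weight
#' decay 5e-4) and batch size 64 are the conventional companions of that
#' schedule. "Steady state" is codified as no validation-accuracy
#' improvement greater than `min_improvement` percentage points over
#' `early_stop_patience` consecutive checks.
#'
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Factor by which the rate is divided at each decay.
#' @param lr_decay_interval Iterations between decays.
#' @param dropout_rate Dropout probability (applied to `dropout` layers).
#' @param batch_size Mini-batch size.
#' @param max_iterations Hard iteration cap.
#' @param check_interval Iterations between validation checks.
#' @param early_stop_patience Checks without improvement before stopping.
#' @param min_improvement Improvement floor in percentage points.
#' @param momentum,weight_decay Momentum SGD hyper-parameters.
#' @param mean_color Optional `c(r, g, b)` to subtract; computed from the
#'   training set when `NULL`.
#' @param rng_seed Seed governing initialization, batch order, augmentation
#'   and dropout; equal seeds give identical runs.
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 0.1, lr_decay_factor = 10,
                         lr_decay_interval = 20000L, dropout_rate = 0.5,
                         batch_size = 64L, max_iterations = 100000L,
                         check_interval = 1000L, early_stop_patience = 5L,
                         min_improvement = 0.1, momentum = 0.9,
                         weight_decay = 5e-4, mean_color = NULL,
                         rng_seed = 1L) {
  stopifnot(initial_lr > 0, lr_decay_factor > 0, lr_decay_interval > 0,
            early_stop_patience >= 1L, batch_size >= 1L)
  structure(
    list(
      initial_lr = initial_lr, lr_decay_factor = lr_decay_factor,
      lr_decay_interval = as.integer(lr_decay_interval),
      dropout_rate = dropout_rate, batch_size = as.integer(batch_size),
      max_iterations = as.integer(max_iterations),
      check_interval = as.integer(check_interval),
      early_stop_patience = as.integer(early_stop_patience),
      min_improvement = min_improvement, momentum = momentum,
      weight_decay = weight_decay, mean_color = mean_color,
      rng_seed = as.integer(rng_seed)
    ),
    class = "train_config"
  )
}

#' Learning rate at given iterations
#'
#' The step schedule: `initial_lr / lr_decay_factor^floor(iter /
#' lr_decay_interval)`.
#'
#' @param cfg A [train_config()].
#' @param iterations Integer vector of (0-based) iteration numbers.
#' @return Numeric vector of learning rates.
#' @export
learning_rate_schedule <- function(cfg, iterations) {
  cfg$initial_lr / cfg$lr_decay_factor^(iterations %/% cfg$lr_decay_interval)
}

# Prepare stored patches for network entry: root storage crops get a
# random window sub-crop (training) or the centred sub-crop (evaluation);
# shoot storage crops get the deterministic 2x downscale; window-sized
# patches pass through.
prep_patch <- function(patch, input_side, jitter) {
  side <- dim(patch)[1L]
  if (side == input_side) return(patch)
  if (side == 2L * input_side) return(downscale_2x(patch, 2L))
  span <- side - input_side
  off <- if (jitter) {
    c(sample.int(span + 1L, 1L), sample.int(span + 1L, 1L)) - 1L
  } else {
    c(span %/% 2L, span %/% 2L)
  }
  patch[off[2L] + seq_len(input_side), off[1L] + seq_len(input_side), ,
        drop = FALSE]
}

label_to_index <- function(labels, class_names) {
  idx <- match(labels, class_names)
  if (anyNA(idx)) {
    abort(sprintf(
      "label(s) outside the classifier vocabulary: %s",
      paste(unique(labels[is.na(idx)]), collapse = ", ")
    ))
  }
  idx
}

#' Train a patch classifier
#'
#' Iterative mini-batch gradient training with cross-entropy loss and
#' momentum SGD under the step learning-rate schedule. The training-set
#' mean colour is subtracted from every input; root-domain storage crops
#' are randomly sub-cropped to the network window on the fly each
#' iteration (jitter augmentation), shoot crops are downscaled once.
#' Validation accuracy is measured every `check_interval` iterations;
#' training halts at steady state (see [train_config()]) or
#' `max_iterations`, and the best-checkpoint parameters are kept. Runs are
#' fully deterministic under `cfg$rng_seed`.
#'
#' @param spec A [network_spec()].
#' @param train,val Patch tibbles (columns `patch`, `label`) from
#'   [build_patch_dataset()]/[split_dataset()].
#' @param cfg A [train_config()].
#' @return A `tip_classifier`: list with the spec, trained parameters, mean
#'   colour, class names, config, per-check `history` tibble and
#'   `best_val_accuracy` (percent).
#' @export
train_network <- function(spec, train, val, cfg = train_config()) {
  stopifnot(inherits(spec, "network_spec"), nrow(train) > 0L, nrow(val) > 0L)
  mean_color <- cfg$mean_color %||% compute_mean_color(train)
  y_train <- label_to_index(train$label, spec$class_names)
  y_val <- label_to_index(val$label, spec$class_names)
  n <- nrow(train)
  # dropout rate from config overrides the spec's layer records
  spec_run <- spec
  spec_run$layers <- lapply(spec$layers, function(l) {
    if (l$kind == "dropout") l$rate <- cfg$dropout_rate
    l
  })

  win <- spec$input_side
  # pre-stack every patch once as normalized engine rows; the random-crop
  # augmentation then reduces to one index gather per batch
  prep_side <- function(p) if (dim(p)[1L] == 2L * win) downscale_2x(p, 2L) else p
  train_patches <- lapply(train$patch, prep_side)
  side <- dim(train_patches[[1L]])[1L]
  if (any(vapply(train_patches, function(p) dim(p)[1L], integer(1L)) != side)) {
    abort("training patches must share one side length")
  }
  if (side < win) abort(sprintf("patch side %d smaller than input side %d", side, win))
  train_rows <- patches_to_rows(train_patches, mean_color)
  span <- side - win
  # column o of `templates`: within-patch row offsets of the window at
  # crop offset (ox = (o-1) %/% (span+1), oy = (o-1) %% (span+1))
  wy <- rep(0:(win - 1L), each = win)
  wx <- rep(0:(win - 1L), times = win)
  templates <- vapply(0:((span + 1L)^2 - 1L), function(o) {
    ox <- o %/% (span + 1L)
    oy <- o %% (span + 1L)
    (wy + oy) * side + (wx + ox) + 1L
  }, integer(win * win))
  batch_rows <- function(sel, offsets) {
    base <- (sel - 1L) * side * side
    idx <- templates[, offsets, drop = FALSE] +
      matrix(base, win * win, length(sel), byrow = TRUE)
    train_rows[as.vector(idx), , drop = FALSE]
  }

  val_rows <- patches_to_rows(
    lapply(val$patch, prep_patch, spec$input_side, jitter = FALSE), mean_color
  )
  val_acc <- function(params) {
    probs <- net_predict_rows(params, spec_run, val_rows, nrow(val))
    100 * mean(max.col(probs, ties.method = "first") == y_val)
  }

  withr::with_seed(cfg$rng_seed, {
    params <- init_network_params(spec_run, seed = sample.int(.Machine$integer.max, 1L))
    velocity <- zero_like(params)
    history <- list()
    best <- list(acc = -Inf, params = params, iteration = 0L)
    stall <- 0L
    running_loss <- NA_real_
    iter <- 0L
    while (iter < cfg$max_iterations) {
      lr <- learning_rate_schedule(cfg, iter)
      sel <- if (n <= cfg$batch_size) seq_len(n) else sample.int(n, cfg$batch_size)
      B <- length(sel)
      offsets <- if (span > 0L) {
        sample.int((span + 1L)^2, B, replace = TRUE)
      } else {
        rep(1L, B)
      }
      M <- batch_rows(sel, offsets)
      fwd <- net_forward(params, spec_run, M, B, training = TRUE)
      p_true <- fwd$probs[cbind(seq_len(B), y_train[sel])]
      loss <- -mean(log(pmax(p_true, 1e-12)))
      if (!is.finite(loss)) {
        abort(sprintf(
          "training diverged at iteration %d (non-finite loss; lr=%g)", iter, lr
        ))
      }
      running_loss <- if (is.na(running_loss)) loss else 0.98 * running_loss + 0.02 * loss
      onehot <- matrix(0, B, spec_run$n_classes)
      onehot[cbind(seq_len(B), y_train[sel])] <- 1
      grads <- net_backward(params, spec_run, fwd, onehot, B)
      upd <- sgd_step(params, grads, velocity, lr, cfg$momentum, cfg$weight_decay)
      params <- upd$params
      velocity <- upd$velocity
      iter <- iter + 1L
      if (iter %% cfg$check_interval == 0L || iter == cfg$max_iterations) {
        acc <- val_acc(params)
        history[[length(history) + 1L]] <- tibble(
          iteration = iter, lr = lr, train_loss = running_loss,
          val_accuracy = acc
        )
        if (acc > best$acc + cfg$min_improvement) {
          best <- list(acc = acc, params = params, iteration = iter)
          stall <- 0L
        } else {
          if (acc > best$acc) best <- list(acc = acc, params = params, iteration = iter)
          stall <- stall + 1L
        }
        if (stall >= cfg$early_stop_patience) break
      }
    }
    structure(
      list(
        spec = spec, params = best$params, mean_color = mean_color,
        class_names = spec$class_names, config = cfg,
        history = dplyr::bind_rows(history),
        best_val_accuracy = best$acc, best_iteration = best$iteration
      ),
      class = "tip_classifier"
    )
  })
}

#' @export
print.tip_classifier <- function(x, ...) {
  cat(sprintf(
    "<tip_classifier> %d classes (%s), input %dx%d, best validation accuracy %.1f%% at iteration %d\n",
    length(x$class_names), paste(x$class_names, collapse = ", "),
    x$spec$input_side, x$spec$input_side, x$best_val_accuracy, x$best_iteration
  ))
  invisible(x)
}

#' Classify patches with a trained model
#'
#' Normalizes inputs exactly as during training (stored mean colour
#' subtracted, scaled to unit range) and runs the forward pass. Rows come
#' back in input order; each row is a softmax distribution over the
#' model's classes (non-negative, sums to one).
#'
#' @param model A `tip_classifier` from [train_network()].
#' @param patches A patch tibble, a list of arrays, or a single
#'   `side x side x 3` array; sides must equal the model's `input_side`.
#' @return Tibble of class probabilities, one column per class.
#' @export
classify_patches <- function(model, patches) {
  stopifnot(inherits(model, "tip_classifier"))
  if (is.data.frame(patches)) patches <- patches$patch
  if (is.array(patches) && length(dim(patches)) == 3L) patches <- list(patches)
  sides <- vapply(patches, function(p) dim(p)[1L], integer(1L))
  if (any(sides != model$spec$input_side)) {
    abort(sprintf(
      "patch side %d does not match the model input side %d",
      sides[which(sides != model$spec$input_side)[1L]], model$spec$input_side
    ))
  }
  rows <- patches_to_rows(patches, model$mean_color)
  probs <- net_predict_rows(model$params, model$spec, rows, length(patches))
  colnames(probs) <- model$class_names
  as_tibble(probs)
}

# Hash of the canonical JSON form of a spec, stable across a JSON
# round-trip (raw rlang::hash would be sensitive to integer/double storage).
spec_hash <- function(spec) {
  rlang::hash(as.character(jsonlite::toJSON(
    list(layers = spec$layers, input_side = spec$input_side,
         class_names = spec$class_names),
    auto_unbox = TRUE, digits = NA
  )))
}

n_parameters <- function(params) {
  sum(vapply(params, function(p) {
    if (length(p) == 0L) 0L else length(p$W) + length(p$b)
  }, integer(1L)))
}

#' Save a trained classifier
#'
#' Writes the parameter archive (`params.rds`) plus a JSON sidecar holding
#' the architecture, mean colour, class vocabulary, training configuration
#' and a hash of the spec; [load_model()] refuses a checkpoint whose spec
#' hash does not match its parameters.
#'
#' @param model A `tip_classifier`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  sidecar <- list(
    format = "tipscan-model", version = 1L,
    spec = model$spec[c("layers", "input_side", "n_classes", "class_names")],
    spec_hash = spec_hash(model$spec),
    mean_color = unname(model$mean_color),
    class_names = model$class_names,
    config = unclass(model$config),
    best_val_accuracy = model$best_val_accuracy,
    history = model$history
  )
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a classifier saved by [save_model()]
#'
#' @param dir Checkpoint directory.
#' @return A `tip_classifier`.
#' @export
load_model <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "model.json"))
  spec <- network_spec(
    lapply(side$spec$layers, function(l) l),
    input_side = side$spec$input_side,
    class_names = unlist(side$spec$class_names)
  )
  if (!identical(spec_hash(spec), side$spec_hash)) {
    abort("checkpoint sidecar does not match its architecture (spec hash mismatch)")
  }
  params <- readRDS(file.path(dir, "params.rds"))
  cfg_fields <- side$config
  cfg <- do.call(train_config, cfg_fields[setdiff(names(cfg_fields), "mean_color")])
  cfg$mean_color <- unlist(cfg_fields$mean_color)
  structure(
    list(
      spec = spec, params = params, mean_color = unlist(side$mean_color),
      class_names = unlist(side$class_names), config = cfg,
      history = dplyr::bind_rows(lapply(side$history, as_tibble)),
      best_val_accuracy = side$best_val_accuracy %||% NA_real_,
      best_iteration = side$best_iteration %||% NA_integer_
    ),
    class = "tip_classifier"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a classifier
#'
#' @param x A `tip_classifier`.
#' @param ... Unused.
#' @return Tibble with one row per validation check: `iteration`, `lr`,
#'   `train_loss`, `val_accuracy`.
#' @export
tidy.tip_classifier <- function(x, ...) {
  x$history
}

#' One-row summary of a trained classifier
#'
#' @param x A `tip_classifier`.
#' @param ... Unused.
#' @return Tibble with `n_classes`, `input_side`, `n_parameters`,
#'   `iterations`, `best_val_accuracy`.
#' @export
glance.tip_classifier <- function(x, ...) {
  tibble(
    n_classes = length(x$class_names),
    input_side = x$spec$input_side,
    n_parameters = n_parameters(x$params),
    iterations = if (nrow(x$history) > 0L) max(x$history$iteration) else 0L,
    best_val_accuracy = x$best_val_accuracy
  )
}
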