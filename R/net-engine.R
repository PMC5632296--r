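# Minimal CNN engine. Activations for a batch of B square feature maps of
# side s with C channels are held as a (B*s*s) x C matrix whose rows are
# ordered sample-major, then y, then x (x fastest). Valid 3x3 convolution
# is computed im2col-style in compiled code (src/conv_ops.cpp): the
# (B*s_out^2) x 9C patch matrix is assembled and multiplied against the
# (9C x filters) kernel matrix by BLAS; 2x2 max pooling and its backward
# scatter are compiled as well. Inputs are centred on the training-set
# mean colour and scaled to unit range, (x - mean) / 255, before entering
# the network.

init_network_params <- function(spec, seed = 1L) {
  withr::with_seed(seed, {
    c_in <- 3L
    params <- vector("list", length(spec$layers))
    for (li in seq_along(spec$layers)) {
      ly <- spec$layers[[li]]
      if (ly$kind == "conv3x3") {
        sd <- sqrt(2 / (9 * c_in))
        params[[li]] <- list(
          W = matrix(stats::rnorm(9L * c_in * ly$filters, 0, sd), 9L * c_in, ly$filters),
          b = numeric(ly$filters)
        )
        c_in <- ly$filters
      } else if (ly$kind == "fully_connected") {
        sd <- sqrt(2 / c_in)
        params[[li]] <- list(
          W = matrix(stats::rnorm(c_in * ly$units, 0, sd), c_in, ly$units),
          b = numeric(ly$units)
        )
        c_in <- ly$units
      } else {
        params[[li]] <- list()
      }
    }
    params
  })
}

# Forward pass. M: (B*s^2) x 3 normalized input rows.
# Returns list(probs = B x K, caches) — caches only kept when `training`.
net_forward <- function(params, spec, M, B, training = FALSE) {
  s <- spec$input_side
  caches <- if (training) vector("list", length(spec$layers))
  for (li in seq_along(spec$layers)) {
    ly <- spec$layers[[li]]
    if (ly$kind == "conv3x3") {
      fw <- .cpp_conv3_forward(M, params[[li]]$W, params[[li]]$b, B, s,
                               isTRUE(training))
      if (training) caches[[li]] <- list(G = fw$G, s_in = s)
      M <- fw$out
      s <- s - 2L
    } else if (ly$kind == "maxpool2x2") {
      pl <- .cpp_pool2_forward(M, B, s)
      if (training) caches[[li]] <- list(winner = pl$winner, s_in = s)
      M <- pl$out
      s <- s %/% 2L
    } else if (ly$kind == "relu") {
      M <- pmax(M, 0)
      if (training) caches[[li]] <- list(pos = M > 0)
    } else if (ly$kind == "dropout") {
      if (training) {
        keep <- matrix(
          (stats::runif(length(M)) >= ly$rate) / (1 - ly$rate),
          nrow(M), ncol(M)
        )
        M <- M * keep
        caches[[li]] <- list(keep = keep)
      }
    } else if (ly$kind == "fully_connected") {
      if (training) caches[[li]] <- list(input = M)
      M <- sweep(M %*% params[[li]]$W, 2L, params[[li]]$b, "+")
    } else if (ly$kind == "softmax") {
      M <- M - apply(M, 1L, max)
      E <- exp(M)
      M <- E / rowSums(E)
    }
  }
  list(probs = M, caches = caches)
}

# Backward pass from softmax + cross-entropy. `onehot` is B x K.
net_backward <- function(params, spec, fwd, onehot, B) {
  grads <- vector("list", length(spec$layers))
  dM <- (fwd$probs - onehot) / B
  for (li in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[li]]
    cache <- fwd$caches[[li]]
    if (ly$kind == "softmax") {
      next # combined with cross-entropy above
    } else if (ly$kind == "fully_connected") {
      grads[[li]] <- list(
        W = crossprod(cache$input, dM),
        b = colSums(dM)
      )
      dM <- tcrossprod(dM, params[[li]]$W)
    } else if (ly$kind == "dropout") {
      dM <- dM * cache$keep
    } else if (ly$kind == "relu") {
      dM <- dM * cache$pos
    } else if (ly$kind == "maxpool2x2") {
      dM <- .cpp_pool2_backward(dM, cache$winner, B, cache$s_in)
    } else if (ly$kind == "conv3x3") {
      bk <- .cpp_conv3_backward(dM, cache$G, params[[li]]$W, B, cache$s_in)
      grads[[li]] <- list(W = bk$dW, b = as.vector(bk$db))
      dM <- bk$dX
    }
  }
  grads
}

sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (li in seq_along(params)) {
    if (is.null(grads[[li]]) || length(params[[li]]) == 0L) next
    for (nm in c("W", "b")) {
      wd <- if (nm == "W") weight_decay else 0
      g <- grads[[li]][[nm]] + wd * params[[li]][[nm]]
      velocity[[li]][[nm]] <- momentum * velocity[[li]][[nm]] - lr * g
      params[[li]][[nm]] <- params[[li]][[nm]] + velocity[[li]][[nm]]
    }
  }
  list(params = params, velocity = velocity)
}

zero_like <- function(params) {
  lapply(params, function(p) {
    if (length(p) == 0L) list() else list(W = p$W * 0, b = p$b * 0)
  })
}

# Predict class probabilities for normalized input rows; chunks the batch
# to bound gather-index cache size and memory. Returns n x K.
net_predict_rows <- function(params, spec, rows, n, chunk = 256L) {
  per <- nrow(rows) / n
  stopifnot(per == spec$input_side^2)
  out <- matrix(0, n, spec$n_classes)
  start <- 1L
  while (start <= n) {
    b <- min(chunk, n - start + 1L)
    sel <- ((start - 1L) * per + 1L):((start + b - 1L) * per)
    out[start:(start + b - 1L), ] <-
      net_forward(params, spec, rows[sel, , drop = FALSE], b)$probs
    start <- start + b
  }
  out
}

# Flatten a (H, W, C) raster into (H*W) x C engine rows, x fastest.
raster_to_rows <- function(raster) {
  d <- dim(raster)
  matrix(aperm(raster, c(2L, 1L, 3L)), nrow = d[1L] * d[2L], ncol = d[3L])
}

# Stack patch arrays into engine rows and normalize: subtract the mean
# colour (0..255 units) and scale to unit range.
patches_to_rows <- function(patches, mean_color) {
  out <- do.call(rbind, lapply(patches, raster_to_rows))
  out[, 1L] <- (out[, 1L] - mean_color[1L]) / 255
  out[, 2L] <- (out[, 2L] - mean_color[2L]) / 255
  out[, 3L] <- (out[, 3L] - mean_color[3L]) / 255
  out
}
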