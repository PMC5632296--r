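test_that("the root network follows the published architecture", {
  spec <- build_root_network()
  tr <- spatial_trace(spec)
  conv <- tr[tr$kind == "conv3x3", ]
  pool <- tr[tr$kind == "maxpool2x2", ]
  # conv-conv-pool, conv-conv-pool, conv-conv: 32-30-28-14-12-10-5-3-1
  expect_equal(conv$size_out, c(30, 28, 12, 10, 3, 1))
  expect_equal(pool$size_out, c(14, 5))
  expect_equal(tr$size_out[nrow(tr)], 1L)
  expect_equal(conv$channels_out[1], 64L)
  expect_equal(max(conv$channels_out), 256L)
  fc <- tr[tr$kind == "fully_connected", ]
  expect_equal(nrow(fc), 3L)
  expect_equal(fc$channels_out[3], 2L)
  expect_equal(spec$class_names, c("root_tip", "root_negative"))
})

test_that("the shoot network follows the published architecture", {
  spec <- build_shoot_network()
  tr <- spatial_trace(spec)
  conv <- tr[tr$kind == "conv3x3", ]
  pool <- tr[tr$kind == "maxpool2x2", ]
  # groups of 2, 3, 3 convolutions with pooling, one final conv:
  # 64-62-60-30-28-26-24-12-10-8-6-3-1
  expect_equal(conv$size_out, c(62, 60, 28, 26, 24, 10, 8, 6, 1))
  expect_equal(pool$size_out, c(30, 12, 3))
  # every pre-pool spatial size is even
  expect_true(all(pool$size_in %% 2 == 0))
  expect_equal(tr$size_out[nrow(tr)], 1L)
  expect_equal(conv$channels_out[1], 64L)
  expect_equal(max(conv$channels_out), 512L)
  fc <- tr[tr$kind == "fully_connected", ]
  expect_equal(fc$channels_out[3], 5L)
  expect_length(spec$class_names, 5L)
})

test_that("invalid architectures are rejected", {
  expect_error(network_spec(
    list(list(kind = "fully_connected", units = 2), list(kind = "softmax")),
    input_side = 32, class_names = c("a", "b")
  ), "1x1")
  expect_error(network_spec(
    list(list(kind = "dropout", rate = 0.5),
         list(kind = "fully_connected", units = 2), list(kind = "softmax")),
    input_side = 1, class_names = c("a", "b")
  ), "dropout")
  expect_error(network_spec(
    list(list(kind = "conv3x3", filters = 4)),
    input_side = 3, class_names = c("a", "b")
  ), "softmax")
})

test_that("the learning-rate step schedule decays by 10 every 20,000 iterations", {
  cfg <- train_config()
  expect_equal(learning_rate_schedule(cfg, c(0, 19999, 20000, 40000)),
               c(0.1, 0.1, 0.01, 0.001))
})

test_that("classification outputs are normalized probability rows in batch order", {
  model <- make_untrained_model()
  patches <- withr::with_seed(2, lapply(1:7, function(i) {
    array(runif(32 * 32 * 3, 0, 255), dim = c(32, 32, 3))
  }))
  probs <- classify_patches(model, patches)
  expect_equal(dim(probs), c(7L, 2L))
  expect_true(all(as.matrix(probs) >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, 7), tolerance = 1e-6)
  # batch-size invariance: one at a time gives the same rows
  single <- do.call(rbind, lapply(patches, function(p) {
    as.matrix(classify_patches(model, p))
  }))
  expect_equal(as.matrix(probs), single, tolerance = 1e-9)
  expect_error(classify_patches(model, array(0, dim = c(16, 16, 3))),
               "input side")
})

test_that("a zeroed final layer yields uniform class probabilities", {
  model <- make_untrained_model()
  last_fc <- max(which(vapply(model$spec$layers,
                              function(l) l$kind == "fully_connected",
                              logical(1))))
  model$params[[last_fc]]$W[] <- 0
  model$params[[last_fc]]$b[] <- 0
  p <- classify_patches(model, array(100, dim = c(32, 32, 3)))
  expect_equal(unname(as.matrix(p)[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("mean-colour handling matches explicit pre-subtraction", {
  model <- make_untrained_model()
  patch <- withr::with_seed(4, array(runif(32 * 32 * 3, 0, 255),
                                     dim = c(32, 32, 3)))
  zero_mean <- model
  zero_mean$mean_color <- c(0, 0, 0)
  expect_equal(
    as.matrix(classify_patches(model, patch)),
    as.matrix(classify_patches(zero_mean, patch - rep(model$mean_color,
                                                      each = 32 * 32))),
    tolerance = 1e-12
  )
})

test_that("training is deterministic under seed and solves a separable toy task", {
  toy <- get_toy_model()
  expect_gte(toy$model$best_val_accuracy, 99)
  expect_lte(max(toy$model$history$iteration), 500)
  # memorization: the trained model reproduces its own training labels
  sel <- toy$split$train[1:10, ]
  patches <- lapply(sel$patch, tipscan:::prep_patch, 32L, jitter = FALSE)
  probs <- classify_patches(toy$model, patches)
  pred <- toy$model$class_names[max.col(as.matrix(probs))]
  expect_equal(pred, sel$label)

  # a second run with the same seed and data reproduces the history exactly
  ds <- toy_patch_set(30L)
  cfg <- dataset_config("root", rng_seed = 5L)
  sp <- split_dataset(ds, cfg)
  tc <- train_config(initial_lr = 0.01, max_iterations = 60L,
                     check_interval = 30L, batch_size = 16L, rng_seed = 3L)
  spec <- build_root_network(filters_base = 2L)
  m1 <- train_network(spec, sp$train, sp$val, tc)
  m2 <- train_network(spec, sp$train, sp$val, tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("models survive a save/load round trip and reject tampered specs", {
  toy <- get_toy_model()
  dir <- withr::local_tempdir()
  save_model(toy$model, dir)
  back <- load_model(dir)
  patch <- lapply(toy$split$val$patch[1:3], tipscan:::prep_patch, 32L,
                  jitter = FALSE)
  expect_equal(as.matrix(classify_patches(back, patch)),
               as.matrix(classify_patches(toy$model, patch)),
               tolerance = 1e-12)
  expect_equal(back$mean_color, unname(toy$model$mean_color))
  # tamper with the stored architecture
  side <- jsonlite::read_json(file.path(dir, "model.json"))
  side$spec$layers[[1]]$filters <- 99
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(load_model(dir), "hash")
})

test_that("tidy and glance summarise a trained classifier", {
  toy <- get_toy_model()
  td <- tidy(toy$model)
  expect_true(all(c("iteration", "lr", "train_loss", "val_accuracy") %in%
                    names(td)))
  gl <- glance(toy$model)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_classes, 2L)
  expect_gt(gl$n_parameters, 0)
})

test_that("divergent training aborts with a diagnostic", {
  ds <- toy_patch_set(20L)
  cfg <- dataset_config("root", rng_seed = 1L)
  sp <- split_dataset(ds, cfg)
  expect_error(
    train_network(build_root_network(filters_base = 2L), sp$train, sp$val,
                  train_config(initial_lr = 1e7, max_iterations = 200L,
                               check_interval = 100L, batch_size = 8L,
                               rng_seed = 1L)),
    "diverged"
  )
})
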