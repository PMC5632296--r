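# End-to-end orchestration with reproducible configuration. Each stage
# reads and writes documented artifacts under the working directory, so
# simulate -> prepare -> train -> scan -> tips -> traits composes into the
# full pipeline; every run appends the config hash, seed and package
# version to a log. The exported functions are the interface; the thin
# command-line dispatcher in inst/cli/tipscan.R forwards to them.

config_error <- function(msg) abort(msg, class = "tipscan_config_error")
data_error <- function(msg) abort(msg, class = "tipscan_data_error")

#' Default pipeline configuration
#'
#' A nested list with one section per stage; [read_pipeline_config()]
#' merges a YAML file over these defaults, and every stage function takes
#' the merged list. A single global seed drives all randomness.
#'
#' @param domain `"root"` or `"shoot"`.
#' @param work_dir Directory for all artifacts.
#' @param seed Global RNG seed.
#' @return Pipeline configuration list.
#' @export
default_pipeline_config <- function(domain = "root", work_dir = "tipscan-run",
                                    seed = 1L) {
  list(
    domain = domain, work_dir = work_dir, seed = as.integer(seed),
    simulate = list(n_images = 8L, image_width = 256L, image_height = 256L),
    dataset = list(),
    network = list(filters_base = 8L),
    train = list(
      initial_lr = 0.01, lr_decay_interval = 1200L, max_iterations = 1500L,
      check_interval = 250L, batch_size = 64L
    ),
    scan = list(stride = 4L, threshold = 0.5, erode_iterations = 3L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults; unknown top-level
#' fields are rejected.
#'
#' @param path YAML file.
#' @param ... Further overrides applied after the file (e.g. from
#'   command-line flags).
#' @return Pipeline configuration list.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) config_error(sprintf("config file not found: '%s'", path))
  user <- yaml::read_yaml(path)
  base <- default_pipeline_config(
    domain = user$domain %||% "root",
    work_dir = user$work_dir %||% "tipscan-run",
    seed = user$seed %||% 1L
  )
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L) {
    config_error(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(base, user)
  utils::modifyList(cfg, list(...))
}

pipeline_log <- function(config, stage, message) {
  dir.create(config$work_dir, recursive = TRUE, showWarnings = FALSE)
  line <- sprintf(
    "%s\tstage=%s\tconfig=%s\tseed=%d\ttipscan=%s\t%s",
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
    rlang::hash(config[setdiff(names(config), "work_dir")]),
    config$seed, as.character(utils::packageVersion("tipscan")), message
  )
  cat(line, "\n", file = file.path(config$work_dir, "run.log"), append = TRUE)
  invisible(line)
}

p_path <- function(config, ...) file.path(config$work_dir, ...)

require_artifact <- function(config, path, producer) {
  if (!file.exists(path)) {
    data_error(sprintf(
      "missing artifact '%s'; run stage '%s' first", path, producer
    ))
  }
  path
}

dataset_config_from <- function(config) {
  do.call(dataset_config, c(
    list(domain = config$domain), config$dataset,
    if (is.null(config$dataset$rng_seed)) list(rng_seed = config$seed)
  ))
}

#' Pipeline stage: simulate synthetic scenes
#'
#' Generates `config$simulate$n_images` annotated scenes of the configured
#' domain (seeds derived from the global seed) and writes them as a
#' manifest under `work_dir/data`.
#'
#' @param config Pipeline configuration list.
#' @return Manifest path, invisibly.
#' @export
pipeline_simulate <- function(config) {
  sim <- config$simulate
  n <- sim$n_images
  fields <- sim[setdiff(names(sim), "n_images")]
  images <- lapply(seq_len(n), function(i) {
    seed_i <- config$seed * 1000L + i
    if (config$domain == "root") {
      generate_root_image(do.call(root_scene_params, c(fields, list(seed = seed_i))))
    } else {
      generate_shoot_image(do.call(shoot_scene_params, c(fields, list(seed = seed_i))))
    }
  })
  path <- write_manifest(images, p_path(config, "data"))
  pipeline_log(config, "simulate", sprintf("%d image(s) -> %s", n, path))
  invisible(path)
}

#' Pipeline stage: prepare patch datasets
#'
#' Reads the manifest, builds the positive/negative patch dataset and the
#' train/validation split, and stores them under `work_dir`.
#'
#' @param config Pipeline configuration list.
#' @return Path of the stored split, invisibly.
#' @export
pipeline_prepare <- function(config) {
  manifest <- require_artifact(config, p_path(config, "data", "manifest.json"),
                               "simulate")
  images <- read_manifest(manifest)
  cfg <- dataset_config_from(config)
  ds <- build_patch_dataset(images, cfg)
  split <- split_dataset(ds, cfg)
  path <- p_path(config, "patches.rds")
  saveRDS(split, path)
  pipeline_log(config, "prepare", sprintf(
    "%d patches (%d train / %d val) -> %s",
    nrow(ds), nrow(split$train), nrow(split$val), path
  ))
  invisible(path)
}

network_from <- function(config) {
  args <- config$network
  if (config$domain == "root") do.call(build_root_network, args)
  else do.call(build_shoot_network, args)
}

#' Pipeline stage: train the classifier
#'
#' @param config Pipeline configuration list.
#' @return Model directory, invisibly.
#' @export
pipeline_train <- function(config) {
  split <- readRDS(require_artifact(config, p_path(config, "patches.rds"), "prepare"))
  spec <- network_from(config)
  tcfg <- do.call(train_config, c(
    config$train,
    if (is.null(config$train$rng_seed)) list(rng_seed = config$seed)
  ))
  model <- train_network(spec, split$train, split$val, tcfg)
  dir <- p_path(config, "model")
  save_model(model, dir)
  pipeline_log(config, "train", sprintf(
    "best validation accuracy %.2f%% at iteration %d -> %s",
    model$best_val_accuracy, model$best_iteration, dir
  ))
  invisible(dir)
}

#' Pipeline stage: classify the validation patches
#'
#' Writes per-patch class probabilities and the argmax decision as CSV.
#'
#' @param config Pipeline configuration list.
#' @return CSV path, invisibly.
#' @export
pipeline_classify <- function(config) {
  split <- readRDS(require_artifact(config, p_path(config, "patches.rds"), "prepare"))
  model <- load_model(require_artifact(config, p_path(config, "model"), "train"))
  patches <- lapply(split$val$patch, prep_patch, model$spec$input_side,
                    jitter = FALSE)
  probs <- classify_patches(model, patches)
  out <- dplyr::bind_cols(
    split$val[, c("source_image_id", "label", "x", "y")], probs,
    tibble(predicted = model$class_names[max.col(as.matrix(probs), ties.method = "first")])
  )
  path <- p_path(config, "val_predictions.csv")
  readr::write_csv(out, path)
  pipeline_log(config, "classify", sprintf("%d rows -> %s", nrow(out), path))
  invisible(path)
}

#' Pipeline stage: scan all images
#'
#' @param config Pipeline configuration list.
#' @return Directory of stored class maps, invisibly.
#' @export
pipeline_scan <- function(config) {
  manifest <- require_artifact(config, p_path(config, "data", "manifest.json"),
                               "simulate")
  model <- load_model(require_artifact(config, p_path(config, "model"), "train"))
  images <- read_manifest(manifest)
  dir <- p_path(config, "maps")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in images) {
    map <- scan_image(model, img, stride = config$scan$stride)
    saveRDS(map, file.path(dir, paste0(img$image_id, ".rds")))
  }
  pipeline_log(config, "scan", sprintf("%d map(s) -> %s", length(images), dir))
  invisible(dir)
}

#' Pipeline stage: extract tips from the stored maps
#'
#' @param config Pipeline configuration list.
#' @return Tip CSV path, invisibly.
#' @export
pipeline_tips <- function(config) {
  dir <- require_artifact(config, p_path(config, "maps"), "scan")
  files <- list.files(dir, pattern = "\\.rds$", full.names = TRUE)
  if (length(files) == 0L) data_error("no class maps found; run stage 'scan' first")
  feature <- if (config$domain == "root") "root_tip" else "leaf_tip"
  tips <- dplyr::bind_rows(lapply(files, function(f) {
    extract_tips(readRDS(f), feature,
                 threshold = config$scan$threshold,
                 iterations = config$scan$erode_iterations)
  }))
  path <- p_path(config, "tips.csv")
  write_tips(tips, path)
  pipeline_log(config, "tips", sprintf("%d tip(s) -> %s", nrow(tips), path))
  invisible(path)
}

#' Pipeline stage: derive the trait table
#'
#' @param config Pipeline configuration list.
#' @return Trait CSV path, invisibly.
#' @export
pipeline_traits <- function(config) {
  tips <- read_tips(require_artifact(config, p_path(config, "tips.csv"), "tips"))
  if (nrow(tips) == 0L) data_error("tip set is empty; nothing to derive traits from")
  traits <- compute_trait_table(tips)
  path <- p_path(config, "traits.csv")
  write_trait_table(traits, path)
  pipeline_log(config, "traits", sprintf("%d row(s) -> %s", nrow(traits), path))
  invisible(path)
}

#' Pipeline stage: evaluate classification and localization
#'
#' Confusion counts and accuracy on the validation patches, plus per-image
#' localization metrics and tip matching against the manifest ground
#' truth; written as JSON.
#'
#' @param config Pipeline configuration list.
#' @return JSON path, invisibly.
#' @export
pipeline_evaluate <- function(config) {
  split <- readRDS(require_artifact(config, p_path(config, "patches.rds"), "prepare"))
  model <- load_model(require_artifact(config, p_path(config, "model"), "train"))
  maps_dir <- require_artifact(config, p_path(config, "maps"), "scan")
  manifest <- read_manifest(p_path(config, "data", "manifest.json"))
  patches <- split$val
  patches$patch <- lapply(patches$patch, prep_patch, model$spec$input_side,
                          jitter = FALSE)
  counts <- confusion_counts(model, patches)
  feature <- if (config$domain == "root") "root_tip" else "leaf_tip"
  loc <- dplyr::bind_rows(lapply(manifest, function(img) {
    f <- file.path(maps_dir, paste0(img$image_id, ".rds"))
    if (!file.exists(f)) return(NULL)
    map <- readRDS(f)
    truth <- ground_truth_tips(img, feature)
    mask <- threshold_map(map, feature, config$scan$threshold)
    det <- extract_tips(map, feature, config$scan$threshold,
                        config$scan$erode_iterations)
    dplyr::bind_cols(
      tibble(image_id = img$image_id),
      localization_metrics(mask, map, truth),
      match_tips(det, truth, radius = map$window / 2)[, c("recall_pct", "spurious_pct")]
    )
  }))
  report <- list(
    classification = list(
      counts = counts,
      accuracy_pct = classification_accuracy(counts)
    ),
    localization = loc
  )
  path <- p_path(config, "evaluation.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, null = "null")
  pipeline_log(config, "evaluate", sprintf(
    "classification %.2f%% -> %s", report$classification$accuracy_pct, path
  ))
  invisible(path)
}

#' Run pipeline stages in order
#'
#' @param config Pipeline configuration list (see
#'   [default_pipeline_config()]).
#' @param stages Stage names, any subset of `simulate`, `prepare`, `train`,
#'   `classify`, `scan`, `tips`, `traits`, `evaluate`, executed in the
#'   given order.
#' @return Named list of each stage's artifact path, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "prepare", "train", "scan",
                                    "tips", "traits")) {
  runners <- list(
    simulate = pipeline_simulate, prepare = pipeline_prepare,
    train = pipeline_train, classify = pipeline_classify,
    scan = pipeline_scan, tips = pipeline_tips, traits = pipeline_traits,
    evaluate = pipeline_evaluate
  )
  unknown <- setdiff(stages, names(runners))
  if (length(unknown) > 0L) {
    config_error(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- list()
  for (s in stages) out[[s]] <- runners[[s]](config)
  invisible(out)
}
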