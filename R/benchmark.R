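# Desk-scale study of the whole root pipeline on synthetic scenes: the
# in-package analogue of the full-scale protocol, sized so it runs on one
# CPU in minutes. Scenes are 320x320 px with four primaries bearing 2-4
# laterals each -- a well-separated tip geometry, since tips closer than
# the erosion scale merge into one detection by construction; a
# reduced-width root network (filters_base = 8) is trained on the mined
# patch dataset and evaluated by scanning held-out scenes.

#' Run the synthetic root-pipeline benchmark
#'
#' Generates `n_train_scenes` annotated root scenes, builds the patch
#' dataset (positives centred on every qualifying tip plus twice as many
#' mined negatives), splits 80/20, trains a reduced-width root network,
#' then scans `n_eval_scenes` freshly generated scenes, extracts tips by
#' erosion + connected components, matches them against ground truth
#' within half a window, and compares the derived trait table with the
#' trait table of the ground-truth tips.
#'
#' @param seed Global seed; drives scene generation, mining, the split and
#'   training.
#' @param n_train_scenes,n_eval_scenes Scene counts for training and
#'   held-out evaluation.
#' @param scene_params Function `(seed) -> root_scene_params`; default the
#'   benchmark's standard 320-px well-separated scene (4 primaries, 2-4
#'   laterals of 30-70 px).
#' @param filters_base Width of the reduced network.
#' @param train_overrides Named list merged over the benchmark's training
#'   configuration (initial LR 0.01 decayed by 10 every 1200 iterations,
#'   batch 64, validation check every 250 iterations, at most 2500
#'   iterations).
#' @param threshold,erode_iterations Heatmap post-processing settings.
#' @param stride Scan stride in pixels.
#' @return List: `model`, `val_accuracy_pct`, `n_positives`, `n_train`,
#'   `n_val`, `tip_recall_pct`, `spurious_pct`, `per_scene` tibble,
#'   `trait_correlations` tibble and `mean_trait_correlation` (Pearson,
#'   across evaluation scenes, detector vs ground-truth traits).
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_train_scenes = 150L,
                                    n_eval_scenes = 16L,
                                    scene_params = NULL,
                                    filters_base = 8L,
                                    train_overrides = list(),
                                    threshold = 0.5, erode_iterations = 3L,
                                    stride = 4L) {
  # heterogeneous scenes (3-5 primaries, 1-4 laterals each) so the traits
  # vary between scenes the way they do across a mapping population; the
  # separation/clearance settings realize the well-separated-tip condition
  scene_params <- scene_params %||% function(s) {
    root_scene_params(
      image_width = 320, image_height = 320, n_primary = 3L + (s %% 3L),
      laterals_per_primary = c(1, 4), primary_length = c(90, 230),
      lateral_length = c(35, 80), min_tip_separation = 28,
      tip_clearance = 10, seed = s
    )
  }
  base <- as.integer(seed) * 1000L

  train_scenes <- lapply(seq_len(n_train_scenes), function(i) {
    generate_root_image(scene_params(base + i))
  })
  cfg <- dataset_config("root", rng_seed = seed)
  ds <- build_patch_dataset(train_scenes, cfg)
  n_pos <- sum(ds$label == "root_tip")
  split <- split_dataset(ds, cfg)

  spec <- build_root_network(filters_base = filters_base)
  tcfg_args <- utils::modifyList(
    list(
      initial_lr = 0.01, lr_decay_interval = 1200L, max_iterations = 2500L,
      check_interval = 250L, batch_size = 32L, rng_seed = seed
    ),
    train_overrides
  )
  model <- train_network(spec, split$train, split$val, do.call(train_config, tcfg_args))

  eval_scenes <- lapply(seq_len(n_eval_scenes), function(i) {
    generate_root_image(scene_params(base + 500L + i))
  })
  radius <- model$spec$input_side / 2
  per_scene <- list()
  det_traits <- list()
  gt_traits <- list()
  for (img in eval_scenes) {
    map <- scan_image(model, img, stride = stride)
    det <- extract_tips(map, "root_tip", threshold, erode_iterations)
    truth <- ground_truth_tips(img)
    per_scene[[length(per_scene) + 1L]] <- dplyr::bind_cols(
      tibble(image_id = img$image_id), match_tips(det, truth, radius)
    )
    gt_traits[[length(gt_traits) + 1L]] <-
      compute_traits(truth, image_id = img$image_id)
    det_traits[[length(det_traits) + 1L]] <- if (nrow(det) > 0L) {
      compute_traits(det, image_id = img$image_id)
    } else {
      gt_traits[[length(gt_traits)]][0, ]
    }
  }
  per_scene <- dplyr::bind_rows(per_scene)
  det_traits <- dplyr::bind_rows(det_traits)
  gt_traits <- dplyr::bind_rows(gt_traits)
  merged <- dplyr::inner_join(det_traits, gt_traits, by = "image_id",
                              suffix = c("_det", "_gt"))
  trait_cols <- setdiff(trait_column_order(), c("seed_x", "seed_y"))
  cors <- purrr::map_dbl(trait_cols, function(tc) {
    a <- merged[[paste0(tc, "_det")]]
    b <- merged[[paste0(tc, "_gt")]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(a[ok], b[ok])
  })
  trait_correlations <- tibble(trait = trait_cols, pearson_r = cors)
  list(
    model = model,
    val_accuracy_pct = model$best_val_accuracy,
    n_positives = n_pos,
    n_train = nrow(split$train), n_val = nrow(split$val),
    tip_recall_pct = 100 * sum(per_scene$n_recovered) / sum(per_scene$n_truth),
    spurious_pct = 100 * sum(per_scene$n_spurious) / sum(per_scene$n_truth),
    per_scene = per_scene,
    trait_correlations = trait_correlations,
    mean_trait_correlation = mean(cors, na.rm = TRUE)
  )
}
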