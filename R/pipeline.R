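#' Default end-to-end run configuration
#'
#' The full configuration tree with every tunable of the pipeline stages. The
#' defaults define a small, fully synthetic experiment (96 x 96 phantoms,
#' 48 x 48 x 8 stacks, an 8-filter two-block classifier) that exercises every
#' stage in minutes on one CPU; scale the phantom and feature sizes up for the
#' full-resolution geometry (1024 -> 508 x 508 x 8, 16 filters).
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "mammocalc_run",
    phantom = list(width = 96L, height = 96L, pixel_spacing = 0.07,
                   n_spots = 5L, pattern = "scattered", spot_contrast = 0.6,
                   tissue_texture_scale = 24, add_artifacts = FALSE,
                   spot_diameter_min = 0.3, spot_diameter_max = 1.0),
    data = list(n_pos = 32L, n_neg = 32L, n_test = 20L, augment = FALSE),
    split = list(train = 0.70, val = 0.20, test = 0.10),
    features = list(out_side = 48L, glcm_window = 9L, glcm_stride = 8L,
                    gabor_mode = "canonical"),
    cnn = list(n_filters = 8L, kernel_side = 3L, pool_side = 2L,
               n_blocks = 2L, dense_units = 32L),
    train = list(learning_rate = 1e-3, batch_size = 8L, epochs = 20L,
                 dropout = 0.2, l2 = 1e-4),
    localize = list(se_radius = NA, threshold_k = 3, min_area = 1L,
                    match_radius_px = 3, all_images = FALSE)
  ), class = "run_config")
}

#' Validate and normalize a run configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, fills missing
#' values from [default_run_config()], and checks ranges. All violations are
#' collected and reported together, not first-only.
#'
#' @param path YAML file path, or a nested list.
#' @return normalized `run_config`, or an error listing every violation.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path) %||% list()
  } else if (is.null(path)) list() else as.list(path)
  def <- default_run_config()
  errors <- character(0)
  merged <- unclass(def)
  for (key in names(user)) {
    if (!key %in% names(def)) {
      errors <- c(errors, sprintf("unknown key '%s'", key))
      next
    }
    if (is.list(def[[key]])) {
      for (sub in names(user[[key]])) {
        if (!sub %in% names(def[[key]]))
          errors <- c(errors, sprintf("unknown key '%s.%s'", key, sub))
        else merged[[key]][[sub]] <- user[[key]][[sub]]
      }
    } else merged[[key]] <- user[[key]]
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(merged$train$learning_rate > 0, "train.learning_rate must be > 0")
  chk(merged$train$epochs >= 1, "train.epochs must be >= 1")
  chk(merged$train$dropout >= 0 && merged$train$dropout < 1,
      "train.dropout must be in [0, 1)")
  chk(merged$data$n_pos >= 0 && merged$data$n_neg >= 0,
      "data.n_pos and data.n_neg must be non-negative")
  chk(abs(merged$split$train + merged$split$val + merged$split$test - 1) < 1e-9,
      "split fractions must sum to 1")
  chk(merged$phantom$spot_contrast > 0 && merged$phantom$spot_contrast <= 1,
      "phantom.spot_contrast must be in (0, 1]")
  chk(merged$features$out_side >= 8, "features.out_side must be >= 8")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(merged) <- "run_config"
  merged
}

run_phantom_spec <- function(cfg, n_spots, seed) {
  ph <- cfg$phantom
  phantom_spec(width = ph$width, height = ph$height,
               pixel_spacing = ph$pixel_spacing, n_spots = n_spots,
               spot_diameter_range = c(ph$spot_diameter_min,
                                       ph$spot_diameter_max),
               pattern = ph$pattern, spot_contrast = ph$spot_contrast,
               tissue_texture_scale = ph$tissue_texture_scale,
               add_artifacts = ph$add_artifacts, seed = seed)
}

# Generate + preprocess + featurize one phantom; returns stack, truth, image.
phantom_to_stack <- function(cfg, n_spots, seed, bank) {
  ph <- generate_phantom(run_phantom_spec(cfg, n_spots, seed))
  img <- preprocess_pipeline(ph$image, side = cfg$phantom$height,
                             window = NULL,
                             artifact_removal = cfg$phantom$add_artifacts)
  stack <- assemble_feature_stack(img, out_side = cfg$features$out_side,
                                  bank = bank,
                                  glcm_window = cfg$features$glcm_window,
                                  glcm_stride = cfg$features$glcm_stride)
  list(stack = stack, truth = ph$truth, image = img, raw = ph$image)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates a labeled phantom cohort, preprocesses and featurizes it, splits
#' it stratified 70/20/10, trains the convolutional classifier, predicts on a
#' freshly generated held-out test set, computes the evaluation report
#' (confusion matrix, five metrics, ROC/AUC, probability distributions), and
#' localizes deposits on classifier-positive test images (all images if
#' `localize.all_images`). Every stage artifact is written into the run
#' directory with a JSON-lines event log; the run is deterministic in
#' `config$seed`.
#'
#' @param config a `run_config` from [validate_config()] /
#'   [default_run_config()].
#' @return list with `metrics`, `auc`, `confusion`, `history`,
#'   `localization` (pooled spot recall/precision over positive test images),
#'   `predictions`, and `run_dir`.
#' @export
run_end_to_end <- function(config = default_run_config()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "events.jsonl")
  unlink(log_path)
  log_event <- function(stage, ...) {
    rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE)
  }
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    log_event(stage, elapsed_s = round(t1 - t0, 2))
    t0 <<- t1
  }
  yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  log_event("start", seed = cfg$seed,
            package_version = as.character(utils::packageVersion("mammocalc")))

  if (cfg$data$n_pos == 0L || cfg$data$n_neg == 0L)
    stop("training requires both classes: set data.n_pos and data.n_neg > 0")

  bank <- build_gabor_bank(cfg$features$gabor_mode)
  base_seed <- as.integer(cfg$seed)
  seed_for <- function(i) (base_seed + 104729L * i) %% .Machine$integer.max

  labels <- c(rep(1L, cfg$data$n_pos), rep(0L, cfg$data$n_neg))
  items <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    items[[i]] <- phantom_to_stack(cfg, if (labels[i] == 1L) cfg$phantom$n_spots
                                        else 0L, seed_for(i), bank)
  }
  tick("phantom+preprocess+features")

  split <- stratified_split(c(pos = cfg$data$n_pos, neg = cfg$data$n_neg),
                            fractions = c(cfg$split$train, cfg$split$val,
                                          cfg$split$test),
                            seed = base_seed)
  assign_split <- character(length(labels))
  assign_split[labels == 1L] <- as.character(split$assignment$pos)
  assign_split[labels == 0L] <- as.character(split$assignment$neg)
  manifest <- data.frame(id = seq_along(labels), label = labels,
                         split = assign_split)
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  tick("split")

  tr <- which(assign_split == "train")
  va <- which(assign_split == "val")
  if (cfg$data$augment) {
    aug <- list()
    for (i in tr) {
      src <- items[[i]]$raw
      for (a in c(90, 180, 270))
        aug[[length(aug) + 1L]] <- list(
          stack = assemble_feature_stack(rotate_image(src, a),
                                         out_side = cfg$features$out_side,
                                         bank = bank,
                                         glcm_window = cfg$features$glcm_window,
                                         glcm_stride = cfg$features$glcm_stride),
          label = labels[i])
    }
    x_train <- c(lapply(items[tr], `[[`, "stack"),
                 lapply(aug, `[[`, "stack"))
    y_train <- c(labels[tr], vapply(aug, `[[`, integer(1), "label"))
  } else {
    x_train <- lapply(items[tr], `[[`, "stack")
    y_train <- labels[tr]
  }

  s <- cfg$features$out_side
  blocks <- rep(list(c(cfg$cnn$n_filters, cfg$cnn$kernel_side,
                       cfg$cnn$pool_side)), cfg$cnn$n_blocks)
  ccfg <- cnn_config(input_shape = c(s, s, 8L), conv_blocks = blocks,
                     dense_units = cfg$cnn$dense_units)
  model <- build_model(ccfg, seed = base_seed)
  tcfg <- train_config(learning_rate = cfg$train$learning_rate,
                       batch_size = cfg$train$batch_size,
                       epochs = cfg$train$epochs,
                       dropout = cfg$train$dropout, l2 = cfg$train$l2,
                       seed = base_seed)
  model <- train_cnn(model, x_train, y_train,
                     lapply(items[va], `[[`, "stack"), labels[va], tcfg)
  utils::write.csv(model$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  save_model(model, file.path(cfg$out_dir, "model.json"))
  tick("train")

  # fresh held-out test cohort, balanced
  n_test <- as.integer(cfg$data$n_test)
  test_labels <- rep(c(1L, 0L), length.out = n_test)
  test_items <- vector("list", n_test)
  for (i in seq_len(n_test)) {
    test_items[[i]] <- phantom_to_stack(
      cfg, if (test_labels[i] == 1L) cfg$phantom$n_spots else 0L,
      seed_for(10000L + i), bank)
  }
  pred <- predict(model, lapply(test_items, `[[`, "stack"))
  pred$truth <- test_labels
  utils::write.csv(pred, file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)
  tick("predict")

  cm <- confusion(pred$label, pred$truth)
  rep_metrics <- metrics(cm)
  roc <- roc_auc(pred$probability, pred$truth)
  utils::write.csv(roc$curve, file.path(cfg$out_dir, "roc.csv"),
                   row.names = FALSE)
  probability_distribution_export(pred,
                                  file.path(cfg$out_dir, "probabilities.csv"))
  metrics_json <- list(confusion = unclass(cm),
                       metrics = unclass(rep_metrics)[
                         c("recall", "specificity", "precision", "accuracy",
                           "f1")],
                       auc = roc$auc)
  tick("evaluate")

  # localization on classifier-positive test images (per the detection-first
  # design), or every image when forced
  loc_idx <- if (cfg$localize$all_images) seq_len(n_test)
             else which(pred$label == 1L)
  matched <- 0L; total_spots <- 0L; total_cand <- 0L
  se_radius <- if (is.na(cfg$localize$se_radius))
    default_se_radius(cfg$phantom$pixel_spacing) else cfg$localize$se_radius
  loc_dir <- file.path(cfg$out_dir, "candidates")
  dir.create(loc_dir, showWarnings = FALSE)
  for (i in loc_idx) {
    loc <- localize_pipeline(test_items[[i]]$image, se_radius = se_radius,
                             k = cfg$localize$threshold_k,
                             min_area = cfg$localize$min_area)
    write_candidates(loc$candidates,
                     file.path(loc_dir, sprintf("test_%03d.csv", i)))
    if (test_labels[i] == 1L) {
      sc <- localization_score(loc$candidates, test_items[[i]]$truth,
                               match_radius_px = cfg$localize$match_radius_px)
      matched <- matched + nrow(sc$matches)
      total_spots <- total_spots + nrow(test_items[[i]]$truth$spots)
      total_cand <- total_cand + nrow(loc$candidates)
    }
  }
  localization <- list(
    spot_recall = if (total_spots > 0) matched / total_spots else NA_real_,
    candidate_precision = if (total_cand > 0) matched / total_cand else NA_real_,
    matched = matched, total_spots = total_spots,
    total_candidates = total_cand)
  metrics_json$localization <- localization
  jsonlite::write_json(metrics_json, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  tick("localize")
  log_event("done")

  list(metrics = rep_metrics, auc = roc$auc, confusion = cm,
       history = model$history, localization = localization,
       predictions = pred, run_dir = cfg$out_dir)
}
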