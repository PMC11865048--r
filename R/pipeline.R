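#' Pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline; round-trips losslessly
#' through YAML. Unknown keys are hard errors, so typos fail loudly. One
#' global `seed` fans out to per-stage sub-seeds via [derive_seed()].
#'
#' @param n_classes number of seed varieties.
#' @param counts_per_class images generated per class by the synth stage.
#' @param image_size side of generated crops (pixels).
#' @param synth,preprocess,augment,train overrides for the stage settings
#'   (named lists merged over the defaults of [scene_spec()],
#'   [preprocess_config()], [augment_config()], [train_config()]).
#' @param seed global seed.
#' @param ... unknown keys are rejected with a schema error.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_classes = 8L, counts_per_class = rep(12L, n_classes),
                            image_size = 32L, synth = list(),
                            preprocess = list(), augment = list(),
                            train = list(), seed = 0L, ...) {
  extra <- names(list(...))
  if (length(extra))
    stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  cfg <- list(n_classes = as.integer(n_classes),
              counts_per_class = as.integer(counts_per_class),
              image_size = as.integer(image_size),
              synth = synth, preprocess = preprocess, augment = augment,
              train = train, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  known <- c("n_classes", "counts_per_class", "image_size", "synth",
             "preprocess", "augment", "train", "seed")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stopf("unknown config key(s): %s", paste(extra, collapse = ", "))
  if (length(cfg$counts_per_class) != cfg$n_classes)
    stopf("counts_per_class must have n_classes = %d entries", cfg$n_classes)
  sub_known <- list(
    synth = c("background_level", "grid", "class_appearance"),
    preprocess = c("threshold", "min_region_area", "crop_padding", "output_size"),
    augment = c("brightness_factor", "noise_mean", "noise_sd", "mirror_axis",
                "rotation_angle"),
    train = c("epochs", "batch_size", "lr0", "decay_rate", "decay_every",
              "momentum", "weight_decay"))
  for (nm in names(sub_known)) {
    extra <- setdiff(names(cfg[[nm]]), sub_known[[nm]])
    if (length(extra))
      stopf("unknown %s config key(s): %s", nm, paste(extra, collapse = ", "))
  }
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()].
#' @return `read_pipeline_config()` returns a validated config.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(config, stage) {
  derive_seed(config$seed, match(stage, c("synth", "preprocess", "augment",
                                          "split", "train", "evaluate",
                                          "profile", "cam")))
}

#' Run the pipeline end to end (or a subset of stages)
#'
#' Stages: `synth` generates per-class crop images and a manifest; `augment`
#' expands it five-fold on disk; `split` produces stratified 8:1:1 manifests;
#' `train` fits the configured network; `evaluate` writes the test confusion
#' matrix and metrics; `profile` writes the two-variant cost table; `cam`
#' writes a Grad-CAM heatmap for the first test image. Each stage writes its
#' artifacts under `out_dir` and a run re-executed with the same config and
#' seed reproduces identical manifests and profiles. A stage whose input
#' artifact is missing raises a dependency error naming the stage that
#' should have produced it.
#'
#' @param config a [pipeline_config()].
#' @param stages character subset of
#'   `c("synth", "augment", "split", "train", "evaluate", "profile", "cam")`.
#' @param out_dir output directory.
#' @param variant network variant for train/profile stages.
#' @return named list of stage results (invisibly: manifests, history,
#'   metrics, profiles, paths).
#' @export
run_pipeline <- function(config, stages = c("synth", "augment", "split"),
                         out_dir, variant = c("hp", "baseline")) {
  variant <- match.arg(variant)
  stages <- match.arg(stages, c("synth", "augment", "split", "train",
                                "evaluate", "profile", "cam"),
                      several.ok = TRUE)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  write_pipeline_config(config, file.path(out_dir, "config_resolved.yaml"))
  res <- list()
  need <- function(file, producer) {
    if (!file.exists(file))
      stopf("missing artifact '%s': run the '%s' stage first", file, producer)
    file
  }
  if ("synth" %in% stages) {
    spec <- do.call(scene_spec, c(
      list(image_size = rep(config$image_size, 2), n_classes = config$n_classes,
           rng_seed = stage_seed(config, "synth")),
      config$synth))
    res$manifest <- generate_dataset(spec, config$counts_per_class,
                                     file.path(out_dir, "crops"),
                                     seed = stage_seed(config, "synth"))
  }
  if ("augment" %in% stages) {
    mpath <- need(file.path(out_dir, "crops", "manifest.csv"), "synth")
    man <- read.csv(mpath, stringsAsFactors = FALSE)
    acfg <- do.call(augment_config,
                    c(config$augment, list(rng_seed = stage_seed(config, "augment"))))
    res$enhanced <- enhance_dataset(man, acfg, out_dir = file.path(out_dir, "enhanced"))
    write.csv(res$enhanced, file.path(out_dir, "enhanced", "manifest.csv"),
              row.names = FALSE)
  }
  if ("split" %in% stages) {
    mpath <- need(file.path(out_dir, "enhanced", "manifest.csv"), "augment")
    man <- read.csv(mpath, stringsAsFactors = FALSE)
    sp <- split_dataset(man, split_ratios(), seed = stage_seed(config, "split"))
    for (nm in names(sp))
      write.csv(sp[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
    res$splits <- sp
  }
  if ("train" %in% stages) {
    tr <- read.csv(need(file.path(out_dir, "train.csv"), "split"),
                   stringsAsFactors = FALSE)
    va <- read.csv(need(file.path(out_dir, "val.csv"), "split"),
                   stringsAsFactors = FALSE)
    tcfg <- do.call(train_config, c(
      config$train, list(input_size = config$image_size,
                         rng_seed = stage_seed(config, "train"))))
    set.seed(stage_seed(config, "train"))
    model <- build_network(network_spec(config$n_classes, config$image_size,
                                        variant))
    res$fit <- train_model(model, tr, va, tcfg)
    write.csv(res$fit$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
    saveRDS(res$fit$best_model, file.path(out_dir, "best_model.rds"))
    yaml::write_yaml(list(variant = variant, n_classes = config$n_classes,
                          input_size = config$image_size,
                          best_epoch = res$fit$best_epoch,
                          class_levels = res$fit$class_levels),
                     file.path(out_dir, "best_model_spec.yaml"))
  }
  if ("evaluate" %in% stages) {
    if (is.null(res$fit)) stopf("the 'evaluate' stage needs 'train' in the same run")
    te <- read.csv(need(file.path(out_dir, "test.csv"), "split"),
                   stringsAsFactors = FALSE)
    pr <- predict_manifest(res$fit$best_model, te, res$fit$class_levels,
                           input_size = config$image_size)
    cm <- confusion_matrix(pr$pred, pr$truth,
                           n_classes = length(res$fit$class_levels))
    res$metrics <- metrics_from_confusion(cm)
    res$confusion <- cm
    write.csv(as.data.frame(unclass(cm)), file.path(out_dir, "confusion.csv"))
    write.csv(res$metrics$per_class, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
  }
  if ("profile" %in% stages) {
    res$profile <- profile_variants(config$n_classes, 224L,
                                    seed = stage_seed(config, "profile"))
    write.csv(res$profile, file.path(out_dir, "profile.csv"), row.names = FALSE)
  }
  if ("cam" %in% stages) {
    if (is.null(res$fit)) stopf("the 'cam' stage needs 'train' in the same run")
    te <- read.csv(need(file.path(out_dir, "test.csv"), "split"),
                   stringsAsFactors = FALSE)
    img <- read_image(te$path[1])
    cls <- match(te$label[1], res$fit$class_levels)
    hm <- grad_cam(res$fit$best_model, img, cls)
    png::writePNG(hm, file.path(out_dir, "gradcam.png"))
    res$cam <- hm
  }
  invisible(res)
}
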