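# End-to-end drivers: simulate/load -> train -> reconstruct -> fuse ->
# segment -> evaluate, plus the canned experiments (threshold sweep,
# fusion-strategy comparison, epoch effect, RGB-pair ablation).

#' Assemble a pipeline configuration
#'
#' @param n_scenes number of synthetic scenes (train + test).
#' @param scene named list of [scene_spec()] overrides; entries may be
#'   `c(lo, hi)` ranges sampled per scene.
#' @param variant,width,depth,heads model settings, see [sr_model()].
#' @param epochs,batch_size,learning_rate,crop_size training settings,
#'   see [sr_train()].
#' @param fusion list: `strategy` (`"vi"`, `"weight"` or `"rgb_pair"`) and
#'   its parameters (`band_i`/`band_j`, `weights`, or `pair`).
#' @param threshold list: `mode` (`"fixed"`/`"adaptive"`) plus `t` or
#'   `s_l`/`s_h`/`phi_l`/`phi_h`; `NULL` picks the scale's default.
#' @param split_ratio train fraction.
#' @param checkpoint which trained weights to deploy, see
#'   [predict.sr_fit()].
#' @param seed master seed; every stochastic stage derives a sub-seed
#'   from it.
#' @param out_dir optional run directory for artifacts.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_scenes = 60L, scene = list(),
                            variant = "srcnet", width = NULL, depth = NULL,
                            heads = 1L, epochs = 10L, batch_size = 16L,
                            learning_rate = 2e-3, crop_size = 32L,
                            fusion = list(strategy = "vi"),
                            threshold = NULL, split_ratio = 0.9,
                            checkpoint = "best_seg", seed = 1L,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full weakly supervised segmentation pipeline
#'
#' Simulates paired scenes, trains the configured reconstruction model on
#' the train split, reconstructs the test split, fuses, segments and
#' evaluates against the generator's ground-truth masks.  With an
#' `out_dir`, masks (PNG), fused maps (TIFF), the history (CSV), the
#' report (JSON) and a resolved-config snapshot with a content hash are
#' written.  Deterministic stages are bitwise-reproducible under the same
#' config.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a list: `report` (aggregate `seg_report`), `per_image` reports,
#'   `fit` (the `sr_fit`), `masks`, `config`, `dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_log <- list()
  stage <- function(name, expr) {
    if (verbose) cat("[vegsr] stage:", name, "\n")
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_log[[name]] <<- round(proc.time()[3] - t0, 3)
    out
  }
  scenes <- stage("simulate",
                  simulate_scenes(config$n_scenes, config$scene,
                                  seed = derive_seed(config$seed, "simulate")))
  n <- length(scenes)
  n_train <- round(config$split_ratio * n)
  idx <- stage("split", with_seed(derive_seed(config$seed, "split"),
                                  sample.int(n, n_train)))
  train <- scenes[idx]
  test <- scenes[-idx]
  fit <- stage("train", {
    model <- sr_model(config$variant, config$width, config$depth,
                      config$heads, seed = derive_seed(config$seed, "init"))
    sr_train(model, train, epochs = config$epochs,
             batch_size = config$batch_size,
             learning_rate = config$learning_rate,
             crop_size = config$crop_size,
             seed = derive_seed(config$seed, "train"),
             eval_data = test, verbose = verbose)
  })
  strat <- config$fusion$strategy %||% "vi"
  out <- stage("reconstruct/fuse/segment", lapply(test, function(s) {
    fusedm <- switch(strat,
      vi = fuse_vi(predict(fit, s$rgb, checkpoint = config$checkpoint),
                   config$fusion$band_i %||% "nir",
                   config$fusion$band_j %||% "green"),
      weight = fuse_weight(predict(fit, s$rgb, checkpoint = config$checkpoint),
                           config$fusion$weights %||% c(-1, 0, 1, 1)),
      rgb_pair = fuse_rgb_pair(s$rgb, config$fusion$pair %||% "GB"),
      stop("unknown fusion strategy: ", strat))
    mask <- if (is.null(config$threshold)) segment(fusedm)
            else do.call(segment, c(list(map = fusedm), config$threshold))
    list(fused = fusedm, mask = mask, gt = s$mask, id = s$rgb$id)
  }))
  per_image <- stage("evaluate",
                     lapply(out, function(o) confusion_miou(o$mask, o$gt)))
  report <- aggregate_seg(per_image)
  res <- list(report = report, per_image = per_image, fit = fit,
              masks = lapply(out, `[[`, "mask"), config = config,
              dir = config$out_dir)
  if (!is.null(config$out_dir)) stage("write", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (o in out) {
      write_mask(o$mask, file.path(config$out_dir, paste0(o$id, "_pred.png")))
      tiff::writeTIFF(pmin(pmax(o$fused$values, 0), 1) * 0 +  # float page
                        (o$fused$values - min(o$fused$values)) /
                        max(1e-12, diff(range(o$fused$values))),
                      file.path(config$out_dir, paste0(o$id, "_fused.tif")),
                      bits.per.sample = 32L)
    }
    utils::write.csv(fit$history,
                     file.path(config$out_dir, "history.csv"),
                     row.names = FALSE)
    snap <- unclass(config)
    snap$out_dir <- NULL
    snap_json <- jsonlite::toJSON(snap, auto_unbox = TRUE, digits = NA,
                                  force = TRUE)
    jsonlite::write_json(
      list(config = snap, config_hash = fnv1a(as.character(snap_json)),
           miou = report$miou, pa = report$pa, mpa = report$mpa,
           seed = config$seed,
           r_version = as.character(getRversion()),
           vegsr_version = as.character(utils::packageVersion("vegsr")),
           stage_seconds = stage_log),
      file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  })
  res$stage_seconds <- stage_log
  res
}

#' Run a canned experiment
#'
#' * `"threshold_sweep"`: trains the configured model, then scores the
#'   test scenes across a threshold grid (columns `t`, `miou`, `pa`,
#'   `mpa`).
#' * `"fusion_compare"`: VI-based vs weight-based fusion with the
#'   empirical adaptive-threshold constants, on mixed scenes containing
#'   vegetation, soil and mulch film (ground-truth spectra by default, so
#'   the comparison isolates the fusion strategies).
#' * `"epoch_effect"`: trains once per seed with per-epoch segmentation
#'   evaluation, with and without strong noise, and records the best-loss
#'   vs best-segmentation epochs.
#' * `"ablation"`: full SR pipeline (train split -> model -> VI fusion)
#'   against the three direct RGB channel-pair fusions on the same test
#'   scenes.
#'
#' @param name experiment name.
#' @param seed master seed.
#' @param out_dir optional directory for CSV (and plot) artifacts.
#' @param plot write PNG plots alongside the CSV (needs `out_dir`).
#' @param ... experiment-specific overrides, see the individual
#'   `experiment_*` functions.
#' @return the experiment's result data frame.
#' @export
run_experiment <- function(name = c("threshold_sweep", "fusion_compare",
                                    "epoch_effect", "ablation"),
                           seed = 1L, out_dir = NULL, plot = FALSE, ...) {
  name <- match.arg(name)
  res <- switch(name,
    threshold_sweep = experiment_threshold_sweep(seed = seed, ...),
    fusion_compare = experiment_fusion_compare(seed = seed, ...),
    epoch_effect = experiment_epoch_effect(seed = seed, ...),
    ablation = experiment_ablation(seed = seed, ...))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    if (plot && name == "threshold_sweep") {
      grDevices::png(file.path(out_dir, paste0(name, ".png")), 600, 400)
      graphics::plot(res$t, res$miou, type = "b", xlab = "threshold t",
                     ylab = "MIoU", main = "VI threshold sweep")
      grDevices::dev.off()
    }
    if (plot && name == "epoch_effect") {
      grDevices::png(file.path(out_dir, paste0(name, ".png")), 600, 400)
      graphics::boxplot(best_seg_epoch - best_loss_epoch ~ arm, data = res,
                        ylab = "seg-best epoch - loss-best epoch")
      grDevices::dev.off()
    }
  }
  res
}

#' Threshold-sweep experiment
#'
#' @param seed master seed.
#' @param grid threshold grid.
#' @param config pipeline config used to obtain reconstructions.
#' @return mean metrics per threshold over the test scenes.
#' @export
experiment_threshold_sweep <- function(seed = 1L,
                                       grid = seq(0, 0.4, by = 0.05),
                                       config = NULL) {
  config <- config %||% pipeline_config(
    n_scenes = 40L, scene = list(height = 48L, width = 48L,
                                 target_veg_fraction = c(0.2, 0.4)),
    epochs = 6L, crop_size = 24L, seed = seed)
  config$seed <- seed
  run <- run_pipeline(config)
  scenes <- simulate_scenes(config$n_scenes, config$scene,
                            seed = derive_seed(seed, "simulate"))
  # re-derive the test split used by run_pipeline
  n <- length(scenes)
  idx <- with_seed(derive_seed(seed, "split"),
                   sample.int(n, round(config$split_ratio * n)))
  test <- scenes[-idx]
  rows <- lapply(grid, function(t) {
    reps <- lapply(test, function(s) {
      fusedm <- fuse_vi(predict(run$fit, s$rgb, checkpoint = "best_seg"))
      confusion_miou(segment_fixed(fusedm, t), s$mask)
    })
    agg <- aggregate_seg(reps)
    data.frame(t = t, miou = agg$miou, pa = agg$pa, mpa = agg$mpa)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_t") <- out$t[which.max(out$miou)]
  out
}

#' Fusion-strategy comparison on mixed scenes
#'
#' @param seed master seed.
#' @param n_scenes scenes per run.
#' @param use_sr reconstruct spectra with a trained model instead of using
#'   the generator's ground-truth spectra.
#' @param fit trained `sr_fit` (required when `use_sr = TRUE`).
#' @return one row per strategy with mean MIoU/PA/MPA.
#' @export
experiment_fusion_compare <- function(seed = 1L, n_scenes = 20L,
                                      use_sr = FALSE, fit = NULL) {
  scenes <- simulate_scenes(
    n_scenes,
    list(layout = "mixed", target_veg_fraction = c(0.2, 0.4),
         film_fraction = c(0.10, 0.20)),
    seed = derive_seed(seed, "fusion_compare"))
  spectra <- lapply(scenes, function(s) {
    if (use_sr) {
      if (is.null(fit)) stop("use_sr = TRUE needs a fitted model")
      predict(fit, s$rgb, checkpoint = "best_seg")
    } else s$spectral_clean
  })
  score <- function(masks) {
    agg <- aggregate_seg(Map(function(m, s) confusion_miou(m, s$mask),
                             masks, scenes))
    c(miou = agg$miou, pa = agg$pa, mpa = agg$mpa)
  }
  vi <- score(lapply(spectra, function(sp) segment(fuse_vi(sp), t = 0.2)))
  wt <- score(lapply(spectra, function(sp) segment(fuse_weight(sp))))
  data.frame(strategy = c("vi", "weight"),
             miou = c(vi["miou"], wt["miou"]),
             pa = c(vi["pa"], wt["pa"]),
             mpa = c(vi["mpa"], wt["mpa"]))
}

#' Epoch-vs-segmentation experiment (strong-noise pathology)
#'
#' For each seed, trains the model on misaligned spectral targets
#' (`strong_noise_px` per-band translation) with per-epoch segmentation
#' evaluation, and again on aligned targets as a control arm.  Records for
#' each run the epoch minimising the reconstruction loss, the epoch
#' maximising segmentation MIoU, and the MIoU attained at both.
#'
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param n_seeds independent replicates.
#' @param strong_noise_px misalignment magnitude of the noisy arm.
#' @param control also run the 0 px control arm.
#' @param n_scenes,size,epochs scale of each run.
#' @param variant model variant (the attention model is the cheap default).
#' @return one row per (seed, arm).
#' @export
experiment_epoch_effect <- function(seed = 1L, n_seeds = 5L,
                                    strong_noise_px = 3, control = TRUE,
                                    n_scenes = 24L, size = 48L,
                                    epochs = 15L, variant = "sranet") {
  arms <- c(noisy = strong_noise_px, if (control) c(clean = 0))
  rows <- list()
  for (r in seq_len(n_seeds)) {
    s <- seed + r - 1L
    for (arm in names(arms)) {
      scenes <- simulate_scenes(
        n_scenes, list(height = size, width = size,
                       target_veg_fraction = c(0.2, 0.4),
                       strong_noise_px = arms[[arm]]),
        seed = derive_seed(s, paste0("epoch_effect_", arm)))
      n_train <- round(0.75 * n_scenes)
      idx <- with_seed(derive_seed(s, "ee_split"),
                       sample.int(n_scenes, n_train))
      fit <- sr_train(sr_model(variant, seed = derive_seed(s, "ee_init")),
                      scenes[idx], epochs = epochs, batch_size = 8L,
                      crop_size = 24L,
                      seed = derive_seed(s, "ee_train"),
                      eval_data = scenes[-idx], eval_max = 6L,
                      eval_segmentation_every = 1L)
      h <- fit$history
      e_loss <- select_checkpoint(h, "reconstruction")
      e_seg <- select_checkpoint(h, "segmentation")
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, arm = arm,
        best_loss_epoch = e_loss, best_seg_epoch = e_seg,
        miou_at_loss_best = h$seg_miou[h$epoch == e_loss],
        miou_at_seg_best = h$seg_miou[h$epoch == e_seg])
    }
  }
  do.call(rbind, rows)
}

#' SR pipeline vs direct RGB-pair fusion (ablation)
#'
#' Trains the convolutional reconstruction model on synthetic pairs, then
#' scores on held-out scenes (a) the full pipeline — reconstruction, NIR
#' vs green vegetation-index fusion, fixed threshold — against (b) the
#' same index applied directly to each RGB channel pair (GB, RB, RG),
#' skipping reconstruction.
#'
#' @param seed master seed.
#' @param n_train,n_test train/held-out scene counts.
#' @param size scene side in pixels.
#' @param epochs training epochs.
#' @param variant model variant.
#' @param t fixed threshold used for every method.
#' @return one row per method (`sr`, `GB`, `RB`, `RG`) with mean MIoU.
#' @export
experiment_ablation <- function(seed = 1L, n_train = 180L, n_test = 20L,
                                size = 64L, epochs = 8L,
                                variant = "srcnet", t = 0.2) {
  scenes <- simulate_scenes(
    n_train + n_test,
    list(height = size, width = size, target_veg_fraction = c(0.2, 0.4)),
    seed = derive_seed(seed, "ablation_scenes"))
  idx <- with_seed(derive_seed(seed, "ablation_split"),
                   sample.int(length(scenes), n_train))
  train <- scenes[idx]
  test <- scenes[-idx]
  fit <- sr_train(sr_model(variant, seed = derive_seed(seed, "ablation_init")),
                  train, epochs = epochs, batch_size = 16L, crop_size = 16L,
                  seed = derive_seed(seed, "ablation_train"),
                  eval_data = test, eval_max = 4L)
  score <- function(mask_fn) {
    agg <- aggregate_seg(lapply(test, function(s)
      confusion_miou(mask_fn(s), s$mask)))
    agg$miou
  }
  sr_miou <- score(function(s)
    segment_fixed(fuse_vi(predict(fit, s$rgb, checkpoint = "best_seg")), t))
  pair_miou <- vapply(c("GB", "RB", "RG"), function(p)
    score(function(s) segment_fixed(fuse_rgb_pair(s$rgb, p), t)), numeric(1))
  data.frame(method = c("sr", names(pair_miou)),
             miou = c(sr_miou, unname(pair_miou)))
}
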