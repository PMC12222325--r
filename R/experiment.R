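#' Run a full few-shot detection experiment
#'
#' End-to-end reproducible pipeline: generate (or reuse) a synthetic
#' dataset, split it 8:2 into train/test, derive a base/novel class split,
#' train the base detector on base classes (cached: re-running with the same
#' `out_dir` resumes from the saved base checkpoint), then for every
#' (shot, seed) pair sample a balanced K-shot set, fine-tune with the full
#' multi-task objective and evaluate bAP50/nAP50/mAP50 on the test set.
#' Per-iteration loss components are logged to CSV per run, a resolved
#' configuration snapshot is written next to the outputs, and the summary
#' reports mean, standard deviation and a t-based 95% confidence interval
#' per shot over seeds.
#'
#' @param out_dir Output root (created if needed).
#' @param spec A [scene_spec()] describing the synthetic data.
#' @param class_profile Per-class image counts (defaults to a mildly
#'   imbalanced profile around 24 images per class).
#' @param n_base Number of base classes.
#' @param shots Integer vector of shot counts (e.g. `c(3, 5, 10)`).
#' @param seeds Integer vector of fine-tuning seeds.
#' @param ratio Train fraction of the train/test split.
#' @param base_cfg,ft_cfg [train_config()]s for the two stages.
#' @param model_cfg A [model_config()].
#' @param use_fam,use_scl Ablation switches for the fine-tuning stage.
#' @param data_seed Seed for data generation, the class split and base
#'   training.
#' @return List with `runs` (per-run tibble: shot, seed, bap, nap, map),
#'   `summary` (per-shot tibble from [summarize_runs()]), `split`, and the
#'   output paths.
#' @export
run_experiment <- function(out_dir,
                           spec = scene_spec(n_classes = 6),
                           class_profile = NULL,
                           n_base = 4,
                           shots = 10,
                           seeds = 0:2,
                           ratio = 0.8,
                           base_cfg = train_config(lr = 0.1, iters = 600,
                                                   eval_interval = 300,
                                                   batch_size = 4),
                           ft_cfg = train_config(lr = 0.05, iters = 300,
                                                 lr_schedule = "cosine",
                                                 eval_interval = 100,
                                                 batch_size = 4),
                           model_cfg = model_config(image_size = spec$image_size[1]),
                           use_fam = TRUE, use_scl = TRUE,
                           data_seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(class_profile)) {
    class_profile <- with_seed(derive_seed(data_seed, "profile"),
                               sample(18:30, spec$n_classes, replace = TRUE))
  }
  data_dir <- file.path(out_dir, "data")
  manifest_path <- file.path(data_dir, "annotations.json")
  manifest <- if (file.exists(manifest_path)) {
    read_coco(manifest_path, root = data_dir)
  } else {
    generate_dataset(spec, class_profile, data_dir, seed = data_seed)
  }
  tt <- split_train_test(manifest, ratio = ratio, seed = derive_seed(data_seed, "split"))
  split <- make_split(manifest$categories$category_id, n_base,
                      seed = derive_seed(data_seed, "classes"))
  write_split(split, file.path(out_dir, "class_split.yaml"))
  # resolved-config snapshot next to the outputs
  yaml::write_yaml(list(
    n_classes = spec$n_classes, image_size = spec$image_size,
    class_profile = class_profile, n_base = n_base, shots = shots,
    seeds = seeds, ratio = ratio, data_seed = data_seed,
    use_fam = use_fam, use_scl = use_scl,
    base = unclass(base_cfg), finetune = unclass(ft_cfg)
  ), file.path(out_dir, "run_config.yaml"))

  base_ckpt <- file.path(out_dir, "base_checkpoint.rds")
  if (file.exists(base_ckpt)) {
    base_model <- load_checkpoint(base_ckpt)
  } else {
    base_cfg$seed <- derive_seed(data_seed, "base")
    model <- init_detector(model_cfg, split$base, seed = data_seed)
    base_model <- train_base(model, tt$train, base_cfg,
                             val_manifest = subset_base(tt$test, split$base))
    save_checkpoint(base_model, base_ckpt)
    utils::write.csv(base_model$history,
                     file.path(out_dir, "base_loss_log.csv"),
                     row.names = FALSE)
  }

  runs <- list()
  for (K in shots) {
    sc <- shot_config(K)
    for (sd_i in seeds) {
      ft_cfg_i <- ft_cfg
      ft_cfg_i$seed <- derive_seed(data_seed, paste0("ft", K, "_", sd_i))
      run_id <- sprintf("shot%d_seed%d", K, sd_i)
      res <- tryCatch({
        ks <- sample_kshot(tt$train, split, K,
                           seed = derive_seed(sd_i, paste0("kshot", K)))
        ft <- finetune(base_model, ks, split, sc, ft_cfg_i,
                       val_manifest = tt$test,
                       use_fam = use_fam, use_scl = use_scl)
        utils::write.csv(ft$history,
                         file.path(out_dir, paste0("loss_", run_id, ".csv")),
                         row.names = FALSE)
        dets <- detect(ft, tt$test)
        ev <- suppressWarnings(evaluate_detections(dets, tt$test))
        sm <- suppressWarnings(split_map(ev, split))
        dplyr::mutate(sm, shot = K, seed = sd_i, .before = 1)
      }, error = function(e) {
        warn(sprintf("run %s failed: %s", run_id, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) runs[[length(runs) + 1L]] <- res
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- summarize_runs(runs)
  utils::write.csv(runs, file.path(out_dir, "runs.csv"), row.names = FALSE)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  list(runs = runs, summary = summary, split = split, out_dir = out_dir,
       train = tt$train, test = tt$test)
}

subset_base <- function(manifest, base_ids) {
  keep <- unique(manifest$annotations$image_id[
    manifest$annotations$category_id %in% base_ids])
  m <- subset_manifest(manifest, keep)
  m$annotations <- m$annotations[m$annotations$category_id %in% base_ids, ]
  m
}

#' Summarize repeated runs per shot
#'
#' Mean, standard deviation, standard error, and a t-based confidence
#' interval (t quantile with k-1 degrees of freedom over k seeds, margin of
#' error `t * SE`) for each metric, per shot.
#'
#' @param runs Tibble with columns `shot`, `seed` and metric columns
#'   (`bap`, `nap`, `map`).
#' @param level Confidence level (default 0.95).
#' @return Tibble with one row per (shot, metric).
#' @export
summarize_runs <- function(runs, level = 0.95) {
  if (nrow(runs) == 0) return(tibble())
  runs |>
    tidyr::pivot_longer(cols = c("bap", "nap", "map"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$shot, .data$metric) |>
    dplyr::summarise(
      k = dplyr::n(),
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() > 1, sd(.data$value), NA_real_),
      .groups = "drop") |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$k),
      moe = ifelse(.data$k > 1,
                   qt(1 - (1 - level) / 2, df = .data$k - 1) * .data$se,
                   NA_real_),
      ci_lo = .data$mean - .data$moe,
      ci_hi = .data$mean + .data$moe)
}
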