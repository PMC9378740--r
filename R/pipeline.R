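# End-to-end pipeline: label -> resample -> shapelets -> stacked ensemble;
# frames -> CNN; ELM fusion. Every artifact records the master seed and a
# config hash; all randomness is derived from the master seed so repeated
# runs are byte-identical.

#' Pipeline configuration
#'
#' @param gaze_csv,meta_csv,frames_dir input paths (see [generate_dataset()]
#'   for the formats)
#' @param out_dir output directory for artifacts
#' @param series_len resampled gaze series length (default 600)
#' @param shapelet_k shapelets to keep (default 10)
#' @param max_candidates candidate cap per extraction (default 500)
#' @param measure shapelet quality measure (default `info_gain`)
#' @param resolution image input side (default 32 for the CPU backbone)
#' @param epochs CNN epochs (default 8)
#' @param n_hidden ELM hidden nodes for the fusion stage (default 10). The
#'   reference configuration of 20 nodes was solved against several hundred
#'   training samples; with the minimum-norm least-squares solve, hidden
#'   width close to the training-set size interpolates label noise, so the
#'   pipeline keeps the width several times below the expected number of
#'   training trials. [elm_train()] itself defaults to 20.
#' @param mode ensemble fusion mode (default `stacking`)
#' @param train_fraction trial-level training fraction (default 2/3)
#' @param n_runs repeated evaluation runs (default 1)
#' @param seed master seed
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(gaze_csv, meta_csv, frames_dir, out_dir,
                            series_len = 600, shapelet_k = 10,
                            max_candidates = 500, measure = "info_gain",
                            resolution = 32, epochs = 8, n_hidden = 10,
                            mode = "stacking", train_fraction = 2 / 3,
                            n_runs = 1, seed = 1) {
  structure(list(gaze_csv = gaze_csv, meta_csv = meta_csv,
                 frames_dir = frames_dir, out_dir = out_dir,
                 series_len = series_len, shapelet_k = shapelet_k,
                 max_candidates = max_candidates, measure = measure,
                 resolution = resolution, epochs = epochs,
                 n_hidden = n_hidden, mode = mode,
                 train_fraction = train_fraction, n_runs = n_runs,
                 seed = seed),
            class = "pipeline_config")
}

# hash of the scientific configuration; output location excluded so reruns
# into different directories carry the same hash
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  derive_seed(1, paste(deparse(cfg), collapse = ""))
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

load_labeled_inputs <- function(cfg) {
  recs <- read_gaze_csv(cfg$gaze_csv)
  recs <- filter_by_detection(recs)$kept
  meta <- read_trial_meta(cfg$meta_csv)
  ids <- vapply(recs, function(r) r$trial_id, character(1))
  meta <- meta[match(ids, meta$trial_id), , drop = FALSE]
  if (anyNA(meta$trial_id)) stop("metadata missing for some gaze trials")
  scores <- peg_score(meta$duration_s, meta$drops)
  labels <- cluster_skill_levels(scores, seed = derive_seed(cfg$seed, "kmeans"))
  list(recs = recs, meta = meta, ids = ids, scores = scores,
       labels = as.character(labels))
}

#' Run the full two-branch pipeline once
#'
#' Labels the trials from their scores, builds both branches on a shared
#' stratified trial-level split, fuses their probabilities with an ELM and
#' scores the held-out trials.
#'
#' @param cfg a [pipeline_config()]
#' @param seed run seed (defaults to the config master seed)
#' @param inputs optional preloaded result of the internal loader, to avoid
#'   re-reading files across repeated runs
#' @return list with branch and fused outcomes, accuracies, confusion
#'   matrix, shapelets, models and the split
#' @export
run_pipeline_once <- function(cfg, seed = cfg$seed, inputs = NULL) {
  if (is.null(inputs)) inputs <- load_labeled_inputs(cfg)
  ids <- inputs$ids; labels <- inputs$labels
  classes <- if (all(labels %in% SKILL_LEVELS)) SKILL_LEVELS else
    sort(unique(labels))
  sp <- stratified_split(labels, cfg$train_fraction,
                         derive_seed(seed, "split"))
  train_ids <- ids[sp$train]; test_ids <- ids[sp$test]

  # --- time-series branch ---
  sset <- gaze_to_series_set(inputs$recs, cfg$series_len)
  tr_set <- series_set(sset$x[sp$train, , drop = FALSE],
                       sset$y[sp$train, , drop = FALSE], train_ids)
  shapelets <- extract_shapelets(tr_set, labels[sp$train], k = cfg$shapelet_k,
                                 measure = cfg$measure,
                                 max_candidates = cfg$max_candidates,
                                 seed = derive_seed(seed, "shapelets"))
  features <- shapelet_transform(sset, shapelets)
  ens_cfg <- stacked_config(mode = cfg$mode,
                            seed = derive_seed(seed, "ensemble"))
  ens <- train_stacked(features[sp$train, , drop = FALSE], labels[sp$train],
                       ens_cfg)
  ts_all <- predict_stacked(ens, features)
  # honest training-trial probabilities for fusion: the stacked model's
  # out-of-fold predictions (no base model saw its own row)
  ts_train_honest <- classifier_outcome(train_ids, ens$oof_probs,
                                        ens$classes)

  # --- image branch ---
  frame_dirs <- file.path(cfg$frames_dir, ids)
  names(frame_dirs) <- ids
  counts <- table(factor(labels, levels = classes))
  rates <- balance_capture_rates(as.numeric(counts))
  names(rates) <- names(counts)
  frameset <- extract_frames(frame_dirs, labels, rates,
                             resolution = cfg$resolution)
  img_cfg <- image_model_config(resolution = cfg$resolution,
                                epochs = cfg$epochs,
                                train_fraction = cfg$train_fraction,
                                seed = derive_seed(seed, "cnn"))
  img_model <- train_image_classifier(frameset, img_cfg,
                                      train_trials = train_ids)
  img_all <- predict_image_trials(img_model, frameset, trials = ids)

  # --- ELM fusion ---
  # Fusion training features mix honesty with distribution match: the ts
  # block uses the stacked model's out-of-fold probabilities, while the img
  # block uses the deployed network's own training-trial probabilities
  # (cross-fitted CNNs at this scale are much weaker than the deployed one
  # and produce features the test-time network never emits).
  img_train <- img_all[match(train_ids, img_all$trial_id), , drop = FALSE]
  Xf_train <- build_fusion_features(ts_train_honest, img_train)
  elm <- elm_train(Xf_train, labels[sp$train], n_hidden = cfg$n_hidden,
                   seed = derive_seed(seed, "elm"))
  ts_test <- ts_all[match(test_ids, ts_all$trial_id), , drop = FALSE]
  img_test <- img_all[match(test_ids, img_all$trial_id), , drop = FALSE]
  Xf_test <- build_fusion_features(ts_test, img_test)
  fused <- elm_predict(elm, Xf_test)

  truth_test <- labels[sp$test]
  conf <- confusion_matrix(truth_test, fused$label, classes = classes)
  list(seed = seed,
       split = list(train = train_ids, test = test_ids),
       labels = stats::setNames(labels, ids),
       scores = stats::setNames(inputs$scores, ids),
       shapelets = shapelets, features = features,
       ensemble = ens, image_model = img_model, elm = elm,
       ts_out = ts_all, img_out = img_all, fused_out = fused,
       fusion_train = Xf_train,
       acc_ts = accuracy(ts_test$label, truth_test),
       acc_img = accuracy(img_test$label, truth_test),
       acc_fused = accuracy(fused$label, truth_test),
       confusion = conf,
       epoch_loss = img_model$losses)
}

#' Generate a synthetic dataset (pipeline stage)
#'
#' @param cfg a [synth_config()]
#' @param dir output directory
#' @return manifest, invisibly
#' @export
cmd_simulate <- function(cfg, dir) {
  log_stage("simulate", paste("seed", cfg$seed, "->", dir))
  generate_dataset(cfg, dir)
}

#' Score and label trials (pipeline stage)
#'
#' @param cfg a [pipeline_config()]
#' @return data.frame `trial_id,score,skill`, written to
#'   `out_dir/labels.csv`
#' @export
cmd_label <- function(cfg) {
  inputs <- load_labeled_inputs(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_labels_csv(inputs$ids, inputs$scores, inputs$labels,
                   file.path(cfg$out_dir, "labels.csv"))
  log_stage("label", paste(length(inputs$ids), "trials labeled; seed",
                           cfg$seed))
  invisible(data.frame(trial_id = inputs$ids, score = inputs$scores,
                       skill = inputs$labels))
}

#' Run the full pipeline with repeated evaluation (pipeline stage)
#'
#' Executes [run_pipeline_once()] `n_runs` times with run seeds derived from
#' the master seed, pools the held-out confusion matrices, and writes
#' `report.json`, `run_accuracies.csv`, `confusion.csv`, the shapelet and
#' prediction CSVs and the per-epoch CNN loss into `out_dir`. Artifacts are
#' deterministic functions of (inputs, config, seed).
#'
#' @param cfg a [pipeline_config()]
#' @return the report list, invisibly
#' @export
cmd_run <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- load_labeled_inputs(cfg)
  runs <- vector("list", cfg$n_runs)
  conf_sum <- NULL
  for (r in seq_len(cfg$n_runs)) {
    rs <- derive_seed(cfg$seed, paste0("pipelinerun", r))
    log_stage("run", sprintf("run %d/%d (seed %d)", r, cfg$n_runs, rs))
    runs[[r]] <- run_pipeline_once(cfg, seed = rs, inputs = inputs)
    conf_sum <- if (is.null(conf_sum)) runs[[r]]$confusion else
      conf_sum + runs[[r]]$confusion
  }
  acc <- function(field) vapply(runs, function(x) x[[field]], numeric(1))
  report <- list(
    master_seed = cfg$seed,
    config_hash = config_hash(cfg),
    n_runs = cfg$n_runs,
    runs = data.frame(run = seq_len(cfg$n_runs),
                      seed = vapply(runs, function(x) x$seed, numeric(1)),
                      acc_ts = acc("acc_ts"), acc_img = acc("acc_img"),
                      acc_fused = acc("acc_fused")),
    mean_acc_ts = mean(acc("acc_ts")),
    mean_acc_img = mean(acc("acc_img")),
    mean_acc_fused = mean(acc("acc_fused")),
    sd_acc_fused = if (cfg$n_runs >= 2) sd(acc("acc_fused")) else NA,
    confusion = unclass(conf_sum),
    fused_accuracy_pct = accuracy_from_confusion(conf_sum)
  )
  last <- runs[[cfg$n_runs]]
  write_labels_csv(inputs$ids, inputs$scores, inputs$labels,
                   file.path(cfg$out_dir, "labels.csv"))
  write_shapelets_csv(last$shapelets, file.path(cfg$out_dir, "shapelets.csv"))
  fm <- data.frame(trial_id = rownames(last$features), last$features)
  write.csv(fm, file.path(cfg$out_dir, "features.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(last$ts_out, file.path(cfg$out_dir, "ts_predictions.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(last$img_out, file.path(cfg$out_dir, "img_predictions.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(last$fused_out, file.path(cfg$out_dir, "fused_predictions.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(epoch = seq_along(last$epoch_loss),
                       loss = last$epoch_loss),
            file.path(cfg$out_dir, "epoch_loss.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(report$runs, file.path(cfg$out_dir, "run_accuracies.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(report$confusion),
            file.path(cfg$out_dir, "confusion.csv"), row.names = FALSE,
            quote = FALSE)
  write_elm_json(last$elm, file.path(cfg$out_dir, "elm_model.json"))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  log_stage("run", sprintf("fused accuracy %.1f%% over %d run(s)",
                           report$fused_accuracy_pct, cfg$n_runs))
  invisible(report)
}

#' Print a saved pipeline report (pipeline stage)
#'
#' @param out_dir directory containing `report.json`
#' @return the report, invisibly
#' @export
cmd_report <- function(out_dir) {
  report <- jsonlite::read_json(file.path(out_dir, "report.json"),
                                simplifyVector = TRUE)
  cat(sprintf("master seed:     %s\n", report$master_seed))
  cat(sprintf("runs:            %s\n", report$n_runs))
  cat(sprintf("mean accuracy:   ts %.3f | image %.3f | fused %.3f\n",
              report$mean_acc_ts, report$mean_acc_img,
              report$mean_acc_fused))
  cat(sprintf("fused accuracy (pooled confusion): %.1f%%\n",
              report$fused_accuracy_pct))
  cat("confusion (rows = actual):\n")
  print(report$confusion)
  invisible(report)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `label`, `run`, `report`. Options are supplied
#' through a JSON config file (`--config path`) whose keys mirror
#' [pipeline_config()] (plus `synth` for `simulate`), with `--seed` and
#' `--out` overrides.
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`)
#' @return exit status 0 on success, invisibly
#' @export
gs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    stop("usage: gazeskill <simulate|label|run|report> --config cfg.json ",
         "[--seed N] [--out dir]")
  }
  sub <- args[1]
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfgj <- if (!is.null(opt$config)) {
    jsonlite::read_json(opt$config, simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(opt$seed)) cfgj$seed <- as.integer(opt$seed)
  if (!is.null(opt$out)) cfgj$out_dir <- opt$out
  if (sub == "simulate") {
    sc <- do.call(synth_config, cfgj$synth %||% list())
    if (!is.null(cfgj$seed)) sc$seed <- as.integer(cfgj$seed)
    cmd_simulate(sc, cfgj$out_dir %||% "synthetic_data")
  } else if (sub %in% c("label", "run", "report")) {
    if (sub == "report") {
      cmd_report(cfgj$out_dir %||% opt$out)
    } else {
      keep <- intersect(names(cfgj), names(formals(pipeline_config)))
      pc <- do.call(pipeline_config, cfgj[keep])
      if (sub == "label") cmd_label(pc) else cmd_run(pc)
    }
  } else {
    stop("unknown subcommand: ", sub)
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
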