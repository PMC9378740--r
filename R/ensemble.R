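#' Stacked-ensemble configuration
#'
#' @param base_models character vector of base-learner kinds (default all
#'   seven)
#' @param k_folds folds for out-of-fold meta-feature generation (default 3,
#'   chosen for small datasets)
#' @param mode `"stacking"` (logistic-regression meta-learner, default) or
#'   `"majority_vote"`
#' @param seed integer master seed for the ensemble
#' @param base a [base_model_config()] with shared base hyperparameters
#' @return a `stacked_config` list
#' @export
stacked_config <- function(base_models = BASE_MODEL_KINDS, k_folds = 3,
                           mode = c("stacking", "majority_vote"), seed = 1,
                           base = base_model_config(seed = seed)) {
  mode <- match.arg(mode)
  stopifnot(all(base_models %in% BASE_MODEL_KINDS), k_folds >= 2)
  structure(list(base_models = base_models, k_folds = k_folds, mode = mode,
                 seed = seed, base = base),
            class = "stacked_config")
}

#' Train the stacked heterogeneous ensemble
#'
#' Base learners are fitted on the full training data. The logistic
#' regression meta-learner is fitted only on out-of-fold base-model class
#' probabilities: the data are split into `k_folds` stratified folds and each
#' base model is refitted `k_folds` times, predicting the held-out fold, so
#' no meta-feature for a sample ever comes from a model that saw it.
#'
#' @param features numeric feature matrix (rows may be named by trial id)
#' @param labels class labels aligned with rows
#' @param config a [stacked_config()]
#' @return a `stacked_model`
#' @export
train_stacked <- function(features, labels, config = stacked_config()) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  classes <- canonical_classes(labels)
  if (length(classes) < 2) stop("training data contains a single class")
  tab <- table(labels)
  if (any(tab < config$k_folds)) {
    stop("every class needs at least k_folds = ", config$k_folds, " samples")
  }
  folds <- stratified_folds(labels, config$k_folds,
                            derive_seed(config$seed, "folds"))
  n <- nrow(X)
  meta <- matrix(NA_real_, n, length(config$base_models) * length(classes))
  for (f in seq_len(config$k_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    for (bi in seq_along(config$base_models)) {
      kind <- config$base_models[bi]
      cfg_f <- config$base
      cfg_f$seed <- derive_seed(config$seed, paste0("fold", f, kind))
      mod <- fit_base_model(kind, X[tr, , drop = FALSE], labels[tr], cfg_f)
      pr <- predict_proba(mod, X[te, , drop = FALSE])
      # align columns in global class order (a fold could miss a class)
      cols <- (bi - 1) * length(classes) + seq_along(classes)
      aligned <- matrix(0, length(te), length(classes))
      aligned[, match(colnames(pr), classes)] <- pr
      meta[te, cols] <- aligned
    }
  }
  stopifnot(!anyNA(meta))
  base_fits <- lapply(config$base_models, function(kind) {
    cfg_f <- config$base
    cfg_f$seed <- derive_seed(config$seed, paste0("full", kind))
    fit_base_model(kind, X, labels, cfg_f)
  })
  names(base_fits) <- config$base_models
  meta_fit <- fit_multinom_lr(meta, labels, classes = classes)
  # honest (out-of-fold) stacked probabilities for the training rows: the
  # meta-learner applied to meta-features no base model computed in-sample
  oof_probs <- predict_proba(meta_fit, meta)
  structure(list(base = base_fits, meta = meta_fit, classes = classes,
                 mode = config$mode, p = ncol(X), config = config,
                 oof_probs = oof_probs, meta_features = meta, folds = folds),
            class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> %d base learners (%s), mode = %s\n",
              length(x$base), paste(names(x$base), collapse = ", "), x$mode))
  invisible(x)
}

base_prob_block <- function(model, X) {
  lapply(model$base, function(m) {
    pr <- predict_proba(m, X)
    aligned <- matrix(0, nrow(X), length(model$classes))
    aligned[, match(colnames(pr), model$classes)] <- pr
    aligned
  })
}

#' Predict with the stacked ensemble
#'
#' In `stacking` mode the fused probabilities come from the meta-learner
#' applied to the base-model probability block. In `majority_vote` mode each
#' base model casts its argmax label; ties are broken by the summed base
#' probabilities.
#'
#' @param model a `stacked_model`
#' @param features feature matrix with the training column count
#' @param mode optional override of the model's fusion mode
#' @return a `classifier_outcome` data.frame: `trial_id`, one probability
#'   column per class, `label`
#' @export
predict_stacked <- function(model, features, mode = NULL) {
  X <- check_feature_matrix(as.matrix(features), model$p)
  mode <- if (is.null(mode)) model$mode else
    match.arg(mode, c("stacking", "majority_vote"))
  blocks <- base_prob_block(model, X)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  if (mode == "stacking") {
    probs <- predict_proba(model$meta, do.call(cbind, blocks))
    probs <- probs[, model$classes, drop = FALSE] # enforce class order
    return(classifier_outcome(ids, probs, model$classes))
  }
  K <- length(model$classes)
  votes <- matrix(0, nrow(X), K)
  psum <- matrix(0, nrow(X), K)
  for (b in blocks) {
    votes[cbind(seq_len(nrow(X)), max.col(b, ties.method = "first"))] <-
      votes[cbind(seq_len(nrow(X)), max.col(b, ties.method = "first"))] + 1
    psum <- psum + b
  }
  # ties: restrict summed probabilities to max-vote classes
  probs <- matrix(0, nrow(X), K)
  for (i in seq_len(nrow(X))) {
    top <- which(votes[i, ] == max(votes[i, ]))
    sel <- if (length(top) == 1) top else top[which.max(psum[i, top])]
    probs[i, ] <- votes[i, ] / sum(votes[i, ])
    # nudge the winner so argmax matches the tie-break
    if (length(top) > 1) probs[i, sel] <- probs[i, sel] + 1e-9
    probs[i, ] <- probs[i, ] / sum(probs[i, ])
  }
  classifier_outcome(ids, probs, model$classes)
}

#' Classifier outcome container
#'
#' @param trial_ids character ids
#' @param probs n-by-K probability matrix (rows sum to 1)
#' @param classes class names in column order
#' @return data.frame `trial_id`, `p_<class>` columns, `label`
#' @export
classifier_outcome <- function(trial_ids, probs, classes) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == length(classes),
            all(abs(rowSums(probs) - 1) < 1e-9), all(probs >= -1e-12))
  out <- data.frame(trial_id = as.character(trial_ids),
                    stringsAsFactors = FALSE)
  for (i in seq_along(classes)) out[[paste0("p_", classes[i])]] <- probs[, i]
  out$label <- classes[max.col(probs, ties.method = "first")]
  class(out) <- c("classifier_outcome", "data.frame")
  out
}

outcome_probs <- function(outcome) {
  as.matrix(outcome[, grep("^p_", names(outcome)), drop = FALSE])
}

#' Repeated stratified-split evaluation
#'
#' Runs `n_runs` rounds of: seed-varied stratified train/test split (default
#' 2/3 train), fit, test accuracy; reports the per-run accuracies with their
#' mean and sample standard deviation.
#'
#' @param features feature matrix
#' @param labels class labels
#' @param model `"ensemble"` (stacked, default) or one base-learner kind
#' @param n_runs number of repeats (default 30)
#' @param train_fraction fraction of each class used for training
#'   (default 2/3)
#' @param seed master seed; run r uses a seed derived from `(seed, r)`
#' @param config a [stacked_config()] used for ensemble runs and for base
#'   hyperparameters
#' @return list with `accuracies` (length `n_runs`), `mean`, `sd` (`NA` when
#'   `n_runs == 1`)
#' @export
evaluate_repeated <- function(features, labels, model = "ensemble",
                              n_runs = 30, train_fraction = 2 / 3, seed = 1,
                              config = stacked_config(seed = seed)) {
  stopifnot(n_runs >= 1)
  labels <- as.character(labels)
  if (any(table(labels) < 3)) {
    stop("every class needs at least 3 samples for stratified evaluation")
  }
  X <- as.matrix(features)
  acc <- vapply(seq_len(n_runs), function(r) {
    rseed <- derive_seed(seed, paste0("run", r))
    sp <- stratified_split(labels, train_fraction, rseed)
    if (model == "ensemble") {
      cfg <- config
      cfg$seed <- rseed
      fit <- train_stacked(X[sp$train, , drop = FALSE], labels[sp$train], cfg)
      pred <- predict_stacked(fit, X[sp$test, , drop = FALSE])$label
    } else {
      cfg <- config$base
      cfg$seed <- rseed
      fit <- fit_base_model(model, X[sp$train, , drop = FALSE],
                            labels[sp$train], cfg)
      pr <- predict_proba(fit, X[sp$test, , drop = FALSE])
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
    }
    accuracy(pred, labels[sp$test])
  }, numeric(1))
  list(accuracies = acc, mean = mean(acc),
       sd = if (n_runs >= 2) sd(acc) else NA_real_)
}
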