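#' Score configuration for the peg-transfer task
#'
#' The task score is the preset cutoff time minus the task duration minus a
#' fixed time penalty per dropped (untransferred) peg. Defaults follow the
#' FLS convention: 300 s cutoff and 17 s per drop.
#'
#' @param cutoff_s cutoff time in seconds (default 300)
#' @param penalty_per_drop_s penalty per dropped peg in seconds (default 17)
#' @return a `score_config` list
#' @export
score_config <- function(cutoff_s = 300, penalty_per_drop_s = 17) {
  stopifnot(cutoff_s > 0, penalty_per_drop_s > 0)
  structure(list(cutoff_s = cutoff_s, penalty_per_drop_s = penalty_per_drop_s),
            class = "score_config")
}

#' Objective peg-transfer score
#'
#' `score = cutoff - duration - penalty_per_drop * drops`, floored at zero.
#' The task is stopped at the cutoff, so durations above it are an error.
#'
#' @param duration_s task duration(s) in seconds (vectorized)
#' @param drops dropped-peg count(s), non-negative integers (vectorized)
#' @param cfg a [score_config()]
#' @return numeric score(s) in seconds-equivalent units, >= 0
#' @export
peg_score <- function(duration_s, drops, cfg = score_config()) {
  stopifnot(inherits(cfg, "score_config"))
  if (any(duration_s > cfg$cutoff_s)) {
    stop("duration exceeds cutoff time (", cfg$cutoff_s, " s)")
  }
  if (any(drops < 0) || any(drops != round(drops))) {
    stop("drops must be non-negative integers")
  }
  pmax(0, cfg$cutoff_s - duration_s - cfg$penalty_per_drop_s * drops)
}

#' Derive skill levels from scores by one-dimensional k-means
#'
#' Clusters the scores into `k` groups (default 3) and maps clusters to
#' ordered labels by ascending cluster mean: lowest-scoring cluster is
#' `novice`, highest is `expert`. Uses multiple random restarts under a local
#' seed, so results are deterministic given `seed` and invariant to centroid
#' initialization order.
#'
#' @param scores numeric vector of peg-transfer scores
#' @param k number of clusters (default 3)
#' @param seed integer seed controlling k-means restarts
#' @param nstart number of k-means restarts (default 10)
#' @return ordered factor of skill levels aligned with `scores`
#' @export
cluster_skill_levels <- function(scores, k = 3, seed = 1, nstart = 10) {
  stopifnot(length(scores) >= k)
  if (length(unique(scores)) < k) {
    stop("fewer distinct scores (", length(unique(scores)),
         ") than clusters (", k, ")")
  }
  km <- with_seed(seed, kmeans(matrix(scores, ncol = 1), centers = k,
                               nstart = nstart, iter.max = 100))
  if (k != 3) {
    stop("skill labeling is defined for k = 3")
  }
  # relabel clusters by ascending mean score
  ord <- order(km$centers[, 1])
  map <- character(k)
  map[ord] <- SKILL_LEVELS
  skill_factor(map[km$cluster])
}

#' Per-class score summary
#'
#' @param scores numeric scores
#' @param labels skill labels aligned with `scores`
#' @return data.frame with one row per level: `skill`, `n`, `mean`, `sd`
#'   (sample standard deviation; `NaN`/`NA` for classes with fewer than two
#'   members)
#' @export
class_summary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- skill_factor(labels)
  out <- data.frame(skill = SKILL_LEVELS, n = 0L, mean = NA_real_,
                    sd = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(SKILL_LEVELS)) {
    s <- scores[labels == SKILL_LEVELS[i]]
    out$n[i] <- length(s)
    out$mean[i] <- if (length(s) >= 1) mean(s) else NA_real_
    out$sd[i] <- if (length(s) >= 2) sd(s) else NA_real_
  }
  out
}

#' Write trial labels to CSV
#'
#' @param trial_ids character trial identifiers
#' @param scores numeric scores
#' @param labels skill labels
#' @param path output path
#' @return `path`, invisibly
#' @export
write_labels_csv <- function(trial_ids, scores, labels, path) {
  write.csv(data.frame(trial_id = trial_ids, score = scores,
                       skill = as.character(labels)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
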