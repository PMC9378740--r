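#' Read gaze recordings from CSV
#'
#' Parses a long-format gaze sample file into one recording per trial. The
#' file must have columns `trial_id`, `participant_id`, `t`, `x`, `y`,
#' `valid` (`valid` coded 0/1). Samples are returned sorted by time within
#' each trial.
#'
#' @param path path to a UTF-8 comma-separated file
#' @return a list of gaze recordings; each element is a list with
#'   `trial_id`, `participant_id` and a data.frame `samples`
#'   (`t`, `x`, `y`, `valid`)
#' @export
read_gaze_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "participant_id", "t", "x", "y", "valid")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("gaze CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("gaze CSV contains no samples")
  if (any(!is.finite(df$t)) || any(df$t < 0)) {
    stop("gaze CSV has non-finite or negative timestamps")
  }
  recs <- lapply(split(df, df$trial_id), function(d) {
    if (anyDuplicated(d$t)) {
      stop("duplicate timestamps within trial ", d$trial_id[1])
    }
    d <- d[order(d$t), , drop = FALSE]
    if (nrow(d) < 2) stop("trial ", d$trial_id[1], " has fewer than 2 samples")
    pid <- unique(d$participant_id)
    if (length(pid) != 1) {
      stop("trial ", d$trial_id[1], " maps to multiple participants")
    }
    new_gaze_recording(
      trial_id = as.character(d$trial_id[1]),
      participant_id = as.character(pid),
      samples = data.frame(t = d$t, x = d$x, y = d$y,
                           valid = as.logical(d$valid))
    )
  })
  unname(recs)
}

new_gaze_recording <- function(trial_id, participant_id, samples) {
  structure(
    list(trial_id = trial_id, participant_id = participant_id,
         samples = samples),
    class = "gaze_recording"
  )
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> trial %s, participant %s, %d samples, %.1f%% valid\n",
              x$trial_id, x$participant_id, nrow(x$samples),
              100 * detection_rate(x)))
  invisible(x)
}

#' Gaze detection rate of a recording
#'
#' Fraction of samples in which the eye tracker reported a valid detection.
#'
#' @param rec a gaze recording as returned by [read_gaze_csv()]
#' @return a number in \[0, 1\]
#' @export
detection_rate <- function(rec) {
  n <- nrow(rec$samples)
  if (is.null(n) || n == 0) stop("empty recording")
  sum(rec$samples$valid) / n
}

#' Filter recordings by participant-level detection rate
#'
#' Recording quality is judged per participant: all samples from all of a
#' participant's trials are pooled, and the participant is removed (with all
#' their trials) when the pooled detection rate is strictly below the
#' threshold. A rate exactly at the threshold is kept.
#'
#' @param recs list of gaze recordings
#' @param threshold minimum acceptable detection rate (default 0.8)
#' @return list with elements `kept` and `removed`, each a list of recordings
#' @export
filter_by_detection <- function(recs, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (length(recs) == 0) return(list(kept = list(), removed = list()))
  pids <- vapply(recs, function(r) r$participant_id, character(1))
  valid_counts <- vapply(recs, function(r) sum(r$samples$valid), numeric(1))
  totals <- vapply(recs, function(r) nrow(r$samples), numeric(1))
  rate_by_pid <- tapply(valid_counts, pids, sum) / tapply(totals, pids, sum)
  keep_pid <- names(rate_by_pid)[rate_by_pid >= threshold]
  keep <- pids %in% keep_pid
  list(kept = recs[keep], removed = recs[!keep])
}

#' Read trial metadata from CSV
#'
#' @param path CSV with header `trial_id,duration_s,drops`
#' @return data.frame with character `trial_id`, numeric `duration_s`,
#'   integer `drops`
#' @export
read_trial_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial_id", "duration_s", "drops")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(df$duration_s < 0)) stop("negative duration_s")
  if (any(df$drops < 0) || any(df$drops != round(df$drops))) {
    stop("drops must be non-negative integers")
  }
  data.frame(trial_id = as.character(df$trial_id),
             duration_s = as.numeric(df$duration_s),
             drops = as.integer(df$drops))
}

#' Write gaze recordings to CSV (inverse of [read_gaze_csv()])
#'
#' @param recs list of gaze recordings
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gaze_csv <- function(recs, path) {
  rows <- lapply(recs, function(r) {
    data.frame(trial_id = r$trial_id, participant_id = r$participant_id,
               t = r$samples$t, x = r$samples$x, y = r$samples$y,
               valid = as.integer(r$samples$valid))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
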