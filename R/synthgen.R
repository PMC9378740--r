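# Seed-controlled synthetic peg-transfer data with planted class structure:
# class-dependent durations and drop counts (so scores cluster like the three
# observed skill groups), gaze random walks carrying class-specific motifs,
# and peg-board frames whose peg jitter shrinks with skill.

#' Synthetic dataset configuration
#'
#' Defaults place the class score distributions near the three observed
#' skill-group means (novice ~81, intermediate ~158, expert ~209
#' seconds-equivalent) with clear separation. Durations are truncated to the
#' 300 s cutoff.
#'
#' @param n_per_class trials per skill level
#' @param series_len resampled gaze series length (default 600)
#' @param class_duration_means duration means in seconds for
#'   novice/intermediate/expert (default 205, 139, 90)
#' @param class_duration_sds duration standard deviations (default 30, 15, 12)
#' @param class_drop_rates Poisson means of dropped pegs (default 0.8, 0.2,
#'   0.05)
#' @param motif_len planted motif length in samples (default 40)
#' @param motif_amplitude motif amplitude in coordinate units (default 6,
#'   about twice the stationary sd of the background walk so the planted
#'   motif is a recoverable target)
#' @param noise_sd random-walk increment standard deviation (default 1)
#' @param n_motifs motifs planted per trial (default 3)
#' @param frame_size synthetic frame side length in pixels (default 64)
#' @param sample_rate_hz gaze sampling rate used for raw series length
#'   (default 2; raw length = duration * rate before resampling)
#' @param seed master seed; all randomness is derived from it
#' @return a `synth_config` list
#' @export
synth_config <- function(n_per_class = 30, series_len = 600,
                         class_duration_means = c(205, 139, 90),
                         class_duration_sds = c(30, 15, 12),
                         class_drop_rates = c(0.8, 0.2, 0.05),
                         motif_len = 40, motif_amplitude = 6, noise_sd = 1,
                         n_motifs = 3, frame_size = 64, sample_rate_hz = 2,
                         seed = 1) {
  stopifnot(n_per_class >= 1, series_len > motif_len, motif_len >= 4,
            motif_amplitude > 0, noise_sd > 0, frame_size %% 8 == 0,
            all(class_duration_means > 0), all(class_duration_sds > 0),
            all(class_drop_rates >= 0))
  structure(list(n_per_class = n_per_class, series_len = series_len,
                 class_duration_means = class_duration_means,
                 class_duration_sds = class_duration_sds,
                 class_drop_rates = class_drop_rates,
                 motif_len = motif_len, motif_amplitude = motif_amplitude,
                 noise_sd = noise_sd, n_motifs = n_motifs,
                 frame_size = frame_size, sample_rate_hz = sample_rate_hz,
                 seed = seed),
            class = "synth_config")
}

# Fixed class motif templates on [0, 1]: distinct deterministic shapes so
# shapelet discovery has a recoverable target.
#  novice:        high-frequency zigzag
#  intermediate:  symmetric triangular ramp
#  expert:        smooth dwell plateau (raised cosine)
class_motif <- function(skill, motif_len) {
  u <- seq(0, 1, length.out = motif_len)
  switch(as.character(skill),
    novice = ifelse(round(u * 8) %% 2 == 0, 1, -1),
    intermediate = 1 - 2 * abs(2 * u - 1),
    expert = 0.5 * (1 - cos(2 * pi * u)),
    stop("unknown skill: ", skill)
  )
}

#' Generate one synthetic trial
#'
#' Duration is normal with the class mean/sd, truncated to (0, 300]; drops
#' are Poisson with the class rate; the gaze trace is a smooth random walk
#' with `n_motifs` copies of the class motif added at random offsets (both
#' channels). All samples are flagged valid.
#'
#' @param skill `"novice"`, `"intermediate"` or `"expert"`
#' @param cfg a [synth_config()]
#' @param seed integer seed for this trial's random stream
#' @param trial_id,participant_id identifiers for the recording
#' @return list with `rec` (gaze recording), `meta` (one-row data.frame
#'   `trial_id,duration_s,drops`), and `motif_offsets`
#' @export
generate_trial <- function(skill, cfg = synth_config(), seed = 1,
                           trial_id = "T001", participant_id = "P01") {
  ki <- match(skill, SKILL_LEVELS)
  if (is.na(ki)) stop("unknown skill: ", skill)
  with_seed(seed, {
    duration <- 0
    while (duration <= 0 || duration > 300) {
      duration <- rnorm(1, cfg$class_duration_means[ki],
                        cfg$class_duration_sds[ki])
    }
    duration <- round(duration, 1)
    drops <- rpois(1, cfg$class_drop_rates[ki])
    n <- max(cfg$motif_len + 2, round(duration * cfg$sample_rate_hz))
    # mean-reverting (Ornstein-Uhlenbeck) walk: gaze stays on screen, so
    # trial baselines are comparable and raw Euclidean distances reflect
    # local shape rather than baseline drift
    ou_walk <- function(n, center) {
      v <- numeric(n)
      theta <- 0.05
      for (i in 2:n) {
        v[i] <- v[i - 1] - theta * v[i - 1] + rnorm(1, 0, cfg$noise_sd)
      }
      center + v
    }
    x <- ou_walk(n, 960)
    y <- ou_walk(n, 540)
    motif <- cfg$motif_amplitude * class_motif(skill, cfg$motif_len)
    offsets <- sort(sample(0:(n - cfg$motif_len), cfg$n_motifs))
    for (o in offsets) {
      idx <- o + seq_len(cfg$motif_len)
      x[idx] <- x[idx] + motif
      y[idx] <- y[idx] + motif
    }
    rec <- new_gaze_recording(
      trial_id = trial_id, participant_id = participant_id,
      samples = data.frame(t = seq(0, duration, length.out = n),
                           x = x, y = y, valid = TRUE))
    list(rec = rec,
         meta = data.frame(trial_id = trial_id, duration_s = duration,
                           drops = drops),
         motif_offsets = offsets)
  })
}

# per-class peg jitter sd as a fraction of the frame size
JITTER_FRAC <- c(novice = 0.06, intermediate = 0.02, expert = 0.005)

#' Generate synthetic peg-board frames for one trial
#'
#' Renders six disk "pegs" at canonical board positions with Gaussian
#' positional jitter whose sd decreases with skill (novice > intermediate >
#' expert), plus pixel noise. Output values are in \[0, 1\].
#'
#' @param skill skill level
#' @param n_frames number of frames (>= 1)
#' @param cfg a [synth_config()]
#' @param seed integer seed for this trial's frame stream
#' @return (n_frames, frame_size, frame_size, 3) array
#' @export
generate_frames <- function(skill, n_frames, cfg = synth_config(), seed = 1) {
  stopifnot(n_frames >= 1)
  ki <- match(skill, SKILL_LEVELS)
  if (is.na(ki)) stop("unknown skill: ", skill)
  s <- cfg$frame_size
  jit <- JITTER_FRAC[[skill]] * s
  # canonical 2 x 3 peg grid
  cx <- s * rep(c(0.25, 0.5, 0.75), 2)
  cy <- s * rep(c(0.35, 0.7), each = 3)
  rad <- s / 14
  ys <- matrix(seq_len(s), s, s)               # row index
  xs <- matrix(seq_len(s), s, s, byrow = TRUE) # column index
  out <- array(0, c(n_frames, s, s, 3))
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      canvas <- matrix(0.1, s, s)
      for (pg in seq_along(cx)) {
        px <- cx[pg] + rnorm(1, 0, jit)
        py <- cy[pg] + rnorm(1, 0, jit)
        canvas[(xs - px)^2 + (ys - py)^2 <= rad^2] <- 0.9
      }
      canvas <- canvas + matrix(rnorm(s * s, 0, 0.02), s, s)
      canvas <- pmin(pmax(canvas, 0), 1)
      for (ch in 1:3) out[f, , , ch] <- canvas
    }
  })
  out
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes the gaze CSV, trial metadata CSV and per-trial PNG frame
#' directories in the formats the pipeline reads, plus a `manifest.json`
#' holding the ground-truth labels, seed and configuration.
#'
#' @param cfg a [synth_config()] with `n_per_class >= 3`
#' @param dir output directory (created if needed)
#' @return the manifest, invisibly: list with `trial_id`, `skill`,
#'   `participant_id`, `n_frames`, `seed` and paths
#' @export
generate_dataset <- function(cfg = synth_config(), dir) {
  stopifnot(cfg$n_per_class >= 3)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames_root <- file.path(dir, "frames")
  dir.create(frames_root, showWarnings = FALSE)
  skills <- rep(SKILL_LEVELS, each = cfg$n_per_class)
  n <- length(skills)
  ids <- sprintf("T%03d", seq_len(n))
  pids <- sprintf("P%02d", (seq_len(n) - 1) %% 10 + 1)
  recs <- vector("list", n)
  metas <- vector("list", n)
  n_frames <- integer(n)
  for (i in seq_len(n)) {
    tr <- generate_trial(skills[i], cfg,
                         seed = derive_seed(cfg$seed, paste0("trial", ids[i])),
                         trial_id = ids[i], participant_id = pids[i])
    recs[[i]] <- tr$rec
    metas[[i]] <- tr$meta
    n_frames[i] <- max(4L, round(tr$meta$duration_s / 15))
    fr <- generate_frames(skills[i], n_frames[i], cfg,
                          seed = derive_seed(cfg$seed, paste0("frames", ids[i])))
    tdir <- file.path(frames_root, ids[i])
    dir.create(tdir, showWarnings = FALSE)
    for (f in seq_len(n_frames[i])) {
      png::writePNG(fr[f, , , ], file.path(tdir, sprintf("%05d.png", f)))
    }
  }
  write_gaze_csv(recs, file.path(dir, "gaze.csv"))
  write.csv(do.call(rbind, metas), file.path(dir, "meta.csv"),
            row.names = FALSE, quote = FALSE)
  manifest <- list(trial_id = ids, skill = skills, participant_id = pids,
                   n_frames = n_frames, seed = cfg$seed,
                   gaze_csv = file.path(dir, "gaze.csv"),
                   meta_csv = file.path(dir, "meta.csv"),
                   frames_dir = frames_root,
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
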