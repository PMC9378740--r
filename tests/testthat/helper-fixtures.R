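# Programmatic fixtures shared across test files.

# three well-separated gaussian blobs in d dimensions
sep_features <- function(n_per_class = 30, d = 4, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_class
  X <- matrix(rnorm(n * d, sd = sd), n, d)
  y <- rep(c("novice", "intermediate", "expert"), each = n_per_class)
  X[y == "intermediate", 1] <- X[y == "intermediate", 1] + sep
  X[y == "expert", 2] <- X[y == "expert", 2] + sep
  rownames(X) <- sprintf("T%03d", seq_len(n))
  list(X = X, y = y)
}

# gaze CSV content on disk; returns the path
write_tiny_gaze_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

gaze_df <- function(trial_id, participant_id, t, x = seq_along(t),
                    y = seq_along(t), valid = 1) {
  data.frame(trial_id = trial_id, participant_id = participant_id,
             t = t, x = x, y = y, valid = valid)
}

# small two-channel series set with optional planted motif in class B
make_motif_set <- function(n_per_class = 10, len = 60, motif_len = 12,
                           amp = 6, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  xm <- matrix(rnorm(n * len), n, len)
  ym <- matrix(rnorm(n * len), n, len)
  motif <- amp * sin(seq(0, 2 * pi, length.out = motif_len))
  offsets <- rep(NA_integer_, n)
  for (i in (n_per_class + 1):n) {
    o <- sample(0:(len - motif_len), 1)
    idx <- o + seq_len(motif_len)
    xm[i, idx] <- xm[i, idx] + motif
    ym[i, idx] <- ym[i, idx] + motif
    offsets[i] <- o
  }
  list(sset = series_set(xm, ym, sprintf("S%02d", seq_len(n))),
       labels = rep(c("A", "B"), each = n_per_class),
       offsets = offsets, motif_len = motif_len)
}
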