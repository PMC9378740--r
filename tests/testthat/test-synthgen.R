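test_that("generate_trial is deterministic and respects the cutoff", {
  cfg <- synth_config(seed = 1)
  t1 <- generate_trial("novice", cfg, seed = 42)
  t2 <- generate_trial("novice", cfg, seed = 42)
  expect_identical(t1, t2)
  t3 <- generate_trial("novice", cfg, seed = 43)
  expect_false(identical(t1$rec$samples, t3$rec$samples))
  expect_lte(t1$meta$duration_s, 300)
  expect_gte(t1$meta$drops, 0)
  expect_true(all(t1$rec$samples$valid))
  expect_error(generate_trial("wizard", cfg, 1), "unknown skill")
})

test_that("expert trials score high with the default configuration", {
  cfg <- synth_config()
  scores <- vapply(1:200, function(s) {
    tr <- generate_trial("expert", cfg, seed = s)
    peg_score(tr$meta$duration_s, tr$meta$drops)
  }, numeric(1))
  # expert score ~ 300 - N(90, 12) - 17 Pois(0.05): P(> 150) > 0.99
  expect_gte(mean(scores > 150), 0.95)
})

test_that("planted motifs are recoverable by matched filtering", {
  cfg <- synth_config(seed = 2)
  tr <- generate_trial("intermediate", cfg, seed = 7)
  x <- tr$rec$samples$x
  template <- cfg$motif_amplitude *
    gazeskill:::class_motif("intermediate", cfg$motif_len)
  template <- template - mean(template)
  score <- vapply(0:(length(x) - cfg$motif_len), function(o) {
    w <- x[o + seq_len(cfg$motif_len)]
    sum((w - mean(w)) * template)
  }, numeric(1))
  # the matched filter peaks locally at every planted offset
  hi <- quantile(score, 0.9)
  for (o in tr$motif_offsets) {
    idx <- pmax(1, o + 1 - 3):pmin(length(score), o + 1 + 3)
    expect_gt(max(score[idx]), hi)
  }
})

test_that("class motifs are distinct fixed shapes", {
  m <- sapply(c("novice", "intermediate", "expert"),
              function(s) gazeskill:::class_motif(s, 32))
  expect_gt(min(dist(t(m))), 1) # pairwise distinct
  expect_identical(m, sapply(c("novice", "intermediate", "expert"),
                             function(s) gazeskill:::class_motif(s, 32)))
})

test_that("generate_frames renders deterministic pegs with class jitter", {
  cfg <- synth_config(frame_size = 32)
  f1 <- generate_frames("expert", 3, cfg, seed = 5)
  f2 <- generate_frames("expert", 3, cfg, seed = 5)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(3, 32, 32, 3))
  expect_true(all(f1 >= 0 & f1 <= 1))
  # jitter estimator: frame-to-frame pixel variance grows with jitter sd
  jitter_stat <- function(skill) {
    fr <- generate_frames(skill, 60, cfg, seed = 11)
    mean(apply(fr[, , , 1], c(2, 3), var))
  }
  expect_gt(jitter_stat("novice"), jitter_stat("expert"))
})

test_that("generate_dataset writes a complete consistent tree", {
  dir <- tempfile()
  man <- generate_dataset(synth_config(n_per_class = 3, frame_size = 16,
                                       seed = 3), dir)
  expect_length(man$trial_id, 9)
  expect_true(file.exists(file.path(dir, "gaze.csv")))
  expect_true(file.exists(file.path(dir, "meta.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  recs <- read_gaze_csv(file.path(dir, "gaze.csv"))
  expect_length(recs, 9)
  meta <- read_trial_meta(file.path(dir, "meta.csv"))
  expect_equal(nrow(meta), 9)
  for (tid in man$trial_id) {
    files <- list.files(file.path(dir, "frames", tid), pattern = "png$")
    expect_equal(length(files), man$n_frames[man$trial_id == tid])
  }
  # regeneration is bit-identical
  dir2 <- tempfile()
  generate_dataset(synth_config(n_per_class = 3, frame_size = 16, seed = 3),
                   dir2)
  expect_identical(readLines(file.path(dir, "gaze.csv")),
                   readLines(file.path(dir2, "gaze.csv")))
  expect_identical(
    png::readPNG(file.path(dir, "frames", "T001", "00001.png")),
    png::readPNG(file.path(dir2, "frames", "T001", "00001.png")))
})
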