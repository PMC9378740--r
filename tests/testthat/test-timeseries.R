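test_that("resample_series interpolates linearly with fixed endpoints", {
  expect_equal(resample_series(c(0, 1, 2, 3, 4), 3), c(0, 2, 4))
  expect_equal(resample_series(c(1, 3), 4), c(1, 5 / 3, 7 / 3, 3))
  v <- rnorm(17)
  expect_identical(resample_series(v, 17), v)
  expect_error(resample_series(c(1, 2), 1), "target_len")
  expect_error(resample_series(1, 5), "at least 2")
  # endpoints preserved for arbitrary lengths
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(sample(5:40, 1))
    out <- resample_series(v, sample(2:50, 1))
    expect_equal(out[1], v[1])
    expect_equal(out[length(out)], v[length(v)])
  }
})

test_that("subsequence_distance matches the exhaustive oracle", {
  expect_equal(subsequence_distance(c(1, 2), c(0, 1, 2, 3)), 0)
  expect_equal(subsequence_distance(c(0, 0), c(1, 1, 1)), sqrt(2))
  expect_error(subsequence_distance(1:5, 1:3), "longer")
  set.seed(21)
  for (i in 1:60) {
    l <- sample(2:6, 1)
    m <- sample(l:20, 1)
    S <- rnorm(l); T <- rnorm(m)
    expect_equal(subsequence_distance(S, T), bf_subseq_dist(S, T),
                 tolerance = 1e-12)
  }
})

test_that("generate_candidates enumerates the full pool", {
  s1 <- series_set(matrix(rnorm(5), 1), matrix(rnorm(5), 1), "A")
  cands <- generate_candidates(s1, 2, 3)
  expect_equal(nrow(cands), 2 * (4 + 3)) # both channels
  expect_equal(attr(cands, "per_channel_count"), 7)

  s2 <- series_set(matrix(rnorm(10), 2), matrix(rnorm(10), 2), c("A", "B"))
  expect_equal(attr(generate_candidates(s2, 5, 5), "per_channel_count"), 2)
  expect_error(generate_candidates(s1, 6, 6), "lmax")
})

test_that("assess_candidate matches brute-force oracles for all measures", {
  # closed-form example: distances 1,2,5,6 with labels A,A,B,B split purely
  expect_equal(gazeskill:::quality_from_distances(c(1, 2, 5, 6),
                                                  c("A", "A", "B", "B"),
                                                  "info_gain"), 1)
  expect_equal(gazeskill:::quality_from_distances(c(1, 2, 5, 6),
                                                  rep("A", 4), "info_gain"),
               0)
  set.seed(31)
  for (i in 1:20) {
    n <- 12
    sset <- series_set(matrix(rnorm(n * 30), n), matrix(rnorm(n * 30), n),
                       sprintf("S%02d", 1:n))
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("a", "b")
    cand <- rnorm(sample(3:8, 1))
    ch <- sample(c("x", "y"), 1)
    d <- sapply(seq_len(n), function(j) bf_subseq_dist(cand, sset[[ch]][j, ]))
    expect_equal(assess_candidate(cand, ch, sset, labels, "info_gain"),
                 bf_info_gain(d, labels), tolerance = 1e-10)
    expect_equal(assess_candidate(cand, ch, sset, labels, "f_stat"),
                 bf_f_stat(d, labels), tolerance = 1e-10)
    expect_equal(assess_candidate(cand, ch, sset, labels, "mood_median"),
                 bf_mood_median(d, labels), tolerance = 1e-10)
  }
})

test_that("info gain is bounded by label entropy and vanishes under permutation", {
  set.seed(41)
  labels <- rep(c("a", "b", "c"), each = 8)
  H <- -sum(rep(1 / 3, 3) * log2(rep(1 / 3, 3)))
  # separated distances give near-maximal gain
  d_sep <- c(rnorm(8, 0, .1), rnorm(8, 5, .1), rnorm(8, 10, .1))
  g <- gazeskill:::quality_from_distances(d_sep, labels, "info_gain")
  expect_gt(g, 0)
  expect_lte(g, H + 1e-12)
  # permutation null: gains bounded and small on average
  gains <- replicate(100, {
    gazeskill:::quality_from_distances(d_sep, sample(labels), "info_gain")
  })
  expect_true(all(gains >= 0 & gains <= H + 1e-12))
  # null gains stay clearly below the separated-label gain
  expect_lt(mean(gains) + 3 * sd(gains), g)
})

test_that("remove_self_similar prunes overlapping ranges on one source only", {
  mk <- function(trial, start, len, q, ch = "x") {
    list(values = rep(0, len), source_trial = trial, start = start,
         length = len, channel = ch, quality = q)
  }
  # overlap on same trial: keep best only
  out <- remove_self_similar(list(mk("T1", 0, 4, .9), mk("T1", 2, 4, .8)))
  expect_length(out, 1)
  expect_equal(out[[1]]$quality, .9)
  # same ranges on different trials: both kept
  out <- remove_self_similar(list(mk("T1", 0, 4, .9), mk("T2", 0, 4, .8)))
  expect_length(out, 2)
  # half-open adjacency is not overlap
  out <- remove_self_similar(list(mk("T1", 0, 4, .9), mk("T1", 4, 4, .8)))
  expect_length(out, 2)
  # same trial, different channel: both kept
  out <- remove_self_similar(list(mk("T1", 0, 4, .9),
                                  mk("T1", 0, 4, .8, ch = "y")))
  expect_length(out, 2)
})

test_that("extract_shapelets recovers a planted motif and caps at k", {
  hits <- 0
  for (s in 1:10) {
    ms <- make_motif_set(seed = s)
    sh <- extract_shapelets(ms$sset, ms$labels, k = 3, lmin = 8, lmax = 16,
                            max_candidates = 800, seed = s)
    top <- sh[[1]]
    src <- match(top$source_trial, ms$sset$trial_ids)
    o <- ms$offsets[src]
    if (!is.na(o) && top$start < o + ms$motif_len &&
        o < top$start + top$length) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)

  # k larger than surviving candidates returns all survivors
  small <- series_set(matrix(rnorm(40), 2), matrix(rnorm(40), 2),
                      c("A", "B"))
  sh <- extract_shapelets(small, c("a", "b"), k = 100, lmin = 18, lmax = 20,
                          max_candidates = Inf, seed = 1)
  expect_lte(length(sh), 100)
  expect_gte(length(sh), 1)
})

test_that("subsampled extraction equals full enumeration when cap not binding", {
  ms <- make_motif_set(n_per_class = 3, len = 30, motif_len = 8, seed = 5)
  full <- extract_shapelets(ms$sset, ms$labels, k = 5, lmin = 6, lmax = 8,
                            max_candidates = Inf, seed = 1)
  capped <- extract_shapelets(ms$sset, ms$labels, k = 5, lmin = 6, lmax = 8,
                              max_candidates = 1e9, seed = 99)
  expect_equal(full, capped)
})

test_that("shapelet_transform equals element-wise brute force", {
  ms <- make_motif_set(n_per_class = 3, len = 40, motif_len = 10, seed = 7)
  sh <- extract_shapelets(ms$sset, ms$labels, k = 4, lmin = 8, lmax = 12,
                          max_candidates = 300, seed = 2)
  fm <- shapelet_transform(ms$sset, sh)
  expect_equal(dim(fm), c(6, length(sh)))
  expect_true(all(fm >= 0))
  for (j in seq_along(sh)) {
    ch <- sh[[j]]$channel
    for (i in 1:6) {
      expect_equal(fm[i, j], bf_subseq_dist(sh[[j]]$values, ms$sset[[ch]][i, ]),
                   tolerance = 1e-12)
    }
  }
  # a series containing its own shapelet has feature 0
  src <- match(sh[[1]]$source_trial, ms$sset$trial_ids)
  expect_equal(fm[src, 1], 0, tolerance = 1e-12)
  # permutation equivariance of rows
  perm <- c(3, 1, 2, 6, 5, 4)
  psset <- series_set(ms$sset$x[perm, ], ms$sset$y[perm, ],
                      ms$sset$trial_ids[perm])
  expect_equal(unname(shapelet_transform(psset, sh)), unname(fm[perm, ]))
})

test_that("shapelets round-trip through CSV", {
  ms <- make_motif_set(n_per_class = 3, len = 40, motif_len = 10, seed = 9)
  sh <- extract_shapelets(ms$sset, ms$labels, k = 3, lmin = 6, lmax = 10,
                          max_candidates = 200, seed = 2)
  p <- tempfile(fileext = ".csv")
  write_shapelets_csv(sh, p)
  sh2 <- read_shapelets_csv(p)
  for (i in seq_along(sh)) {
    expect_equal(sh2[[i]]$values, unname(sh[[i]]$values))
    expect_equal(sh2[[i]]$start, sh[[i]]$start)
    expect_equal(sh2[[i]]$channel, sh[[i]]$channel)
  }
})

test_that("gaze_to_series_set interpolates invalid samples", {
  df <- gaze_df("A", "P1", t = 0:4, x = c(0, 2, 999, 6, 8),
                y = c(0, 1, 2, 3, 4), valid = c(1, 1, 0, 1, 1))
  recs <- read_gaze_csv(write_tiny_gaze_csv(df))
  sset <- gaze_to_series_set(recs, 5)
  expect_equal(sset$x[1, ], c(0, 2, 4, 6, 8)) # invalid point bridged
})
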