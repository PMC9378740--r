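test_that("balance_capture_rates inverts class video counts", {
  expect_equal(balance_capture_rates(c(1, 3, 8)), c(1, 1 / 3, 1 / 8))
  expect_equal(balance_capture_rates(c(5, 5, 5)), c(1, 1, 1))
  expect_error(balance_capture_rates(c(0, 3, 8)), "at least one")
})

write_frame_tree <- function(skills, n_frames, cfg, root = tempfile()) {
  dir.create(root)
  dirs <- character(length(skills))
  for (i in seq_along(skills)) {
    d <- file.path(root, sprintf("T%02d", i))
    dir.create(d)
    fr <- generate_frames(skills[i], n_frames, cfg, seed = i)
    for (f in seq_len(n_frames)) {
      png::writePNG(fr[f, , , ], file.path(d, sprintf("%05d.png", f)))
    }
    dirs[i] <- d
  }
  names(dirs) <- sprintf("T%02d", seq_along(skills))
  dirs
}

test_that("extract_frames applies stride subsampling and resizing", {
  cfg <- synth_config(frame_size = 32)
  dirs <- write_frame_tree("novice", 24, cfg)
  rates <- c(novice = 1 / 3)
  fs <- extract_frames(dirs, "novice", rates, resolution = 32)
  expect_equal(dim(fs$frames), c(8, 32, 32, 3))
  fs_all <- extract_frames(dirs, "novice", c(novice = 1), resolution = 32)
  expect_equal(dim(fs_all$frames)[1], 24)
  # resize path
  fs16 <- extract_frames(dirs, "novice", c(novice = 1), resolution = 16)
  expect_equal(dim(fs16$frames)[2:3], c(16, 16))
})

test_that("balanced rates equalize per-class frame counts", {
  cfg <- synth_config(frame_size = 16)
  skills <- rep(c("novice", "intermediate", "expert"), c(1, 2, 4))
  dirs <- write_frame_tree(skills, 12, cfg)
  rates <- balance_capture_rates(c(1, 2, 4))
  names(rates) <- c("novice", "intermediate", "expert")
  fs <- extract_frames(dirs, skills, rates, resolution = 16)
  counts <- table(fs$label)
  expect_true(max(counts) - min(counts) <= length(dirs)) # within rounding
})

test_that("aggregate_trial_prediction averages frame probabilities", {
  out <- aggregate_trial_prediction(
    matrix(c(0, 0, 1, 0, 0, 1), 2, byrow = TRUE),
    classes = c("novice", "intermediate", "expert"))
  expect_equal(out$label, "expert")
  expect_equal(out$p_expert, 1)
  # tie broken toward the lower-ordered (first) class
  tie <- aggregate_trial_prediction(
    matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE),
    classes = c("a", "b", "c"))
  expect_equal(tie$label, "a")
  expect_equal(tie$p_a + tie$p_b + tie$p_c, 1)
  expect_error(aggregate_trial_prediction(matrix(0, 0, 3)), "no frames")
})

test_that("train_image_classifier separates synthetic classes", {
  cfg <- synth_config(frame_size = 32)
  skills <- rep(c("novice", "intermediate", "expert"), each = 6)
  dirs <- write_frame_tree(skills, 10, cfg)
  fs <- extract_frames(dirs, skills, resolution = 32)
  icfg <- image_model_config(resolution = 32, epochs = 8, seed = 4)
  model <- train_image_classifier(fs, icfg)
  # trial-level split: no trial on both sides
  expect_length(intersect(model$train_trials, model$test_trials), 0)
  expect_setequal(c(model$train_trials, model$test_trials), names(dirs))
  # loss decreases over epochs
  expect_lt(model$losses[length(model$losses)], model$losses[1])
  # held-out frames separable by construction
  te <- fs$trial_id %in% model$test_trials
  pr <- predict_frame_probs(model, fs$frames[te, , , , drop = FALSE])
  acc <- mean(colnames(pr)[max.col(pr, ties.method = "first")] ==
                fs$label[te])
  expect_gte(acc, 0.9)
  # trial aggregation is a convex combination
  out <- predict_image_trials(model, fs, trials = model$test_trials)
  probs <- as.matrix(out[, grep("^p_", names(out))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("train_image_classifier rejects degenerate inputs", {
  cfg <- synth_config(frame_size = 16)
  dirs <- write_frame_tree(rep("novice", 3), 4, cfg)
  fs <- extract_frames(dirs, rep("novice", 3), resolution = 16)
  expect_error(train_image_classifier(fs, image_model_config(resolution = 16)),
               "2 classes")
  expect_error(
    train_image_classifier(fs, image_model_config(
      backbone = "inception_resnet_v2", resolution = 16)),
    "bundled")
})

test_that("resize_bilinear preserves size-matched input", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_identical(resize_bilinear(img, 16), img)
  out <- resize_bilinear(img, 8)
  expect_equal(dim(out), c(8, 8, 3))
  expect_true(all(out >= 0 & out <= 1))
})
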