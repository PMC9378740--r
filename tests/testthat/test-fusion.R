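test_that("build_fusion_features concatenates branch probabilities", {
  ts <- classifier_outcome("T1", matrix(c(1, 0, 0), 1),
                           c("novice", "intermediate", "expert"))
  img <- classifier_outcome("T1", matrix(c(1, 0, 0), 1),
                            c("novice", "intermediate", "expert"))
  X <- build_fusion_features(ts, img)
  expect_equal(unname(X[1, ]), c(1, 0, 0, 1, 0, 0))
  expect_equal(ncol(X), 6)
  expect_true(all(X >= 0 & X <= 1))

  img2 <- classifier_outcome("T2", matrix(c(1, 0, 0), 1),
                             c("novice", "intermediate", "expert"))
  expect_error(build_fusion_features(ts, img2), "mismatch")

  # row alignment by trial id, not position
  ts2 <- classifier_outcome(c("T1", "T2"),
                            rbind(c(1, 0, 0), c(0, 1, 0)),
                            c("novice", "intermediate", "expert"))
  img3 <- classifier_outcome(c("T2", "T1"),
                             rbind(c(0, 0, 1), c(1, 0, 0)),
                             c("novice", "intermediate", "expert"))
  X2 <- build_fusion_features(ts2, img3)
  expect_equal(unname(X2["T1", ]), c(1, 0, 0, 1, 0, 0))
  expect_equal(unname(X2["T2", ]), c(0, 1, 0, 0, 0, 1))
})

test_that("ELM interpolates when hidden width reaches sample count", {
  for (s in 1:10) {
    set.seed(s + 100)
    n <- 12
    X <- matrix(runif(n * 6), n, 6)
    y <- sample(c("novice", "intermediate", "expert"), n, replace = TRUE)
    model <- elm_train(X, y, n_hidden = n, seed = s)
    pred <- elm_predict(model, X)
    expect_equal(pred$label, y)
  }
})

test_that("ELM handles degenerate targets sensibly", {
  X <- matrix(runif(20 * 3), 20, 3)
  m <- elm_train(X, rep("expert", 20), n_hidden = 5, seed = 1)
  expect_true(all(elm_predict(m, X)$label == "expert"))

  # identical rows with conflicting labels cannot both be fitted
  X2 <- rbind(c(1, 2, 3), c(1, 2, 3))
  m2 <- elm_train(X2, c("novice", "expert"), n_hidden = 10, seed = 2)
  pred <- elm_predict(m2, X2)
  expect_equal(pred$label[1], pred$label[2]) # least-squares compromise
  expect_lte(mean(pred$label == c("novice", "expert")), 0.5)

  expect_error(elm_train(rbind(c(1, NA)), "a"), "non-finite")
})

test_that("ELM training is deterministic and the solve is bit-stable", {
  set.seed(9)
  X <- matrix(runif(30 * 6), 30, 6)
  y <- sample(c("a", "b", "c"), 30, replace = TRUE)
  m1 <- elm_train(X, y, n_hidden = 20, seed = 77)
  m2 <- elm_train(X, y, n_hidden = 20, seed = 77)
  expect_identical(m1$W, m2$W)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-8)
  # re-solve beta on the same hidden activations
  H <- tanh(X %*% m1$W + matrix(m1$b, 30, 20, byrow = TRUE))
  beta2 <- gazeskill:::pinv(H) %*% gazeskill:::one_hot(y, m1$classes)
  expect_equal(unname(m1$beta), unname(beta2), tolerance = 1e-8)
  # duplicate input rows produce identical outputs
  pred <- elm_predict(m1, X[c(1, 1, 2), ])
  expect_equal(pred[1, -1], pred[2, -1], ignore_attr = TRUE)
  probs <- as.matrix(pred[, grep("^p_", names(pred))])
  expect_equal(unname(rowSums(probs)), rep(1, 3), tolerance = 1e-9)
  expect_error(elm_predict(m1, X[, 1:3]), "dimension mismatch")
})

test_that("ELM model round-trips through JSON", {
  set.seed(5)
  X <- matrix(runif(15 * 6), 15, 6)
  y <- sample(c("a", "b"), 15, replace = TRUE)
  m <- elm_train(X, y, n_hidden = 8, seed = 3)
  p <- tempfile(fileext = ".json")
  write_elm_json(m, p)
  m2 <- read_elm_json(p)
  expect_equal(m2$beta, unname(m$beta))
  expect_equal(elm_predict(m2, X)$label, elm_predict(m, X)$label)
})

test_that("accuracy_from_confusion computes trace over total", {
  expect_equal(accuracy_from_confusion(diag(c(5, 5, 5))), 100.0)
  off <- matrix(c(0, 3, 1, 2, 0, 4, 5, 1, 0), 3, byrow = TRUE)
  expect_equal(accuracy_from_confusion(off), 0.0)
  expect_error(accuracy_from_confusion(matrix(0, 3, 3)), "empty")
  expect_error(accuracy_from_confusion(matrix(c(1.5, 0, 0, 1), 2)),
               "integer")
  # invariance under simultaneous row/column permutation
  m <- matrix(c(7, 6, 0, 4, 15, 9, 0, 3, 82), 3, byrow = TRUE)
  perm <- c(3, 1, 2)
  expect_equal(accuracy_from_confusion(m[perm, perm]),
               accuracy_from_confusion(m))
})

test_that("confusion_matrix uses canonical skill ordering", {
  cm <- confusion_matrix(c("novice", "expert"), c("novice", "novice"))
  expect_equal(rownames(cm), c("novice", "intermediate", "expert"))
  expect_equal(cm["expert", "novice"], 2 - 1)
  expect_equal(sum(cm), 2)
})
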