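test_that("train_stacked reaches perfect training accuracy on separable data", {
  fx <- sep_features(n_per_class = 30, sep = 10, seed = 1)
  model <- train_stacked(fx$X, fx$y, stacked_config(seed = 7))
  out <- predict_stacked(model, fx$X)
  expect_equal(mean(out$label == fx$y), 1.0)
  probs <- as.matrix(out[, grep("^p_", names(out))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("train_stacked validates its inputs", {
  fx <- sep_features(n_per_class = 10, seed = 2)
  expect_error(train_stacked(fx$X[fx$y == "novice", ],
                             fx$y[fx$y == "novice"]), "single class")
  # a class with fewer members than k_folds
  small <- rbind(fx$X[1:2, ], fx$X[11:20, ], fx$X[21:30, ])
  slab <- c(fx$y[1:2], fx$y[11:20], fx$y[21:30])
  expect_error(train_stacked(small, slab, stacked_config(k_folds = 3)),
               "k_folds")
})

test_that("fused label follows unanimous base models in both modes", {
  fx <- sep_features(n_per_class = 20, sep = 12, seed = 3)
  model <- train_stacked(fx$X, fx$y, stacked_config(seed = 1))
  blocks <- gazeskill:::base_prob_block(model, fx$X)
  votes <- sapply(blocks, function(b) max.col(b, ties.method = "first"))
  unanimous <- apply(votes, 1, function(v) length(unique(v)) == 1)
  expect_gt(sum(unanimous), 0)
  stack_lab <- predict_stacked(model, fx$X, mode = "stacking")$label
  vote_lab <- predict_stacked(model, fx$X, mode = "majority_vote")$label
  agreed <- model$classes[votes[unanimous, 1]]
  expect_equal(vote_lab[unanimous], agreed)
  expect_equal(stack_lab[unanimous], agreed)
})

test_that("majority voting picks the plurality class", {
  # 4 vs 3 votes, constructed through fake base models
  fake <- function(cls) {
    structure(list(cls = cls, classes = c("a", "b", "c"), p = 1),
              class = c("fake_base", "gs_model"))
  }
  registerS3method("predict_proba", "fake_base",
                   function(model, X, ...) {
                     pr <- matrix(0.05, nrow(X), 3,
                                  dimnames = list(NULL, model$classes))
                     pr[, model$cls] <- 0.9
                     pr
                   },
                   envir = asNamespace("gazeskill"))
  model <- structure(
    list(base = c(lapply(1:4, function(i) fake("a")),
                  lapply(1:3, function(i) fake("b"))),
         classes = c("a", "b", "c"), mode = "majority_vote", p = 1),
    class = "stacked_model")
  out <- predict_stacked(model, matrix(0, 5, 1))
  expect_equal(out$label, rep("a", 5))
})

test_that("no meta-feature leaks from a model that saw the sample", {
  # out-of-fold construction: fold f rows must be predicted by a model
  # fitted on the complement; recompute each fold model independently and
  # compare with the stored meta-features
  fx <- sep_features(n_per_class = 9, seed = 4)
  cfg <- stacked_config(base_models = "random_forest", seed = 9)
  model <- train_stacked(fx$X, fx$y, cfg)
  folds <- model$folds
  for (f in unique(folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    cfg_f <- cfg$base
    cfg_f$seed <- gazeskill:::derive_seed(cfg$seed,
                                          paste0("fold", f, "random_forest"))
    m <- fit_base_model("random_forest", fx$X[tr, , drop = FALSE], fx$y[tr],
                        cfg_f)
    pr <- predict_proba(m, fx$X[te, , drop = FALSE])
    aligned <- matrix(0, length(te), 3)
    aligned[, match(colnames(pr), model$classes)] <- pr
    expect_equal(unname(model$meta_features[te, ]), unname(aligned))
  }
  expect_false(anyNA(model$meta_features))
})

test_that("evaluate_repeated reports mean/sd and is reproducible", {
  fx <- sep_features(n_per_class = 12, sep = 12, seed = 5)
  cfg <- stacked_config(base_models = c("random_forest", "xgboost"),
                        seed = 1)
  r1 <- evaluate_repeated(fx$X, fx$y, model = "ensemble", n_runs = 3,
                          seed = 31, config = cfg)
  expect_equal(r1$mean, 1.0)
  expect_equal(r1$sd, 0.0)
  r2 <- evaluate_repeated(fx$X, fx$y, model = "ensemble", n_runs = 3,
                          seed = 31, config = cfg)
  expect_identical(r1, r2)
  one <- evaluate_repeated(fx$X, fx$y, model = "random_forest", n_runs = 1,
                           seed = 2, config = cfg)
  expect_true(is.na(one$sd))
  expect_error(evaluate_repeated(fx$X[c(1, 13, 25), ], fx$y[c(1, 13, 25)],
                                 n_runs = 2, seed = 1),
               "at least 3")
})
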