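# Tree-based base learners built on the shared CART/Newton-tree backend in
# src/trees.cpp. All learners present the same interface: fit_* returns an
# object with class c(kind, "gs_model"); predict_proba() yields an n x K
# probability matrix with columns in `model$classes` order.

as_class_int <- function(y, classes) {
  match(as.character(y), classes) - 1L
}

#' @export
predict_proba <- function(model, X, ...) UseMethod("predict_proba")

fit_forest <- function(X, y, n_trees = 100, bootstrap = TRUE,
                       random_split = FALSE, mtry = NULL,
                       max_depth = 30L, min_leaf = 1L, seed = 1) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  yi <- as_class_int(y, classes)
  n <- nrow(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  w <- rep(1, n)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    rows <- if (bootstrap) sample(n, n, replace = TRUE) else seq_len(n)
    cpp_build_class_tree(X, yi, w, length(classes), as.integer(mtry),
                         as.integer(max_depth), as.integer(min_leaf),
                         random_split, as.integer(rows - 1L))
  }))
  structure(list(trees = trees, classes = classes, p = ncol(X)),
            class = c(if (random_split) "gs_extra_trees" else "gs_random_forest",
                      "gs_forest", "gs_model"))
}

fit_random_forest <- function(X, y, n_trees = 100, seed = 1) {
  fit_forest(X, y, n_trees = n_trees, bootstrap = TRUE,
             random_split = FALSE, seed = seed)
}

fit_extra_trees <- function(X, y, n_trees = 100, seed = 1) {
  fit_forest(X, y, n_trees = n_trees, bootstrap = FALSE,
             random_split = TRUE, seed = seed)
}

#' @export
predict_proba.gs_forest <- function(model, X, ...) {
  X <- check_feature_matrix(X, model$p)
  acc <- matrix(0, nrow(X), length(model$classes))
  for (tr in model$trees) acc <- acc + cpp_predict_tree(tr, X)
  probs <- acc / length(model$trees)
  colnames(probs) <- model$classes
  probs
}

# AdaBoost (SAMME) with decision stumps
fit_adaboost <- function(X, y, n_trees = 100, learning_rate = 0.1, seed = 1) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  K <- length(classes)
  yi <- as_class_int(y, classes)
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  with_seed(seed, {
    for (m in seq_len(n_trees)) {
      tr <- cpp_build_class_tree(X, yi, w, K, ncol(X), 1L, 1L, FALSE,
                                 as.integer(seq_len(n) - 1L))
      pred <- max.col(cpp_predict_tree(tr, X), ties.method = "first") - 1L
      err <- sum(w * (pred != yi)) / sum(w)
      if (err >= 1 - 1 / K) break
      err <- max(err, 1e-10)
      alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
      stumps[[length(stumps) + 1]] <- tr
      alphas <- c(alphas, alpha)
      if (err <= 1e-10) break
      w <- w * exp(alpha * (pred != yi))
      w <- w / sum(w)
    }
  })
  structure(list(trees = stumps, alphas = alphas, classes = classes,
                 p = ncol(X)),
            class = c("gs_adaboost", "gs_model"))
}

#' @export
predict_proba.gs_adaboost <- function(model, X, ...) {
  X <- check_feature_matrix(X, model$p)
  K <- length(model$classes)
  score <- matrix(0, nrow(X), K)
  for (i in seq_along(model$trees)) {
    pred <- max.col(cpp_predict_tree(model$trees[[i]], X),
                    ties.method = "first")
    score[cbind(seq_len(nrow(X)), pred)] <-
      score[cbind(seq_len(nrow(X)), pred)] + model$alphas[i]
  }
  tot <- rowSums(score)
  tot[tot == 0] <- 1
  probs <- score / tot
  probs[rowSums(score) == 0, ] <- 1 / K
  colnames(probs) <- model$classes
  probs
}

# Newton-boosted trees for multinomial deviance; lambda/eta distinguish the
# plain gradient-boosting configuration from the regularized (xgboost-style)
# one.
fit_boosted_trees <- function(X, y, n_rounds = 100, eta = 0.1, max_depth = 3L,
                              lambda = 0, seed = 1, min_leaf = 1L) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  K <- length(classes)
  Y <- one_hot(y, classes)
  n <- nrow(X)
  Fm <- matrix(0, n, K)
  all_trees <- vector("list", n_rounds)
  rows <- as.integer(seq_len(n) - 1L)
  with_seed(seed, {
    for (m in seq_len(n_rounds)) {
      P <- softmax_rows(Fm)
      round_trees <- vector("list", K)
      for (k in seq_len(K)) {
        g <- P[, k] - Y[, k]
        h <- pmax(P[, k] * (1 - P[, k]), 1e-6)
        tr <- cpp_build_reg_tree(X, g, h, lambda, ncol(X),
                                 as.integer(max_depth), as.integer(min_leaf),
                                 FALSE, rows)
        round_trees[[k]] <- tr
        Fm[, k] <- Fm[, k] + eta * cpp_predict_tree(tr, X)[, 1]
      }
      all_trees[[m]] <- round_trees
    }
  })
  structure(list(trees = all_trees, classes = classes, eta = eta, p = ncol(X)),
            class = c("gs_boosted_trees", "gs_model"))
}

fit_gbdt <- function(X, y, n_trees = 100, seed = 1) {
  fit_boosted_trees(X, y, n_rounds = n_trees, eta = 0.1, max_depth = 3L,
                    lambda = 0, seed = seed)
}

fit_xgboost <- function(X, y, n_trees = 100, max_depth = 3L, seed = 1) {
  fit_boosted_trees(X, y, n_rounds = n_trees, eta = 0.3,
                    max_depth = max_depth, lambda = 1, seed = seed)
}

#' @export
predict_proba.gs_boosted_trees <- function(model, X, ...) {
  X <- check_feature_matrix(X, model$p)
  K <- length(model$classes)
  Fm <- matrix(0, nrow(X), K)
  for (round_trees in model$trees) {
    for (k in seq_len(K)) {
      Fm[, k] <- Fm[, k] + model$eta *
        cpp_predict_tree(round_trees[[k]], X)[, 1]
    }
  }
  probs <- softmax_rows(Fm)
  colnames(probs) <- model$classes
  probs
}

check_feature_matrix <- function(X, p) {
  X <- as.matrix(X)
  if (ncol(X) != p) {
    stop("feature count mismatch: model expects ", p, " columns, got ", ncol(X))
  }
  if (any(!is.finite(X))) stop("non-finite feature values")
  X
}
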