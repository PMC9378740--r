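# Non-tree base learners: multilayer perceptron, RBF-kernel SVM with Platt
# scaling + pairwise coupling, and the multinomial logistic regression used
# as the stacking meta-learner.

# ---- multinomial logistic regression (softmax, Adam, small L2) ----

fit_multinom_lr <- function(X, y, l2 = 1e-4, max_iter = 500, lr = 0.1,
                            classes = sort(unique(as.character(y)))) {
  X <- as.matrix(X)
  K <- length(classes)
  Y <- one_hot(y, classes)
  Xb <- cbind(1, X)
  W <- matrix(0, ncol(Xb), K)
  m <- v <- W * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(Xb)
  for (it in seq_len(max_iter)) {
    P <- softmax_rows(Xb %*% W)
    G <- t(Xb) %*% (P - Y) / n + l2 * W
    m <- b1 * m + (1 - b1) * G
    v <- b2 * v + (1 - b2) * G^2
    mh <- m / (1 - b1^it); vh <- v / (1 - b2^it)
    W <- W - lr * mh / (sqrt(vh) + eps)
  }
  structure(list(W = W, classes = classes, p = ncol(X)),
            class = c("gs_multinom_lr", "gs_model"))
}

#' @export
predict_proba.gs_multinom_lr <- function(model, X, ...) {
  X <- check_feature_matrix(X, model$p)
  probs <- softmax_rows(cbind(1, X) %*% model$W)
  colnames(probs) <- model$classes
  probs
}

# ---- multilayer perceptron ----
# One hidden relu layer (100 units), Adam, full batch, cross-entropy with
# small L2; iteration cap per config (default 3000) with a 1e-4 loss-change
# early stop after 10 stale iterations.

fit_mlp <- function(X, y, hidden = 100L, max_iter = 3000, lr = 1e-3,
                    l2 = 1e-4, tol = 1e-4, patience = 10, seed = 1) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  K <- length(classes)
  Y <- one_hot(y, classes)
  p <- ncol(X)
  # standardize inputs for conditioning; store for prediction
  mu <- colMeans(X)
  sg <- apply(X, 2, sd); sg[sg == 0 | !is.finite(sg)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  n <- nrow(Xs)
  params <- with_seed(seed, list(
    W1 = matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden),
    b1 = rep(0, hidden),
    W2 = matrix(rnorm(hidden * K, sd = sqrt(2 / hidden)), hidden, K),
    b2 = rep(0, K)
  ))
  mstate <- lapply(params, function(z) z * 0)
  vstate <- lapply(params, function(z) z * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  best_loss <- Inf; stale <- 0
  for (it in seq_len(max_iter)) {
    H <- pmax(Xs %*% params$W1 +
                matrix(params$b1, n, hidden, byrow = TRUE), 0)
    P <- softmax_rows(H %*% params$W2 +
                        matrix(params$b2, n, K, byrow = TRUE))
    loss <- -mean(log(pmax(rowSums(P * Y), 1e-12))) +
      l2 / 2 * (sum(params$W1^2) + sum(params$W2^2))
    if (loss > best_loss - tol) stale <- stale + 1 else stale <- 0
    if (loss < best_loss) best_loss <- loss
    if (stale >= patience) break
    dZ2 <- (P - Y) / n
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = t(H) %*% dZ2 + l2 * params$W2,
      b2 = colSums(dZ2)
    )
    dH <- dZ2 %*% t(params$W2)
    dH[H <= 0] <- 0
    grads$W1 <- t(Xs) %*% dH + l2 * params$W1
    grads$b1 <- colSums(dH)
    for (nm in names(params)) {
      mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grads[[nm]]
      vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grads[[nm]]^2
      mh <- mstate[[nm]] / (1 - beta1^it)
      vh <- vstate[[nm]] / (1 - beta2^it)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  structure(list(params = params, classes = classes, mu = mu, sg = sg, p = p,
                 hidden = hidden),
            class = c("gs_mlp", "gs_model"))
}

#' @export
predict_proba.gs_mlp <- function(model, X, ...) {
  X <- check_feature_matrix(X, model$p)
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sg, "/")
  n <- nrow(Xs)
  H <- pmax(Xs %*% model$params$W1 +
              matrix(model$params$b1, n, model$hidden, byrow = TRUE), 0)
  probs <- softmax_rows(H %*% model$params$W2 +
                          matrix(model$params$b2, n,
                                 length(model$classes), byrow = TRUE))
  colnames(probs) <- model$classes
  probs
}

# ---- RBF-kernel SVM: one-vs-one SMO, Platt scaling, pairwise coupling ----

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# simplified SMO (binary, labels +-1)
smo_binary <- function(K, y, C = 1, tol = 1e-3, max_passes = 10,
                       max_iter = 2000) {
  n <- length(y)
  alpha <- rep(0, n); b <- 0
  fcache <- function(i) sum(alpha * y * K[, i]) + b
  passes <- 0; iter <- 0
  while (passes < max_passes && iter < max_iter) {
    changed <- 0
    iter <- iter + 1
    for (i in seq_len(n)) {
      Ei <- fcache(i) - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- i
        while (j == i) j <- floor(runif(1, 1, n + 1))
        Ej <- fcache(j) - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        alpha[j] <- aj_old - y[j] * (Ei - Ej) / eta
        alpha[j] <- min(H, max(L, alpha[j]))
        if (abs(alpha[j] - aj_old) < 1e-5) next
        alpha[i] <- ai_old + y[i] * y[j] * (aj_old - alpha[j])
        b1 <- b - Ei - y[i] * (alpha[i] - ai_old) * K[i, i] -
          y[j] * (alpha[j] - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (alpha[i] - ai_old) * K[i, j] -
          y[j] * (alpha[j] - aj_old) * K[j, j]
        b <- if (alpha[i] > 0 && alpha[i] < C) b1
             else if (alpha[j] > 0 && alpha[j] < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  list(alpha = alpha, b = b)
}

# Platt sigmoid on training decision values with regularized targets
platt_sigmoid <- function(f, y01) {
  np <- sum(y01 == 1); nn <- sum(y01 == 0)
  t_pos <- (np + 1) / (np + 2); t_neg <- 1 / (nn + 2)
  targ <- ifelse(y01 == 1, t_pos, t_neg)
  # logistic regression on f: minimize cross-entropy over (A, B), Newton steps
  A <- 0; B <- log((nn + 1) / (np + 1))
  for (it in 1:100) {
    z <- A * f + B
    p <- 1 / (1 + exp(z)) # P(y=1) = 1/(1+exp(A f + B))
    g <- p - targ
    # gradient wrt (A, B): d z -> -g (since p decreasing in z)
    w <- pmax(p * (1 - p), 1e-12)
    gA <- sum(-g * f); gB <- sum(-g)
    hAA <- sum(w * f * f) + 1e-12; hAB <- sum(w * f); hBB <- sum(w) + 1e-12
    det <- hAA * hBB - hAB^2
    if (abs(det) < 1e-12) break
    dA <- (gB * hAB - gA * hBB) / det
    dB <- (gA * hAB - gB * hAA) / det
    A <- A + dA; B <- B + dB
    if (max(abs(dA), abs(dB)) < 1e-8) break
  }
  c(A = A, B = B)
}

fit_svm_rbf <- function(X, y, C = 1, gamma = NULL, seed = 1) {
  X <- as.matrix(X)
  classes <- sort(unique(as.character(y)))
  y <- as.character(y)
  if (is.null(gamma)) {
    v <- var(as.numeric(X))
    gamma <- 1 / (ncol(X) * ifelse(v > 0, v, 1))
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  models <- with_seed(seed, lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    Xi <- X[idx, , drop = FALSE]
    yi <- ifelse(y[idx] == pr[1], 1, -1)
    K <- rbf_kernel(Xi, Xi, gamma)
    fit <- smo_binary(K, yi, C = C)
    f <- as.numeric(K %*% (fit$alpha * yi) + fit$b)
    sig <- platt_sigmoid(f, as.integer(yi == 1))
    list(pair = pr, X = Xi, y = yi, alpha = fit$alpha, b = fit$b, sig = sig)
  }))
  structure(list(models = models, classes = classes, gamma = gamma,
                 p = ncol(X)),
            class = c("gs_svm_rbf", "gs_model"))
}

#' @export
predict_proba.gs_svm_rbf <- function(model, X, ...) {
  X <- check_feature_matrix(X, model$p)
  classes <- model$classes
  K <- length(classes)
  n <- nrow(X)
  # pairwise P(class i beats class j)
  R <- array(0.5, c(n, K, K))
  for (m in model$models) {
    Kx <- rbf_kernel(X, m$X, model$gamma)
    f <- as.numeric(Kx %*% (m$alpha * m$y) + m$b)
    pij <- 1 / (1 + exp(m$sig["A"] * f + m$sig["B"]))
    pij <- pmin(pmax(pij, 1e-7), 1 - 1e-7)
    i <- match(m$pair[1], classes); j <- match(m$pair[2], classes)
    R[, i, j] <- pij
    R[, j, i] <- 1 - pij
  }
  # pairwise coupling: p_i = 1 / (sum_j 1/r_ij - (K - 2)), normalized
  probs <- matrix(0, n, K)
  for (i in seq_len(K)) {
    inv_sum <- rep(0, n)
    for (j in setdiff(seq_len(K), i)) inv_sum <- inv_sum + 1 / R[, i, j]
    probs[, i] <- 1 / pmax(inv_sum - (K - 2), 1e-7)
  }
  probs <- probs / rowSums(probs)
  colnames(probs) <- classes
  probs
}

# ---- configuration and dispatcher ----

BASE_MODEL_KINDS <- c("svm_rbf", "random_forest", "extra_trees", "mlp",
                      "adaboost", "gbdt", "xgboost")

#' Base-learner configuration
#'
#' Hyperparameters for the seven heterogeneous base learners. Defaults:
#' 100 trees for all tree ensembles, AdaBoost learning rate 0.1, XGBoost
#' maximum tree depth 3, MLP iteration cap 3000, RBF kernel for the SVM.
#'
#' @param n_trees number of trees for tree ensembles (default 100)
#' @param learning_rate AdaBoost shrinkage (default 0.1)
#' @param max_depth XGBoost maximum tree depth (default 3)
#' @param mlp_iters MLP iteration cap (default 3000)
#' @param seed integer seed
#' @return a `base_model_config` list
#' @export
base_model_config <- function(n_trees = 100, learning_rate = 0.1,
                              max_depth = 3, mlp_iters = 3000, seed = 1) {
  stopifnot(n_trees > 0, learning_rate > 0, max_depth > 0, mlp_iters > 0)
  structure(list(n_trees = n_trees, learning_rate = learning_rate,
                 max_depth = max_depth, mlp_iters = mlp_iters, seed = seed),
            class = "base_model_config")
}

#' Fit one base learner
#'
#' @param kind one of `svm_rbf`, `random_forest`, `extra_trees`, `mlp`,
#'   `adaboost`, `gbdt`, `xgboost`
#' @param X numeric feature matrix
#' @param y class labels
#' @param config a [base_model_config()]
#' @return fitted model answering to [predict_proba()]
#' @export
fit_base_model <- function(kind, X, y, config = base_model_config()) {
  kind <- match.arg(kind, BASE_MODEL_KINDS)
  seed <- derive_seed(config$seed, kind)
  switch(kind,
    svm_rbf = fit_svm_rbf(X, y, seed = seed),
    random_forest = fit_random_forest(X, y, n_trees = config$n_trees,
                                      seed = seed),
    extra_trees = fit_extra_trees(X, y, n_trees = config$n_trees,
                                  seed = seed),
    mlp = fit_mlp(X, y, max_iter = config$mlp_iters, seed = seed),
    adaboost = fit_adaboost(X, y, n_trees = config$n_trees,
                            learning_rate = config$learning_rate,
                            seed = seed),
    gbdt = fit_gbdt(X, y, n_trees = config$n_trees, seed = seed),
    xgboost = fit_xgboost(X, y, n_trees = config$n_trees,
                          max_depth = config$max_depth, seed = seed)
  )
}
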