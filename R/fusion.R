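# Extreme learning machine late fusion of the time-series and image branches.

#' Build fusion features from the two branch outcomes
#'
#' Concatenates the time-series branch class probabilities (3) with the
#' image branch trial probabilities (3) for the same trials, in outcome row
#' order of `ts_out`.
#'
#' @param ts_out,img_out `classifier_outcome` data.frames covering the same
#'   trial ids
#' @return n-by-6 numeric matrix with trial ids as row names
#' @export
build_fusion_features <- function(ts_out, img_out) {
  if (!setequal(ts_out$trial_id, img_out$trial_id) ||
      nrow(ts_out) != nrow(img_out)) {
    stop("trial id mismatch between branches")
  }
  img_out <- img_out[match(ts_out$trial_id, img_out$trial_id), , drop = FALSE]
  X <- cbind(outcome_probs(ts_out), outcome_probs(img_out))
  colnames(X) <- c(paste0("ts_", sub("^p_", "", colnames(X)[1:3])),
                   paste0("img_", sub("^p_", "", colnames(X)[4:6])))
  rownames(X) <- ts_out$trial_id
  X
}

#' Train an extreme learning machine classifier
#'
#' A single hidden layer with tanh activation. Input weights `W` and bias
#' `b` are drawn once from uniform(-1, 1) under the seed and then frozen;
#' the output weights `beta` are the minimum-norm least-squares solution
#' (Moore-Penrose pseudo-inverse of the hidden activations against one-hot
#' targets).
#'
#' @param X n-by-d numeric feature matrix, finite
#' @param y class labels
#' @param n_hidden hidden nodes (default 20)
#' @param seed integer seed for the random weights
#' @return an `elm_model`
#' @export
elm_train <- function(X, y, n_hidden = 20, seed = 1) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite inputs")
  stopifnot(nrow(X) >= 1, n_hidden >= 1)
  classes <- canonical_classes(y)
  d <- ncol(X)
  Wb <- with_seed(seed, list(
    W = matrix(runif(d * n_hidden, -1, 1), d, n_hidden),
    b = runif(n_hidden, -1, 1)
  ))
  H <- tanh(X %*% Wb$W + matrix(Wb$b, nrow(X), n_hidden, byrow = TRUE))
  beta <- pinv(H) %*% one_hot(y, classes)
  structure(list(W = Wb$W, b = Wb$b, beta = beta, classes = classes,
                 n_hidden = n_hidden, d = d, seed = seed),
            class = "elm_model")
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> %d inputs -> %d tanh hidden nodes -> %d classes\n",
              x$d, x$n_hidden, length(x$classes)))
  invisible(x)
}

#' Predict with a fitted ELM
#'
#' Scores are `tanh(XW + b) %*% beta`; probabilities are the softmax of the
#' scores (raw least-squares scores are unbounded).
#'
#' @param model an `elm_model`
#' @param X feature matrix with the training column count
#' @param trial_ids optional ids for the outcome (default row names or index)
#' @return a `classifier_outcome` data.frame
#' @export
elm_predict <- function(model, X, trial_ids = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop("dimension mismatch: model expects ", model$d, " inputs")
  }
  H <- tanh(X %*% model$W + matrix(model$b, nrow(X), model$n_hidden,
                                   byrow = TRUE))
  scores <- H %*% model$beta
  probs <- softmax_rows(scores)
  if (is.null(trial_ids)) trial_ids <- rownames(X)
  if (is.null(trial_ids)) trial_ids <- as.character(seq_len(nrow(X)))
  classifier_outcome(trial_ids, probs, model$classes)
}

#' Overall accuracy from a confusion matrix
#'
#' @param m square matrix of non-negative integer counts, rows = actual,
#'   columns = predicted
#' @return percentage `100 * trace / total`, rounded to one decimal
#' @export
accuracy_from_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (any(m < 0) || any(m != round(m))) {
    stop("confusion matrix must hold non-negative integer counts")
  }
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  round(100 * sum(diag(m)) / total, 1)
}

#' Confusion matrix of predicted vs actual skill labels
#'
#' @param actual,predicted label vectors (character or factor)
#' @param classes class order (default the three skill levels)
#' @return K-by-K integer matrix, rows = actual, columns = predicted
#' @export
confusion_matrix <- function(actual, predicted, classes = SKILL_LEVELS) {
  a <- factor(as.character(actual), levels = classes)
  p <- factor(as.character(predicted), levels = classes)
  unclass(table(Actual = a, Predicted = p))
}

#' Serialize / restore an ELM model as JSON
#'
#' @param model an `elm_model`
#' @param path file path
#' @return `path` invisibly; `read_elm_json` returns the model
#' @export
write_elm_json <- function(model, path) {
  jsonlite::write_json(
    list(W = as.numeric(model$W), b = as.numeric(model$b),
         beta = as.numeric(model$beta), classes = model$classes,
         n_hidden = model$n_hidden, d = model$d, seed = model$seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_elm_json
#' @export
read_elm_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W = matrix(j$W, j$d, j$n_hidden),
                 b = as.numeric(j$b),
                 beta = matrix(j$beta, j$n_hidden, length(j$classes)),
                 classes = j$classes, n_hidden = j$n_hidden, d = j$d,
                 seed = j$seed),
            class = "elm_model")
}
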