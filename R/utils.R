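#' @useDynLib gazeskill, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx kmeans median rnorm runif rpois sd var predict
#' @importFrom utils read.csv write.csv
NULL

SKILL_LEVELS <- c("novice", "intermediate", "expert")

#' Skill-level factor
#'
#' Canonical ordered factor for the three skill levels. Ordering is
#' novice < intermediate < expert throughout the package.
#'
#' @param x character vector of levels
#' @return ordered factor with levels novice, intermediate, expert
#' @export
skill_factor <- function(x) {
  bad <- setdiff(unique(as.character(x)), SKILL_LEVELS)
  if (length(bad) > 0) {
    stop("unknown skill level(s): ", paste(bad, collapse = ", "))
  }
  factor(as.character(x), levels = SKILL_LEVELS, ordered = TRUE)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic package internals run through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a reproducible child seed < 2^31 from a master seed and a text tag.
# Simple 32-bit FNV-style fold; stable across platforms and R sessions.
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- as.double(master %% 2147483647)
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

softmax_rows <- function(m) {
  m <- as.matrix(m)
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

one_hot <- function(y, levels_) {
  y <- factor(as.character(y), levels = levels_)
  stopifnot(!anyNA(y))
  m <- matrix(0, length(y), length(levels_),
              dimnames = list(NULL, levels_))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

# Moore-Penrose pseudo-inverse via SVD (tolerance as in MASS::ginv)
pinv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

# Stratified index split: returns list(train=, test=) with train_fraction of
# each class in train (rounded, at least 1 per class on each side when the
# class has >= 2 members).
stratified_split <- function(labels, train_fraction, seed) {
  labels <- as.character(labels)
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(length(idx) * train_fraction)
      n_tr <- max(1L, min(length(idx) - 1L, n_tr))
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

# Stratified k-fold assignment: integer vector of fold ids 1..k
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- sample(idx)
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

accuracy <- function(pred, truth) {
  mean(as.character(pred) == as.character(truth))
}

# class order for model outputs: canonical skill order when the labels are
# skill levels, alphabetical otherwise
canonical_classes <- function(labels) {
  u <- unique(as.character(labels))
  if (all(u %in% SKILL_LEVELS)) SKILL_LEVELS[SKILL_LEVELS %in% u] else sort(u)
}
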