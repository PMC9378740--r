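# Independent brute-force oracles used to validate the package
# implementations. These deliberately share no code with R/.

# minimum Euclidean distance of S to all windows of T, plain loop
bf_subseq_dist <- function(S, T) {
  l <- length(S)
  best <- Inf
  for (off in 0:(length(T) - l)) {
    d <- sqrt(sum((S - T[off + seq_len(l)])^2))
    if (d < best) best <- d
  }
  best
}

bf_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# exhaustive information gain over all midpoints between consecutive sorted
# distances
bf_info_gain <- function(d, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) return(0)
  parent <- bf_entropy(table(labels))
  sd_ <- sort(unique(d))
  best <- 0
  if (length(sd_) < 2) return(0)
  for (i in seq_len(length(sd_) - 1)) {
    thr <- (sd_[i] + sd_[i + 1]) / 2
    left <- labels[d <= thr]
    right <- labels[d > thr]
    gain <- parent -
      length(left) / length(d) * bf_entropy(table(left)) -
      length(right) / length(d) * bf_entropy(table(right))
    best <- max(best, gain)
  }
  best
}

bf_f_stat <- function(d, labels) {
  groups <- split(d, as.character(labels))
  k <- length(groups)
  n <- length(d)
  gm <- mean(d)
  ssb <- sum(sapply(groups, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

bf_mood_median <- function(d, labels) {
  labels <- as.character(labels)
  med <- median(d)
  above <- d > med
  if (all(above) || all(!above)) return(0)
  tab <- table(above, labels)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# exact optimal 1-D 3-partition by within-cluster sum of squares (exhaustive
# over the two cut points of the sorted values)
bf_best_3partition <- function(v) {
  s <- sort(v)
  n <- length(s)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  wss <- function(i, j) {
    m <- cs[j] - if (i > 1) cs[i - 1] else 0
    q <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    q - m^2 / (j - i + 1)
  }
  best <- Inf; cut <- c(1, 2)
  for (a in 1:(n - 2)) {
    for (b in (a + 1):(n - 1)) {
      w <- wss(1, a) + wss(a + 1, b) + wss(b + 1, n)
      if (w < best) { best <- w; cut <- c(a, b) }
    }
  }
  r <- rank(v, ties.method = "first")
  out <- rep("expert", n)
  out[r <= cut[1]] <- "novice"
  out[r > cut[1] & r <= cut[2]] <- "intermediate"
  out
}
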