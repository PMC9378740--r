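#' Series set container
#'
#' Holds the resampled two-channel (x, y) gaze series for a set of trials.
#' All series share one length; values are stored as two n-by-length
#' matrices, one per channel, with rows aligned to `trial_ids`.
#'
#' @param x n-by-length matrix of x-coordinate series
#' @param y n-by-length matrix of y-coordinate series
#' @param trial_ids character vector of length n
#' @return a `series_set` object
#' @export
series_set <- function(x, y, trial_ids) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(identical(dim(x), dim(y)), nrow(x) == length(trial_ids),
            all(is.finite(x)), all(is.finite(y)))
  structure(list(x = x, y = y, trial_ids = as.character(trial_ids),
                 length = ncol(x)),
            class = "series_set")
}

#' @export
print.series_set <- function(x, ...) {
  cat(sprintf("<series_set> %d trials x %d points x 2 channels (x,y)\n",
              nrow(x$x), x$length))
  invisible(x)
}

#' Resample a series to a fixed length
#'
#' Linear interpolation at evenly spaced fractional positions over the
#' original index range. The first and last values are always preserved;
#' `target_len == length(series)` is the identity.
#'
#' @param series numeric vector (length >= 2)
#' @param target_len output length (>= 2)
#' @return numeric vector of length `target_len`
#' @export
resample_series <- function(series, target_len) {
  n <- length(series)
  if (n < 2) stop("series must have at least 2 points")
  if (target_len < 2) stop("target_len must be at least 2")
  if (target_len == n) return(series)
  approx(x = seq(0, n - 1), y = series,
         xout = seq(0, n - 1, length.out = target_len))$y
}

#' Build a series set from gaze recordings
#'
#' Invalid samples are dropped and the gaps bridged by linear interpolation
#' over time before resampling each channel to `target_len` points.
#'
#' @param recs list of gaze recordings
#' @param target_len common output length
#' @return a [series_set()]
#' @export
gaze_to_series_set <- function(recs, target_len) {
  n <- length(recs)
  stopifnot(n >= 1)
  xm <- matrix(0, n, target_len)
  ym <- matrix(0, n, target_len)
  ids <- character(n)
  for (i in seq_len(n)) {
    s <- recs[[i]]$samples
    v <- s[s$valid, , drop = FALSE]
    if (nrow(v) < 2) {
      stop("trial ", recs[[i]]$trial_id, " has fewer than 2 valid samples")
    }
    # interpolate over invalid gaps onto the full time grid, then resample
    xi <- approx(v$t, v$x, xout = s$t, rule = 2)$y
    yi <- approx(v$t, v$y, xout = s$t, rule = 2)$y
    xm[i, ] <- resample_series(xi, target_len)
    ym[i, ] <- resample_series(yi, target_len)
    ids[i] <- recs[[i]]$trial_id
  }
  series_set(xm, ym, ids)
}

#' Shapelet-to-series distance
#'
#' Minimum Euclidean distance between `S` and every contiguous subsequence of
#' `T` of the same length. With `znorm = TRUE` both the shapelet and each
#' window are standardized (mean 0, sd 1) before the distance is taken.
#'
#' @param S numeric subsequence, length l
#' @param T numeric series, length m >= l
#' @param znorm standardize subsequences before comparing (default FALSE)
#' @return non-negative scalar distance
#' @export
subsequence_distance <- function(S, T, znorm = FALSE) {
  l <- length(S); m <- length(T)
  if (l > m) stop("subsequence longer than series")
  if (!znorm) return(cpp_subseq_dist(as.numeric(S), as.numeric(T)))
  zn <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) return(v * 0)
    (v - mean(v)) / s
  }
  Sz <- zn(S)
  best <- Inf
  for (off in 0:(m - l)) {
    d <- sqrt(sum((Sz - zn(T[off + seq_len(l)]))^2))
    if (d < best) best <- d
  }
  best
}

#' Enumerate shapelet candidates
#'
#' All contiguous subsequences of every series and channel with lengths in
#' `[lmin, lmax]`. Candidates are returned as an index table (not
#' materialized values): one row per candidate with `channel`, `trial`
#' (row index into the set), `start` (0-based) and `length`.
#'
#' @param sset a [series_set()]
#' @param lmin,lmax candidate length bounds, `2 <= lmin <= lmax <= length`
#' @return data.frame of candidate coordinates
#' @export
generate_candidates <- function(sset, lmin, lmax) {
  stopifnot(inherits(sset, "series_set"))
  L <- sset$length
  if (!(2 <= lmin && lmin <= lmax && lmax <= L)) {
    stop("need 2 <= lmin <= lmax <= series length (", L, ")")
  }
  n <- nrow(sset$x)
  lens <- lmin:lmax
  per_series <- sum(L - lens + 1)
  grid <- do.call(rbind, lapply(lens, function(l) {
    data.frame(start = 0:(L - l), length = l)
  }))
  out <- do.call(rbind, lapply(c("x", "y"), function(ch) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(channel = ch, trial = i, start = grid$start,
                 length = grid$length, stringsAsFactors = FALSE)
    }))
  }))
  attr(out, "per_channel_count") <- n * per_series
  out
}

candidate_values <- function(sset, cand) {
  m <- sset[[cand$channel]]
  m[cand$trial, cand$start + seq_len(cand$length)]
}

#' Quality of a shapelet candidate
#'
#' Computes the distance from the candidate to every series in the set (on
#' the candidate's channel) and scores how well the distance list separates
#' the class labels:
#' \describe{
#'   \item{info_gain}{maximum over split thresholds of the entropy reduction
#'     (log base 2) of the label distribution}
#'   \item{f_stat}{one-way ANOVA F statistic of distances grouped by label}
#'   \item{mood_median}{Pearson chi-square statistic of the above/below
#'     pooled-median contingency table}
#' }
#'
#' @param values numeric candidate subsequence
#' @param channel `"x"` or `"y"`
#' @param sset a [series_set()]
#' @param labels class labels aligned with the set's trials
#' @param measure quality measure (default `info_gain`)
#' @param znorm standardize subsequences before distance (default FALSE)
#' @return scalar quality (finite, >= 0)
#' @export
assess_candidate <- function(values, channel, sset, labels,
                             measure = c("info_gain", "f_stat", "mood_median"),
                             znorm = FALSE) {
  measure <- match.arg(measure)
  stopifnot(channel %in% c("x", "y"), length(labels) == nrow(sset$x))
  d <- shapelet_distances(values, channel, sset, znorm)
  quality_from_distances(d, labels, measure)
}

shapelet_distances <- function(values, channel, sset, znorm = FALSE) {
  if (!znorm) {
    cpp_subseq_dist_rows(as.numeric(values), sset[[channel]])
  } else {
    apply(sset[[channel]], 1, function(row) {
      subsequence_distance(values, row, znorm = TRUE)
    })
  }
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

quality_from_distances <- function(d, labels, measure) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (measure == "info_gain") {
    if (length(classes) < 2) return(0)
    ord <- order(d)
    ys <- labels[ord]
    ds <- d[ord]
    n <- length(ds)
    parent <- entropy_bits(table(labels))
    # cumulative class counts after each sorted position
    counts <- sapply(classes, function(cl) cumsum(ys == cl))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = n)
    total <- table(factor(labels, levels = classes))
    best <- 0
    for (i in seq_len(n - 1)) {
      if (ds[i + 1] <= ds[i]) next # split only between distinct values
      left <- counts[i, ]
      right <- as.numeric(total) - left
      gain <- parent - (i / n) * entropy_bits(left) -
        ((n - i) / n) * entropy_bits(right)
      if (gain > best) best <- gain
    }
    return(best)
  }
  if (measure == "f_stat") {
    if (length(classes) < 2) return(0)
    groups <- split(d, labels)
    k <- length(groups)
    n <- length(d)
    gm <- mean(d)
    ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
    if (ssw <= 0 || n <= k) return(if (ssb > 0) Inf else 0)
    return((ssb / (k - 1)) / (ssw / (n - k)))
  }
  # mood_median: 2 x K contingency chi-square around the pooled median
  med <- median(d)
  above <- d > med
  if (all(above) || all(!above) || length(classes) < 2) return(0)
  tab <- table(above, factor(labels, levels = classes))
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp_tab)^2 / exp_tab)
}

#' Prune self-similar shapelets
#'
#' Greedy scan over shapelets sorted by quality (descending): a shapelet is
#' kept only if its half-open index range `[start, start + length)` on the
#' same source trial and channel does not overlap any already-kept range.
#'
#' @param shapelets list of shapelet records sorted by quality descending
#' @return pruned list, original order preserved
#' @export
remove_self_similar <- function(shapelets) {
  kept <- list()
  for (sh in shapelets) {
    clash <- any(vapply(kept, function(k) {
      k$source_trial == sh$source_trial && k$channel == sh$channel &&
        sh$start < k$start + k$length && k$start < sh$start + sh$length
    }, logical(1)))
    if (!clash) kept[[length(kept) + 1]] <- sh
  }
  kept
}

#' Extract the top-k shapelets from a labelled series set
#'
#' Enumerates candidates (or a seed-controlled random subsample of at most
#' `max_candidates` of them), scores each with the chosen quality measure,
#' sorts by quality (ties broken by shorter length, then earlier start, then
#' lower trial id), prunes self-similar candidates and returns at most `k`
#' shapelets. Both gaze channels are searched independently.
#'
#' @param sset a [series_set()]
#' @param labels class labels aligned with trials
#' @param k maximum number of shapelets (default 10)
#' @param lmin,lmax candidate length bounds; default 3% and 10% of the
#'   series length (at least 2)
#' @param measure quality measure, see [assess_candidate()]
#' @param max_candidates cap on the number of scored candidates
#'   (default 500; `Inf` for full enumeration)
#' @param seed integer seed for candidate subsampling
#' @param znorm standardize subsequences before distance (default FALSE)
#' @return list of shapelets; each has `values`, `source_trial`, `start`,
#'   `length`, `channel`, `quality`
#' @export
extract_shapelets <- function(sset, labels, k = 10,
                              lmin = max(2L, round(0.03 * sset$length)),
                              lmax = max(2L, round(0.10 * sset$length)),
                              measure = "info_gain",
                              max_candidates = 500, seed = 1,
                              znorm = FALSE) {
  stopifnot(k >= 1, length(labels) == nrow(sset$x))
  cands <- generate_candidates(sset, lmin, lmax)
  if (nrow(cands) == 0) stop("no candidates generated")
  if (is.finite(max_candidates) && nrow(cands) > max_candidates) {
    pick <- with_seed(seed, sample(nrow(cands), max_candidates))
    cands <- cands[sort(pick), , drop = FALSE]
  }
  qual <- numeric(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    v <- candidate_values(sset, cands[i, ])
    qual[i] <- quality_from_distances(
      shapelet_distances(v, cands$channel[i], sset, znorm), labels, measure)
  }
  tid <- sset$trial_ids[cands$trial]
  ord <- order(-qual, cands$length, cands$start, tid)
  shapelets <- lapply(ord, function(i) {
    list(values = candidate_values(sset, cands[i, ]),
         source_trial = tid[i],
         start = cands$start[i],
         length = cands$length[i],
         channel = cands$channel[i],
         quality = qual[i])
  })
  pruned <- remove_self_similar(shapelets)
  pruned[seq_len(min(k, length(pruned)))]
}

#' Shapelet transform: distances of every series to every shapelet
#'
#' @param sset a [series_set()]
#' @param shapelets list of shapelets from [extract_shapelets()]
#' @param znorm standardize subsequences before distance (default FALSE)
#' @return n-by-k numeric matrix; entry (i, j) is the distance of series i
#'   (on shapelet j's channel) to shapelet j. Row names are trial ids.
#' @export
shapelet_transform <- function(sset, shapelets, znorm = FALSE) {
  stopifnot(length(shapelets) >= 1)
  cols <- lapply(shapelets, function(sh) {
    if (!sh$channel %in% c("x", "y")) stop("unknown channel: ", sh$channel)
    if (sh$length > sset$length) stop("shapelet longer than series")
    shapelet_distances(sh$values, sh$channel, sset, znorm)
  })
  fm <- do.call(cbind, cols)
  rownames(fm) <- sset$trial_ids
  colnames(fm) <- paste0("sh", seq_along(shapelets))
  fm
}

#' Write/read shapelets as CSV
#'
#' One row per shapelet: `channel,source_trial,start,length,quality`
#' followed by the values `v1..vl` (ragged rows padded with NA).
#'
#' @param shapelets list of shapelets
#' @param path output path
#' @return `path`, invisibly
#' @export
write_shapelets_csv <- function(shapelets, path) {
  lmax <- max(vapply(shapelets, function(s) s$length, numeric(1)))
  rows <- lapply(shapelets, function(s) {
    vals <- c(s$values, rep(NA_real_, lmax - s$length))
    cbind(data.frame(channel = s$channel, source_trial = s$source_trial,
                     start = s$start, length = s$length, quality = s$quality),
          as.data.frame(t(vals)))
  })
  df <- do.call(rbind, rows)
  names(df)[-(1:5)] <- paste0("v", seq_len(lmax))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shapelets_csv
#' @export
read_shapelets_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    vals <- as.numeric(df[i, -(1:5)])
    vals <- vals[!is.na(vals)]
    list(values = vals, source_trial = as.character(df$source_trial[i]),
         start = df$start[i], length = df$length[i],
         channel = df$channel[i], quality = df$quality[i])
  })
}
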