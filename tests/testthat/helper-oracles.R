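# Independent brute-force oracles the implementation is checked against.
# These deliberately use the dumbest possible algorithm.

# Pairwise differencing by explicit loop.
oracle_ilis <- function(times) {
  if (length(times) < 2) return(numeric(0))
  out <- numeric(length(times) - 1)
  for (i in 2:length(times)) out[i - 1] <- times[i] - times[i - 1]
  out
}

# Enumerate all maximal runs with internal gaps < max_ili by scanning every
# start index.
oracle_bouts <- function(times, max_ili = 1, min_licks = 4) {
  n <- length(times)
  runs <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) < max_ili) j <- j + 1
    runs[[length(runs) + 1]] <- times[i:j]
    i <- j + 1
  }
  is_bout <- vapply(runs, function(r) length(r) >= min_licks, logical(1))
  list(
    n_bouts = sum(is_bout),
    bout_sizes = vapply(runs[is_bout], length, integer(1)),
    bout_starts = vapply(runs[is_bout], min, numeric(1)),
    bout_ends = vapply(runs[is_bout], max, numeric(1)),
    stray = unlist(runs[!is_bout]) %||% numeric(0)
  )
}

# Merged-timeline scan, one pair at a time.
oracle_quick_switches <- function(tw, ts, window = 60) {
  tl <- rbind(data.frame(t = tw, b = rep("water", length(tw))),
              data.frame(t = ts, b = rep("sucrose", length(ts))))
  tl <- tl[order(tl$t), ]
  ws <- 0; sw <- 0
  if (nrow(tl) >= 2) {
    for (i in 2:nrow(tl)) {
      if (tl$b[i] != tl$b[i - 1] && (tl$t[i] - tl$t[i - 1]) < window) {
        if (tl$b[i - 1] == "water") ws <- ws + 1 else sw <- sw + 1
      }
    }
  }
  c(water_to_sucrose = ws, sucrose_to_water = sw)
}

oracle_returns <- function(tw, ts, pause = 300) {
  tl <- rbind(data.frame(t = tw, b = rep("water", length(tw))),
              data.frame(t = ts, b = rep("sucrose", length(ts))))
  tl <- tl[order(tl$t), ]
  w <- 0; s <- 0
  if (nrow(tl) >= 2) {
    for (i in 2:nrow(tl)) {
      if ((tl$t[i] - tl$t[i - 1]) > pause) {
        if (tl$b[i] == "water") w <- w + 1 else s <- s + 1
      }
    }
  }
  c(water = w, sucrose = s)
}

# O(n^2) topographic prominence: walk out from each local maximum sample
# by sample until a strictly higher sample (or the edge).
oracle_peaks <- function(x, prominence) {
  n <- length(x)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) peaks <- c(peaks, i)
  }
  keep <- logical(length(peaks))
  prom <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    lmin <- x[p]; j <- p
    while (j > 1 && x[j - 1] <= x[p]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    lbase <- if (j == 1) min(x[1:p]) else lmin
    rmin <- x[p]; j <- p
    while (j < n && x[j + 1] <= x[p]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    rbase <- if (j == n) min(x[p:n]) else rmin
    prom[k] <- x[p] - max(lbase, rbase)
    keep[k] <- prom[k] > prominence
  }
  list(index = peaks[keep], prominence = prom[keep])
}

# Random sorted lick train with a mix of short and long gaps.
random_train <- function(n, p_long = 0.2, short_max = 0.9, long_max = 600) {
  gaps <- ifelse(runif(n) < p_long,
                 runif(n, 1.0, long_max),
                 runif(n, 0.06, short_max))
  cumsum(gaps)
}

# Nearest-neighbor matching of detected to true lick times within tol;
# returns hits and spurious (unmatched detections).
match_events <- function(truth, detected, tol = 0.005) {
  if (!length(truth) || !length(detected)) {
    return(c(hits = 0, spurious = length(detected)))
  }
  idx <- findInterval(truth, detected)
  lo <- pmax(idx, 1)
  hi <- pmin(idx + 1, length(detected))
  near <- ifelse(abs(detected[lo] - truth) <= abs(detected[hi] - truth), lo, hi)
  ok <- abs(detected[near] - truth) <= tol
  hits <- length(unique(near[ok]))
  c(hits = hits, spurious = length(detected) - hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
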