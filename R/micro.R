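#' Interlick intervals of a train
#'
#' @param train a [lick_train()] or sorted numeric vector of times (s).
#' @return Numeric vector of the n-1 successive intervals (s); empty for
#'   fewer than two licks.
#' @examples
#' compute_ilis(c(1.0, 1.1, 1.3))
#' @export
compute_ilis <- function(train) {
  diff(lick_times(train))
}

#' Classify interlick intervals into burst / cluster / pause groups
#'
#' Mouse licking is rhythmic at ~8 Hz; its ILI histogram separates into
#' three groups, interpreted as uninterrupted rhythmic licking (burst,
#' <180 ms) and the miss of one (cluster, 180-320 ms) or two (pause,
#' 320-1000 ms) licks. Intervals of 1 s or more separate lick bouts.
#' Binning is half-open (`[a, b)`) throughout, so an ILI of exactly
#' 0.180 s is a cluster.
#'
#' @param ilis numeric vector of ILIs (s); negative values indicate an
#'   unsorted train and raise an error.
#' @param boundaries strictly increasing class boundaries (s); defaults
#'   `c(0.180, 0.320, 1.000)`.
#' @return An object of class `ili_classification`: per-group `counts`
#'   (burst, cluster, pause, inter_bout), `fractions` of the three
#'   within-bout groups (relative to ILIs < the bout boundary), `n_within`
#'   and the `boundaries` used.
#' @examples
#' classify_ilis(c(0.1, 0.25, 0.5, 2.0))$counts
#' @export
classify_ilis <- function(ilis, boundaries = c(0.180, 0.320, 1.000)) {
  if (length(boundaries) != 3 || any(diff(boundaries) <= 0)) {
    stop("boundaries must be three strictly increasing values", call. = FALSE)
  }
  if (any(ilis < 0)) stop("negative ILI: input train was not sorted", call. = FALSE)
  grp <- findInterval(ilis, c(0, boundaries))
  counts <- tabulate(grp, nbins = 4L)
  names(counts) <- c("burst", "cluster", "pause", "inter_bout")
  n_within <- sum(counts[1:3])
  fractions <- if (n_within > 0) counts[1:3] / n_within else
    setNames(rep(NA_real_, 3), names(counts)[1:3])
  structure(list(counts = counts, fractions = fractions,
                 n_within = n_within, boundaries = boundaries),
            class = "ili_classification")
}

#' @export
print.ili_classification <- function(x, ...) {
  cat(sprintf(
    "<ili_classification> %d within-bout ILIs: burst %.1f%%, cluster %.1f%%, pause %.1f%% (+%d inter-bout)\n",
    x$n_within, 100 * x$fractions[["burst"]], 100 * x$fractions[["cluster"]],
    100 * x$fractions[["pause"]], x$counts[["inter_bout"]]
  ))
  invisible(x)
}

#' Segment a lick train into bouts
#'
#' A lick bout is four or more consecutive licks whose internal ILIs are
#' all below `max_ili` (strictly: an ILI of exactly 1.000 s splits runs).
#' Maximal runs shorter than `min_licks` become stray licks. Intrabout
#' lick frequency is `(n - 1) / duration`, the rate implied by the n-1
#' intervals of an n-lick bout; session-level means over bouts are
#' unweighted.
#'
#' @param train a [lick_train()] or sorted numeric vector of times (s).
#' @param max_ili bout-splitting ILI threshold (s).
#' @param min_licks minimum licks per bout.
#' @return An object of class `bout_set`: `bouts` (data.frame with
#'   `start`, `end`, `n_licks`, `duration`, `freq_hz`), `stray_times`,
#'   and totals `n_bouts`, `licks_in_bouts`, `n_stray`,
#'   `mean_licks_per_bout`, `mean_intrabout_freq`.
#' @examples
#' segment_bouts(c(0, 0.1, 0.2, 0.3, 0.4))
#' @export
segment_bouts <- function(train, max_ili = 1.000, min_licks = 4) {
  tt <- lick_times(train)
  n <- length(tt)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_licks = integer(0), duration = numeric(0),
                      freq_hz = numeric(0))
  if (n == 0) {
    return(structure(list(bouts = empty, stray_times = numeric(0),
                          n_bouts = 0L, licks_in_bouts = 0L, n_stray = 0L,
                          mean_licks_per_bout = NA_real_,
                          mean_intrabout_freq = NA_real_,
                          max_ili = max_ili, min_licks = min_licks),
                     class = "bout_set"))
  }
  run <- cumsum(c(1L, as.integer(diff(tt) >= max_ili)))
  sizes <- tabulate(run)
  is_bout_run <- sizes >= min_licks
  bouts <- empty
  if (any(is_bout_run)) {
    idx <- which(is_bout_run)
    starts <- vapply(idx, function(r) tt[match(r, run)], numeric(1))
    ends <- vapply(idx, function(r) tt[n + 1L - match(r, rev(run))], numeric(1))
    nl <- sizes[idx]
    bouts <- data.frame(start = starts, end = ends, n_licks = nl,
                        duration = ends - starts,
                        freq_hz = (nl - 1) / (ends - starts))
  }
  stray <- tt[!is_bout_run[run]]
  structure(list(
    bouts = bouts, stray_times = stray,
    n_bouts = nrow(bouts),
    licks_in_bouts = sum(bouts$n_licks),
    n_stray = length(stray),
    mean_licks_per_bout = if (nrow(bouts)) mean(bouts$n_licks) else NA_real_,
    mean_intrabout_freq = if (nrow(bouts)) mean(bouts$freq_hz) else NA_real_,
    max_ili = max_ili, min_licks = min_licks
  ), class = "bout_set")
}

#' @export
print.bout_set <- function(x, ...) {
  cat(sprintf(
    "<bout_set> %d bouts (%d licks) + %d stray; mean %.1f licks/bout @ %.1f Hz\n",
    x$n_bouts, x$licks_in_bouts, x$n_stray,
    x$mean_licks_per_bout, x$mean_intrabout_freq
  ))
  invisible(x)
}

#' Bin licks (and bout starts) into fixed time intervals
#'
#' Half-open bins `[k*w, (k+1)*w)` covering `[0, session_length)`; counts
#' conserve totals. The 30 min default matches the standard overnight
#' drinking time course.
#'
#' @param train a [lick_train()] or sorted numeric times (s).
#' @param bin_width bin width, s (> 0).
#' @param session_length session span, s; default the last event rounded
#'   up to a whole bin.
#' @param bouts optional [segment_bouts()] result; adds bout-start counts.
#' @return data.frame with `bin_start`, `bin_end`, `licks` and (if `bouts`
#'   given) `bout_starts`.
#' @export
bin_events <- function(train, bin_width = 1800, session_length = NULL,
                       bouts = NULL) {
  check_pos(bin_width, "bin_width")
  tt <- lick_times(train)
  session_length <- session_length %||%
    (if (length(tt)) ceiling(max(tt) / bin_width) * bin_width else bin_width)
  n_bins <- max(1L, as.integer(ceiling(session_length / bin_width)))
  idx <- pmin(floor(tt / bin_width) + 1L, n_bins)
  out <- data.frame(
    bin_start = (seq_len(n_bins) - 1) * bin_width,
    bin_end = seq_len(n_bins) * bin_width,
    licks = tabulate(idx, nbins = n_bins)
  )
  if (!is.null(bouts)) {
    bs <- bouts$bouts$start
    bidx <- pmin(floor(bs / bin_width) + 1L, n_bins)
    out$bout_starts <- tabulate(bidx, nbins = n_bins)
  }
  out
}
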