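#' Lick detection parameters
#'
#' Defaults follow the standard contact-lickometer detection rule: a lick
#' is a local maximum with topographic prominence above 80 mV and width at
#' half-prominence between 15 and 80 ms; detected events closer than 50 ms
#' are double-peak noise and removed by [remove_double_peaks()].
#'
#' @param prominence_mV minimum topographic prominence (strict >), mV.
#' @param width_min_s,width_max_s width-at-half-prominence band, s.
#' @param min_ili_s minimum interlick interval after cleaning, s.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(prominence_mV = 80, width_min_s = 0.015,
                             width_max_s = 0.080, min_ili_s = 0.050) {
  if (!(width_min_s > 0 && width_min_s < width_max_s)) {
    stop_field("width_min_s", "need 0 < width_min < width_max")
  }
  check_pos(prominence_mV, "prominence_mV")
  check_pos(min_ili_s, "min_ili_s")
  structure(list(prominence_mV = prominence_mV, width_min_s = width_min_s,
                 width_max_s = width_max_s, min_ili_s = min_ili_s),
            class = "detection_params")
}

# Indices of local maxima of x; plateaus contribute their midpoint.
find_local_maxima <- function(x) {
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  sv <- s[nz]
  k <- which(sv[-length(sv)] == 1 & sv[-1] == -1)
  left <- nz[k] + 1L
  right <- nz[k + 1L]
  as.integer((left + right) %/% 2)
}

# Peaks of x with topographic prominence > prominence and width at half
# prominence in [wmin, wmax] seconds. Prominence of a peak is its height
# above the higher of the two lowest points one must descend to on the way
# to higher terrain (or the record edge). Only maxima that could possibly
# pass the prominence bar (height > global min + prominence) are examined;
# lower maxima can neither pass nor terminate another candidate's search,
# and the raw inter-candidate minima capture everything between.
peak_filter <- function(x, fs, prominence, wmin, wmax) {
  empty <- data.frame(index = integer(0), time = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      width = numeric(0))
  pk <- find_local_maxima(x)
  if (!length(pk)) return(empty)
  h <- x[pk]
  keep <- h > min(x) + prominence
  pk <- pk[keep]; h <- h[keep]
  K <- length(pk)
  if (!K) return(empty)

  # valleys: v[1] edge..first, v[k+1] between peak k and k+1, v[K+1] last..edge
  bounds <- c(1L, pk, length(x))
  v <- vapply(seq_len(K + 1L), function(k) min(x[bounds[k]:bounds[k + 1L]]),
              numeric(1))

  prom <- numeric(K)
  for (k in seq_len(K)) {
    lm <- v[k]
    j <- k - 1L
    while (j >= 1L && h[j] <= h[k]) {
      lm <- min(lm, v[j])
      j <- j - 1L
    }
    rm_ <- v[k + 1L]
    j <- k + 1L
    while (j <= K && h[j] <= h[k]) {
      rm_ <- min(rm_, v[j + 1L])
      j <- j + 1L
    }
    prom[k] <- h[k] - max(lm, rm_)
  }

  sel <- which(prom > prominence)
  width <- rep(NA_real_, K)
  n <- length(x)
  for (k in sel) {
    th <- h[k] - prom[k] / 2
    i <- pk[k]
    while (i > 1L && x[i - 1L] > th) i <- i - 1L
    lp <- if (i == 1L) 1 else (i - 1) + (th - x[i - 1L]) / (x[i] - x[i - 1L])
    j <- pk[k]
    while (j < n && x[j + 1L] > th) j <- j + 1L
    rp <- if (j == n) n else j + (x[j] - th) / (x[j] - x[j + 1L])
    width[k] <- (rp - lp) / fs
  }

  ok <- sel[width[sel] >= wmin & width[sel] <= wmax]
  data.frame(index = pk[ok], time = (pk[ok] - 1) / fs, height = h[ok],
             prominence = prom[ok], width = width[ok])
}

#' Detect licks in lickometer voltage traces
#'
#' Converts voltage into lick timestamp trains by peak detection: each
#' event is a local maximum whose topographic prominence exceeds
#' `prominence_mV` and whose width at half-prominence lies within the
#' configured band; the lick time is the peak sample time. An empty train
#' is a valid result. Optionally subtracts a running-median baseline
#' before detection (slow drift correction; off by default).
#'
#' @param rec a [session_recording()], a `voltage_trace` from
#'   [render_voltage()], or a bare numeric trace in mV.
#' @param params a [detection_params()].
#' @param fs sampling rate; required only when `rec` is a bare vector.
#' @param detrend if `TRUE`, subtract a running median (window ~0.5 s).
#' @return For a `session_recording`, a named list of two [lick_train()]s
#'   keyed by bottle content (via the recording's channel map); otherwise
#'   a single `lick_train`.
#' @export
detect_licks <- function(rec, params = detection_params(), fs = NULL,
                         detrend = FALSE) {
  one <- function(x, fs, bottle = NA_character_) {
    if (length(x) <= params$width_max_s * fs) {
      stop("trace shorter than the maximum pulse width", call. = FALSE)
    }
    if (detrend) {
      k <- min(length(x), as.integer(fs * 0.5) * 2L + 1L)
      x <- x - stats::runmed(x, k)
    }
    pks <- peak_filter(x, fs, params$prominence_mV,
                       params$width_min_s, params$width_max_s)
    lick_train(pks$time, bottle = bottle, amplitude = pks$height)
  }
  if (inherits(rec, "session_recording")) {
    out <- list(
      one(rec$ch1, rec$fs, rec$channel_map[["ch1"]]),
      one(rec$ch2, rec$fs, rec$channel_map[["ch2"]])
    )
    names(out) <- unname(rec$channel_map[c("ch1", "ch2")])
    out[c("water", "sucrose")]
  } else if (inherits(rec, "voltage_trace")) {
    one(rec$mv, rec$fs)
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric trace", call. = FALSE)
    one(as.numeric(rec), fs)
  }
}

#' Remove double-peak noise events from a lick train
#'
#' Detected events with interlick intervals below `min_ili_s` (default
#' 50 ms) are double peaks arising from contact noise, not separate licks.
#' A greedy left-to-right scan keeps a lick only if it falls at least
#' `min_ili_s` after the last *kept* lick; the first lick is always kept.
#' The operation is idempotent and never increases the lick count.
#'
#' @param train a [lick_train()] or sorted numeric vector of times (s).
#' @param min_ili_s minimum allowed interlick interval (s).
#' @return A cleaned object of the same kind as the input.
#' @examples
#' remove_double_peaks(c(0, 0.030, 0.200))  # drops 0.030
#' @export
remove_double_peaks <- function(train, min_ili_s = 0.050) {
  tt <- lick_times(train)
  if (length(tt) > 1 && any(diff(tt) < 0)) stop("train must be sorted")
  keep <- logical(length(tt))
  last <- -Inf
  for (i in seq_along(tt)) {
    if (tt[i] - last >= min_ili_s) {
      keep[i] <- TRUE
      last <- tt[i]
    }
  }
  if (inherits(train, "lick_train")) {
    lick_train(tt[keep], train$bottle,
               if (!is.null(train$amplitude)) train$amplitude[keep])
  } else {
    tt[keep]
  }
}
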