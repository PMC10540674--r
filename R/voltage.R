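#' Render a lick train as a synthetic lickometer voltage trace
#'
#' Each lick becomes a positive Gaussian-shaped deflection (the junction
#' potential a contact lickometer records, ~400 mV), with jittered
#' amplitude and width, optional additive Gaussian noise, and optional
#' double-peak artifacts: a second, narrower echo pulse <50 ms after the
#' main one, the noise phenomenon the <50 ms ILI filter exists to remove.
#'
#' @param train a [lick_train()] or numeric vector of lick times (s).
#' @param fs sampling rate, Hz; must be >= 1000 so 15-80 ms pulse widths
#'   are resolvable.
#' @param pulse_amp nominal pulse amplitude, mV.
#' @param amp_cv coefficient of variation of per-lick amplitude jitter.
#' @param width_range range (s) of the pulse full width at half maximum.
#' @param noise_sd additive Gaussian noise sd, mV.
#' @param p_double_peak probability a lick carries a double-peak echo
#'   (offset 38-48 ms, i.e. an ILI < 50 ms before cleaning).
#' @param duration trace duration (s); default last lick + 0.5 s.
#' @return A list of class `voltage_trace`: `mv` (numeric trace), `fs`,
#'   and `t0 = 0` (time of the first sample).
#' @seealso [detect_licks()] for the inverse operation.
#' @export
render_voltage <- function(train, fs = 2000, pulse_amp = 400, amp_cv = 0.05,
                           width_range = c(0.018, 0.045), noise_sd = 5,
                           p_double_peak = 0, duration = NULL) {
  if (fs < 1000) {
    stop("fs must be >= 1000 Hz to resolve 15-80 ms pulse widths",
         call. = FALSE)
  }
  tt <- lick_times(train)
  duration <- duration %||% (if (length(tt)) max(tt) + 0.5 else 1)
  n <- ceiling(duration * fs) + 1L
  x <- numeric(n)

  add_pulse <- function(x, center, amp, fwhm) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    i0 <- max(1L, floor((center - 4 * sigma) * fs) + 1L)
    i1 <- min(n, ceiling((center + 4 * sigma) * fs) + 1L)
    if (i0 > i1) return(x)
    ts <- (seq(i0, i1) - 1) / fs
    x[i0:i1] <- x[i0:i1] + amp * exp(-((ts - center)^2) / (2 * sigma^2))
    x
  }

  for (tc in tt) {
    dbl <- runif(1) < p_double_peak
    # narrow main pulse when an echo follows, so the two peaks stay separable
    fwhm <- if (dbl) runif(1, 0.016, 0.022) else runif(1, width_range[1], width_range[2])
    amp <- pulse_amp * (1 + rnorm(1, 0, amp_cv))
    x <- add_pulse(x, tc, amp, fwhm)
    if (dbl) {
      x <- add_pulse(x, tc + runif(1, 0.038, 0.044), 0.75 * amp,
                     runif(1, 0.024, 0.032))
    }
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  structure(list(mv = x, fs = fs, t0 = 0), class = "voltage_trace")
}

#' Two-channel session recording
#'
#' Raw per-bottle voltage traces plus session metadata (the digitized
#' lickometer signal and the bookkeeping needed downstream: channel-to-
#' bottle map, bottle weights, clock anchors).
#'
#' @param ch1,ch2 numeric voltage traces (mV), equal length.
#' @param fs sampling rate (Hz).
#' @param channel_map named character vector mapping channels to bottle
#'   contents, e.g. `c(ch1 = "water", ch2 = "sucrose")`. Contents follow
#'   this map, never file/channel order.
#' @param metadata list of session metadata (mouse_id, night, condition,
#'   volumes, dark anchors, ...). `volumes` may be `NA` (unknown weights);
#'   QC flags such sessions later.
#' @return An object of class `session_recording`.
#' @export
session_recording <- function(ch1, ch2, fs,
                              channel_map = c(ch1 = "water", ch2 = "sucrose"),
                              metadata = list()) {
  if (length(ch1) != length(ch2)) {
    stop("channel length mismatch", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop("missing or invalid sampling rate", call. = FALSE)
  }
  if (!setequal(unname(channel_map), c("water", "sucrose"))) {
    stop("channel_map must assign 'water' and 'sucrose'", call. = FALSE)
  }
  vols <- metadata$volumes %||% c(water = NA_real_, sucrose = NA_real_)
  if (any(!is.na(vols) & vols < 0)) stop("volumes must be >= 0", call. = FALSE)
  metadata$volumes <- vols
  structure(list(ch1 = as.numeric(ch1), ch2 = as.numeric(ch2), fs = fs,
                 channel_map = channel_map, metadata = metadata),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d samples/channel @ %g Hz (%.1f s), map: %s\n",
              length(x$ch1), x$fs, length(x$ch1) / x$fs,
              paste(names(x$channel_map), x$channel_map, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Read a session recording from disk
#'
#' Reads a two-channel voltage recording. The supported on-disk format is
#' delimited text with columns `time_s, ch1_mV, ch2_mV` (header required);
#' the sampling rate is inferred from the time column and checked for
#' uniformity. Other declared formats are rejected with an error.
#'
#' @param path file path.
#' @param format declared format; only `"delimited"` is supported.
#' @param channel_map,metadata passed to [session_recording()].
#' @param sep field separator (default any whitespace/comma autodetected by
#'   extension: `.csv` uses comma, otherwise whitespace).
#' @return A `session_recording`.
#' @export
read_recording <- function(path, format = "delimited",
                           channel_map = c(ch1 = "water", ch2 = "sucrose"),
                           metadata = list(), sep = NULL) {
  if (!identical(format, "delimited")) {
    stop(sprintf("unknown or unsupported format '%s'", format), call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- sep %||% (if (grepl("\\.csv$", path)) "," else "")
  d <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(d) < 3) stop("expected columns time_s, ch1_mV, ch2_mV", call. = FALSE)
  dt <- diff(d[[1]])
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6)) {
    stop("missing sampling rate: time column is absent or non-uniform",
         call. = FALSE)
  }
  session_recording(d[[2]], d[[3]], fs = 1 / dt[1],
                    channel_map = channel_map, metadata = metadata)
}

#' Write a session recording as delimited text
#'
#' @param rec a `session_recording`.
#' @param path output path (`.csv` for comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  d <- data.frame(time_s = (seq_along(rec$ch1) - 1) / rec$fs,
                  ch1_mV = rec$ch1, ch2_mV = rec$ch2)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
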