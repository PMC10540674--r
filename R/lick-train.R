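#' Lick train: ordered lick timestamps for one bottle
#'
#' The atomic event stream all downstream metrics consume: a strictly
#' increasing vector of lick times (seconds from session start) for one
#' bottle in one session, optionally with per-lick peak amplitudes.
#'
#' @param times numeric vector of lick times in seconds, strictly increasing.
#' @param bottle bottle label, conventionally `"water"` or `"sucrose"`
#'   (content, not side).
#' @param amplitude optional numeric vector of per-lick peak amplitudes (mV),
#'   same length as `times`.
#' @return An object of class `lick_train`.
#' @examples
#' lick_train(c(0, 0.12, 0.25), bottle = "water")
#' @export
lick_train <- function(times, bottle = NA_character_, amplitude = NULL) {
  times <- as.numeric(times)
  if (anyNA(times)) stop("lick times must not contain NA")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("lick times must be strictly increasing")
  }
  if (length(times) && any(times < 0)) stop("lick times must be >= 0")
  if (!is.null(amplitude) && length(amplitude) != length(times)) {
    stop("amplitude must match the number of licks")
  }
  structure(
    list(times = times, bottle = as.character(bottle), amplitude = amplitude),
    class = "lick_train"
  )
}

#' Extract lick times from a train or numeric vector
#'
#' Most operations accept either a `lick_train` or a bare numeric vector of
#' sorted times; this accessor normalizes both.
#'
#' @param x a `lick_train` or numeric vector.
#' @return numeric vector of lick times (seconds).
#' @export
lick_times <- function(x) {
  if (inherits(x, "lick_train")) x$times else as.numeric(x)
}

#' @export
print.lick_train <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "<lick_train> bottle=%s, %d licks%s\n", x$bottle, n,
    if (n) sprintf(", span %.1f-%.1f s", min(x$times), max(x$times)) else ""
  ))
  invisible(x)
}

#' @export
length.lick_train <- function(x) length(x$times)
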