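#' Sucrose preference
#'
#' Percentage of total intake taken from the sucrose bottle,
#' `100 * S / (S + W)`; applied identically to volumes (mL) or lick
#' counts. Undefined (returned as `NA`, never 50) when both amounts are
#' zero.
#'
#' @param amount_sucrose,amount_water nonnegative amounts (vectors are
#'   recycled elementwise).
#' @return Preference in percent, `NA` where undefined.
#' @examples
#' preference(3, 1)  # 75
#' @export
preference <- function(amount_sucrose, amount_water) {
  if (any(amount_sucrose < 0, na.rm = TRUE) ||
      any(amount_water < 0, na.rm = TRUE)) {
    stop("amounts must be >= 0", call. = FALSE)
  }
  tot <- amount_sucrose + amount_water
  ifelse(is.na(tot) | tot == 0, NA_real_, 100 * amount_sucrose / tot)
}

# Merge two per-bottle trains into one labeled timeline.
merge_timeline <- function(train_water, train_sucrose) {
  tw <- lick_times(train_water)
  ts <- lick_times(train_sucrose)
  o <- order(c(tw, ts))
  list(time = c(tw, ts)[o],
       bottle = c(rep("water", length(tw)), rep("sucrose", length(ts)))[o])
}

#' Quick switches between bottles
#'
#' Counts transitions from one bottle to the other with less than `window`
#' seconds between the last lick at the first bottle and the first lick at
#' the other (strict <; a gap of exactly 60 s does not count). An excess
#' of water-to-sucrose over sucrose-to-water switches is read as error
#' correction: the mouse samples the wrong bottle and promptly corrects.
#'
#' @param train_water,train_sucrose per-bottle trains (sorted).
#' @param window maximum gap (s), default 60.
#' @return Named integer vector
#'   `c(water_to_sucrose = , sucrose_to_water = )`.
#' @examples
#' quick_switches(c(10, 300), c(40, 250, 1000))
#' @export
quick_switches <- function(train_water, train_sucrose, window = 60) {
  m <- merge_timeline(train_water, train_sucrose)
  n <- length(m$time)
  if (n < 2) return(c(water_to_sucrose = 0L, sucrose_to_water = 0L))
  gap <- diff(m$time)
  from <- m$bottle[-n]
  to <- m$bottle[-1]
  hit <- gap < window & from != to
  c(water_to_sucrose = sum(hit & from == "water"),
    sucrose_to_water = sum(hit & from == "sucrose"))
}

#' Returns to a bottle after a drinking-free pause
#'
#' On the merged two-bottle timeline, every gap longer than `pause`
#' seconds (strict >; default 5 min) between consecutive licks defines a
#' return event, attributed to the bottle of the first lick after the
#' gap. Returning preferentially to the sucrose bottle indicates memory
#' of the reward location. The interval before the session's first lick
#' is not a pause (a return presupposes a previous visit).
#'
#' @param train_water,train_sucrose per-bottle trains (sorted).
#' @param pause minimum drinking-free gap (s), default 300.
#' @param per_bottle if `TRUE`, use the per-bottle reading instead: a
#'   return to bottle B is a lick at B more than `pause` seconds after
#'   the previous lick *at B* (the merged-timeline reading is primary).
#' @return Named integer vector `c(water = , sucrose = )`.
#' @examples
#' returns_after_pause(c(90, 95, 100), c(500, 501))
#' @export
returns_after_pause <- function(train_water, train_sucrose, pause = 300,
                                per_bottle = FALSE) {
  if (per_bottle) {
    cnt <- function(tt) sum(diff(lick_times(tt)) > pause)
    return(c(water = cnt(train_water), sucrose = cnt(train_sucrose)))
  }
  m <- merge_timeline(train_water, train_sucrose)
  n <- length(m$time)
  if (n < 2) return(c(water = 0L, sucrose = 0L))
  after <- m$bottle[-1][diff(m$time) > pause]
  c(water = sum(after == "water"), sucrose = sum(after == "sucrose"))
}

# Restrict a train to a half-open window [start, end).
clip_train <- function(train, start, end) {
  tt <- lick_times(train)
  kept <- tt[tt >= start & tt < end]
  if (inherits(train, "lick_train")) lick_train(kept, train$bottle) else kept
}

#' Per-session SPT metrics
#'
#' Assembles all per-session quantities from cleaned per-bottle lick
#' trains: per-bottle volume, total licks, bout counts and statistics,
#' returns after pauses; quick-switch counts by direction; binned lick
#' and bout-start series; and volume- and lick-based preference. With
#' `windows = TRUE` the memory metrics are also recomputed on the first
#' and last 2 h of the dark phase, the windows in which within-night
#' memory emergence is visible.
#'
#' @param train_water,train_sucrose cleaned per-bottle [lick_train()]s.
#' @param volumes named vector `c(water = , sucrose = )` in mL (`NA` if
#'   weights unknown).
#' @param session_length session span (s).
#' @param dark_onset,dark_offset dark-phase window (s from session start).
#' @param bin_width temporal bin width (s), default 30 min.
#' @param max_ili,min_licks_bout bout criteria, see [segment_bouts()].
#' @param switch_window quick-switch gap (s), see [quick_switches()].
#' @param pause return pause (s), see [returns_after_pause()].
#' @param windows attach first/last 2 h sub-metrics.
#' @return An object of class `session_metrics`: `bottle_stats`
#'   (data.frame, one row per bottle: volume, licks, n_bouts,
#'   licks_per_bout, intrabout_freq, returns), `switches`,
#'   `preference_volume`, `preference_licks`, `bins`, and (optionally)
#'   `windows$first_2h` / `windows$last_2h`.
#' @export
session_metrics <- function(train_water, train_sucrose,
                            volumes = c(water = NA_real_, sucrose = NA_real_),
                            session_length = 57600,
                            dark_onset = 0, dark_offset = 43200,
                            bin_width = 1800, max_ili = 1.000,
                            min_licks_bout = 4, switch_window = 60,
                            pause = 300, windows = TRUE) {
  core <- function(w, s, vols) {
    bw <- segment_bouts(w, max_ili, min_licks_bout)
    bs <- segment_bouts(s, max_ili, min_licks_bout)
    ret <- returns_after_pause(w, s, pause)
    list(
      bottle_stats = data.frame(
        bottle = c("water", "sucrose"),
        volume = c(vols[["water"]], vols[["sucrose"]]),
        licks = c(length(lick_times(w)), length(lick_times(s))),
        n_bouts = c(bw$n_bouts, bs$n_bouts),
        licks_per_bout = c(bw$mean_licks_per_bout, bs$mean_licks_per_bout),
        intrabout_freq = c(bw$mean_intrabout_freq, bs$mean_intrabout_freq)
      ),
      returns = ret,
      switches = quick_switches(w, s, switch_window),
      bouts = list(water = bw, sucrose = bs)
    )
  }

  full <- core(train_water, train_sucrose, volumes)
  full$bottle_stats$returns <- unname(full$returns[c("water", "sucrose")])
  nw <- full$bottle_stats$licks[1]
  ns <- full$bottle_stats$licks[2]

  out <- list(
    bottle_stats = full$bottle_stats,
    switches = full$switches,
    preference_volume = preference(volumes[["sucrose"]], volumes[["water"]]),
    preference_licks = preference(ns, nw),
    bins = {
      bnw <- bin_events(train_water, bin_width, session_length,
                        full$bouts$water)
      bns <- bin_events(train_sucrose, bin_width, session_length,
                        full$bouts$sucrose)
      data.frame(bin_start = bnw$bin_start, bin_end = bnw$bin_end,
                 licks_water = bnw$licks, licks_sucrose = bns$licks,
                 bouts_water = bnw$bout_starts, bouts_sucrose = bns$bout_starts)
    },
    session_length = session_length,
    dark_onset = dark_onset, dark_offset = dark_offset
  )

  # 2 h windows only make sense when the dark phase spans at least 2 h
  if (windows && (dark_offset - dark_onset) >= 7200) {
    out$windows <- list(
      first_2h = windowed_metrics(train_water, train_sucrose,
                                  window = "first_2h_of_dark",
                                  session_length = session_length,
                                  dark_onset = dark_onset,
                                  dark_offset = dark_offset,
                                  max_ili = max_ili,
                                  min_licks_bout = min_licks_bout,
                                  switch_window = switch_window,
                                  pause = pause),
      last_2h = windowed_metrics(train_water, train_sucrose,
                                 window = "last_2h_of_dark",
                                 session_length = session_length,
                                 dark_onset = dark_onset,
                                 dark_offset = dark_offset,
                                 max_ili = max_ili,
                                 min_licks_bout = min_licks_bout,
                                 switch_window = switch_window,
                                 pause = pause)
    )
  }
  class(out) <- "session_metrics"
  out
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf(
    "<session_metrics> pref(volume) %.1f%%, pref(licks) %.1f%%\n",
    x$preference_volume, x$preference_licks
  ))
  print(x$bottle_stats, row.names = FALSE)
  invisible(x)
}

#' Metrics restricted to an analysis window
#'
#' Recomputes counts, bout statistics, memory metrics and lick preference
#' on licks within a half-open window. Named windows are anchored on the
#' dark phase: `first_2h_of_dark` is `[dark_onset, dark_onset + 7200)`,
#' `last_2h_of_dark` is `[dark_offset - 7200, dark_offset)`; `full` is
#' the whole session. Pauses and switch gaps are evaluated on the clipped
#' trains only. Volumes are not apportioned to windows (bottles are
#' weighed once per night), so windowed volume metrics are `NA`.
#'
#' @inheritParams session_metrics
#' @param window `"first_2h_of_dark"`, `"last_2h_of_dark"`, `"full"`, or
#'   a numeric `c(start, end)` in seconds.
#' @return A `session_metrics` (without nested windows or bins).
#' @export
windowed_metrics <- function(train_water, train_sucrose,
                             window = "full",
                             session_length = 57600,
                             dark_onset = 0, dark_offset = 43200,
                             max_ili = 1.000, min_licks_bout = 4,
                             switch_window = 60, pause = 300) {
  win <- if (is.numeric(window)) {
    window
  } else {
    switch(window,
      full = c(0, session_length),
      first_2h_of_dark = c(dark_onset, dark_onset + 7200),
      last_2h_of_dark = c(dark_offset - 7200, dark_offset),
      stop(sprintf("unknown window '%s'", window), call. = FALSE)
    )
  }
  if (win[1] < 0 || win[2] > session_length || win[1] >= win[2]) {
    stop("window outside the recording span", call. = FALSE)
  }
  w <- clip_train(train_water, win[1], win[2])
  s <- clip_train(train_sucrose, win[1], win[2])
  m <- session_metrics(w, s, volumes = c(water = NA_real_, sucrose = NA_real_),
                       session_length = session_length,
                       dark_onset = dark_onset, dark_offset = dark_offset,
                       max_ili = max_ili, min_licks_bout = min_licks_bout,
                       switch_window = switch_window, pause = pause,
                       windows = FALSE)
  m$window <- win
  m
}

#' Average a mouse's test nights into a final result
#'
#' Final sucrose preference is the arithmetic mean of the per-night
#' preferences over included nights (the sucrose side switches between
#' nights, but trains are keyed by content, so metrics track content
#' across the switch). All per-bottle metrics are averaged the same way,
#' unweighted. QC-excluded nights are omitted and recorded; a result
#' based on a single night is flagged.
#'
#' @param metrics_list list of [session_metrics()], one per night.
#' @param include logical vector: which nights pass QC (default all).
#' @param mouse_id,sex,condition carried metadata.
#' @return An object of class `mouse_result`: identity fields,
#'   `final_preference` (volume-based, %), `final_preference_licks`,
#'   averaged `bottle_stats` and `switches`, `n_nights_included`,
#'   `single_night`, `missing` (all nights excluded), and
#'   `nights_excluded`.
#' @export
average_nights <- function(metrics_list, include = NULL,
                           mouse_id = NA_character_, sex = NA_character_,
                           condition = NA_character_) {
  if (!length(metrics_list)) stop("need >= 1 night", call. = FALSE)
  include <- include %||% rep(TRUE, length(metrics_list))
  kept <- metrics_list[include]
  res <- list(
    mouse_id = mouse_id, sex = sex, condition = condition,
    n_nights_included = length(kept),
    nights_excluded = which(!include),
    single_night = length(kept) == 1,
    missing = length(kept) == 0
  )
  if (res$missing) {
    res$final_preference <- NA_real_
    res$final_preference_licks <- NA_real_
    res$bottle_stats <- NULL
    res$switches <- c(water_to_sucrose = NA_real_, sucrose_to_water = NA_real_)
    class(res) <- "mouse_result"
    return(res)
  }
  res$final_preference <-
    mean(vapply(kept, `[[`, numeric(1), "preference_volume"))
  res$final_preference_licks <-
    mean(vapply(kept, `[[`, numeric(1), "preference_licks"))
  num_cols <- setdiff(names(kept[[1]]$bottle_stats), "bottle")
  bs <- kept[[1]]$bottle_stats[, "bottle", drop = FALSE]
  for (cn in num_cols) {
    bs[[cn]] <- rowMeans(do.call(cbind, lapply(kept, function(m) {
      m$bottle_stats[[cn]]
    })))
  }
  res$bottle_stats <- bs
  res$switches <- rowMeans(do.call(cbind, lapply(kept, `[[`, "switches")))
  res$per_night <- metrics_list
  class(res) <- "mouse_result"
  res
}

#' @export
print.mouse_result <- function(x, ...) {
  cat(sprintf(
    "<mouse_result> %s (%s, %s): final preference %s over %d night(s)%s\n",
    x$mouse_id, x$sex, x$condition,
    if (is.na(x$final_preference)) "missing"
    else sprintf("%.1f%%", x$final_preference),
    x$n_nights_included,
    if (isTRUE(x$single_night)) " [single night]" else ""
  ))
  invisible(x)
}

#' Classify the stress phenotype from post-stress preference
#'
#' After chronic stress, mice with a final sucrose preference below the
#' cutoff (default 70\%, 2-3 SD below the stress-naive mean) are
#' susceptible; others are resilient. The boundary value itself (exactly
#' 70\%) is assigned resilient, a documented tie-break: the defining
#' inequalities are strict on both sides and leave it open. A missing
#' preference yields `"n/a"`.
#'
#' @param post_stress_preference preference in percent (vectorized).
#' @param cutoff percent cutoff, default 70.
#' @return Character vector in `c("susceptible", "resilient", "n/a")`.
#' @examples
#' classify_phenotype(c(65, 75, 70, NA))
#' @export
classify_phenotype <- function(post_stress_preference, cutoff = 70) {
  if (any(post_stress_preference < 0 | post_stress_preference > 100,
          na.rm = TRUE)) {
    stop("preference must be in [0, 100]", call. = FALSE)
  }
  ifelse(is.na(post_stress_preference), "n/a",
         ifelse(post_stress_preference < cutoff, "susceptible", "resilient"))
}
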