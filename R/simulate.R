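# Within-bout ILI mixture: regular rhythmic interval, or an exact 2x/3x
# multiple of a fresh base draw ("miss" of one or two licks). Base draws are
# truncated so each mixture component maps exactly onto its classification
# group (<180 / 180-320 / 320-1000 ms) and never violates the 50 ms
# double-peak floor.
draw_ilis <- function(m, cfg) {
  if (m <= 0) return(list(ili = numeric(0), mult = integer(0)))
  u <- runif(m)
  mult <- ifelse(u < cfg$p_skip1, 2L, ifelse(u < cfg$p_skip1 + cfg$p_skip2, 3L, 1L))
  lo <- c(0.0600, 0.0905, 0.1070)[mult]
  hi <- c(0.1750, 0.1595, 0.1595)[mult]
  base <- pmin(pmax(rnorm(m, cfg$ili_base_mean, cfg$ili_base_sd), lo), hi)
  list(ili = base * mult, mult = mult)
}

#' Simulate one two-bottle overnight drinking session
#'
#' Draws a session from the generative model described in [sim_config()]:
#' candidate bout initiations from an inhomogeneous Poisson process under
#' the circadian envelope (by thinning), bottle choice by preference ratio
#' or, after a >5 min drinking-free pause, by the location-memory return
#' probability; bout sizes from a shifted negative binomial (minimum 4
#' licks); within-bout ILIs from the burst/cluster/pause mixture; optional
#' short water probes before sucrose bouts (error-correction quick-switch
#' substrate); and per-bottle volumes proportional to lick count with
#' multiplicative lognormal noise.
#'
#' @param config a [sim_config()].
#' @return An object of class `spt_session`: a list with elements
#'   \describe{
#'     \item{water, sucrose}{[lick_train()]s keyed by bottle content.}
#'     \item{volumes}{named vector of measured volumes (mL), noise applied.}
#'     \item{truth}{ground truth: per-lick table (`time`, `bottle`, `bout`,
#'       `kind` in bout/probe), per-bout table (bottle, start, size,
#'       return-context flag, probe flag), the generator's return draws,
#'       noise-free volumes, and an (initially empty) artifact log.}
#'     \item{config}{the config used.}
#'   }
#' @examples
#' s <- simulate_session(sim_config(seed = 42))
#' length(s$sucrose) > length(s$water)
#' @export
simulate_session <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  with_seed(config$seed, sim_session_impl(config))
}

sim_session_impl <- function(cfg) {
  env <- circadian_envelope(cfg)
  grid <- seq(0, cfg$session_length, by = 60)
  emax <- max(env(grid))
  lam_max <- cfg$base_bout_rate / 3600 * emax
  n_cand <- rpois(1, lam_max * cfg$session_length)
  cand <- sort(runif(n_cand, 0, cfg$session_length))
  cand <- cand[runif(length(cand)) < env(cand) / emax]

  p_suc <- cfg$pref_bout_ratio / (1 + cfg$pref_bout_ratio)
  p_ret <- function(t) {
    if (is.null(cfg$p_return_ramp)) return(cfg$p_return_sucrose)
    cfg$p_return_ramp[1] +
      (cfg$p_return_ramp[2] - cfg$p_return_ramp[1]) * t / cfg$session_length
  }

  lick_rows <- vector("list", length(cand) * 2L)
  bout_rows <- vector("list", length(cand))
  ret_rows <- list()
  n_lr <- 0L; n_br <- 0L
  last_lick <- -Inf
  bout_id <- 0L

  for (t0 in cand) {
    if (t0 < last_lick + cfg$interbout_refractory) next
    if (t0 > cfg$session_length - 30) next
    gap <- t0 - last_lick
    is_return <- is.finite(last_lick) && gap > 300
    if (is_return) {
      pr <- p_ret(t0)
      bottle <- if (runif(1) < pr) "sucrose" else "water"
      ret_rows[[length(ret_rows) + 1L]] <-
        data.frame(time = t0, bottle = bottle, p_return = pr)
    } else {
      bottle <- if (runif(1) < p_suc) "sucrose" else "water"
    }

    # Error-correction probe: a stray water touch shortly before a
    # sucrose-intended bout. Never on return-context bouts, so the return
    # draw above stays observable from the emitted stream.
    had_probe <- FALSE
    if (!is_return && bottle == "sucrose" && runif(1) < cfg$p_error_switch) {
      offset <- runif(1, 5, 30)
      n_probe <- sample.int(3L, 1L)
      pt <- (t0 - offset) + c(0, cumsum(draw_ilis(n_probe - 1L, cfg)$ili))
      if (pt[1] > 0 && pt[1] > last_lick + cfg$interbout_refractory &&
          max(pt) < t0 - 1) {
        had_probe <- TRUE
        n_lr <- n_lr + 1L
        lick_rows[[n_lr]] <- data.frame(
          time = pt, bottle = "water", bout = NA_integer_,
          kind = "probe", intended = "sucrose"
        )
      }
    }

    mu <- if (bottle == "sucrose") cfg$bout_size_mean_sucrose else cfg$bout_size_mean_water
    n <- 4L + rnbinom(1, size = cfg$bout_size_dispersion, mu = mu - 4)
    times <- t0 + c(0, cumsum(draw_ilis(n - 1L, cfg)$ili))
    times <- times[times < cfg$session_length]
    if (!length(times)) next

    bout_id <- bout_id + 1L
    n_lr <- n_lr + 1L
    lick_rows[[n_lr]] <- data.frame(
      time = times, bottle = bottle, bout = bout_id,
      kind = "bout", intended = bottle
    )
    n_br <- n_br + 1L
    bout_rows[[n_br]] <- data.frame(
      bout = bout_id, bottle = bottle, start = t0, n_licks = length(times),
      is_return = is_return, had_probe = had_probe
    )
    last_lick <- max(times)
  }

  licks <- if (n_lr) do.call(rbind, lick_rows[seq_len(n_lr)]) else
    data.frame(time = numeric(0), bottle = character(0), bout = integer(0),
               kind = character(0), intended = character(0))
  bouts <- if (n_br) do.call(rbind, bout_rows[seq_len(n_br)]) else
    data.frame(bout = integer(0), bottle = character(0), start = numeric(0),
               n_licks = integer(0), is_return = logical(0),
               had_probe = logical(0))
  returns <- if (length(ret_rows)) do.call(rbind, ret_rows) else
    data.frame(time = numeric(0), bottle = character(0), p_return = numeric(0))
  rownames(licks) <- rownames(bouts) <- rownames(returns) <- NULL

  n_w <- sum(licks$bottle == "water")
  n_s <- sum(licks$bottle == "sucrose")
  true_vol <- cfg$volume_per_lick * c(water = n_w, sucrose = n_s)
  noise <- if (cfg$volume_noise_cv > 0) {
    sdl <- sqrt(log(1 + cfg$volume_noise_cv^2))
    rlnorm(2, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else c(1, 1)

  structure(list(
    water = lick_train(licks$time[licks$bottle == "water"], "water"),
    sucrose = lick_train(licks$time[licks$bottle == "sucrose"], "sucrose"),
    volumes = true_vol * noise,
    truth = list(
      licks = licks, bouts = bouts, returns = returns,
      true_volumes = true_vol,
      artifacts = data.frame(type = character(0), bottle = character(0),
                             start = numeric(0), end = numeric(0),
                             detail = character(0))
    ),
    config = cfg
  ), class = "spt_session")
}

#' @export
print.spt_session <- function(x, ...) {
  cat(sprintf(
    "<spt_session> %d water + %d sucrose licks, %d bouts, volumes %.2f/%.2f mL\n",
    length(x$water), length(x$sucrose), nrow(x$truth$bouts),
    x$volumes[["water"]], x$volumes[["sucrose"]]
  ))
  invisible(x)
}

#' Simulate a cohort of mouse-nights
#'
#' Generates `n_mice x nights` sessions from a preset (or explicit config
#' template). The sucrose side alternates between nights, as in the real
#' test design; per-session seeds are `seed, seed+1, ...` in mouse-major
#' order, so the whole cohort is reproducible from one integer.
#'
#' @param n_mice number of mice (>= 1).
#' @param nights nights per mouse (>= 1, default 2).
#' @param preset preset name passed to [sim_preset()]; ignored if `config`
#'   is supplied.
#' @param config optional `sim_config` template overriding `preset`.
#' @param seed base integer seed.
#' @param first_sucrose_side side of the sucrose bottle on night 1.
#' @param dir optional directory: if given, the cohort is also written as
#'   tidy text via [write_cohort()].
#' @return An object of class `spt_cohort`: `sessions` (named list of
#'   `spt_session`s, names `"m<mouse>_n<night>"`) and `manifest`
#'   (one row per session: mouse_id, sex, night, condition, sucrose_side,
#'   seed, measured volumes, post-stress flag).
#' @examples
#' co <- simulate_cohort(2, nights = 2, preset = "naive", seed = 1)
#' co$manifest[, c("mouse_id", "night", "sucrose_side")]
#' @export
simulate_cohort <- function(n_mice, nights = 2, preset = "naive",
                            config = NULL, seed = 1L,
                            first_sucrose_side = "left", dir = NULL) {
  if (n_mice < 1) stop_field("n_mice", "must be >= 1")
  if (nights < 1) stop_field("nights", "must be >= 1")
  template <- config %||% sim_preset(preset)
  post_stress <- is.null(config) &&
    preset %in% c("acute", "chronic_susceptible", "chronic_resilient")
  condition <- if (is.null(config)) preset else "custom"

  sessions <- list()
  manifest <- list()
  sides <- c("left", "right")
  start_i <- match(first_sucrose_side, sides)
  if (is.na(start_i)) stop_field("first_sucrose_side", "must be left or right")
  k <- 0L
  for (m in seq_len(n_mice)) {
    for (ngt in seq_len(nights)) {
      k <- k + 1L
      cfg <- template
      cfg$sucrose_side <- sides[((start_i - 1 + ngt - 1) %% 2) + 1]
      cfg$seed <- as.integer(seed + (m - 1L) * nights + (ngt - 1L))
      s <- simulate_session(cfg)
      id <- sprintf("m%02d_n%d", m, ngt)
      sessions[[id]] <- s
      manifest[[k]] <- data.frame(
        session = id,
        mouse_id = sprintf("m%02d", m),
        sex = if (m %% 2 == 1) "M" else "F",
        night = ngt,
        condition = condition,
        post_stress = post_stress,
        sucrose_side = cfg$sucrose_side,
        seed = cfg$seed,
        vol_water_ml = unname(s$volumes["water"]),
        vol_sucrose_ml = unname(s$volumes["sucrose"]),
        session_length = cfg$session_length,
        dark_onset = cfg$dark_onset,
        dark_offset = cfg$dark_offset
      )
    }
  }
  cohort <- structure(
    list(sessions = sessions, manifest = do.call(rbind, manifest)),
    class = "spt_cohort"
  )
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.spt_cohort <- function(x, ...) {
  cat(sprintf(
    "<spt_cohort> %d sessions (%d mice), condition(s): %s\n",
    nrow(x$manifest), length(unique(x$manifest$mouse_id)),
    paste(unique(x$manifest$condition), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a cohort as tidy delimited text
#'
#' `write_cohort()` stores the event streams as `events.csv` (columns
#' `mouse_id, night, bottle, time_s`) and session metadata as
#' `manifest.csv`. `read_cohort()` reads them back into the minimal cohort
#' structure the pipeline consumes (lick trains + volumes; ground truth is
#' not serialized).
#'
#' @param cohort an `spt_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns an `spt_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- lapply(names(cohort$sessions), function(id) {
    s <- cohort$sessions[[id]]
    mrow <- cohort$manifest[cohort$manifest$session == id, ]
    rbind(
      data.frame(mouse_id = mrow$mouse_id, night = mrow$night,
                 bottle = "water", time_s = s$water$times),
      data.frame(mouse_id = mrow$mouse_id, night = mrow$night,
                 bottle = "sucrose", time_s = s$sucrose$times)
    )
  })
  ev <- do.call(rbind, ev)
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(cohort$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  ev <- read.csv(file.path(dir, "events.csv"))
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  sessions <- lapply(seq_len(nrow(manifest)), function(i) {
    mrow <- manifest[i, ]
    sub <- ev[ev$mouse_id == mrow$mouse_id & ev$night == mrow$night, ]
    list(
      water = lick_train(sort(sub$time_s[sub$bottle == "water"]), "water"),
      sucrose = lick_train(sort(sub$time_s[sub$bottle == "sucrose"]), "sucrose"),
      volumes = c(water = mrow$vol_water_ml, sucrose = mrow$vol_sucrose_ml)
    )
  })
  names(sessions) <- manifest$session
  structure(list(sessions = sessions, manifest = manifest),
            class = "spt_cohort")
}

#' Inject recording artifacts into a session
#'
#' Corrupts a simulated session the way real recordings fail: a `leak`
#' inflates a bottle's measured volume with no accompanying licks; a
#' `dropout` (lost cage-to-digitizer connection) deletes all licks in a
#' time window; `crosstalk` copies a fraction of one bottle's events onto
#' the other channel. Overlapping dropout windows are merged, not errored.
#' Every corruption is appended to the session's artifact log so QC tests
#' can check recall.
#'
#' @param session an `spt_session` (or compatible list with `water`,
#'   `sucrose`, `volumes`, `truth`).
#' @param artifacts list of specs, each a list with `type` in
#'   `"leak"`/`"dropout"`/`"crosstalk"` and fields: leak needs `bottle`,
#'   `volume_ml`; dropout needs `start`, `end` (s), optional `bottle`
#'   (default both); crosstalk needs `from`, `to`, `fraction`.
#' @return The corrupted session, artifact log updated.
#' @export
inject_artifacts <- function(session, artifacts) {
  log_rows <- list()
  # merge overlapping dropout windows first
  dps <- Filter(function(a) identical(a$type, "dropout"), artifacts)
  rest <- Filter(function(a) !identical(a$type, "dropout"), artifacts)
  if (length(dps)) {
    win <- do.call(rbind, lapply(dps, function(a) {
      c(start = a$start, end = a$end)
    }))
    win <- win[order(win[, "start"]), , drop = FALSE]
    merged <- list(win[1, ])
    for (i in seq_len(nrow(win))[-1]) {
      last <- merged[[length(merged)]]
      if (win[i, "start"] <= last["end"]) {
        last["end"] <- max(last["end"], win[i, "end"])
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- win[i, ]
    }
    dps <- lapply(merged, function(w) {
      list(type = "dropout", start = unname(w["start"]), end = unname(w["end"]))
    })
  }

  for (a in c(rest, dps)) {
    if (a$type == "leak") {
      session$volumes[a$bottle] <- session$volumes[a$bottle] + a$volume_ml
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        type = "leak", bottle = a$bottle, start = NA_real_, end = NA_real_,
        detail = sprintf("+%.3g mL", a$volume_ml)
      )
    } else if (a$type == "dropout") {
      bottles <- if (is.null(a$bottle)) c("water", "sucrose") else a$bottle
      for (b in bottles) {
        tt <- session[[b]]$times
        session[[b]] <- lick_train(tt[tt < a$start | tt >= a$end], b)
      }
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        type = "dropout", bottle = paste(bottles, collapse = "+"),
        start = a$start, end = a$end, detail = ""
      )
    } else if (a$type == "crosstalk") {
      src <- session[[a$from]]$times
      pick <- src[runif(length(src)) < a$fraction]
      jitter <- pick + runif(length(pick), 0.001, 0.004)
      dst <- sort(unique(c(session[[a$to]]$times, jitter)))
      session[[a$to]] <- lick_train(dst, a$to)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        type = "crosstalk", bottle = sprintf("%s->%s", a$from, a$to),
        start = NA_real_, end = NA_real_,
        detail = sprintf("%d events copied", length(pick))
      )
    } else {
      stop(sprintf("unknown artifact type '%s'", a$type), call. = FALSE)
    }
  }
  if (length(log_rows)) {
    session$truth$artifacts <- rbind(session$truth$artifacts,
                                     do.call(rbind, log_rows))
  }
  session
}
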