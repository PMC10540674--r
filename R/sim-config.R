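#' Configuration of a simulated mouse-night drinking session
#'
#' Full generative parameterization of one overnight two-bottle session.
#' Defaults describe a stress-naive mouse recorded for 16 h starting at
#' lights-off (7 P.M.): bout initiation follows an inhomogeneous point
#' process under a two-bump circadian envelope (a spike ~1 h after dark
#' onset, a trough in the middle of the night, and a second spike ~9 h
#' after dark onset), sucrose bouts are initiated `pref_bout_ratio` times
#' more often than water bouts and are about twice as large, within-bout
#' interlick intervals (ILIs) follow a three-component mixture (regular
#' rhythmic licks plus single-skip "cluster" and double-skip "pause"
#' intervals at exact 2x/3x multiples of a fresh base draw), returns to a
#' bottle after a >5 min pause are governed by a location-memory
#' probability, and consumed volume is proportional to lick count with
#' multiplicative lognormal weighing noise.
#'
#' @param session_length session duration in seconds (default 16 h).
#' @param dark_onset,dark_offset dark-phase window, seconds from session
#'   start (default 0 to 12 h: recording starts at lights-off).
#' @param circadian_peaks data.frame with columns `center`, `width`,
#'   `weight` (seconds, seconds, dimensionless): Gaussian bumps of the
#'   bout-initiation envelope.
#' @param dark_baseline envelope baseline during the dark phase
#'   (dimensionless, added to the bumps).
#' @param base_bout_rate bout initiations per hour at unit envelope.
#' @param pref_bout_ratio multiplier on sucrose-bottle bout initiation
#'   (>1 means sucrose preference); the non-return bottle choice is
#'   Bernoulli with p = ratio/(1+ratio).
#' @param bout_size_mean_water,bout_size_mean_sucrose mean licks per bout;
#'   sizes are 4 + negative-binomial (the bout definition's 4-lick floor).
#' @param bout_size_dispersion negative-binomial size (overdispersion)
#'   parameter of the shifted bout-size distribution.
#' @param ili_base_mean,ili_base_sd seconds; base within-bout ILI.
#' @param p_skip1,p_skip2 probabilities that a within-bout interval is a
#'   single skip (ILI doubled, a "cluster" interval) or double skip
#'   (tripled, a "pause" interval).
#' @param p_return_sucrose probability that the first bout after a
#'   >=5 min drinking-free pause targets the sucrose bottle (location
#'   memory strength).
#' @param p_return_ramp optional length-2 vector `c(start, end)`: linear
#'   ramp of the return probability across the session (within-night
#'   learning); overrides `p_return_sucrose`.
#' @param p_error_switch probability that a sucrose-intended (non-return)
#'   bout is preceded by a short (<4 lick) water probe within <60 s: the
#'   substrate of water-to-sucrose quick switches.
#' @param volume_per_lick mL per lick (default 0.002).
#' @param volume_noise_cv coefficient of variation of multiplicative
#'   lognormal volume noise (weighing error).
#' @param sucrose_side which physical side holds the sucrose bottle this
#'   night, `"left"` or `"right"`.
#' @param interbout_refractory minimum gap (s) between a bout's last lick
#'   and the next bout initiation; must exceed the 1 s bout-splitting
#'   criterion so generated bouts are identifiable.
#' @param seed integer RNG seed; identical configs give identical sessions.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [sim_preset()] for named condition presets,
#'   [simulate_session()] to draw a session.
#' @export
sim_config <- function(session_length = 57600,
                       dark_onset = 0,
                       dark_offset = 43200,
                       circadian_peaks = data.frame(
                         center = c(3600, 32400),
                         width = c(4000, 5000),
                         weight = c(1, 0.75)
                       ),
                       dark_baseline = 0.10,
                       base_bout_rate = 10,
                       pref_bout_ratio = 3,
                       bout_size_mean_water = 15,
                       bout_size_mean_sucrose = 30,
                       bout_size_dispersion = 3,
                       ili_base_mean = 0.120,
                       ili_base_sd = 0.020,
                       p_skip1 = 0.04,
                       p_skip2 = 0.01,
                       p_return_sucrose = 0.80,
                       p_return_ramp = NULL,
                       p_error_switch = 0.10,
                       volume_per_lick = 0.002,
                       volume_noise_cv = 0.10,
                       sucrose_side = c("left", "right"),
                       interbout_refractory = 1.5,
                       seed = 1L) {
  cfg <- list(
    session_length = session_length,
    dark_onset = dark_onset,
    dark_offset = dark_offset,
    circadian_peaks = circadian_peaks,
    dark_baseline = dark_baseline,
    base_bout_rate = base_bout_rate,
    pref_bout_ratio = pref_bout_ratio,
    bout_size_mean_water = bout_size_mean_water,
    bout_size_mean_sucrose = bout_size_mean_sucrose,
    bout_size_dispersion = bout_size_dispersion,
    ili_base_mean = ili_base_mean,
    ili_base_sd = ili_base_sd,
    p_skip1 = p_skip1,
    p_skip2 = p_skip2,
    p_return_sucrose = p_return_sucrose,
    p_return_ramp = p_return_ramp,
    p_error_switch = p_error_switch,
    volume_per_lick = volume_per_lick,
    volume_noise_cv = volume_noise_cv,
    sucrose_side = match.arg(sucrose_side),
    interbout_refractory = interbout_refractory,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("not a sim_config")
  check_pos(cfg$session_length, "session_length")
  if (cfg$dark_onset < 0 || cfg$dark_onset >= cfg$session_length) {
    stop_field("dark_onset", "must lie within the session")
  }
  if (cfg$dark_offset <= cfg$dark_onset || cfg$dark_offset > cfg$session_length) {
    stop_field("dark_offset", "must lie after dark_onset, within the session")
  }
  cp <- cfg$circadian_peaks
  if (!is.data.frame(cp) || !all(c("center", "width", "weight") %in% names(cp)) ||
      nrow(cp) < 1) {
    stop_field("circadian_peaks", "need a data.frame with center/width/weight")
  }
  if (any(cp$width <= 0) || any(cp$weight < 0)) {
    stop_field("circadian_peaks", "widths must be > 0 and weights >= 0")
  }
  check_pos(cfg$dark_baseline, "dark_baseline", strict = FALSE)
  check_pos(cfg$base_bout_rate, "base_bout_rate")
  check_pos(cfg$pref_bout_ratio, "pref_bout_ratio")
  if (cfg$bout_size_mean_water < 4 || cfg$bout_size_mean_sucrose < 4) {
    stop_field("bout_size_mean", "mean licks/bout must be >= 4 (bout floor)")
  }
  check_pos(cfg$bout_size_dispersion, "bout_size_dispersion")
  check_pos(cfg$ili_base_mean, "ili_base_mean")
  check_pos(cfg$ili_base_sd, "ili_base_sd")
  check_prob(cfg$p_skip1, "p_skip1")
  check_prob(cfg$p_skip2, "p_skip2")
  if (cfg$p_skip1 + cfg$p_skip2 > 1) {
    stop_field("p_skip1", "p_skip1 + p_skip2 must be <= 1")
  }
  check_prob(cfg$p_return_sucrose, "p_return_sucrose")
  if (!is.null(cfg$p_return_ramp)) {
    if (length(cfg$p_return_ramp) != 2) {
      stop_field("p_return_ramp", "must be c(start, end)")
    }
    check_prob(cfg$p_return_ramp[1], "p_return_ramp")
    check_prob(cfg$p_return_ramp[2], "p_return_ramp")
  }
  check_prob(cfg$p_error_switch, "p_error_switch")
  check_pos(cfg$volume_per_lick, "volume_per_lick")
  check_pos(cfg$volume_noise_cv, "volume_noise_cv", strict = FALSE)
  if (cfg$interbout_refractory <= 1) {
    stop_field("interbout_refractory", "must exceed the 1 s bout criterion")
  }
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  cfg
}

#' Named condition presets for the simulator
#'
#' Presets parameterize the qualitative group differences the SPT is used
#' to measure: stress-naive mice show strong sucrose preference; acutely
#' stressed mice initiate fewer but larger bouts, front-load drinking after
#' lights-off, and return less often to the sucrose bottle; after chronic
#' stress, susceptible mice lose preference (final preference below the
#' 70\% cutoff: fewer sucrose bouts, smaller sucrose/water bout-size
#' asymmetry, weakened location memory) while resilient mice retain it.
#'
#' @param name one of `"naive"`, `"acute"`, `"chronic_susceptible"`,
#'   `"chronic_resilient"`.
#' @param ... overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name, ...) {
  args <- switch(name,
    naive = list(),
    acute = list(
      pref_bout_ratio = 2,
      bout_size_mean_water = 22,
      bout_size_mean_sucrose = 40,
      base_bout_rate = 8,
      p_return_sucrose = 0.65,
      circadian_peaks = data.frame(
        center = c(3600, 32400),
        width = c(4000, 5000),
        weight = c(1.3, 0.35)
      )
    ),
    chronic_susceptible = list(
      pref_bout_ratio = 1.5,
      bout_size_mean_water = 15,
      bout_size_mean_sucrose = 18,
      base_bout_rate = 8,
      p_return_sucrose = 0.60
    ),
    chronic_resilient = list(
      pref_bout_ratio = 2.5,
      bout_size_mean_water = 15,
      bout_size_mean_sucrose = 26,
      p_return_sucrose = 0.80
    ),
    stop(sprintf("unknown preset '%s'", name), call. = FALSE)
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Bout-initiation intensity envelope (dimensionless, >= 0) as a function of
# session time.
circadian_envelope <- function(cfg) {
  force(cfg)
  function(t) {
    e <- ifelse(t >= cfg$dark_onset & t < cfg$dark_offset, cfg$dark_baseline, 0)
    for (i in seq_len(nrow(cfg$circadian_peaks))) {
      p <- cfg$circadian_peaks[i, ]
      e <- e + p$weight * exp(-((t - p$center)^2) / (2 * p$width^2))
    }
    e
  }
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> %.1f h session, dark [%g, %g) s\n",
      "  bout rate %.3g/h (x%.3g sucrose), bout size means w=%.3g s=%.3g\n",
      "  ILI base %.0f +/- %.0f ms, skips (%.3g, %.3g)\n",
      "  p_return_sucrose %s, p_error_switch %.3g, seed %d\n"
    ),
    x$session_length / 3600, x$dark_onset, x$dark_offset,
    x$base_bout_rate, x$pref_bout_ratio,
    x$bout_size_mean_water, x$bout_size_mean_sucrose,
    x$ili_base_mean * 1000, x$ili_base_sd * 1000, x$p_skip1, x$p_skip2,
    if (is.null(x$p_return_ramp)) sprintf("%.3g", x$p_return_sucrose)
    else sprintf("ramp %.3g->%.3g", x$p_return_ramp[1], x$p_return_ramp[2]),
    x$p_error_switch, x$seed
  ))
  invisible(x)
}
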