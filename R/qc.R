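#' Quality control: volume-versus-lick correlation across a cohort
#'
#' A working lickometer produces a tight linear relation between the
#' volume consumed from a bottle and the number of licks recorded at it.
#' This fits volume on total licks by least squares, pooled across
#' bottle-session points (one point per bottle per session), reports the
#' coefficient of determination, and flags outliers automatically.
#' Because weighing error is multiplicative (it scales with the amount
#' consumed), raw-scale residuals are heteroscedastic: large sucrose
#' volumes carry proportionally larger noise and classical studentized
#' residuals over-flag them. Outliers are therefore judged on the ratio
#' scale against a robust proportional reference (the median per-lick
#' volume): `log(volume / expected)` is studentized robustly
#' (median/MAD), and a point is flagged when its robust z exceeds
#' `resid_threshold` (positive, volume excess per lick: `leak`;
#' negative, lick excess or volume deficit: `connection`). Sessions
#' whose total lick count falls below `min_licks` are `low_signal`;
#' points with unknown volume are `manual` (weights missing). A session
#' is excluded if any of its points is flagged; the primary reason
#' follows the precedence leak > connection > low_signal > manual.
#'
#' @param points data.frame with columns `session`, `bottle`, `licks`,
#'   `volume` (mL; `NA` = unknown). At least 3 points with known volume
#'   are required.
#' @param min_licks minimum per-session total lick count.
#' @param resid_threshold cutoff on the robustly studentized ratio
#'   residual.
#' @return An object of class `qc_report`: the fitted `slope`/`intercept`,
#'   `r_squared` (all known points), `r_squared_clean` (refit excluding
#'   flagged points), the annotated `points` table (classical studentized
#'   residual, robust ratio-residual z, and flag per point), and
#'   `exclusions` (session, reason).
#' @examples
#' pts <- data.frame(session = rep(1:6, each = 2),
#'                   bottle = rep(c("water", "sucrose"), 6),
#'                   licks = c(200, 900, 250, 1000, 220, 950,
#'                             210, 980, 240, 920, 230, 990))
#' pts$volume <- 0.002 * pts$licks
#' qc_cohort(pts)$r_squared
#' @export
qc_cohort <- function(points, min_licks = 50, resid_threshold = 3) {
  need <- c("session", "bottle", "licks", "volume")
  if (!all(need %in% names(points))) {
    stop("points needs columns session, bottle, licks, volume", call. = FALSE)
  }
  known <- is.finite(points$volume)
  if (!any(known)) stop("all volumes unknown", call. = FALSE)
  if (sum(known) < 3) stop("need >= 3 bottle-sessions with known volumes",
                           call. = FALSE)

  fit <- lm(volume ~ licks, data = points[known, ])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  rs <- suppressWarnings(rstudent(fit))
  rs[!is.finite(rs)] <- 0  # perfect fit: no outliers by definition

  # ratio residuals: log(observed / expected) against a robust proportional
  # fit (median per-lick volume), so one gross outlier cannot drag the
  # reference line and implicate clean points
  slope_rob <- stats::median(points$volume[known] /
                               pmax(points$licks[known], 1))
  expected_v <- pmax(slope_rob * points$licks[known], 1e-6)
  u <- log(pmax(points$volume[known], 1e-9) / expected_v)
  med <- stats::median(u)
  scale_u <- max(stats::mad(u, center = med), 1e-8)
  z <- (u - med) / scale_u

  points$studentized_resid <- NA_real_
  points$studentized_resid[known] <- rs
  points$ratio_resid_z <- NA_real_
  points$ratio_resid_z[known] <- z
  flag <- rep(NA_character_, nrow(points))
  flag[known][which(z > resid_threshold)] <- "leak"
  flag[known][which(z < -resid_threshold)] <- "connection"
  session_licks <- tapply(points$licks, points$session, sum)
  low <- points$session %in% names(session_licks)[session_licks < min_licks]
  flag[is.na(flag) & low] <- "low_signal"
  flag[is.na(flag) & !known] <- "manual"
  points$flag <- flag

  ok <- known & is.na(flag)
  r2_clean <- if (sum(ok) >= 3 && any(!is.na(flag))) {
    suppressWarnings(summary(lm(volume ~ licks, data = points[ok, ]))$r.squared)
  } else r2

  prec <- c(leak = 1, connection = 2, low_signal = 3, manual = 4)
  bad <- unique(points$session[!is.na(flag)])
  exclusions <- data.frame(
    session = bad,
    reason = vapply(bad, function(s) {
      fl <- flag[points$session == s & !is.na(flag)]
      names(prec)[min(prec[fl])]
    }, character(1))
  )
  rownames(exclusions) <- NULL

  structure(list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2, r_squared_clean = r2_clean,
    points = points, exclusions = exclusions,
    min_licks = min_licks, resid_threshold = resid_threshold
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> volume ~ licks: slope %.4g mL/lick, R^2 = %.3f (clean %.3f)\n",
    x$slope, x$r_squared, x$r_squared_clean
  ))
  if (nrow(x$exclusions)) {
    cat(sprintf("  %d session(s) excluded: %s\n", nrow(x$exclusions),
                paste(sprintf("%s (%s)", x$exclusions$session,
                              x$exclusions$reason), collapse = ", ")))
  } else cat("  no exclusions\n")
  invisible(x)
}

# Per-bottle-session QC points from a cohort (lick counts on cleaned
# trains plus measured volumes).
qc_points <- function(cohort) {
  do.call(rbind, lapply(names(cohort$sessions), function(id) {
    s <- cohort$sessions[[id]]
    data.frame(
      session = id,
      bottle = c("water", "sucrose"),
      licks = c(length(s$water), length(s$sucrose)),
      volume = c(s$volumes[["water"]], s$volumes[["sucrose"]])
    )
  }))
}
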