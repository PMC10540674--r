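#!/usr/bin/env Rscript
# Preference and memory metrics on the naive cohort: volume- and
# lick-based sucrose preference with two-night averaging, quick switches
# between bottles (<60 s), returns to a bottle after a >5-min pause, and
# the first-2h / last-2h window contrast that exposes within-night
# location-memory formation.

suppressPackageStartupMessages(library(lickspt))

co <- read_cohort("results/cohorts/naive")
dir.create("results", showWarnings = FALSE)

per_session <- do.call(rbind, lapply(seq_len(nrow(co$manifest)), function(i) {
  mrow <- co$manifest[i, ]
  s <- co$sessions[[mrow$session]]
  m <- session_metrics(s$water, s$sucrose, volumes = s$volumes,
                       session_length = mrow$session_length,
                       dark_onset = mrow$dark_onset,
                       dark_offset = mrow$dark_offset)
  w1 <- m$windows$first_2h$bottle_stats$returns
  w2 <- m$windows$last_2h$bottle_stats$returns
  data.frame(
    session = mrow$session, mouse_id = mrow$mouse_id, night = mrow$night,
    preference_volume = m$preference_volume,
    preference_licks = m$preference_licks,
    switch_w_to_s = unname(m$switches["water_to_sucrose"]),
    switch_s_to_w = unname(m$switches["sucrose_to_water"]),
    returns_water = m$bottle_stats$returns[1],
    returns_sucrose = m$bottle_stats$returns[2],
    ret_suc_frac_first2h = if (sum(w1) > 0) w1[2] / sum(w1) else NA,
    ret_suc_frac_last2h = if (sum(w2) > 0) w2[2] / sum(w2) else NA
  )
}))
write.csv(per_session, "results/preference_memory.csv", row.names = FALSE)

final <- aggregate(cbind(preference_volume, preference_licks) ~ mouse_id,
                   per_session, mean)
cat(sprintf("Final (two-night) sucrose preference: mean %.1f%% by volume, %.1f%% by licks\n",
            mean(final$preference_volume), mean(final$preference_licks)))
cat(sprintf("Quick switches per night: %.1f water->sucrose vs %.1f sucrose->water\n",
            mean(per_session$switch_w_to_s), mean(per_session$switch_s_to_w)))
cat(sprintf("Returns after >5-min pauses: %.1f to sucrose vs %.1f to water per night\n",
            mean(per_session$returns_sucrose), mean(per_session$returns_water)))
cat(sprintf("Sucrose-return fraction: %.2f (first 2 h) vs %.2f (last 2 h)\n",
            mean(per_session$ret_suc_frac_first2h, na.rm = TRUE),
            mean(per_session$ret_suc_frac_last2h, na.rm = TRUE)))
cat("\nMice preferentially return to the sucrose bottle after long pauses and\n")
cat("correct errors with water-to-sucrose quick switches; both read out\n")
cat("reward-location memory rather than consumption itself.\n")
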