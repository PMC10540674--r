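test_that("preference implements 100*S/(S+W) with a missing, not 50, undefined case", {
  expect_equal(preference(3, 1), 75)
  expect_equal(preference(2, 2), 50)
  expect_equal(preference(1500, 500), 75)  # identical on lick counts
  expect_true(is.na(preference(0, 0)))
  expect_error(preference(-1, 2), ">= 0")
  # strictly increasing in S for fixed W > 0
  s_grid <- seq(0.1, 5, by = 0.1)
  p <- preference(s_grid, 1)
  expect_true(all(diff(p) > 0))
})

test_that("quick switches count close opposite-bottle transitions by direction", {
  qs <- quick_switches(c(10, 300), c(40, 250, 1000))
  expect_equal(unname(qs), c(1, 1))
  expect_equal(unname(quick_switches(c(1, 2, 3), numeric(0))), c(0, 0))
  expect_equal(unname(quick_switches(numeric(0), c(1, 2))), c(0, 0))
  # boundary: a gap of exactly the window does not count
  expect_equal(sum(quick_switches(c(0), c(60))), 0)
  expect_equal(sum(quick_switches(c(0), c(59.999))), 1)
})

test_that("returns after a pause attribute the first lick after each long gap", {
  r <- returns_after_pause(c(90, 95, 100), c(500, 501))
  expect_equal(unname(r), c(0, 1))
  # continuous drinking: no qualifying pause
  r2 <- returns_after_pause(seq(0, 3000, by = 200), numeric(0))
  expect_equal(sum(r2), 0)
  # gap of exactly the pause does not count (strict >)
  expect_equal(sum(returns_after_pause(c(0), c(300))), 0)
  expect_equal(sum(returns_after_pause(c(0), c(300.001))), 1)
  # the interval before the first lick is not a pause
  expect_equal(sum(returns_after_pause(c(10000), numeric(0))), 0)
  # per-bottle variant
  rp <- returns_after_pause(c(0, 400), c(200, 560), per_bottle = TRUE)
  expect_equal(unname(rp), c(1, 1))
  rm <- returns_after_pause(c(0, 400), c(200, 560))
  expect_equal(sum(rm), 0)  # merged timeline has no gap > 300
})

test_that("switch and return counts match merged-timeline oracles", {
  set.seed(6)
  for (i in 1:300) {
    tw <- random_train(sample(0:40, 1), long_max = 900)
    ts <- random_train(sample(0:40, 1), long_max = 900) + runif(1, 0, 1e-3)
    expect_equal(quick_switches(tw, ts), oracle_quick_switches(tw, ts))
    expect_equal(returns_after_pause(tw, ts), oracle_returns(tw, ts))
  }
})

test_that("relabeling bottles swaps direction- and bottle-attributed counts", {
  set.seed(7)
  for (i in 1:50) {
    tw <- random_train(30, long_max = 900)
    ts <- random_train(30, long_max = 900) + 0.0005
    qs <- quick_switches(tw, ts)
    qs_swapped <- quick_switches(ts, tw)
    expect_equal(unname(qs[["water_to_sucrose"]]),
                 unname(qs_swapped[["sucrose_to_water"]]))
    r <- returns_after_pause(tw, ts)
    r_swapped <- returns_after_pause(ts, tw)
    expect_equal(unname(r[["water"]]), unname(r_swapped[["sucrose"]]))
  }
})

test_that("windowed metrics partition the night and respect the span", {
  s <- simulate_session(sim_config(seed = 23))
  full <- windowed_metrics(s$water, s$sucrose, "full")
  first <- windowed_metrics(s$water, s$sucrose, window = c(0, 7200))
  mid <- windowed_metrics(s$water, s$sucrose, window = c(7200, 36000))
  last <- windowed_metrics(s$water, s$sucrose, window = c(36000, 57600))
  for (b in 1:2) {
    expect_equal(full$bottle_stats$licks[b],
                 first$bottle_stats$licks[b] + mid$bottle_stats$licks[b] +
                   last$bottle_stats$licks[b])
  }
  # licks only in the first hour: last-2h metrics are all zero
  early_w <- lick_train(c(100, 100.1, 100.2, 100.3), "water")
  early_s <- lick_train(c(200, 200.1, 200.2, 200.3), "sucrose")
  lw <- windowed_metrics(early_w, early_s, "last_2h_of_dark")
  expect_equal(sum(lw$bottle_stats$licks), 0)
  expect_equal(sum(lw$bottle_stats$n_bouts), 0)
  expect_error(windowed_metrics(early_w, early_s, window = c(-10, 100)),
               "outside")
  expect_error(windowed_metrics(early_w, early_s, window = c(0, 1e6)),
               "outside")
})

test_that("session metrics assemble per-bottle tables and preferences", {
  s <- simulate_session(sim_config(seed = 28))
  m <- session_metrics(s$water, s$sucrose, volumes = s$volumes)
  expect_s3_class(m, "session_metrics")
  expect_equal(m$bottle_stats$licks,
               c(length(s$water), length(s$sucrose)))
  expect_equal(m$preference_licks,
               preference(length(s$sucrose), length(s$water)))
  expect_equal(sum(m$bins$licks_water), length(s$water))
  expect_equal(sum(m$bins$licks_sucrose), length(s$sucrose))
  expect_equal(sum(m$bins$bouts_water), segment_bouts(s$water)$n_bouts)
  expect_true(!is.null(m$windows$first_2h))
})

test_that("night averaging is content-aligned, unweighted, and handles exclusions", {
  mk <- function(pref_vol, licks_w, licks_s) {
    w <- lick_train(seq(0, by = 0.1, length.out = licks_w), "water")
    s <- lick_train(seq(5000, by = 0.1, length.out = licks_s), "sucrose")
    vols <- c(water = 100 - pref_vol, sucrose = pref_vol) / 25
    session_metrics(w, s, vols, windows = FALSE)
  }
  n1 <- mk(80, 100, 400)  # sucrose left
  n2 <- mk(90, 120, 500)  # sucrose right: content alignment is implicit
  res <- average_nights(list(n1, n2), mouse_id = "m01")
  expect_equal(res$final_preference, 85)
  expect_equal(res$bottle_stats$licks,
               c((100 + 120) / 2, (400 + 500) / 2))
  expect_false(res$single_night)

  res1 <- average_nights(list(n1, n2), include = c(TRUE, FALSE))
  expect_equal(res1$final_preference, 80)
  expect_true(res1$single_night)
  expect_equal(res1$nights_excluded, 2L)

  res0 <- average_nights(list(n1, n2), include = c(FALSE, FALSE))
  expect_true(res0$missing)
  expect_true(is.na(res0$final_preference))

  expect_error(average_nights(list()), ">= 1")
})

test_that("phenotype classification applies the 70% cutoff with its tie-break", {
  expect_equal(classify_phenotype(65), "susceptible")
  expect_equal(classify_phenotype(75), "resilient")
  expect_equal(classify_phenotype(70.0), "resilient")
  expect_equal(classify_phenotype(NA), "n/a")
  expect_equal(classify_phenotype(c(69.9, 70.1)),
               c("susceptible", "resilient"))
  expect_error(classify_phenotype(120), "\\[0, 100\\]")
})

test_that("lick- and volume-based preference agree up to weighing noise", {
  diffs <- numeric(0)
  for (seed in 1:20) {
    s <- simulate_session(sim_config(seed = seed))
    pv <- preference(s$volumes[["sucrose"]], s$volumes[["water"]])
    pl <- preference(length(s$sucrose), length(s$water))
    diffs <- c(diffs, abs(pv - pl))
  }
  expect_lt(max(diffs), 5)
})
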