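make_pulse_trace <- function(times, fs = 2000, amp = 400, fwhm = 0.040,
                             duration = NULL) {
  render_voltage(lick_train(sort(times)), fs = fs, pulse_amp = amp,
                 amp_cv = 0, width_range = c(fwhm, fwhm), noise_sd = 0,
                 duration = duration)
}

test_that("flat and sub-threshold traces yield empty trains", {
  flat <- detect_licks(rep(0, 5000), fs = 2000)
  expect_equal(length(flat), 0)
  weak <- detect_licks(make_pulse_trace(c(0.5, 1.0), amp = 40))
  expect_equal(length(weak), 0)
})

test_that("a single clean pulse is detected at its apex", {
  tr <- make_pulse_trace(0.5, fwhm = 0.040)
  d <- detect_licks(tr)
  expect_equal(length(d), 1)
  expect_lt(abs(d$times - 0.5), 1 / tr$fs + 1e-9)
})

test_that("clean multi-pulse traces round-trip exactly", {
  set.seed(21)
  tt <- c(0.5, 0.62, 0.75, 1.2, 3.0)
  tr <- render_voltage(lick_train(tt), fs = 2000, noise_sd = 0,
                       p_double_peak = 0)
  d <- detect_licks(tr)
  expect_equal(length(d), length(tt))
  expect_true(all(abs(d$times - tt) <= 1 / tr$fs + 1e-9))
})

test_that("pulses outside the width band are rejected", {
  wide <- detect_licks(make_pulse_trace(1.0, fwhm = 0.150, duration = 2))
  expect_equal(length(wide), 0)
  narrow <- detect_licks(make_pulse_trace(1.0, fwhm = 0.005, duration = 2))
  expect_equal(length(narrow), 0)
  inband <- detect_licks(make_pulse_trace(1.0, fwhm = 0.020, duration = 2))
  expect_equal(length(inband), 1)
})

test_that("double-peak artifacts produce two raw peaks per lick, one after cleaning", {
  set.seed(33)
  tt <- cumsum(runif(60, 0.15, 0.4))
  tr <- render_voltage(lick_train(tt), fs = 2000, noise_sd = 4,
                       p_double_peak = 1)
  raw <- detect_licks(tr)
  expect_equal(length(raw), 2 * length(tt))
  cleaned <- remove_double_peaks(raw)
  expect_equal(length(cleaned), length(tt))
  m <- match_events(tt, cleaned$times, tol = 0.005)
  expect_equal(unname(m["hits"]), length(tt))
})

test_that("double-peak removal applies the kept-anchor greedy rule", {
  expect_equal(remove_double_peaks(c(0, 0.030, 0.200)), c(0, 0.200))
  # 0.030 is dropped; 0.060 is >= 50 ms after the kept lick at 0
  expect_equal(remove_double_peaks(c(0, 0.030, 0.060)), c(0, 0.060))
  tt <- c(0, 0.06, 0.3, 0.5)
  expect_equal(remove_double_peaks(tt), tt)
})

test_that("double-peak removal is idempotent, monotone, and enforces the gap", {
  set.seed(44)
  for (i in 1:50) {
    tt <- cumsum(runif(sample(2:80, 1), 0.005, 0.3))
    out <- remove_double_peaks(tt)
    expect_lte(length(out), length(tt))
    expect_identical(remove_double_peaks(out), out)
    if (length(out) > 1) expect_true(all(diff(out) >= 0.050))
    expect_true(out[1] == tt[1])  # first lick always kept
  }
})

test_that("detection is translation invariant", {
  set.seed(55)
  tt <- cumsum(runif(20, 0.1, 0.3))
  tr1 <- render_voltage(lick_train(tt), fs = 2000, noise_sd = 0)
  set.seed(55)
  tr2 <- render_voltage(lick_train(tt + 5), fs = 2000, noise_sd = 0,
                        duration = max(tt) + 5.5)
  d1 <- detect_licks(tr1)
  d2 <- detect_licks(tr2)
  expect_equal(length(d1), length(d2))
  expect_true(all(abs((d2$times - 5) - d1$times) <= 1 / 2000 + 1e-9))
})

test_that("peak prominence agrees with a brute-force oracle", {
  set.seed(66)
  for (i in 1:20) {
    # rough terrain with a few genuine pulses
    x <- stats::filter(rnorm(2000, 0, 30), rep(1 / 8, 8), sides = 2)
    x[is.na(x)] <- 0
    x <- as.numeric(x)
    for (c0 in sample(200:1800, 5)) {
      x[(c0 - 40):(c0 + 40)] <- x[(c0 - 40):(c0 + 40)] +
        runif(1, 100, 400) * exp(-((-40:40)^2) / (2 * runif(1, 10, 25)^2))
    }
    ours <- lickspt:::peak_filter(x, fs = 1000, prominence = 80,
                                  wmin = 0, wmax = Inf)
    theirs <- oracle_peaks(x, prominence = 80)
    expect_equal(ours$index, theirs$index)
    expect_equal(ours$prominence, theirs$prominence, tolerance = 1e-10)
  }
})

test_that("session recordings validate channels and map contents explicitly", {
  expect_error(session_recording(1:10, 1:9, fs = 1000), "length mismatch")
  expect_error(session_recording(1:10, 1:10, fs = NA), "sampling rate")
  set.seed(3)
  trw <- render_voltage(lick_train(c(0.3, 0.5)), fs = 2000, noise_sd = 0,
                        duration = 1)
  trs <- render_voltage(lick_train(c(0.7)), fs = 2000, noise_sd = 0,
                        duration = 1)
  # swapped map: contents follow the map, not channel order
  rec <- session_recording(trw$mv, trs$mv, fs = 2000,
                           channel_map = c(ch1 = "sucrose", ch2 = "water"))
  d <- detect_licks(rec)
  expect_equal(length(d$sucrose), 2)
  expect_equal(length(d$water), 1)
})

test_that("recordings round-trip through delimited text", {
  set.seed(8)
  trw <- render_voltage(lick_train(c(0.2, 0.4, 0.6)), fs = 2000,
                        noise_sd = 2, duration = 1)
  trs <- render_voltage(lick_train(c(0.5)), fs = 2000, noise_sd = 2,
                        duration = 1)
  rec <- session_recording(trw$mv, trs$mv, fs = 2000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs, 2000, tolerance = 1e-6)
  expect_equal(length(back$ch1), length(rec$ch1))
  d <- detect_licks(back)
  expect_equal(length(d$water), 3)
  expect_equal(length(d$sucrose), 1)
  expect_error(read_recording(path, format = "abf"), "unknown")
  expect_error(read_recording("no/such/file.csv"), "not found")
})

test_that("missing volumes load as unknown and are flagged later by QC", {
  rec <- session_recording(rep(0, 2000), rep(0, 2000), fs = 1000)
  expect_true(all(is.na(rec$metadata$volumes)))
})
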