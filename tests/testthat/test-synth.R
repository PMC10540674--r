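test_that("invalid configs are rejected with the offending field named", {
  expect_error(sim_config(p_skip1 = 1.2), "p_skip1")
  expect_error(sim_config(p_skip1 = 0.7, p_skip2 = 0.5), "p_skip1")
  expect_error(sim_config(base_bout_rate = 0), "base_bout_rate")
  expect_error(sim_config(ili_base_sd = -1), "ili_base_sd")
  expect_error(sim_config(bout_size_mean_water = 2), "bout_size_mean")
  expect_error(sim_config(dark_offset = 1e9), "dark_offset")
  expect_error(sim_config(p_return_ramp = c(0.5, 1.5)), "p_return_ramp")
  expect_error(sim_preset("no_such_preset"), "unknown preset")
})

test_that("identical configs give identical sessions", {
  a <- simulate_session(sim_config(seed = 5))
  b <- simulate_session(sim_config(seed = 5))
  expect_identical(a$water$times, b$water$times)
  expect_identical(a$sucrose$times, b$sucrose$times)
  expect_identical(a$volumes, b$volumes)
  d <- simulate_session(sim_config(seed = 6))
  expect_false(identical(a$sucrose$times, d$sucrose$times))
})

test_that("emitted trains respect timestamp and spacing invariants", {
  for (seed in 1:5) {
    s <- simulate_session(sim_config(seed = seed))
    for (b in c("water", "sucrose")) {
      tt <- s[[b]]$times
      expect_true(all(diff(tt) > 0))
      expect_true(all(diff(tt) >= 0.050))
      expect_true(all(tt >= 0 & tt < s$config$session_length))
    }
    # every lick belongs to a bout or is a labeled probe
    expect_true(all(s$truth$licks$kind %in% c("bout", "probe")))
    expect_true(all(is.na(s$truth$licks$bout) == (s$truth$licks$kind == "probe")))
  }
})

test_that("symmetric configuration yields balanced bottles", {
  cfg0 <- sim_config(pref_bout_ratio = 1, bout_size_mean_sucrose = 15,
                     p_return_sucrose = 0.5, p_error_switch = 0)
  nw <- ns <- 0
  for (seed in 1:40) {
    cfg0$seed <- seed
    s <- simulate_session(cfg0)
    nw <- nw + length(s$water)
    ns <- ns + length(s$sucrose)
  }
  p <- ns / (nw + ns)
  se <- sqrt(0.25 / (nw + ns))
  # bottle identity is decided per bout, so licks are clustered; allow the
  # design effect of ~mean bout size on top of binomial error
  expect_lt(abs(p - 0.5), 4 * se * sqrt(15))
})

test_that("degenerate ILI mixture gives pure burst licking", {
  s <- simulate_session(sim_config(p_skip1 = 0, p_skip2 = 0, seed = 2))
  ilis <- c(compute_ilis(s$water), compute_ilis(s$sucrose))
  within <- ilis[ilis < 1]
  expect_true(all(within < 0.180))
  cl <- classify_ilis(ilis)
  expect_equal(unname(cl$fractions["burst"]), 1)
})

test_that("ILI mixture fractions match the skip probabilities", {
  s1 <- 0.10; s2 <- 0.05
  cfg <- sim_config(p_skip1 = s1, p_skip2 = s2, base_bout_rate = 20,
                    p_error_switch = 0, seed = 31)
  counts <- c(burst = 0, cluster = 0, pause = 0)
  n_tot <- 0
  for (seed in 31:36) {
    cfg$seed <- seed
    s <- simulate_session(cfg)
    cl <- classify_ilis(c(compute_ilis(s$water), compute_ilis(s$sucrose)))
    counts <- counts + cl$counts[1:3]
    n_tot <- n_tot + cl$n_within
  }
  expect_gt(n_tot, 10000)
  expect_lt(abs(counts[["cluster"]] / n_tot - s1), 4 * sqrt(s1 * (1 - s1) / n_tot))
  expect_lt(abs(counts[["pause"]] / n_tot - s2), 4 * sqrt(s2 * (1 - s2) / n_tot))
  expect_lt(abs(counts[["burst"]] / n_tot - (1 - s1 - s2)),
            4 * sqrt((1 - s1 - s2) * (s1 + s2) / n_tot))
})

test_that("default preference matches the closed-form bout-mixture expectation", {
  # expected lick share: rho*mu_s / (rho*mu_s + mu_w), modified slightly by
  # the return-memory mixture; agreement within a few points over 10 seeds
  nw <- ns <- 0
  for (seed in 1:10) {
    s <- simulate_session(sim_config(seed = seed))
    nw <- nw + length(s$water)
    ns <- ns + length(s$sucrose)
  }
  pref <- 100 * ns / (nw + ns)
  closed <- 100 * (3 * 30) / (3 * 30 + 15)
  expect_gt(pref, 70)
  expect_lt(abs(pref - closed), 5)
})

test_that("volumes are proportional to licks with multiplicative noise", {
  s0 <- simulate_session(sim_config(volume_noise_cv = 0, seed = 9))
  expect_equal(unname(s0$volumes["water"]), 0.002 * length(s0$water))
  expect_equal(unname(s0$volumes["sucrose"]), 0.002 * length(s0$sucrose))
  ratio <- numeric(0)
  for (seed in 1:15) {
    s <- simulate_session(sim_config(seed = seed))
    ratio <- c(ratio, s$volumes / s$truth$true_volumes)
  }
  expect_lt(abs(mean(ratio) - 1), 0.1)
  expect_lt(abs(sd(ratio) - 0.10), 0.05)
})

test_that("cohort bookkeeping: session count, side alternation, determinism", {
  co <- simulate_cohort(2, nights = 2, preset = "naive", seed = 1)
  expect_equal(nrow(co$manifest), 4)
  expect_equal(length(co$sessions), 4)
  expect_equal(co$manifest$sucrose_side,
               c("left", "right", "left", "right"))
  expect_equal(co$manifest$seed, 1:4)
  co2 <- simulate_cohort(2, nights = 2, preset = "naive", seed = 1)
  for (id in names(co$sessions)) {
    expect_identical(co$sessions[[id]]$sucrose$times,
                     co2$sessions[[id]]$sucrose$times)
  }
  co3 <- simulate_cohort(1, nights = 2, preset = "naive", seed = 1,
                         first_sucrose_side = "right")
  expect_equal(co3$manifest$sucrose_side, c("right", "left"))
})

test_that("cohort round-trips through tidy text files byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  simulate_cohort(2, nights = 1, preset = "naive", seed = 3, dir = dir1)
  simulate_cohort(2, nights = 1, preset = "naive", seed = 3, dir = dir2)
  expect_identical(readLines(file.path(dir1, "events.csv")),
                   readLines(file.path(dir2, "events.csv")))
  co <- read_cohort(dir1)
  expect_s3_class(co, "spt_cohort")
  orig <- simulate_cohort(2, nights = 1, preset = "naive", seed = 3)
  expect_equal(co$sessions[["m01_n1"]]$sucrose$times,
               orig$sessions[["m01_n1"]]$sucrose$times, tolerance = 1e-12)
})

test_that("artifact injection corrupts sessions and logs what changed", {
  s <- simulate_session(sim_config(seed = 4))
  leaked <- inject_artifacts(s, list(list(type = "leak", bottle = "sucrose",
                                          volume_ml = 2)))
  expect_equal(unname(leaked$volumes["sucrose"] - s$volumes["sucrose"]), 2)
  expect_identical(leaked$sucrose$times, s$sucrose$times)
  expect_equal(leaked$truth$artifacts$type, "leak")

  gone <- inject_artifacts(s, list(list(type = "dropout", start = 0,
                                        end = s$config$session_length)))
  expect_equal(length(gone$water), 0)
  expect_equal(length(gone$sucrose), 0)

  # overlapping dropout windows are merged, not errored
  m <- inject_artifacts(s, list(list(type = "dropout", start = 0, end = 1000),
                                list(type = "dropout", start = 500, end = 2000)))
  expect_equal(sum(m$truth$artifacts$type == "dropout"), 1)
  expect_equal(m$truth$artifacts$end[m$truth$artifacts$type == "dropout"], 2000)
  expect_true(all(m$sucrose$times >= 2000 | m$sucrose$times < 0))

  ct <- inject_artifacts(s, list(list(type = "crosstalk", from = "sucrose",
                                      to = "water", fraction = 0.5)))
  expect_gt(length(ct$water), length(s$water))
  expect_error(inject_artifacts(s, list(list(type = "flood"))),
               "unknown artifact")
})
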