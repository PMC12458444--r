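test_that("activity binarization follows the per-minute displacement rule", {
  # stationary fly: every complete minute inactive
  expect_equal(binarize_activity(make_traj(rep(3, 600), L = 65)),
               rep(FALSE, 10))

  # 5 mm displacement per minute with a 1 mm threshold: all active
  pos <- cumsum(rep(5 / 60, 600))
  expect_true(all(binarize_activity(make_traj(pos))))

  # partial trailing minute dropped
  expect_length(binarize_activity(make_traj(rep(0, 90), L = 1)), 1L)

  expect_error(binarize_activity(make_traj(rep(0, 90), L = 1), -1),
               "non-negative")
})

test_that("binarization matches a brute-force per-minute displacement sum", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(180:600, 1)
    pos <- pmin(pmax(cumsum(rnorm(n, 0, 0.05)) + 30, 0), 65)
    tr <- make_traj(pos, L = 65)
    eps <- runif(1, 0, 2)
    got <- binarize_activity(tr, eps)
    # oracle: displacement |dx| binned by the minute of the later sample
    n_min <- floor(n / 60)
    disp <- abs(diff(pos))
    minute <- floor((seq_along(disp)) / 60) + 1L  # later sample time = index
    want <- vapply(seq_len(n_min), function(m)
      sum(disp[minute == m & minute <= n_min]) > eps, logical(1))
    expect_identical(got, want)
  }
})

test_that("sleep bouts are maximal inactive runs of at least five minutes", {
  # A A A I I I I I A A: exactly one 5-minute bout (inclusive threshold)
  flags <- c(TRUE, TRUE, TRUE, rep(FALSE, 5), TRUE, TRUE)
  b <- detect_sleep_bouts(flags)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration_min, 5)
  expect_equal(b$start_s, 3 * 60)
  expect_equal(b$end_s, 8 * 60)

  expect_equal(nrow(detect_sleep_bouts(rep(TRUE, 20))), 0L)
  expect_equal(nrow(detect_sleep_bouts(c(rep(FALSE, 4), rep(TRUE, 6)))), 0L)
  expect_error(detect_sleep_bouts(flags, min_bout_min = 0), ">= 1")
})

test_that("bout detection matches a brute-force run-length scanner", {
  set.seed(22)
  for (rep in 1:1000) {
    flags <- runif(sample(5:120, 1)) < runif(1)
    got <- detect_sleep_bouts(flags)
    want <- brute_force_bouts(flags)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_s, want$start_s)
      expect_equal(got$end_s, want$end_s)
      expect_equal(got$duration_min, want$duration_min)
    }
  }
})

test_that("sleep minutes per hour is bout minutes over window hours", {
  b <- data.frame(start_s = c(0, 3600), end_s = c(1200, 4200),
                  duration_min = c(20, 10))
  expect_equal(sleep_minutes_per_hour(b, 120 * 60), 15)
  full <- data.frame(start_s = 0, end_s = 3600, duration_min = 60)
  expect_equal(sleep_minutes_per_hour(full, 3600), 60)
  expect_error(sleep_minutes_per_hour(full, 1800), "beyond")
})

test_that("baseline speed equals mean pre-stimulus speed and the path-length oracle", {
  sp <- c(0, rep(2, 3600))
  expect_equal(baseline_speed(traj_from_speeds(sp), 3600), 2)

  sp <- c(0, rep(0, 1800), rep(4, 1800))
  expect_equal(baseline_speed(traj_from_speeds(sp), 3600), 2)

  set.seed(23)
  pos <- pmin(pmax(cumsum(rnorm(3700, 0, 0.5)) + 30, 0), 65)
  tr <- make_traj(pos, L = 65)
  # oracle: summed path length over the displacements landing in the hour
  want <- sum(abs(diff(pos))[1:3600]) / 3600
  expect_equal(baseline_speed(tr, 3600), want, tolerance = 1e-9)

  expect_error(baseline_speed(tr, 3000), "insufficient")
})

test_that("startle duration is the first smoothed return to baseline", {
  # post-stimulus smoothed speeds on a 10-s grid: 3, 2.5, 2, 1.5, 1.0
  # with baseline 1.0 the first at-or-below sample is 50 s after stimulus
  sp <- c(0, rep(1, 360), 3, 2.5, 2, 1.5, 1, 0.5, 0.5)
  tr <- traj_from_speeds(sp, dt = 10)
  d <- startle_duration(tr, 3600, baseline = 1.0, smooth_window_s = 10)
  expect_equal(d$duration_s, 50)
  expect_false(d$censored)

  # already at baseline immediately after the stimulus
  d0 <- startle_duration(tr, 3600, baseline = 3.5, smooth_window_s = 10)
  expect_equal(d0$duration_s, 0)

  # never returns within the cap: censored at cap
  fast <- traj_from_speeds(c(0, rep(5, 100)), dt = 1)
  dc <- startle_duration(fast, 10, baseline = 1, cap_s = 60)
  expect_equal(dc$duration_s, 60)
  expect_true(dc$censored)

  expect_error(startle_duration(fast, 10, baseline = -1), "non-negative")
})

test_that("startle magnitude is the post-minute speed excess", {
  sp <- c(0, rep(1, 3600), rep(4, 70))
  tr <- traj_from_speeds(sp)
  expect_equal(startle_magnitude(tr, 3600, baseline = 1), 3)
  expect_equal(startle_magnitude(tr, 3600, baseline = 4), 0)
  expect_error(startle_magnitude(tr, 3640, baseline = 1), "truncated")
})

test_that("startle aggregation is the mean over stimuli", {
  expect_equal(aggregate_startle(c(10, 20)), 15)
  expect_equal(aggregate_startle(42), 42)
  expect_equal(aggregate_startle(c(3, 7, 14)), mean(c(3, 7, 14)))
  expect_error(aggregate_startle(numeric(0)), "no per-stimulus")
})

test_that("zone occupancy uses half-open eighths with the food zone first", {
  L <- 65
  # evenly spanning [0, L): exactly 1/8 per zone
  tr <- make_traj((0:799) / 800 * L, L = L)
  expect_equal(zone_occupancy(tr), rep(1 / 8, 8))

  tr0 <- make_traj(rep(0, 10), L = L)
  expect_equal(zone_occupancy(tr0)[1], 1)
  expect_equal(zone_occupancy(tr0)[8], 0)

  # x = L/8 belongs to zone 2 (half-open bins); x = L to zone 8
  edge <- make_traj(c(L / 8, L / 8, L), L = L)
  oc <- zone_occupancy(edge)
  expect_equal(oc[1], 0)
  expect_equal(oc[2], 2 / 3)
  expect_equal(oc[8], 1 / 3)

  # brute-force binning oracle on random positions
  set.seed(24)
  x <- runif(500, 0, L)
  trr <- make_traj(x, L = L)
  want <- vapply(0:7, function(i)
    mean(x >= i * L / 8 & (x < (i + 1) * L / 8 | (i == 7 & x == L))),
    numeric(1))
  expect_equal(zone_occupancy(trr), want)
  expect_equal(sum(zone_occupancy(trr)), 1)
})

test_that("arcsine-square-root transform hits its landmarks", {
  expect_equal(arcsin_sqrt(0), 0)
  expect_equal(arcsin_sqrt(1), pi / 2)
  expect_equal(arcsin_sqrt(0.5), pi / 4)
  expect_error(arcsin_sqrt(1.2), "\\[0, 1\\]")
})

test_that("sleep scoring is monotone in added inactivity and stable under active padding", {
  set.seed(25)
  for (rep in 1:50) {
    flags <- runif(60) < 0.5
    sleep0 <- sleep_minutes_per_hour(detect_sleep_bouts(flags), 3600)
    act <- which(flags)
    if (length(act)) {
      flags2 <- flags
      flags2[sample(act, 1)] <- FALSE
      sleep1 <- sleep_minutes_per_hour(detect_sleep_bouts(flags2), 3600)
      expect_gte(sleep1, sleep0)
    }
    # appending active minutes at either end preserves the bout set
    b0 <- detect_sleep_bouts(flags)
    b_end <- detect_sleep_bouts(c(flags, TRUE, TRUE))
    expect_equal(b0, b_end)
    b_front <- detect_sleep_bouts(c(TRUE, TRUE, flags))
    expect_equal(b0$duration_min, b_front$duration_min)
    expect_equal(b0$start_s + 120, b_front$start_s)
  }
})

test_that("full phenotyping recovers the configured genotype ordering of sleep", {
  cfg <- simulation_config(seed = 26, design = toy_design(dur = 3700),
                           temperatures = 25, blocks = "B1")
  sim <- simulate_cohort(cfg, n_per_cell = 12)
  phen <- compute_phenotypes(sim$trajectories, cfg$design)
  d <- merge(phen, sim$metadata, by = "fly_id")
  m <- tapply(d$sleep_min_per_hour, d$genotype, mean)
  # sleep_geno_mult defaults: STD 1 > HET 0.85 > INV 0.7
  expect_gt(m[["STD"]], m[["INV"]])
  expect_true(all(is.finite(as.matrix(phen[, -1]))))
  expect_true(all(phen$sleep_min_per_hour >= 0 & phen$sleep_min_per_hour <= 60))
  expect_true(all(phen$prop_near_food + phen$prop_far_food <= 1 + 1e-12))
})
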