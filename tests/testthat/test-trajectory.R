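make_traj <- function(y, dt = 0.05) trajectory(seq_along(y) * dt, y)

test_that("the trailing moving average behaves like a 4-point FIR filter", {
  # constant signal is unchanged
  const <- make_traj(rep(2e-6, 30))
  expect_equal(moving_average(const)$y_m, rep(2e-6, 30))
  # a unit impulse spreads into four samples of 1/4
  imp <- make_traj(c(rep(0, 9), 1, rep(0, 10)))
  sm <- moving_average(imp)$y_m
  expect_equal(sm[10:13], rep(0.25, 4))
  expect_equal(sm[c(1:9, 14:20)], rep(0, 16))
  # white-noise variance drops by the window length
  set.seed(4)
  noise <- make_traj(rnorm(1e4))
  expect_equal(var(moving_average(noise)$y_m[5:1e4]), 0.25, tolerance = 0.1)
  # shrinking-window edge policy preserves length and the first sample
  expect_equal(length(sm), 20)
  ramp <- moving_average(make_traj(c(4, 8, 12, 16, 20)))
  expect_equal(ramp$y_m[1:3], c(4, 6, 8))
  expect_error(moving_average(make_traj(c(1, 2, 3))), "shorter")
})

test_that("trajectories are segmented on the cyclic schedule boundaries", {
  sched <- frequency_schedule()
  # a full 3.8 s cycle at 20 fps: three segments of 1.3 / 1.8 / 0.7 s
  tr <- segment_by_schedule(make_traj(rep(0, 76)), sched)
  expect_identical(unique(tr$segment), 1:3)
  expect_equal(as.vector(table(tr$segment)), c(26, 36, 14))
  expect_equal(unique(tr$frequency_hz[tr$segment == 2]), 1.2e6)
  # shorter than the first dwell: a single partial segment
  short <- segment_by_schedule(make_traj(rep(0, 10)), sched)
  expect_identical(unique(short$segment), 1L)
  # shifting the origin by a whole cycle changes nothing
  shifted <- segment_by_schedule(make_traj(rep(0, 76)), sched,
                                 t0 = -sum(sched$duration_s))
  expect_identical(shifted$segment, tr$segment)
  expect_identical(shifted$frequency_hz, tr$frequency_hz)
})

test_that("balance validation applies the 10%-of-mean-step criterion in the
           final 250 ms", {
  sched <- frequency_schedule(c(1e6, 2e6), c(1, 1))
  dt <- 0.05
  t <- seq(dt, 2, by = dt)
  # settled two-level trajectory: both segments valid
  y <- ifelse(t <= 1, 10e-6, 20e-6)
  rec <- validate_balance(segment_by_schedule(trajectory(t, y), sched))
  expect_true(all(rec$valid))
  expect_equal(rec$balance_m, c(10e-6, 20e-6))
  # a segment still ramping through its final window is invalid
  y2 <- ifelse(t <= 1, 10e-6, 10e-6 + (t - 1) * 10e-6)  # ramps to 20 um
  rec2 <- validate_balance(segment_by_schedule(trajectory(t, y2), sched))
  expect_false(rec2$valid[2])
  expect_identical(rec2$reason[2], "unsettled")
  # an under-sampled final window is flagged, not crashed
  coarse <- trajectory(c(1, 2), c(0, 5e-6))
  seg <- segment_by_schedule(coarse, frequency_schedule(c(1e6, 2e6), c(1, 1)))
  rec3 <- validate_balance(seg)
  expect_false(any(rec3$valid))
  expect_true(all(rec3$reason == "insufficient samples"))
})

test_that("the settling-time threshold matches the analytic exponential
           oracle", {
  # two 1 s segments; the second relaxes from 0 to delta with constant tau
  dt <- 0.05
  Td <- 1
  win <- 0.25
  # analytic threshold: residual at the window start equals 10% of the step
  g <- function(tau) (exp(-(Td - win) / tau) - exp(-Td / tau)) -
    0.1 * (1 - exp(-Td / tau))
  tau_star <- uniroot(g, c(0.01, 1))$root
  run_tau <- function(tau) {
    t <- seq(dt, 2 * Td, by = dt)
    y <- ifelse(t <= Td, 0, 10e-6 * (1 - exp(-(t - Td) / tau)))
    sched <- frequency_schedule(c(1e6, 2e6), c(Td, Td))
    validate_balance(segment_by_schedule(trajectory(t, y), sched))$valid[2]
  }
  expect_true(run_tau(0.9 * tau_star))
  expect_false(run_tau(1.1 * tau_star))
})

test_that("validation is equivariant under rescaling of all positions", {
  set.seed(12)
  sched <- frequency_schedule()
  t <- seq(0.05, 3.8, by = 0.05)
  y <- cumsum(rnorm(length(t), sd = 1e-6))
  base <- validate_balance(segment_by_schedule(trajectory(t, y), sched))
  for (k in c(0.2, 5, 1000)) {
    scaled <- validate_balance(
      segment_by_schedule(trajectory(t, k * y), sched))
    expect_identical(scaled$valid, base$valid)
    expect_equal(scaled$balance_m, k * base$balance_m)
  }
})

test_that("truncation reproduces the full validation at factor 1 and decays
           to zero", {
  dev <- device_state()
  sched <- frequency_schedule()
  set.seed(33)
  taus <- runif(30, 0.05, 1.2)
  trajs <- lapply(seq_along(taus), function(i)
    simulate_trajectory(c(-0.25, -0.45, -0.38), 5e-6, dev, sched,
                        tau = taus[i], noise_sd = 0, seed = 400 + i))
  res <- truncation_analysis(trajs, sched, factors = c(0.3, 0.5, 0.75, 1))
  full <- mean(unlist(lapply(trajs, function(tr)
    validate_balance(tr)$valid)))
  expect_equal(res$fraction_valid[res$factor == 1], full)
  expect_true(all(diff(res$fraction_valid) >= 0))
  expect_gt(full, 0.5)                   # most of the cohort settles in time
  tiny <- truncation_analysis(trajs[1:3], sched, factors = 0.02)
  expect_equal(tiny$fraction_valid, 0)
  expect_equal(res$total_duration_s, c(0.3, 0.5, 0.75, 1) * 3.8)
})

test_that("simulated trajectories settle to the forward-model balance
           positions", {
  dev <- device_state()
  sched <- frequency_schedule()
  cms <- c(-0.25, -0.45, -0.38)
  targets <- vapply(1:3, function(k)
    balance_position(5e-6, cms[k], dev, sched$frequency_hz[k])$position_m,
    numeric(1))
  tr <- simulate_trajectory(cms, 5e-6, dev, sched, tau = 0.02, noise_sd = 0,
                            y0 = targets[1] * 1.4, seed = 2)
  finals <- vapply(split(tr$y_m, tr$segment), function(z) z[length(z)],
                   numeric(1))
  expect_equal(unname(finals), targets, tolerance = 1e-3)
  # a glacial settling time keeps the cell at its initial position
  frozen <- simulate_trajectory(cms, 5e-6, dev, sched, tau = 1e6,
                                noise_sd = 0, y0 = 30e-6, seed = 2)
  expect_equal(frozen$y_m, rep(30e-6, nrow(frozen)), tolerance = 1e-4)
  # observation noise has the requested standard deviation
  noisy <- simulate_trajectory(cms[1], 5e-6, dev,
                               frequency_schedule(1.2e6, 50),
                               tau = 0.01, noise_sd = 0.25e-6, seed = 77)
  expect_equal(sd(noisy$y_m[100:1000]), 0.25e-6, tolerance = 0.1)
  # seed determinism
  expect_identical(simulate_trajectory(cms, 5e-6, dev, sched, seed = 5),
                   simulate_trajectory(cms, 5e-6, dev, sched, seed = 5))
})

test_that("a settled noise-free trajectory inverts back to the input
           Re[CM]", {
  dev <- device_state()
  sched <- frequency_schedule()
  cms <- c(-0.22, -0.42, -0.35)
  tr <- moving_average(simulate_trajectory(cms, 5e-6, dev, sched,
                                           tau = 0.02, noise_sd = 0,
                                           seed = 3))
  rec <- validate_balance(tr)
  expect_true(all(rec$valid))
  back <- vapply(seq_len(nrow(rec)), function(k)
    invert_cm(rec$balance_m[k], 5e-6, dev, rec$frequency_hz[k]), numeric(1))
  expect_equal(back, cms, tolerance = 1e-3)
})

test_that("trajectory CSV round-trips with its segmentation", {
  tr <- segment_by_schedule(make_traj(sin(1:76)), frequency_schedule())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$y_m, tr$y_m)
  expect_equal(back$segment, tr$segment)
})
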