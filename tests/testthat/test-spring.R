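test_that("the spring argument has the force-balance scalings", {
  dev <- device_state()
  u0 <- spring_argument(5e-6, -0.2, dev, 1e6)
  # voltage enters squared
  dev2 <- device_state(rms_voltage = dev$rms_voltage * 2)
  expect_equal(spring_argument(5e-6, -0.2, dev2, 1e6), u0 / 4)
  # linear in 1/|Re CM|
  expect_equal(spring_argument(5e-6, -0.1, dev, 1e6), u0 * 2)
  # linear in flow rate
  dev3 <- device_state(flow_rate = dev$flow_rate * 3)
  expect_equal(spring_argument(5e-6, -0.2, dev3, 1e6), u0 * 3)
  # term-by-term arithmetic oracle for the fully specified default device
  with(dev, {
    drag <- 3 * viscosity * sin(electrode_angle) *
      (6 * flow_rate / (channel_width * channel_height^3)) *
      (channel_height - 5e-6) * gap^3
    dep <- 5e-6 * (EPS0 * 78.5) * 0.2 * rms_voltage^2
    expect_equal(u0, drag / dep)
  })
  expect_error(spring_argument(5e-6, 0.2, dev, 1e6), "no-balance")
  expect_error(spring_argument(5e-6, -0.2, dev, -1), "positive")
  expect_error(spring_argument(25e-6, -0.2, dev, 1e6), "geometry")
})

test_that("balance position inverts the exponential force decay", {
  dev <- device_state()
  # u = 1 sits exactly at the electrode center
  cm_unity <- -spring_argument(5e-6, -1, dev, 1e6)  # the Re[CM] giving u = 1
  expect_equal(balance_position(5e-6, cm_unity, dev, 1e6)$position_m, 0)
  # doubling the voltage moves the cell out by lambda log 4
  d1 <- balance_position(5e-6, -0.2, dev, 1e6)$position_m
  dev2 <- device_state(rms_voltage = dev$rms_voltage * 2)
  d2 <- balance_position(5e-6, -0.2, dev2, 1e6)$position_m
  expect_equal(d2 - d1, dev$decay_length * log(4))
  # monotone in |Re CM|
  cms <- seq(-0.06, -0.5, length.out = 40)
  ds <- balance_position(5e-6, cms, dev, 1e6)$position_m
  expect_true(all(diff(ds) > 0))
  # too-weak DEP clamps to the electrode center with a warning
  expect_warning(d0 <- balance_position(5e-6, -0.01, dev, 1e6)$position_m,
                 "clamped")
  expect_equal(d0, 0)
})

test_that("inversion round-trips the forward model to 1e-9", {
  dev <- device_state()
  set.seed(99)
  n <- 1000
  R <- runif(n, 3e-6, 8e-6)
  f <- 10^runif(n, 5, 8)
  u1 <- vapply(seq_len(n), function(i)
    spring_argument(R[i], -1, dev, f[i]), numeric(1))
  cm <- -runif(n, 1, 20) * u1          # guarantees u <= 1 (no clamping)
  cm <- pmax(cm, -0.4999)
  delta <- vapply(seq_len(n), function(i)
    balance_position(R[i], cm[i], dev, f[i])$position_m, numeric(1))
  back <- vapply(seq_len(n), function(i)
    invert_cm(delta[i], R[i], dev, f[i]), numeric(1))
  expect_equal(back, cm, tolerance = 1e-9)
  # independent bisection oracle on the forward model for one case
  target <- balance_position(5e-6, -0.3, dev, 2e6)$position_m
  root <- uniroot(function(c)
    balance_position(5e-6, c, dev, 2e6)$position_m - target,
    c(-0.5, -0.06), tol = 1e-12)$root
  expect_equal(invert_cm(target, 5e-6, dev, 2e6), root, tolerance = 1e-6)
  # delta = 0 maps back to the Re[CM] giving u = 1
  expect_equal(invert_cm(0, 5e-6, dev, 2e6),
               -spring_argument(5e-6, -1, dev, 2e6))
})

test_that("the balance position only sees Re[CM] V^2 as a product", {
  dev <- device_state()
  for (k in c(0.5, 2, 3.7)) {
    devk <- device_state(rms_voltage = dev$rms_voltage / sqrt(k))
    expect_equal(balance_position(5e-6, -0.2 * k, devk, 1e6)$position_m,
                 balance_position(5e-6, -0.2, dev, 1e6)$position_m)
  }
})

test_that("bead calibration recovers a known normalization", {
  dev <- device_state()
  bead <- dielectric_material(2.5, 1e-4)
  R_b <- 5.13e-6
  freqs <- c(5e5, 1.2e6, 2e6, 25e6)
  p_true <- c(1, 1.15, 1.3, 0.8)       # already 1 at the lowest frequency
  dev_p <- device_state(normalization =
                          data.frame(frequency_hz = freqs, p = p_true))
  cm_b <- Re(cm_factor(bead, dev$medium, freqs))
  delta <- vapply(seq_along(freqs), function(i)
    balance_position(R_b, cm_b[i], dev_p, freqs[i])$position_m, numeric(1))
  fit <- calibrate_p(data.frame(frequency_hz = freqs, delta_m = delta),
                     bead, R_b, dev)
  expect_equal(fit$p, p_true, tolerance = 1e-9)
  # single-frequency calibration is identically 1 after normalization
  one <- calibrate_p(data.frame(frequency_hz = 1e6, delta_m = delta[2]),
                     bead, R_b, dev)
  expect_equal(one$p, 1)
  # the calibrated table feeds back into the forward model exactly
  dev_cal <- device_state(normalization = fit)
  expect_equal(balance_position(R_b, cm_b[3], dev_cal, freqs[3])$position_m,
               delta[3], tolerance = 1e-9)
})

test_that("position noise propagates into the calibrated p as predicted", {
  dev <- device_state()
  bead <- dielectric_material(2.5, 1e-4)
  freqs <- c(5e5, 25e6)
  cm_b <- Re(cm_factor(bead, dev$medium, freqs))
  delta <- vapply(seq_along(freqs), function(i)
    balance_position(5e-6, cm_b[i], dev, freqs[i])$position_m, numeric(1))
  noise <- 0.5e-6
  set.seed(31)
  err <- replicate(1000, {
    noisy <- delta + rnorm(2, sd = noise)
    fit <- calibrate_p(data.frame(frequency_hz = freqs,
                                  delta_m = pmax(noisy, 0)),
                       bead, 5e-6, dev)
    log(fit$p[2])                      # true value is log 1 = 0
  })
  # log p error is the difference of two position errors over lambda
  predicted_sd <- sqrt(2) * noise / dev$decay_length
  expect_lt(abs(mean(err)), 3 * predicted_sd / sqrt(1000) * 5)
  expect_equal(sd(err), predicted_sd, tolerance = 0.1)
})

test_that("size correction removes all radius dependence", {
  dev <- device_state()
  # identity at the reference radius
  expect_equal(size_correct(8e-6, 5e-6, 5e-6, dev, 1e6), 8e-6)
  # same Re[CM], different radii -> identical corrected positions
  cm <- -0.25
  d_small <- balance_position(4e-6, cm, dev, 1e6)$position_m
  d_large <- balance_position(7e-6, cm, dev, 1e6)$position_m
  expect_false(isTRUE(all.equal(d_small, d_large)))
  expect_equal(size_correct(d_small, 4e-6, 5e-6, dev, 1e6),
               size_correct(d_large, 7e-6, 5e-6, dev, 1e6))
  # ordering by |Re CM| survives the correction
  set.seed(17)
  cms <- sort(runif(100, -0.45, -0.1))
  Rs <- runif(100, 3.5e-6, 7.5e-6)
  deltas <- vapply(1:100, function(i)
    balance_position(Rs[i], cms[i], dev, 1e6)$position_m, numeric(1))
  corr <- vapply(1:100, function(i)
    size_correct(deltas[i], Rs[i], 5e-6, dev, 1e6), numeric(1))
  expect_true(all(diff(corr[order(cms)]) < 0))  # |CM| decreasing -> delta down
})

test_that("device configuration round-trips through YAML", {
  dev <- device_state(rms_voltage = 3.3,
                      normalization = data.frame(
                        frequency_hz = c(1e6, 1e7), p = c(1, 1.2)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_device_yaml(dev, path)
  back <- read_device_yaml(path)
  expect_equal(back$rms_voltage, 3.3)
  expect_equal(back$normalization$p, c(1, 1.2))
  expect_equal(normalization_at(back, 3.16e6), normalization_at(dev, 3.16e6))
  expect_equal(spring_argument(5e-6, -0.2, back, 2e6),
               spring_argument(5e-6, -0.2, dev, 2e6))
})
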