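test_that("radar parameter invariants hold and are validated", {
  p <- radar_params()
  expect_equal(p$lambda_p, (p$c / sqrt(p$epsilon)) / p$f_p, tolerance = 1e-14)
  expect_equal(p$C1, p$B_amp * sin(4 * pi * p$R_o / p$lambda_p))
  expect_equal(p$C2, p$B_amp * (4 * pi / p$lambda_p) *
                 cos(4 * pi * p$R_o / p$lambda_p))
  expect_silent(validate_radar_params(p))
  bad <- p; bad$C1 <- bad$C1 * 1.01
  expect_error(validate_radar_params(bad), "C1")
  expect_error(radar_params(epsilon = 0.5))
})

test_that("closed-form baseband collapses to the constant and null cases", {
  p <- default_radar
  t <- time_grid(1)
  zero <- displacement_series(t, rep(0, length(t)), 64)
  expect_equal(baseband_exact(zero, p)$b, rep(p$C1, length(t)))
  expect_equal(baseband_linear(zero, p)$b, rep(p$C1, length(t)))
  # wall at exactly a quarter wavelength: phase pi null
  p2 <- radar_params(R_o = 5e-3)
  dr_null <- displacement_series(t, rep(p2$R_o - p2$lambda_p / 4, length(t)),
                                 64)
  expect_lt(max(abs(baseband_exact(dr_null, p2)$b)), 1e-12)
})

test_that("non-uniform sampling and oversized displacement are rejected", {
  t <- c(0, 1 / 64, 2.5 / 64, 3 / 64)
  expect_error(displacement_series(t, rep(0, 4), 64), "non-uniform")
  big <- tone_displacement(1, amp = 0.2 * default_radar$R_o)
  expect_error(baseband_linear(big, default_radar), "displacement too large")
})

test_that("linearized baseband is exactly affine and matches the exact form", {
  p <- default_radar
  dr <- tone_displacement(1, amp = 2.8e-5)
  bl <- baseband_linear(dr, p)
  # affine: doubling dr doubles the deviation from C1 exactly
  dr2 <- displacement_series(dr$t, 2 * dr$dr, dr$fs)
  bl2 <- baseband_linear(dr2, p)
  expect_equal(bl2$b - p$C1, 2 * (bl$b - p$C1))
  expect_equal(abs(cor(bl$b, dr$dr)), 1, tolerance = 1e-12)
  # closed forms agree: relative RMS error under the smallness condition
  be <- baseband_exact(dr, p)
  expect_lt(4 * pi * max(abs(dr$dr)) / p$lambda_p, 0.01)
  rel_rms <- sqrt(mean((be$b - bl$b)^2)) / sqrt(mean(be$b^2))
  expect_lt(rel_rms, 1e-3)
})

test_that("Taylor remainder bound holds over randomized displacements", {
  p <- default_radar
  for (seed in 1:20) {
    set.seed(seed)
    amp <- runif(1, 0.1, 1) * min(1e-2 * p$R_o,
                                  1e-2 * p$lambda_p / (4 * pi))
    t <- time_grid(2)
    dr <- displacement_series(t, amp * rowSums(
      sapply(1:4, function(k) runif(1, -1, 1) *
               sin(2 * pi * k * runif(1, 0.5, 2) * t + runif(1, 0, 2 * pi)))
    ) / 4, 64)
    bound <- 0.5 * p$B_amp * (4 * pi * max(abs(dr$dr)) / p$lambda_p)^2
    err <- max(abs(baseband_exact(dr, p)$b - baseband_linear(dr, p)$b))
    expect_lte(err, bound)
  }
})

test_that("pulse-level mixing reproduces the closed-form baseband", {
  p <- default_radar
  # constant displacement: constant mixer output
  t <- time_grid(0.5)
  zero <- displacement_series(t, rep(0, length(t)), 64)
  b0 <- simulate_pulse_mixing(zero, p)$b
  expect_lt(sd(b0) / abs(mean(b0)), 1e-3)
  # slow ramp: monotone, with the slope sign of -C2
  ramp <- displacement_series(t, seq(0, 2.8e-5, length.out = length(t)), 64)
  br <- simulate_pulse_mixing(ramp, p)$b
  expect_true(all(diff(br) * sign(-p$C2) > 0))
  # sinusoid: affine match to the exact closed form within 1% RMS
  dr <- tone_displacement(1, amp = 2.8e-5, duration_s = 2)
  bm <- simulate_pulse_mixing(dr, p)$b
  be <- baseband_exact(dr, p)$b
  cal <- lm(be ~ bm)
  expect_lt(sqrt(mean(resid(cal)^2)) / sd(be), 1e-2)
  # 1 Hz spectral line amplitude matches within 1% after gain calibration
  spec_of <- function(b) {
    X <- Mod(fft(b - mean(b)))
    X[1 + round(1 * length(b) / 64)]  # 1 Hz bin (2 s record: bin 3)
  }
  gain <- abs(coef(cal)[["bm"]])
  expect_equal(gain * spec_of(bm), spec_of(be), tolerance = 1e-2)
  expect_error(simulate_pulse_mixing(dr, p, oversample = 4), "alias")
})

test_that("a pure-tone displacement keeps its frequency in the baseband", {
  p <- default_radar
  for (f0 in c(0.9, 1.4, 2.2)) {
    dr <- tone_displacement(f0, amp = 2.8e-5, duration_s = 30)
    sp <- compute_spectrum(baseband_exact(dr, p))
    peak <- sp$freq_hz[which.max(sp$mag)]
    expect_lt(abs(peak - f0), sp$df_hz + 1e-12)
  }
})
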