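test_that("turbulence depth follows the logistic flow response", {
  tp <- turbulence_params(depth_max = 0.4, Q50 = 600, slope = 50)
  expect_equal(turbulence_depth(tp, 600), 0.2)          # midpoint: half depth
  expect_equal(turbulence_depth(tp, 1e9), 0)            # high-flow limit
  expect_gt(turbulence_depth(tp, 200), 0.395)           # low-flow saturation
  # waveform with flow -> Inf equals the modulation-off waveform
  pp <- physio_params()
  d_off <- simulate_displacement(pp, turbulence_params(depth_max = 0),
                                 flow = 500, seed = 7, duration_s = 30)
  d_far <- simulate_displacement(pp, turbulence_params(depth_max = 0.5),
                                 flow = 1e9, seed = 7, duration_s = 30)
  expect_equal(d_far$dr, d_off$dr)
})

test_that("modulation off leaves harmonic ratios set by the amplitude profile", {
  pp <- physio_params(phase_jitter_sd = 0, amp_jitter_cv = 0,
                      baseline_drift_amp = 0)
  d <- simulate_displacement(pp, turbulence_params(depth_max = 0),
                             flow = 900, duration_s = 60, fs = 64, seed = 2)
  bb <- baseband_linear(d, default_radar)
  sp <- compute_spectrum(bb)
  hf <- extract_harmonics(sp, detect_fundamental(sp))
  expected <- pp$amp_profile[2:6] / pp$amp_profile[1:5]
  expect_equal(unname(hf$hr), expected, tolerance = 0.02)
})

test_that("sampling below the highest simulated frequency is refused", {
  expect_error(simulate_displacement(physio_params(f0 = 2.5),
                                     turbulence_params(), flow = 800,
                                     fs = 16, seed = 1),
               "fs below")
})

test_that("cohort simulation is deterministic and carries its manifest", {
  spec <- cohort_spec(n_patients = 6, seed = 123, duration_s = 30)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(lapply(c1$records, `[[`, "b"),
                   lapply(c2$records, `[[`, "b"))
  expect_equal(nrow(c1$manifest), 6)
  expect_true(all(c1$manifest$k_mult %in% 3:5))
  expect_true(all(c1$manifest$flow_mL_min >= 200 &
                    c1$manifest$flow_mL_min <= 1500))
  # downstream features are byte-identical too
  f1 <- feature_table(c1)
  f2 <- feature_table(c2)
  expect_identical(f1, f2)
})

test_that("degenerate flow distributions warn but do not fail", {
  spec <- cohort_spec(n_patients = 3, flow_distribution = rep(800, 3),
                      seed = 1, duration_s = 30)
  expect_warning(simulate_cohort(spec), "degenerate")
})

test_that("turbulence strengthens its harmonic ratio monotonically in depth", {
  depths <- seq(0, 0.5, by = 0.1)
  pp <- physio_params()
  mean_hr <- sapply(depths, function(d) {
    mean(sapply(1:12, function(s) {
      tp <- turbulence_params(k_mult = 3, depth_max = d)
      dr <- simulate_displacement(pp, tp, flow = 250, duration_s = 30,
                                  seed = 1000 + s)
      sp <- compute_spectrum(baseband_linear(dr, default_radar))
      extract_harmonics(sp, detect_fundamental(sp))$hr[["hr32"]]
    }))
  })
  # non-decreasing up to Monte-Carlo noise
  expect_true(all(diff(mean_hr) > -0.02))
  expect_gt(mean_hr[length(mean_hr)], mean_hr[1] + 0.5)
})

test_that("high-flow stratum harmonic-ratio means match the clinical reference", {
  ref_mean <- c(0.380, 0.491, 0.785, 0.711, 0.751)
  ref_sd <- c(0.178, 0.285, 0.456, 0.273, 0.347)
  n <- 34
  pp <- physio_params()
  hrs <- t(sapply(1:n, function(s) {
    dr <- simulate_displacement(pp, turbulence_params(), flow = 1200,
                                duration_s = 60, seed = 200 + s)
    sp <- compute_spectrum(bandpass(baseband_linear(dr, default_radar)))
    extract_harmonics(sp, detect_fundamental(sp))$hr
  }))
  for (j in 1:5) {
    se_diff <- sqrt(ref_sd[j]^2 / n + var(hrs[, j]) / n)
    expect_lt(abs(mean(hrs[, j]) - ref_mean[j]), 2 * se_diff)
  }
})
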