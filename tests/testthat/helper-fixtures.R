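# Shared fixtures: all synthetic, built in code at test time.

default_radar <- radar_params()

# uniform time grid of `duration_s` seconds at `fs`
time_grid <- function(duration_s, fs = 64) {
  seq(0, by = 1 / fs, length.out = round(duration_s * fs))
}

# displacement record that is a single tone
tone_displacement <- function(freq, amp = 2.8e-5, duration_s = 2, fs = 64) {
  t <- time_grid(duration_s, fs)
  displacement_series(t, amp * sin(2 * pi * freq * t), fs)
}

# baseband record that is a sum of tones (amplitudes `amps` at `freqs`)
tone_record <- function(freqs, amps, duration_s = 60, fs = 64,
                        phases = rep(0, length(freqs))) {
  t <- time_grid(duration_s, fs)
  b <- rowSums(mapply(function(f, a, ph) a * sin(2 * pi * f * t + ph),
                      freqs, amps, phases))
  baseband_signal(t, b, fs, patient_id = "tone")
}

# harmonic-series record at fundamental f0 with per-harmonic amplitudes
harmonic_record <- function(amps, f0 = 1.2, duration_s = 60, fs = 64) {
  tone_record(f0 * seq_along(amps), amps, duration_s, fs)
}

# samples with exactly the requested mean and SD
samples_with_summary <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  mean + sd * x
}

# brute-force AUC: P(random positive outranks random negative), ties at 1/2
brute_auc <- function(dv_pos, dv_neg) {
  gt <- outer(dv_pos, dv_neg, ">")
  eq <- outer(dv_pos, dv_neg, "==")
  mean(gt + 0.5 * eq)
}

# feature data.frame built directly from an HR matrix (bypasses spectra)
features_from_matrix <- function(x, flows) {
  colnames(x) <- hr_feature_names()
  cbind(data.frame(patient_id = sprintf("S%03d", seq_len(nrow(x))),
                   flow_mL_min = flows, f0_hz = 1.2,
                   P1 = 1, P2 = 1, P3 = 1, P4 = 1, P5 = 1, P6 = 1),
        as.data.frame(x))
}
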