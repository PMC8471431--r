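#' Radar sensing-chain parameters
#'
#' Bundles the physical constants of the pulse-radar chain that senses
#' vessel-wall motion: a damped sinusoidal pulse at carrier frequency
#' `f_p` is emitted towards the arteriovenous fistula (AVF), the echo from
#' the wall at distance `R_o - dr(t)` is mixed with a delayed replica of the
#' emitted pulse, and low-pass filtering leaves a baseband signal
#' `B_amp * sin(4*pi*(R_o - dr)/lambda_p)`, where `lambda_p` is the carrier
#' wavelength in tissue. For wall displacements much smaller than `R_o` the
#' baseband is affine in displacement, `C1 - C2 * dr`.
#'
#' @param f_p Carrier frequency inside each pulse (Hz). Default 1.38e9, the
#'   measured antenna resonance of the sensor this model emulates.
#' @param epsilon Effective relative permittivity of skin and subcutaneous
#'   tissue (dimensionless, >= 1). Default 36, a mid-range soft-tissue value
#'   near 1.4 GHz giving a tissue wavelength of about 36 mm.
#' @param R_o Initial antenna-to-wall standoff distance (m), < 6e-3 for a
#'   fistula under the skin. Default 6e-3.
#' @param A Emitted pulse envelope amplitude (arbitrary units).
#' @param B_amp Baseband amplitude scale (arbitrary units).
#' @param tau Reference-pulse delay (s). `NULL` (default) picks the
#'   quadrature-aligned delay nearest the nominal round trip
#'   `2*R_o*sqrt(epsilon)/c`, i.e. an odd quarter-multiple of the carrier
#'   period, which maximises displacement sensitivity of the mixer and makes
#'   the pulse-level chain reproduce the closed-form baseband.
#' @param pulse_duration Duration of each emitted pulse (s). Default 4e-9.
#' @param prf Pulse repetition frequency (Hz). Default 250e3.
#' @param c_light Propagation speed in vacuum (m/s).
#'
#' @return An object of class `radar_params`: a list with the fields above
#'   plus the derived `lambda_p` (tissue wavelength, m) and the linearization
#'   constants `C1 = B_amp*sin(4*pi*R_o/lambda_p)` and
#'   `C2 = B_amp*(4*pi/lambda_p)*cos(4*pi*R_o/lambda_p)`.
#' @export
#' @examples
#' p <- radar_params()
#' p$lambda_p  # ~0.036 m in tissue
radar_params <- function(f_p = 1.38e9, epsilon = 36, R_o = 6e-3,
                         A = 1, B_amp = 1, tau = NULL,
                         pulse_duration = 4e-9, prf = 250e3,
                         c_light = 299792458) {
  stopifnot(f_p > 0, epsilon >= 1, R_o > 0, A > 0, B_amp > 0,
            pulse_duration > 0, prf > 0)
  lambda_p <- (c_light / sqrt(epsilon)) / f_p
  if (is.null(tau)) {
    # quadrature-aligned reference delay nearest the nominal round trip
    round_trip <- 2 * R_o * sqrt(epsilon) / c_light
    tau <- (round(f_p * round_trip - 0.25) + 0.25) / f_p
    if (tau < 0) tau <- 0.25 / f_p
  }
  p <- list(A = A, f_p = f_p, tau = tau, pulse_duration = pulse_duration,
            prf = prf, c = c_light, epsilon = epsilon,
            lambda_p = lambda_p, R_o = R_o, B_amp = B_amp)
  p$C1 <- B_amp * sin(4 * pi * R_o / lambda_p)
  p$C2 <- B_amp * (4 * pi / lambda_p) * cos(4 * pi * R_o / lambda_p)
  structure(p, class = "radar_params")
}

#' Validate radar parameters
#'
#' Re-derives `lambda_p`, `C1` and `C2` from the primitive fields and checks
#' the stored values against them (relative tolerance 1e-12).
#'
#' @param p A `radar_params` object.
#' @return `p`, invisibly; errors if any invariant fails.
#' @export
validate_radar_params <- function(p) {
  stopifnot(inherits(p, "radar_params"))
  lam <- (p$c / sqrt(p$epsilon)) / p$f_p
  if (abs(lam - p$lambda_p) > 1e-12 * lam)
    stop("lambda_p inconsistent with c, epsilon and f_p")
  C1 <- p$B_amp * sin(4 * pi * p$R_o / p$lambda_p)
  C2 <- p$B_amp * (4 * pi / p$lambda_p) * cos(4 * pi * p$R_o / p$lambda_p)
  if (abs(C1 - p$C1) > 1e-12 * max(1, abs(C1)))
    stop("stored C1 does not match its defining expression")
  if (abs(C2 - p$C2) > 1e-12 * max(1, abs(C2)))
    stop("stored C2 does not match its defining expression")
  if (p$R_o <= 0) stop("R_o must be positive")
  invisible(p)
}

#' Wall-displacement time series
#'
#' @param t Sample times (s), uniformly spaced.
#' @param dr Wall displacement (m), same length as `t`. Positive values move
#'   the wall towards the antenna.
#' @param fs Sampling rate (Hz).
#' @return A `displacement_series` object (list with `t`, `dr`, `fs`).
#' @export
displacement_series <- function(t, dr, fs) {
  stopifnot(length(t) == length(dr), length(t) >= 2, fs > 0,
            all(is.finite(t)), all(is.finite(dr)))
  dt <- diff(t)
  if (any(abs(dt - 1 / fs) > 1e-9))
    stop("non-uniform sampling: sample times must be spaced by 1/fs")
  structure(list(t = as.numeric(t), dr = as.numeric(dr), fs = fs),
            class = "displacement_series")
}

#' Baseband signal record
#'
#' @param t Sample times (s).
#' @param b Baseband amplitude (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param patient_id Opaque record identifier.
#' @param flow_mL_min Access-flow label (mL/min), or `NA` when unlabeled.
#' @return A `baseband_signal` object.
#' @export
baseband_signal <- function(t, b, fs, patient_id = NA_character_,
                            flow_mL_min = NA_real_) {
  stopifnot(length(t) == length(b), fs > 0, all(is.finite(b)))
  structure(list(t = as.numeric(t), b = as.numeric(b), fs = fs,
                 patient_id = patient_id,
                 flow_mL_min = as.numeric(flow_mL_min)),
            class = "baseband_signal")
}

#' @export
print.baseband_signal <- function(x, ...) {
  cat(sprintf("<baseband_signal> %s: %d samples @ %g Hz (%.1f s), flow = %s mL/min\n",
              x$patient_id, length(x$b), x$fs, length(x$b) / x$fs,
              ifelse(is.na(x$flow_mL_min), "NA",
                     format(x$flow_mL_min))))
  invisible(x)
}

#' Exact (closed-form) baseband demodulation
#'
#' Evaluates `B_amp * sin(4*pi*(R_o - dr)/lambda_p)` elementwise: the
#' low-pass residue of mixing the wall echo with the quadrature-aligned
#' reference pulse.
#'
#' @param dr A `displacement_series`.
#' @param p A `radar_params` object.
#' @return A `baseband_signal` on the same time grid.
#' @export
baseband_exact <- function(dr, p) {
  stopifnot(inherits(dr, "displacement_series"))
  validate_radar_params(p)
  b <- p$B_amp * sin(4 * pi * (p$R_o - dr$dr) / p$lambda_p)
  baseband_signal(dr$t, b, dr$fs)
}

#' Linearized baseband demodulation
#'
#' First-order expansion of [baseband_exact()] about `dr = 0`:
#' `B(t) = C1 - C2 * dr(t)`, valid while `max|dr| << R_o`. The call refuses
#' displacements exceeding `0.1 * R_o`.
#'
#' @inheritParams baseband_exact
#' @return A `baseband_signal` on the same time grid.
#' @export
baseband_linear <- function(dr, p) {
  stopifnot(inherits(dr, "displacement_series"))
  validate_radar_params(p)
  if (max(abs(dr$dr)) >= 0.1 * p$R_o)
    stop("displacement too large relative to R_o for the linearized model ",
         "(max|dr| must be < 0.1*R_o)")
  b <- p$C1 - p$C2 * dr$dr
  baseband_signal(dr$t, b, dr$fs)
}

#' Pulse-level simulation of the mixing chain
#'
#' Brute-force validation path for the closed-form baseband: for every
#' displacement sample it synthesises one emitted damped sinusoidal pulse,
#' its echo delayed by the round trip `2*(R_o - dr)/(c/sqrt(epsilon))`, and
#' the reference pulse delayed by `tau`, multiplies echo and reference on a
#' fine radio-frequency grid and averages the product over the pulse window
#' (the low-pass step that removes the `2*f_p` component). The result equals
#' [baseband_exact()] up to a fixed gain set by the pulse energy.
#'
#' @inheritParams baseband_exact
#' @param oversample Samples per carrier period on the radio-frequency grid;
#'   must be > 2 (Nyquist for the `2*f_p` mixing product needs > 4; values
#'   below 8 are refused as too coarse).
#' @return A `baseband_signal` on `dr`'s time grid (uncalibrated gain).
#' @export
simulate_pulse_mixing <- function(dr, p, oversample = 16) {
  stopifnot(inherits(dr, "displacement_series"))
  validate_radar_params(p)
  if (oversample < 8)
    stop("oversample too small: the radio-frequency grid would alias the ",
         "2*f_p mixing product (need oversample >= 8)")
  v <- p$c / sqrt(p$epsilon)              # propagation speed in tissue
  delay <- 2 * (p$R_o - dr$dr) / v        # per-sample echo round trip
  dt_rf <- 1 / (oversample * p$f_p)
  t_end <- p$pulse_duration + max(max(delay), p$tau)
  t_rf <- seq(0, t_end, by = dt_rf)
  damping <- p$pulse_duration / 3         # envelope decays to ~5% at gate end
  pulse <- function(ts) {
    env <- ifelse(ts >= 0 & ts <= p$pulse_duration,
                  p$A * exp(-ts / damping), 0)
    env * sin(2 * pi * p$f_p * ts)
  }
  x_ref <- pulse(t_rf - p$tau)
  b <- vapply(delay, function(d) mean(pulse(t_rf - d) * x_ref), numeric(1))
  baseband_signal(dr$t, b, dr$fs)
}
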