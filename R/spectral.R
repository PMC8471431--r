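#' One-sided amplitude spectrum of a baseband record
#'
#' Removes the mean, applies a Hann taper to control leakage, takes the FFT
#' and returns the one-sided magnitude spectrum scaled by the taper's
#' coherent gain, so a bin-centered sinusoid of amplitude `a` produces a
#' spectral line of height `a`.
#'
#' @param x A `baseband_signal` of at least 30 s (>= 20 cardiac cycles at
#'   the slowest physiologic rate).
#' @param window `"hann"` (default) or `"rect"` (no taper).
#' @return A `vwm_spectrum` object: `freq_hz`, `mag`, `df_hz`,
#'   `window_name`.
#' @export
compute_spectrum <- function(x, window = c("hann", "rect")) {
  stopifnot(inherits(x, "baseband_signal"))
  window <- match.arg(window)
  if (anyNA(x$b)) stop("record contains NA samples")
  n <- length(x$b)
  if (n / x$fs < 30)
    stop("record too short for harmonic analysis: need >= 30 s, got ",
         round(n / x$fs, 1), " s")
  b <- x$b - mean(x$b)
  w <- if (window == "hann")
    0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))) else rep(1, n)
  X <- stats::fft(b * w)
  half <- seq_len(floor(n / 2) + 1)
  mag <- 2 * Mod(X[half]) / sum(w)
  mag[1] <- mag[1] / 2
  structure(list(freq_hz = (half - 1) * x$fs / n, mag = mag,
                 df_hz = x$fs / n, window_name = window),
            class = "vwm_spectrum")
}

#' Detect the cardiac fundamental frequency
#'
#' Finds the maximal spectral magnitude within the physiologic band
#' (0.66--3.0 Hz, 40--180 bpm), requires it to be prominent (at least
#' `prominence` times the median magnitude in the band), and refines the
#' location by three-point parabolic interpolation.
#'
#' @param spec A `vwm_spectrum`.
#' @param band Search band in Hz.
#' @param prominence Required ratio of the peak to the in-band median.
#' @return Fundamental frequency `f0` in Hz.
#' @export
detect_fundamental <- function(spec, band = c(0.66, 3.0), prominence = 3) {
  stopifnot(inherits(spec, "vwm_spectrum"))
  in_band <- which(spec$freq_hz >= band[1] & spec$freq_hz <= band[2])
  if (length(in_band) < 3) stop("spectrum does not resolve the cardiac band")
  i <- in_band[which.max(spec$mag[in_band])]
  if (spec$mag[i] < prominence * stats::median(spec$mag[in_band]))
    stop("no fundamental: no prominent cardiac peak in [", band[1], ", ",
         band[2], "] Hz")
  # parabolic refinement on the peak bin and its neighbours
  y1 <- spec$mag[i - 1]; y2 <- spec$mag[i]; y3 <- spec$mag[i + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > .Machine$double.eps) 0.5 * (y1 - y3) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  spec$freq_hz[i] + delta * spec$df_hz
}

#' Extract harmonic peaks and harmonic ratios
#'
#' For harmonics `k = 1..6`, takes `P_k` as the maximal magnitude within
#' `k*f0 +/- max(0.15*f0, 2*df)` (the half-width tolerates heart-rate drift
#' over a 1-minute record) and forms the five consecutive harmonic ratios
#' P2/P1, P3/P2, P4/P3, P5/P4, P6/P5 — the classification features. A
#' harmonic whose peak does not exceed twice the local median magnitude is
#' flagged as at the noise floor (not fatal).
#'
#' @param spec A `vwm_spectrum`.
#' @param f0 Fundamental frequency (Hz), e.g. from [detect_fundamental()].
#' @return A `harmonic_features` object: `f0_hz`, `peaks` (P1..P6), `hr`
#'   (named hr21, hr32, hr43, hr54, hr65), `noise_floor_flags`.
#' @export
extract_harmonics <- function(spec, f0) {
  stopifnot(inherits(spec, "vwm_spectrum"), f0 > 0)
  if (6 * f0 >= max(spec$freq_hz))
    stop("sixth harmonic above the spectrum's Nyquist limit")
  half_width <- max(0.15 * f0, 2 * spec$df_hz)
  peaks <- numeric(6)
  flags <- logical(6)
  for (k in 1:6) {
    win <- which(abs(spec$freq_hz - k * f0) <= half_width)
    peaks[k] <- max(spec$mag[win])
    local <- which(abs(spec$freq_hz - k * f0) <= max(1, 3 * half_width))
    flags[k] <- peaks[k] <= 2 * stats::median(spec$mag[local])
  }
  if (any(peaks <= 0)) stop("non-positive harmonic peak magnitude")
  hr <- peaks[2:6] / peaks[1:5]
  names(hr) <- c("hr21", "hr32", "hr43", "hr54", "hr65")
  structure(list(f0_hz = f0, peaks = peaks, hr = hr,
                 noise_floor_flags = flags),
            class = "harmonic_features")
}

#' Harmonic-ratio feature table for a cohort
#'
#' Runs the record pipeline (optional band-pass conditioning, spectrum,
#' fundamental detection, harmonic extraction) over every record and
#' assembles the interchange feature table. Records in which no prominent
#' cardiac fundamental is found are excluded and reported in the
#' `rejections` attribute.
#'
#' @param cohort A `vwm_cohort` from [simulate_cohort()], or a plain list of
#'   `baseband_signal` records.
#' @param fspec A `filter_spec`, or `NULL` to skip band-pass conditioning.
#' @return A data.frame with one row per accepted record: `patient_id`,
#'   `flow_mL_min`, `f0_hz`, `P1`..`P6`, `hr21`..`hr65`, `quality_flags`
#'   (comma-separated indices of noise-floor harmonics, empty when clean),
#'   with attribute `rejections` (data.frame of `patient_id`, `reason`).
#' @export
feature_table <- function(cohort, fspec = filter_spec()) {
  records <- if (inherits(cohort, "vwm_cohort")) cohort$records else cohort
  stopifnot(length(records) >= 1)
  rows <- list(); rej <- list()
  for (r in records) {
    res <- tryCatch({
      y <- if (!is.null(fspec)) bandpass(r, fspec) else r
      sp <- compute_spectrum(y)
      f0 <- detect_fundamental(sp)
      hf <- extract_harmonics(sp, f0)
      data.frame(patient_id = r$patient_id, flow_mL_min = r$flow_mL_min,
                 f0_hz = hf$f0_hz,
                 P1 = hf$peaks[1], P2 = hf$peaks[2], P3 = hf$peaks[3],
                 P4 = hf$peaks[4], P5 = hf$peaks[5], P6 = hf$peaks[6],
                 hr21 = hf$hr[["hr21"]], hr32 = hf$hr[["hr32"]],
                 hr43 = hf$hr[["hr43"]], hr54 = hf$hr[["hr54"]],
                 hr65 = hf$hr[["hr65"]],
                 quality_flags = paste(which(hf$noise_floor_flags),
                                       collapse = ","),
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rej[[length(rej) + 1]] <- data.frame(patient_id = r$patient_id,
                                           reason = conditionMessage(res),
                                           stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1]] <- res
  }
  if (!length(rows)) stop("no record passed fundamental detection")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rejections") <- if (length(rej)) do.call(rbind, rej) else
    data.frame(patient_id = character(), reason = character())
  out
}

#' Names of the five harmonic-ratio feature columns
#' @return Character vector `c("hr21", "hr32", "hr43", "hr54", "hr65")`.
#' @export
hr_feature_names <- function() c("hr21", "hr32", "hr43", "hr54", "hr65")
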