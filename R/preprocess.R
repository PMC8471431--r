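#' Band-pass filter specification for the acquisition chain
#'
#' The device conditions the baseband with a Hamming-window, linear-phase
#' FIR band-pass covering the cardiac fundamental and its first harmonics
#' (0.2--10 Hz at the 64 Hz A/D rate). The default order of 513 taps (an
#' 8 s impulse response) is the smallest standard order whose Hamming
#' transition band keeps at least 20 dB of attenuation at DC, only 0.2 Hz
#' below the low edge.
#'
#' @param low_cut_hz Low band edge (Hz).
#' @param high_cut_hz High band edge (Hz).
#' @param fs_hz Sampling rate the filter is designed for (Hz).
#' @param n_taps Odd number of taps (type-I linear phase).
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(low_cut_hz = 0.2, high_cut_hz = 10, fs_hz = 64,
                        n_taps = 513) {
  stopifnot(low_cut_hz > 0, high_cut_hz > low_cut_hz,
            high_cut_hz < fs_hz / 2)
  if (n_taps %% 2 != 1) stop("n_taps must be odd for type-I linear phase")
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 fs_hz = fs_hz, n_taps = as.integer(n_taps),
                 window_name = "hamming"),
            class = "filter_spec")
}

#' Design the Hamming-window FIR band-pass
#'
#' @param spec A `filter_spec`.
#' @return Numeric vector of `n_taps` symmetric coefficients.
#' @export
#' @examples
#' h <- design_fir(filter_spec())
#' sum(h)  # DC gain, deep in the stopband
design_fir <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  w <- c(spec$low_cut_hz, spec$high_cut_hz) / (spec$fs_hz / 2)
  h <- signal::fir1(spec$n_taps - 1L, w, type = "pass",
                    window = signal::hamming(spec$n_taps))
  as.numeric(h)
}

#' Evaluate an FIR magnitude response
#'
#' @param h Coefficient vector.
#' @param f_hz Frequencies (Hz) at which to evaluate.
#' @param fs_hz Sampling rate (Hz).
#' @return Magnitude (linear units) at each frequency.
#' @export
fir_response <- function(h, f_hz, fs_hz) {
  n <- seq_along(h) - 1
  vapply(f_hz, function(f) Mod(sum(h * exp(-2i * pi * f / fs_hz * n))),
         numeric(1))
}

#' Band-pass filter a baseband record
#'
#' Applies the FIR by direct convolution with reflect padding of one filter
#' length at each end, then shifts by the `(n_taps-1)/2`-sample group delay
#' so the output stays time-aligned with the input. Length is preserved.
#'
#' @param x A `baseband_signal`.
#' @param spec A `filter_spec`; its `fs_hz` must equal `x$fs` (resample
#'   first with [resample_to_device()] otherwise).
#' @param compensate_delay Shift the output back by the group delay
#'   (default `TRUE`); magnitude-based spectral features are insensitive to
#'   this choice.
#' @return A filtered `baseband_signal` of the same length.
#' @export
bandpass <- function(x, spec = filter_spec(), compensate_delay = TRUE) {
  stopifnot(inherits(x, "baseband_signal"), inherits(spec, "filter_spec"))
  if (abs(x$fs - spec$fs_hz) > 1e-9)
    stop("record sampling rate (", x$fs, " Hz) differs from filter design ",
         "rate (", spec$fs_hz, " Hz); resample first")
  n <- length(x$b)
  if (n < 3 * spec$n_taps)
    stop("record too short to filter: need at least 3*n_taps = ",
         3 * spec$n_taps, " samples, got ", n)
  h <- design_fir(spec)
  L <- spec$n_taps
  pad_head <- rev(x$b[2:(L + 1)])
  pad_tail <- rev(x$b[(n - L):(n - 1)])
  padded <- c(pad_head, x$b, pad_tail)
  y <- stats::filter(padded, h, method = "convolution", sides = 1)
  # causal output at padded index i spans samples (i-L+1):i; sample k of the
  # original record sits at padded index L+k, and the symmetric FIR delays
  # by (L-1)/2 samples
  shift <- if (compensate_delay) (L - 1) / 2 else 0
  out <- x
  out$b <- as.numeric(y[L + seq_len(n) + shift])
  out
}

#' Resample a record to the device rate
#'
#' Anti-alias filters (when decimating) and linearly interpolates onto the
#' uniform target grid. Refuses sources slow enough to alias the 10 Hz
#' analysis band edge.
#'
#' @param x A `baseband_signal`.
#' @param target_fs Target rate (Hz), default 64.
#' @return A `baseband_signal` at `target_fs`.
#' @export
resample_to_device <- function(x, target_fs = 64) {
  stopifnot(inherits(x, "baseband_signal"), target_fs > 0)
  if (x$fs < 20)
    stop("source sampling rate ", x$fs,
         " Hz would alias the 10 Hz band edge; refusing to resample")
  if (abs(x$fs - target_fs) < 1e-12) return(x)
  b <- x$b
  if (x$fs > target_fs) {
    # zero-phase anti-alias low-pass below the new Nyquist
    n_aa <- 255
    h <- signal::fir1(n_aa - 1, 0.9 * target_fs / x$fs,
                      window = signal::hamming(n_aa))
    L <- n_aa
    nn <- length(b)
    padded <- c(rev(b[2:(L + 1)]), b, rev(b[(nn - L):(nn - 1)]))
    y <- stats::filter(padded, h, method = "convolution", sides = 2)
    b <- as.numeric(y[L + seq_len(nn)])
  }
  t_new <- seq(0, x$t[length(x$t)], by = 1 / target_fs)
  b_new <- stats::approx(x$t, b, xout = t_new)$y
  baseband_signal(t_new, b_new, target_fs, x$patient_id, x$flow_mL_min)
}
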