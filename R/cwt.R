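#' Default geometric scale grid for the Morlet CWT
#'
#' Builds `n_scales` geometrically spaced scales whose equivalent Fourier
#' frequencies span `[f_min, f_max]`. Scales are dimensionless (in samples)
#' and returned in strictly increasing order, so the "lowest" scales are the
#' highest frequencies (scale and Fourier frequency are reciprocal for the
#' Morlet wavelet). The default grid of 138 scales covers 1-60 Hz at
#' 512 S/s, spanning the delta through gamma bands.
#'
#' @param fs Sampling rate (S/s).
#' @param n_scales Number of scales (default 138).
#' @param f_min,f_max Frequency span in Hz; requires
#'   `0 < f_min < f_max < fs/2`.
#' @param omega0 Morlet center-frequency parameter (radians; default 6).
#' @return Numeric vector of scales, strictly increasing.
#' @export
#' @examples
#' s <- default_scale_grid(512)
#' length(s)
#' range(scale_to_frequency(s, 512))
default_scale_grid <- function(fs, n_scales = 138L, f_min = 1, f_max = 60,
                               omega0 = 6) {
  if (!(f_min > 0 && f_min < f_max && f_max < fs / 2))
    stop_invalid("need 0 < f_min < f_max < fs/2 (got %g, %g at fs %g)",
                 f_min, f_max, fs)
  if (!is_count(n_scales) || n_scales < 1L)
    stop_invalid("n_scales must be a positive integer")
  s_min <- frequency_to_scale(f_max, fs, omega0)
  s_max <- frequency_to_scale(f_min, fs, omega0)
  if (n_scales == 1L) return(sqrt(s_min * s_max))
  exp(seq(log(s_min), log(s_max), length.out = n_scales))
}

#' Convert Morlet scales to equivalent Fourier frequencies (and back)
#'
#' Uses the standard Morlet center-frequency relation
#' `f = omega0 * fs / (2 * pi * s)` for scales measured in samples.
#'
#' @param scales,freq Scales (samples) or frequencies (Hz).
#' @param fs Sampling rate (S/s).
#' @param omega0 Morlet center-frequency parameter.
#' @return Numeric vector.
#' @export
scale_to_frequency <- function(scales, fs, omega0 = 6) {
  omega0 * fs / (2 * pi * scales)
}

#' @rdname scale_to_frequency
#' @export
frequency_to_scale <- function(freq, fs, omega0 = 6) {
  omega0 * fs / (2 * pi * freq)
}

#' Continuous Morlet wavelet transform of a single channel
#'
#' Computes the scalogram `|X(s, tau)|` by correlating the signal with
#' scaled, conjugated Morlet wavelets (`pi^(-1/4) exp(i omega0 u - u^2/2)`,
#' `1/sqrt(s)` amplitude normalization) at every sample shift. Convolution is
#' FFT-based with zero padding at the boundaries; boundary columns are
#' retained, so the magnitude matrix has one column per input sample.
#'
#' @param x Numeric vector (one EEG channel).
#' @param fs Sampling rate (S/s).
#' @param scales Positive scale grid, see [default_scale_grid()].
#' @param omega0 Morlet center-frequency parameter.
#' @param support_sigmas Truncation half-width of the wavelet in units of its
#'   Gaussian envelope's standard deviation.
#' @param subject_id,channel,class_label Optional provenance carried through
#'   to tiles.
#' @param output `"magnitude"` (default) or `"complex"`, which additionally
#'   stores the complex coefficients (the transform is linear in them).
#' @return Object of class `pw_scalogram` with fields `magnitude`
#'   (`length(scales)` x `length(x)`, nonnegative), `scales`, `freqs`, `fs`,
#'   and `coefficients` when `output = "complex"`.
#' @export
morlet_cwt <- function(x, fs, scales = default_scale_grid(fs), omega0 = 6,
                       support_sigmas = 4,
                       subject_id = NA_character_, channel = NA_character_,
                       class_label = NA_integer_,
                       output = c("magnitude", "complex")) {
  output <- match.arg(output)
  n <- length(x)
  if (n == 0L) stop_invalid("empty signal")
  if (!all(is.finite(x))) stop_invalid("signal contains non-finite values")
  if (any(scales <= 0)) stop_invalid("scales must be positive")
  scales <- sort(as.numeric(scales))
  kmax <- ceiling(support_sigmas * max(scales))
  if (n < 2L * kmax + 1L)
    stop_invalid(paste0("signal (%d samples) shorter than the support of the ",
                        "largest wavelet (%d samples); use a shorter maximum ",
                        "scale or a longer signal"), n, 2L * kmax + 1L)
  nfft <- stats::nextn(n + 2L * kmax + 1L, c(2, 3, 5))
  xhat <- stats::fft(c(x, numeric(nfft - n)))
  mag <- matrix(0, nrow = length(scales), ncol = n)
  coef <- if (output == "complex")
    matrix(complex(real = 0), nrow = length(scales), ncol = n) else NULL
  for (si in seq_along(scales)) {
    s <- scales[si]
    K <- ceiling(support_sigmas * s)
    k <- (-K):K
    u <- k / s
    # h[k] = conj(psi(k/s)) / sqrt(s); correlation X(tau) = sum_k x(tau+k) h[k]
    h <- pi^(-0.25) * exp(-1i * omega0 * u - u^2 / 2) / sqrt(s)
    gpad <- complex(real = numeric(nfft), imaginary = numeric(nfft))
    # convolution kernel g[m] = h[-m]; place m in -K..K circularly
    gpad[1L] <- h[K + 1L]                      # m = 0
    if (K > 0L) {
      gpad[2L:(K + 1L)] <- h[K:1L]             # m = 1..K  -> h[-m]
      gpad[(nfft - K + 1L):nfft] <- h[(2L * K + 1L):(K + 2L)]  # m = -K..-1
    }
    y <- stats::fft(xhat * stats::fft(gpad), inverse = TRUE) / nfft
    mag[si, ] <- Mod(y[seq_len(n)])
    if (!is.null(coef)) coef[si, ] <- y[seq_len(n)]
  }
  structure(list(magnitude = mag, coefficients = coef, scales = scales,
                 freqs = scale_to_frequency(scales, fs, omega0),
                 fs = fs, omega0 = omega0,
                 subject_id = subject_id, channel = channel,
                 class_label = class_label, normalized = FALSE),
            class = "pw_scalogram")
}

#' @export
print.pw_scalogram <- function(x, ...) {
  cat(sprintf(
    "<pw_scalogram> %s/%s: %d scales x %d samples (%.1f-%.1f Hz)%s\n",
    x$subject_id, x$channel, nrow(x$magnitude), ncol(x$magnitude),
    min(x$freqs), max(x$freqs), if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' Min-max scale a scalogram to the unit interval
#'
#' Rescales the whole per-recording-per-channel magnitude matrix to `[0, 1]`
#' so that all tiles cut from it share one intensity frame. A constant
#' matrix maps to all zeros (documented degenerate rule). Idempotent.
#'
#' @param scal A `pw_scalogram`.
#' @return The scalogram with magnitude in `[0, 1]` and `normalized = TRUE`.
#' @export
magnitude_normalize <- function(scal) {
  stopifnot(inherits(scal, "pw_scalogram"))
  if (any(is.na(scal$magnitude)))
    stop_invalid("magnitude contains NaN")
  rng <- range(scal$magnitude)
  scal$magnitude <- if (rng[2L] > rng[1L])
    (scal$magnitude - rng[1L]) / (rng[2L] - rng[1L])
  else
    matrix(0, nrow(scal$magnitude), ncol(scal$magnitude))
  scal$normalized <- TRUE
  scal
}
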