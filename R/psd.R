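#' Canonical EEG frequency bands
#'
#' @return Named list of `c(lower, upper)` band edges in Hz: delta 1-4,
#'   theta 4-8, alpha 8-12, beta 12-35, gamma 35-45.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 35), gamma = c(35, 45))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with a Hann window and 50% overlap;
#' one-sided density scaling so that the integral over frequency
#' approximates the signal variance.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (S/s).
#' @param nperseg Segment length (samples); capped at `length(x)`.
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` (Hz) and `power` (density, unit^2/Hz).
#' @export
welch_psd <- function(x, fs, nperseg = 1024L, overlap = 0.5) {
  n <- length(x)
  if (n < 8L) stop_invalid("signal too short for a PSD estimate")
  m <- min(as.integer(nperseg), n)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / m)  # periodic Hann
  step <- max(1L, as.integer(m * (1 - overlap)))
  starts <- seq(1L, n - m + 1L, by = step)
  nf <- m %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + m - 1L)] * w
    sp <- Mod(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / length(starts) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when m is even)
  dbl <- rep(2, nf); dbl[1L] <- 1
  if (m %% 2L == 0L) dbl[nf] <- 1
  list(freq = (seq_len(nf) - 1L) * fs / m, power = psd * dbl)
}

#' Band-integrated power of a recording
#'
#' Welch PSD per channel, averaged over channels, then integrated over each
#' frequency band. Used as the spectral oracle for the synthetic generator.
#'
#' @param rec A `pw_recording`.
#' @param bands Named list of band edges, see [eeg_bands()].
#' @param nperseg Welch segment length.
#' @return Named numeric vector of band powers.
#' @export
band_power_summary <- function(rec, bands = eeg_bands(), nperseg = 1024L) {
  stopifnot(inherits(rec, "pw_recording"))
  if (ncol(rec$samples) == 0L || nrow(rec$samples) == 0L)
    stop_invalid("empty recording")
  psd <- NULL
  for (ch in seq_len(nrow(rec$samples))) {
    p <- welch_psd(rec$samples[ch, ], rec$fs, nperseg = nperseg)
    psd <- if (is.null(psd)) p$power else psd + p$power
  }
  psd <- psd / nrow(rec$samples)
  freq <- welch_psd(rec$samples[1L, ], rec$fs, nperseg = nperseg)$freq
  df <- freq[2L] - freq[1L]
  vapply(bands, function(b) sum(psd[freq >= b[1L] & freq < b[2L]]) * df,
         numeric(1))
}
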