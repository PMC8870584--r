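#' Class-conditional spectral profile for the synthetic EEG generator
#'
#' Describes one class of subject as a set of relative band amplitudes laid
#' over a 1/f^alpha background plus white noise. Band oscillators are
#' sinusoids at randomized frequencies and phases within each band.
#'
#' @param class_label Integer class code (see [pd_classes()]).
#' @param band_powers Named numeric vector of relative band amplitudes; names
#'   must be a subset of `names(eeg_bands())`. All values must be >= 0.
#' @param background_exponent Exponent alpha of the 1/f^alpha background.
#' @param background_amp Amplitude of the background component.
#' @param noise_sd Standard deviation of additive white noise.
#' @param n_oscillators Sinusoids per band (amplitudes scaled so band power
#'   is independent of the count).
#' @return An object of class `pw_class_spectrum`.
#' @export
class_spectrum <- function(class_label, band_powers,
                           background_exponent = 1,
                           background_amp = 1,
                           noise_sd = 0.5,
                           n_oscillators = 3L) {
  class_label <- as.integer(class_label)
  if (!class_label %in% pd_classes())
    stop_invalid("class_label must be 0, 1 or 2")
  if (is.null(names(band_powers)) ||
      !all(names(band_powers) %in% names(eeg_bands())))
    stop_invalid("band_powers must be named after eeg_bands()")
  if (any(band_powers < 0)) stop_invalid("band amplitudes must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(class_label = class_label,
                 band_powers = band_powers,
                 background_exponent = background_exponent,
                 background_amp = background_amp,
                 noise_sd = noise_sd,
                 n_oscillators = as.integer(n_oscillators)),
            class = "pw_class_spectrum")
}

#' Default class spectra: HC, PD-OFF and PD-ON
#'
#' The class contrasts follow the spectral signature reported for PD in
#' resting EEG: elevated theta power and reduced beta and gamma power off
#' medication, with the on-medication state placed at the geometric midpoint
#' between HC and PD-OFF. `"strong"` doubles the log-contrast and is used for
#' reduced-scale separability experiments.
#'
#' @param contrast `"moderate"` (default) or `"strong"`.
#' @return Named list of three `pw_class_spectrum` objects
#'   (`hc`, `pd_off`, `pd_on`).
#' @export
default_class_spectra <- function(contrast = c("moderate", "strong")) {
  contrast <- match.arg(contrast)
  hc <- c(delta = 1, theta = 1, alpha = 1.2, beta = 0.8, gamma = 0.4)
  ratio <- switch(contrast,
    moderate = c(theta = 2,  beta = 0.5,  gamma = 0.5),
    strong   = c(theta = 4,  beta = 0.25, gamma = 0.25))
  off <- hc
  off[names(ratio)] <- off[names(ratio)] * ratio
  on <- sqrt(hc * off)  # geometric midpoint
  list(hc     = class_spectrum(0L, hc),
       pd_off = class_spectrum(1L, off),
       pd_on  = class_spectrum(2L, on))
}

#' Cohort layout for the synthetic generator
#'
#' Defaults mirror the study conditions this pipeline emulates: 16 healthy
#' controls and 15 PD patients (each contributing an OFF- and an
#' ON-medication recording), 32 channels at 512 S/s, about two minutes each.
#'
#' @param n_hc Number of healthy-control subjects.
#' @param n_pd Number of PD subjects (each yields two recordings).
#' @param duration_s Recording duration in seconds.
#' @param fs Sampling rate (S/s).
#' @param n_channels Number of channels.
#' @param seed Master seed; per-recording seeds are derived from it.
#' @return An object of class `pw_cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 16L, n_pd = 15L, duration_s = 120,
                        fs = 512, n_channels = 32L, seed = 1L) {
  if (!is_count(n_hc) || !is_count(n_pd) || n_hc < 0 || n_pd < 0)
    stop_invalid("n_hc and n_pd must be non-negative integers")
  if (n_hc < 1L && n_pd < 1L)
    stop_invalid("cohort must contain at least one subject")
  structure(list(n_hc = as.integer(n_hc), n_pd = as.integer(n_pd),
                 duration_s = duration_s, fs = fs,
                 n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "pw_cohort_spec")
}

# 1/f^alpha noise via spectral shaping of white noise, unit variance
one_over_f_noise <- function(n, fs, exponent) {
  wn <- stats::rnorm(n)
  if (exponent == 0) return(wn / stats::sd(wn))
  W <- stats::fft(wn)
  k <- seq_len(n) - 1L
  fmag <- pmin(k, n - k) * fs / n
  scale <- c(0, fmag[-1L]^(-exponent / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE) / n)
  x / stats::sd(x)
}

#' Generate one synthetic EEG recording
#'
#' Each channel is the sum of a 1/f^alpha background, band-limited sinusoidal
#' oscillators with randomized frequencies and phases, and white noise.
#' Deterministic for a fixed seed.
#'
#' @param spectrum A `pw_class_spectrum`.
#' @param duration_s Duration in seconds (> 0).
#' @param fs Sampling rate (must exceed twice the highest band edge).
#' @param n_channels Number of channels.
#' @param subject_id Subject identifier.
#' @param seed Integer seed (required).
#' @return A `pw_recording`.
#' @export
#' @examples
#' sp <- default_class_spectra()$hc
#' rec <- generate_recording(sp, duration_s = 2, fs = 256, n_channels = 2,
#'                           subject_id = "demo", seed = 7)
#' rec
generate_recording <- function(spectrum, duration_s, fs, n_channels = 32L,
                               subject_id = "sub-01", seed) {
  stopifnot(inherits(spectrum, "pw_class_spectrum"))
  if (missing(seed)) stop_invalid("seed is required for reproducibility")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_invalid("duration_s must be positive")
  if (!is.numeric(fs) || fs <= 0) stop_invalid("fs must be positive")
  bands <- eeg_bands()[names(spectrum$band_powers)]
  hi <- max(vapply(bands, `[`, numeric(1), 2L))
  if (fs <= 2 * hi)
    stop_invalid("fs (%g) must exceed twice the highest band edge (%g Hz)",
                 fs, hi)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    samples <- matrix(0, nrow = n_channels, ncol = n)
    for (ch in seq_len(n_channels)) {
      x <- numeric(n)
      if (spectrum$background_amp > 0)
        x <- x + spectrum$background_amp *
          one_over_f_noise(n, fs, spectrum$background_exponent)
      else
        stats::rnorm(n)  # keep the RNG stream aligned across amplitude settings
      for (b in names(bands)) {
        amp <- spectrum$band_powers[[b]]
        edges <- bands[[b]]
        fr <- stats::runif(spectrum$n_oscillators, edges[1L], edges[2L])
        ph <- stats::runif(spectrum$n_oscillators, 0, 2 * pi)
        if (amp > 0) {
          a <- amp / sqrt(spectrum$n_oscillators)
          for (o in seq_len(spectrum$n_oscillators))
            x <- x + a * sin(2 * pi * fr[o] * t + ph[o])
        }
      }
      if (spectrum$noise_sd > 0)
        x <- x + stats::rnorm(n, 0, spectrum$noise_sd)
      samples[ch, ] <- x
    }
    recording(samples, fs, subject_id = subject_id,
              class_label = spectrum$class_label)
  })
}

#' Generate a synthetic cohort
#'
#' Produces `n_hc` HC recordings plus `n_pd` pairs of recordings (OFF and ON
#' medication) sharing a subject id, so the default study layout yields
#' 16 + 15 x 2 = 46 recordings.
#'
#' @param cohort A `pw_cohort_spec`.
#' @param spectra Named list with elements `hc`, `pd_off`, `pd_on`
#'   (see [default_class_spectra()]); only the classes actually requested
#'   need to be present.
#' @return List of `pw_recording` objects (class `pw_cohort`).
#' @export
generate_cohort <- function(cohort = cohort_spec(),
                            spectra = default_class_spectra()) {
  stopifnot(inherits(cohort, "pw_cohort_spec"))
  if (cohort$n_hc > 0L && is.null(spectra$hc))
    stop_invalid("spectra$hc required for HC subjects")
  if (cohort$n_pd > 0L && (is.null(spectra$pd_off) || is.null(spectra$pd_on)))
    stop_invalid("spectra$pd_off and spectra$pd_on required for PD subjects")
  recs <- list()
  i <- 0L
  for (s in seq_len(cohort$n_hc)) {
    i <- i + 1L
    recs[[length(recs) + 1L]] <- generate_recording(
      spectra$hc, cohort$duration_s, cohort$fs, cohort$n_channels,
      subject_id = sprintf("hc%02d", s), seed = cohort$seed + i)
  }
  for (s in seq_len(cohort$n_pd)) {
    sid <- sprintf("pd%02d", s)
    for (sp in list(spectra$pd_off, spectra$pd_on)) {
      i <- i + 1L
      recs[[length(recs) + 1L]] <- generate_recording(
        sp, cohort$duration_s, cohort$fs, cohort$n_channels,
        subject_id = sid, seed = cohort$seed + i)
    }
  }
  structure(recs, class = c("pw_cohort", "list"), cohort_spec = cohort)
}

#' @export
print.pw_cohort <- function(x, ...) {
  cls <- vapply(x, function(r) r$class_label, integer(1))
  cat(sprintf("<pw_cohort> %d recordings (%d HC, %d PD-OFF, %d PD-ON)\n",
              length(x), sum(cls == 0L), sum(cls == 1L), sum(cls == 2L)))
  invisible(x)
}
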