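#' Class encoding for the screening problem
#'
#' Recordings are labelled with an integer code: 0 for healthy controls (HC),
#' 1 for Parkinson's disease patients off medication (PD-OFF) and 2 for the
#' same patients on dopaminergic medication (PD-ON).
#'
#' @return Named integer vector `c(HC = 0L, PD_OFF = 1L, PD_ON = 2L)`.
#' @export
#' @examples
#' pd_classes()
pd_classes <- function() c(HC = 0L, PD_OFF = 1L, PD_ON = 2L)

#' Standard 32-electrode montage
#'
#' Channel names of the 32-electrode cap used by the resting-state recordings
#' this pipeline targets (BioSemi 32 layout), including the four default
#' analysis channels Fp1, FC1, CP5 and Fp2.
#'
#' @return Character vector of 32 electrode names.
#' @export
montage_32 <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
}

#' Construct a multichannel EEG recording
#'
#' The canonical container for one subject's EEG: a channels-by-samples
#' numeric matrix plus metadata. Values must be finite; recordings with
#' NaN/Inf are rejected rather than repaired.
#'
#' @param samples Numeric matrix, channels in rows, time samples in columns.
#' @param fs Sampling rate in samples per second.
#' @param channel_names Character vector, one name per row of `samples`.
#'   Defaults to the first `nrow(samples)` names of [montage_32()].
#' @param subject_id Subject identifier string.
#' @param class_label Integer class code, see [pd_classes()].
#' @return An object of class `pw_recording`.
#' @export
recording <- function(samples, fs, channel_names = NULL,
                      subject_id = "sub-01", class_label = 0L) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop_invalid("samples must be a numeric matrix (channels x time)")
  if (!all(is.finite(samples)))
    stop_invalid("samples contain non-finite values (NaN/Inf); clean the input first")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_invalid("fs must be a single positive number")
  if (is.null(channel_names)) {
    nm <- montage_32()
    channel_names <- if (nrow(samples) <= 32L) nm[seq_len(nrow(samples))]
      else sprintf("Ch%02d", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples))
    stop_invalid("channel_names length (%d) != number of channels (%d)",
                 length(channel_names), nrow(samples))
  class_label <- as.integer(class_label)
  if (!class_label %in% pd_classes())
    stop_invalid("class_label must be one of 0 (HC), 1 (PD_OFF), 2 (PD_ON)")
  structure(list(subject_id = as.character(subject_id),
                 class_label = class_label,
                 fs = as.numeric(fs),
                 channel_names = as.character(channel_names),
                 samples = samples),
            class = "pw_recording")
}

#' @export
print.pw_recording <- function(x, ...) {
  cls <- names(pd_classes())[match(x$class_label, pd_classes())]
  cat(sprintf("<pw_recording> %s [%s]: %d channels x %d samples @ %g S/s (%.1f s)\n",
              x$subject_id, cls, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Select a subset of channels from a recording
#'
#' Returns a sub-recording containing the requested channels in the order
#' given; all metadata is preserved. The default analysis channels of the
#' pipeline are Fp1, FC1, CP5 and Fp2.
#'
#' @param rec A `pw_recording`.
#' @param names Character vector of channel names to keep.
#' @return A `pw_recording` with `length(names)` channels.
#' @export
select_channels <- function(rec, names) {
  stopifnot(inherits(rec, "pw_recording"))
  idx <- match(names, rec$channel_names)
  if (anyNA(idx))
    stop_invalid("unknown channel(s): %s; available: %s",
                 paste(names[is.na(idx)], collapse = ", "),
                 paste(rec$channel_names, collapse = ", "))
  recording(rec$samples[idx, , drop = FALSE], rec$fs,
            channel_names = rec$channel_names[idx],
            subject_id = rec$subject_id, class_label = rec$class_label)
}
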