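#' Read a BrainVision EEG recording
#'
#' Minimal reader for the BrainVision triplet (`.vhdr` header, binary signal
#' file, optional `.vmrk` markers) sufficient for BIDS EEG exports:
#' multiplexed or vectorized binary data in IEEE float-32 or int-16, with
#' per-channel resolution scaling. Class labels are not stored in the format;
#' supply `class_label` directly or a `participants` table mapping subject
#' ids to class codes.
#'
#' @param header_path Path to the `.vhdr` header file.
#' @param class_label Integer class code (see [pd_classes()]); ignored when a
#'   `participants` table is given.
#' @param subject_id Subject identifier; defaults to the header file stem.
#' @param participants Optional data frame with columns `subject_id` and
#'   `class_label`.
#' @return A `pw_recording`.
#' @export
read_brainvision <- function(header_path, class_label = 0L,
                             subject_id = NULL, participants = NULL) {
  if (!file.exists(header_path))
    stop_invalid("header file not found: %s", header_path)
  lines <- readLines(header_path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  kv <- grep("=", lines, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  get1 <- function(key, default = NULL) {
    i <- match(tolower(key), tolower(keys))
    if (is.na(i)) default else trimws(vals[i])
  }
  data_file <- get1("DataFile")
  if (is.null(data_file)) stop_invalid("header lacks DataFile entry")
  data_path <- file.path(dirname(header_path), data_file)
  if (!file.exists(data_path))
    stop_invalid("companion data file not found: %s", data_path)
  n_chan <- as.integer(get1("NumberOfChannels"))
  samp_int <- as.numeric(get1("SamplingInterval"))  # microseconds
  fs <- 1e6 / samp_int
  fmt <- toupper(get1("BinaryFormat", "IEEE_FLOAT_32"))
  orient <- toupper(get1("DataOrientation", "MULTIPLEXED"))
  ch_idx <- grep("^Ch[0-9]+$", keys)
  if (length(ch_idx) != n_chan)
    stop_invalid("header declares %d channels but lists %d Ch entries",
                 n_chan, length(ch_idx))
  ord <- order(as.integer(sub("^Ch", "", keys[ch_idx])))
  ch_parts <- strsplit(vals[ch_idx][ord], ",", fixed = TRUE)
  ch_names <- vapply(ch_parts, function(p) trimws(p[1L]), character(1))
  ch_res <- vapply(ch_parts, function(p) {
    r <- if (length(p) >= 3L) suppressWarnings(as.numeric(p[3L])) else NA_real_
    if (is.na(r)) 1 else r
  }, numeric(1))
  sz <- file.size(data_path)
  bytes <- switch(fmt, IEEE_FLOAT_32 = 4L, INT_16 = 2L,
                  stop_invalid("unsupported BinaryFormat: %s", fmt))
  if (sz %% (bytes * n_chan) != 0L)
    stop_invalid("data file size (%d bytes) inconsistent with %d channels of %s",
                 sz, n_chan, fmt)
  n_samp <- as.integer(sz / (bytes * n_chan))
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, what = "numeric", n = n_chan * n_samp, size = 4L,
            endian = "little")
  } else {
    readBin(con, what = "integer", n = n_chan * n_samp, size = 2L,
            signed = TRUE, endian = "little")
  }
  m <- if (orient == "MULTIPLEXED") matrix(raw, nrow = n_chan)
       else matrix(raw, nrow = n_samp)[, , drop = FALSE] |> t()
  m <- m * ch_res
  if (is.null(subject_id))
    subject_id <- sub("\\.vhdr$", "", basename(header_path))
  if (!is.null(participants)) {
    i <- match(subject_id, participants$subject_id)
    if (is.na(i))
      stop_invalid("subject '%s' not found in participants table", subject_id)
    class_label <- participants$class_label[i]
  }
  recording(m, fs, channel_names = ch_names, subject_id = subject_id,
            class_label = class_label)
}
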