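#' Write a recording as delimited text plus a JSON sidecar
#'
#' The signal matrix (channels x samples) is written as a headerless
#' tab-separated file `<base>.tsv`; metadata (subject id, class label,
#' sampling rate, channel names) goes to `<base>.json`. The pair round-trips
#' through [read_recording()] at full double precision.
#'
#' @param rec A `pw_recording`.
#' @param base Path prefix (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_recording <- function(rec, base) {
  stopifnot(inherits(rec, "pw_recording"))
  tsv <- paste0(base, ".tsv")
  js <- paste0(base, ".json")
  dir.create(dirname(tsv), recursive = TRUE, showWarnings = FALSE)
  # %.17g guarantees doubles survive the text round trip bit-exactly
  chr <- matrix(sprintf("%.17g", rec$samples), nrow(rec$samples))
  data.table::fwrite(data.table::as.data.table(chr), tsv,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(subject_id = rec$subject_id,
                            class_label = rec$class_label,
                            fs = rec$fs,
                            channels = rec$channel_names),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a recording written by [write_recording()]
#'
#' @param base Path prefix, or the `.tsv` path itself.
#' @return A `pw_recording`.
#' @export
read_recording <- function(base) {
  if (grepl("\\.tsv$", base)) base <- sub("\\.tsv$", "", base)
  js <- paste0(base, ".json")
  if (!file.exists(js)) stop_invalid("sidecar not found: %s", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  read_matrix(paste0(base, ".tsv"), fs = meta$fs,
              channel_names = meta$channels,
              subject_id = meta$subject_id,
              class_label = meta$class_label)
}

#' Read a plain delimited numeric matrix as a recording
#'
#' Accepts any rectangular delimited numeric table (TSV/CSV/whitespace).
#' Rows are channels by default; set `transpose = TRUE` for samples-by-
#' channels input. Ragged rows and non-numeric cells are format errors; the
#' offending cell is named with its row and column.
#'
#' @param path File path.
#' @param fs Sampling rate (S/s).
#' @param channel_names Optional channel names (default montage prefix).
#' @param subject_id Subject identifier.
#' @param class_label Integer class code.
#' @param transpose If `TRUE`, the file stores samples x channels.
#' @return A `pw_recording`.
#' @export
read_matrix <- function(path, fs, channel_names = NULL,
                        subject_id = "sub-01", class_label = 0L,
                        transpose = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  nf <- utils::count.fields(path, sep = sep, quote = "")
  if (length(unique(nf)) > 1L)
    stop_invalid("ragged table in %s: rows have %s fields", path,
                 paste(unique(nf), collapse = "/"))
  dt <- data.table::fread(path, header = FALSE, sep = if (sep == "") " " else sep,
                          colClasses = "character", quote = "")
  m <- matrix(NA_real_, nrow = nrow(dt), ncol = ncol(dt))
  for (j in seq_len(ncol(dt))) {
    v <- dt[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & nzchar(v))
    if (length(bad))
      stop_invalid("non-numeric value '%s' at row %d, column %d of %s",
                   v[bad[1L]], bad[1L], j, path)
    m[, j] <- num
  }
  if (transpose) m <- t(m)
  recording(m, fs, channel_names = channel_names,
            subject_id = subject_id, class_label = class_label)
}
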