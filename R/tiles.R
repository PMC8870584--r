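#' Construct a tile set
#'
#' Container for labelled grayscale wavelet images: a `tile_size` x
#' `tile_size` x n array of pixel values in `[0, 1]` plus a provenance table
#' (`subject_id`, `channel`, `class_label`, `tile_index`), which subject-wise
#' cross-validation relies on.
#'
#' @param tiles 3-d array (height x width x n) with values in `[0, 1]`.
#' @param info Data frame with one row per tile and columns `subject_id`,
#'   `channel`, `class_label`, `tile_index`.
#' @return An object of class `pw_tileset`.
#' @export
tileset <- function(tiles, info) {
  if (length(dim(tiles)) != 3L) stop_invalid("tiles must be a 3-d array")
  n <- dim(tiles)[3L]
  need <- c("subject_id", "channel", "class_label", "tile_index")
  if (!all(need %in% names(info)))
    stop_invalid("info must have columns %s", paste(need, collapse = ", "))
  if (nrow(info) != n)
    stop_invalid("info has %d rows for %d tiles", nrow(info), n)
  if (n > 0L) {
    rng <- range(tiles)
    if (rng[1L] < 0 || rng[2L] > 1)
      stop_invalid("tile pixel values must lie in [0, 1]")
    if (anyNA(info[need]))
      stop_invalid("tile provenance is incomplete")
  }
  structure(list(tiles = tiles,
                 info = as.data.frame(info)[need]),
            class = "pw_tileset")
}

#' @export
print.pw_tileset <- function(x, ...) {
  d <- dim(x$tiles)
  cat(sprintf("<pw_tileset> %d tiles of %dx%d", d[3L], d[1L], d[2L]))
  if (d[3L] > 0L) {
    tab <- table(x$info$class_label)
    cat(" | classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "))
    cat(sprintf(" | %d subjects", length(unique(x$info$subject_id))))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.pw_tileset <- function(x) dim(x$tiles)[3L]

#' @export
`[.pw_tileset` <- function(x, i) {
  idx <- seq_len(length(x))[i]
  tileset(x$tiles[, , idx, drop = FALSE], x$info[idx, , drop = FALSE])
}

#' @export
c.pw_tileset <- function(...) {
  xs <- list(...)
  stopifnot(all(vapply(xs, inherits, logical(1), "pw_tileset")))
  d <- dim(xs[[1L]]$tiles)[1:2]
  arrs <- lapply(xs, `[[`, "tiles")
  total <- sum(vapply(arrs, function(a) dim(a)[3L], integer(1)))
  tiles <- array(0, c(d[1L], d[2L], total))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[3L]
    if (k > 0L) tiles[, , at + seq_len(k)] <- a
    at <- at + k
  }
  info <- do.call(rbind, lapply(xs, `[[`, "info"))
  tileset(tiles, info)
}

#' Cut a normalized scalogram into square grayscale tiles
#'
#' Keeps the `n_keep_scales` lowest scales (the highest frequencies, since
#' scale is reciprocal to frequency) and splits the time axis into
#' consecutive non-overlapping windows of `tile_size` columns, discarding the
#' final partial window. A scalogram shorter than one tile yields an empty
#' tile set with a warning, not an error.
#'
#' @param scal A normalized `pw_scalogram` (see [magnitude_normalize()]).
#' @param tile_size Tile edge length in pixels (default 128).
#' @param n_keep_scales Number of scales to keep (default 128; must not
#'   exceed the number of scales in the scalogram).
#' @param keep `"lowest"` (default) keeps the smallest scales; `"highest"`
#'   is available for sensitivity analysis.
#' @return A `pw_tileset` with `floor(n_times / tile_size)` tiles.
#' @export
tile_scalogram <- function(scal, tile_size = 128L, n_keep_scales = 128L,
                           keep = c("lowest", "highest")) {
  stopifnot(inherits(scal, "pw_scalogram"))
  keep <- match.arg(keep)
  ns <- nrow(scal$magnitude)
  if (n_keep_scales > ns)
    stop_invalid("n_keep_scales (%d) exceeds available scales (%d)",
                 n_keep_scales, ns)
  rng <- range(scal$magnitude)
  if (!isTRUE(scal$normalized) && (rng[1L] < 0 || rng[2L] > 1))
    stop_invalid("scalogram must be normalized to [0, 1] first; see magnitude_normalize()")
  rows <- if (keep == "lowest") seq_len(n_keep_scales)
          else seq.int(ns - n_keep_scales + 1L, ns)
  nt <- ncol(scal$magnitude) %/% tile_size
  if (nt == 0L) {
    warning(sprintf("scalogram of width %d is shorter than one %d-column tile; returning empty tile set",
                    ncol(scal$magnitude), tile_size))
    return(tileset(array(0, c(tile_size, tile_size, 0L)),
                   data.frame(subject_id = character(), channel = character(),
                              class_label = integer(), tile_index = integer())))
  }
  tiles <- array(0, c(n_keep_scales, tile_size, nt))
  for (t in seq_len(nt))
    tiles[, , t] <- scal$magnitude[rows, ((t - 1L) * tile_size + 1L):(t * tile_size)]
  tileset(tiles,
          data.frame(subject_id = scal$subject_id, channel = scal$channel,
                     class_label = scal$class_label, tile_index = seq_len(nt)))
}

#' Full recording-to-tiles pipeline
#'
#' For each requested channel: Morlet CWT over the scale grid, per-channel
#' min-max scaling, and segmentation into square tiles with provenance.
#'
#' @param rec A `pw_recording`.
#' @param channels Channel names to process (default: all channels).
#' @param n_scales,f_min,f_max,omega0 Scale-grid parameters, see
#'   [default_scale_grid()].
#' @param tile_size,n_keep_scales Tiling parameters, see [tile_scalogram()].
#' @return A `pw_tileset` pooled over the requested channels.
#' @export
scalogram_tiles <- function(rec, channels = NULL, n_scales = 138L,
                            f_min = 1, f_max = 60, omega0 = 6,
                            tile_size = 128L, n_keep_scales = 128L) {
  stopifnot(inherits(rec, "pw_recording"))
  if (is.null(channels)) channels <- rec$channel_names
  rec <- select_channels(rec, channels)
  scales <- default_scale_grid(rec$fs, n_scales, f_min, f_max, omega0)
  out <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    scal <- morlet_cwt(rec$samples[i, ], rec$fs, scales, omega0,
                       subject_id = rec$subject_id, channel = channels[i],
                       class_label = rec$class_label)
    out[[i]] <- tile_scalogram(magnitude_normalize(scal),
                               tile_size = tile_size,
                               n_keep_scales = n_keep_scales)
  }
  do.call(c, out)
}

#' Export tiles as 8-bit grayscale PNG files
#'
#' Writes one PNG per tile plus a `manifest.csv` mapping each file to its
#' provenance. Pixel values are quantized to 8 bits, so an export/import
#' round trip reproduces pixels to within 1/255.
#'
#' @param ts A `pw_tileset`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame (`path`, `subject_id`,
#'   `channel`, `class_label`, `tile_index`).
#' @export
export_tiles_png <- function(ts, out_dir) {
  stopifnot(inherits(ts, "pw_tileset"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, mode = 2L) != 0L)
    stop_invalid("output directory is not writable: %s", out_dir)
  n <- length(ts)
  paths <- character(n)
  for (i in seq_len(n)) {
    inf <- ts$info[i, ]
    fn <- sprintf("%s_%s_c%d_t%05d.png", inf$subject_id, inf$channel,
                  inf$class_label, inf$tile_index)
    png::writePNG(ts$tiles[, , i], file.path(out_dir, fn))
    paths[i] <- fn
  }
  manifest <- cbind(data.frame(path = paths), ts$info)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}

#' Re-import tiles exported by [export_tiles_png()]
#'
#' @param dir Directory containing `manifest.csv` and the PNG files.
#' @return A `pw_tileset`.
#' @export
read_tiles_png <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_invalid("manifest not found: %s", mf)
  manifest <- as.data.frame(data.table::fread(mf))
  if (nrow(manifest) == 0L)
    return(tileset(array(0, c(128L, 128L, 0L)),
                   manifest[c("subject_id", "channel", "class_label", "tile_index")]))
  first <- png::readPNG(file.path(dir, manifest$path[1L]))
  tiles <- array(0, c(nrow(first), ncol(first), nrow(manifest)))
  tiles[, , 1L] <- first
  for (i in seq_len(nrow(manifest))[-1L])
    tiles[, , i] <- png::readPNG(file.path(dir, manifest$path[i]))
  tileset(tiles, manifest[c("subject_id", "channel", "class_label", "tile_index")])
}
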