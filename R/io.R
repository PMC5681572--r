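# Readers and writers for the package's plain-text artifact formats.
# Events travel as TSV (times in ms, microsecond precision); continuous
# recordings as channel-major 32-bit float binary plus a JSON sidecar.

.EVENT_COLS <- c("animal_id", "epoch", "regime", "hemisphere", "layer",
                 "time_ms")

#' Write spike events to TSV
#'
#' Header columns `animal_id, epoch, regime, hemisphere, layer, time_ms`;
#' times written with microsecond precision.
#'
#' @param events a `spike_events` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)[, .EVENT_COLS]
  df$time_ms <- sprintf("%.6f", df$time_ms)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spike events from TSV
#'
#' Validates the header and every record (numeric time, layer in 1..6,
#' hemisphere contra/ipsi); parse errors name the offending line.  Events
#' are returned in canonical (animal, epoch, time) order.
#'
#' @param path TSV file written by [write_events()] or compatible.
#' @return a `spike_events` data frame.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(.EVENT_COLS, names(df))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!nrow(df)) {
    warning("no events in ", path)
    return(.empty_events())
  }
  line_of <- function(i) i + 1L  # header is line 1
  tm <- suppressWarnings(as.numeric(df$time_ms))
  if (anyNA(tm))
    stop("non-numeric time_ms at line ", line_of(which(is.na(tm))[1L]),
         " of ", path, call. = FALSE)
  ly <- suppressWarnings(as.integer(df$layer))
  bad <- is.na(ly) | ly < 1L | ly > 6L
  if (any(bad))
    stop("layer outside 1-6 at line ", line_of(which(bad)[1L]), " of ", path,
         call. = FALSE)
  bad_h <- !df$hemisphere %in% .HEMIS
  if (any(bad_h))
    stop("unknown hemisphere at line ", line_of(which(bad_h)[1L]), " of ",
         path, call. = FALSE)
  ep <- suppressWarnings(as.integer(df$epoch))
  if (anyNA(ep))
    stop("non-integer epoch at line ", line_of(which(is.na(ep))[1L]), " of ",
         path, call. = FALSE)
  .as_spike_events(data.frame(
    animal_id = suppressWarnings(as.integer(df$animal_id)),
    epoch = ep, regime = df$regime, hemisphere = df$hemisphere,
    layer = ly, time_ms = tm))
}

#' Write a laminar recording as float32 binary plus JSON sidecar
#'
#' The binary file holds the samples channel-major (all samples of channel
#' 1, then channel 2, ...) as little-endian 32-bit floats.  The sidecar
#' records `sampling_rate_hz`, `channel_order`, `depths_mm`,
#' `stimulus_onsets_ms` and `n_samples`.
#'
#' @param recording a [laminar_recording()].
#' @param bin_path,sidecar_path output paths.
#' @return `bin_path`, invisibly.
#' @export
write_recording <- function(recording, bin_path, sidecar_path) {
  stopifnot(inherits(recording, "laminar_recording"))
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording$samples), con, size = 4L,
           endian = "little")
  side <- list(sampling_rate_hz = recording$sampling_rate,
               channel_order = .chan12_labels(),
               depths_mm = recording$channels$depth_mm[1:6],
               stimulus_onsets_ms = recording$stimulus_onsets_ms,
               n_samples = nrow(recording$samples))
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(bin_path)
}

#' Read a laminar recording from float32 binary plus JSON sidecar
#'
#' @param bin_path,sidecar_path files written by [write_recording()].
#' @return a [laminar_recording()].
#' @export
read_recording <- function(bin_path, sidecar_path) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("sampling_rate_hz", "channel_order", "depths_mm"))
    if (is.null(side[[f]]))
      stop("sidecar ", sidecar_path, " is missing field `", f, "`",
           call. = FALSE)
  nchan <- length(side$channel_order)
  nbytes <- file.info(bin_path)$size
  if (is.na(nbytes) || nbytes %% (4L * nchan) != 0)
    stop("format error: ", bin_path, " byte length (", nbytes,
         ") is not a multiple of 4 x ", nchan, " channels", call. = FALSE)
  n <- nbytes / (4L * nchan)
  if (!is.null(side$n_samples) && side$n_samples != n)
    stop("format error: ", bin_path, " holds ", n,
         " samples/channel but sidecar declares ", side$n_samples,
         call. = FALSE)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n * nchan, size = 4L, endian = "little")
  laminar_recording(matrix(x, nrow = n, ncol = nchan),
                    sampling_rate = side$sampling_rate_hz,
                    stimulus_onsets_ms =
                      as.numeric(side$stimulus_onsets_ms %||% numeric()),
                    depths_mm = side$depths_mm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dump delay matrices in long format
#'
#' One row per (reference, spike layer, target layer) cell with its mean
#' delay and pair count; suitable for TSV export of per-animal matrices.
#'
#' @param collapsed a `delay_matrices_collapsed` (see
#'   [collapse_references()]).
#' @param animal_id,regime identifiers copied into the output.
#' @return data frame with columns `animal_id`, `regime`, `reference`,
#'   `spike_layer`, `target_layer`, `mean_delay_ms`, `count`.
#' @export
delay_matrix_long <- function(collapsed, animal_id = NA, regime = NA) {
  rows <- list()
  for (ref in c("same", "other")) {
    m <- collapsed[[ref]]$mean
    n <- collapsed[[ref]]$count
    rows[[ref]] <- data.frame(
      animal_id = animal_id, regime = regime,
      reference = if (ref == "same") "same_S1" else "other_S1",
      spike_layer = rep(1:6, 6), target_layer = rep(1:6, each = 6),
      mean_delay_ms = as.vector(m), count = as.vector(n))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
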