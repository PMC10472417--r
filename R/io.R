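#' File interfaces: electrode positions, EDF recordings, event tables
#'
#' Plain-text electrode positions (.sfp), European Data Format (EDF, 16-bit)
#' for recordings, and BIDS-style tab-separated event tables.
#'
#' @name hdesi-io
NULL

#' Read / write electrode positions as .sfp text
#'
#' Whitespace-separated `label x y z` rows in mm; fiducials are stored as
#' rows `FidNz` (nasion), `FidT9` (LPA) and `FidT10` (RPA).
#'
#' @param array An `electrode_array`.
#' @param path File path.
#' @export
write_sfp <- function(array, path) {
  stopifnot(inherits(array, "electrode_array"))
  fid <- array$fiducials
  lines <- c(
    sprintf("FidNz\t%.6f\t%.6f\t%.6f", fid[1, 1], fid[1, 2], fid[1, 3]),
    sprintf("FidT9\t%.6f\t%.6f\t%.6f", fid[2, 1], fid[2, 2], fid[2, 3]),
    sprintf("FidT10\t%.6f\t%.6f\t%.6f", fid[3, 1], fid[3, 2], fid[3, 3]),
    sprintf("%s\t%.6f\t%.6f\t%.6f", array$channel_ids,
            array$positions[, 1], array$positions[, 2], array$positions[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sfp
#' @param scalp_radius_mm Scalp radius recorded on the returned array; by
#'   default inferred as the mean electrode distance from the centroid-free
#'   origin.
#' @export
read_sfp <- function(path, scalp_radius_mm = NULL) {
  df <- utils::read.table(path, col.names = c("label", "x", "y", "z"),
                          colClasses = c("character", rep("numeric", 3)))
  fid_rows <- match(c("FidNz", "FidT9", "FidT10"), df$label)
  if (any(is.na(fid_rows))) {
    stop("sfp file lacks FidNz/FidT9/FidT10 fiducial rows", call. = FALSE)
  }
  fid <- as.matrix(df[fid_rows, c("x", "y", "z")])
  rownames(fid) <- c("nasion", "lpa", "rpa")
  el <- df[-fid_rows, , drop = FALSE]
  pos <- as.matrix(el[, c("x", "y", "z")])
  rownames(pos) <- el$label
  if (is.null(scalp_radius_mm)) {
    scalp_radius_mm <- mean(sqrt(rowSums(pos^2)))
  }
  structure(
    list(channel_ids = el$label, positions = pos, fiducials = fid,
         scalp_radius_mm = scalp_radius_mm, center = c(0, 0, 0)),
    class = "electrode_array")
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, physical dimension
#' uV, one data record per second (the sampling rate must therefore be an
#' integer). The physical range is set symmetrically from the data extreme,
#' so the round-trip error is bounded by range / 2^15 per sample.
#'
#' @param recording A `sim_recording` (or list with `data`,
#'   `sampling_rate_hz`, `channel_ids`).
#' @param path Output file.
#' @export
write_edf <- function(recording, path) {
  x <- recording$data
  rate <- recording$sampling_rate_hz
  ids <- recording$channel_ids
  if (is.null(ids)) ids <- sprintf("E%03d", seq_len(nrow(x)))
  if (rate != round(rate)) stop("EDF export needs an integer rate", call. = FALSE)
  n_ch <- nrow(x)
  n_rec <- floor(ncol(x) / rate)
  if (n_rec < 1) stop("recording shorter than one EDF record", call. = FALSE)
  x <- x[, seq_len(n_rec * rate), drop = FALSE]
  pmax_ <- max(1, max(abs(x)))
  # store the range exactly as written; keep the ASCII field within 8 bytes
  # (7 incl. sign for the negative minimum)
  fmt <- if (pmax_ >= 1e5) "%.0f" else "%.6g"
  pmax_ <- as.numeric(sprintf(fmt, pmax_ * 1.000001 + (pmax_ >= 1e5)))
  phys_min <- -pmax_; phys_max <- pmax_
  dig_min <- -32768L; dig_max <- 32767L

  pad <- function(s, n) {
    s <- substr(s, 1, n)
    sprintf(paste0("%-", n, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(as.character(256 * (1 + n_ch)), 8), pad("", 44),
    pad(as.character(n_rec), 8), pad("1", 8), pad(as.character(n_ch), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, n) {
    writeChar(paste0(vapply(vals, pad, character(1), n = n), collapse = ""),
              con, eos = NULL)
  }
  field(ids, 16)
  field(rep("", n_ch), 80)                       # transducer
  field(rep("uV", n_ch), 8)
  field(rep(sprintf("%.6g", phys_min), n_ch), 8)
  field(rep(sprintf("%.6g", phys_max), n_ch), 8)
  field(rep(as.character(dig_min), n_ch), 8)
  field(rep(as.character(dig_max), n_ch), 8)
  field(rep("", n_ch), 80)                       # prefiltering
  field(rep(as.character(rate), n_ch), 8)
  field(rep("", n_ch), 32)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    dig <- round((t(x[, idx, drop = FALSE]) - phys_min) * scale) + dig_min
    storage.mode(dig) <- "integer"
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Counterpart of [write_edf()]; supports continuous 16-bit EDF with a
#' uniform sampling rate across signals.
#'
#' @param path EDF file.
#' @return List with `data` (channels x samples, physical units),
#'   `sampling_rate_hz`, `channel_ids`, class `sim_recording` (without
#'   ground-truth events).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii <- function(n) {
    raw_ <- readBin(con, "raw", n)
    if (length(raw_) < n) return(NULL)
    raw_[raw_ == as.raw(0)] <- as.raw(32)   # tolerate embedded nuls
    rawToChar(raw_)
  }
  fixed <- read_ascii(256)
  if (is.null(fixed)) {
    stop("malformed EDF: truncated fixed header", call. = FALSE)
  }
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  n_rec <- num(substr(fixed, 237, 244))
  rec_dur <- num(substr(fixed, 245, 252))
  n_ch <- num(substr(fixed, 253, 256))
  if (any(is.na(c(n_rec, rec_dur, n_ch))) || n_ch < 1 || rec_dur <= 0) {
    stop("malformed EDF: invalid record counts in header", call. = FALSE)
  }
  sig_hdr <- read_ascii(256 * n_ch)
  if (is.null(sig_hdr)) {
    stop("malformed EDF: truncated signal header", call. = FALSE)
  }
  # byte offsets of the per-field blocks: label 16, transducer 80, dim 8,
  # phys_min 8, phys_max 8, dig_min 8, dig_max 8, prefilter 80,
  # n_samples 8, reserved 32
  off <- c(label = 0, transducer = 16, dim = 96, phys_min = 104,
           phys_max = 112, dig_min = 120, dig_max = 128, prefilter = 136,
           n_samp = 216)
  fldb <- function(name, width) {
    start <- off[[name]] * n_ch
    vapply(seq_len(n_ch), function(i) {
      trimws(substr(sig_hdr, start + (i - 1) * width + 1, start + i * width))
    }, character(1))
  }
  labels <- fldb("label", 16)
  phys_min <- as.numeric(fldb("phys_min", 8))
  phys_max <- as.numeric(fldb("phys_max", 8))
  dig_min <- as.numeric(fldb("dig_min", 8))
  dig_max <- as.numeric(fldb("dig_max", 8))
  n_samp <- as.numeric(fldb("n_samp", 8))
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, n_samp)))) {
    stop("malformed EDF: invalid signal header fields", call. = FALSE)
  }
  if (length(unique(n_samp)) != 1) {
    stop("EDF with per-signal rates is not supported", call. = FALSE)
  }
  ns <- n_samp[1]
  raw_ <- readBin(con, "integer", n = n_rec * n_ch * ns, size = 2,
                  endian = "little")
  if (length(raw_) < n_rec * n_ch * ns) {
    stop("malformed EDF: truncated data section", call. = FALSE)
  }
  data <- matrix(0, n_ch, n_rec * ns)
  arr <- array(raw_, dim = c(ns, n_ch, n_rec))
  for (ch in seq_len(n_ch)) {
    scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    data[ch, ] <- (as.vector(arr[, ch, ]) - dig_min[ch]) * scale +
      phys_min[ch]
  }
  structure(
    list(data = data, sampling_rate_hz = ns / rec_dur, channel_ids = labels,
         events = data.frame()),
    class = "sim_recording")
}

#' Read / write BIDS-style event tables
#'
#' Tab-separated with columns onset (s), duration (s), trial_type, sample,
#' and any extra columns present (e.g. grid_index, channel, probability,
#' provenance). Round trips are exact for numeric and character columns.
#'
#' @param events A data frame; minimally an `onset` column (or `time_s`,
#'   renamed on write).
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  df <- as.data.frame(events)
  if (!"onset" %in% names(df)) {
    tcol <- intersect(c("time_s", "peak_time_s"), names(df))[1]
    if (is.na(tcol)) stop("events need an onset/time_s column", call. = FALSE)
    names(df)[names(df) == tcol] <- "onset"
  }
  if (!"duration" %in% names(df)) df$duration <- 0
  front <- intersect(c("onset", "duration", "trial_type", "sample"), names(df))
  df <- df[, c(front, setdiff(names(df), front)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE)
}
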