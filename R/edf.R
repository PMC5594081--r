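#' Construct an EEG recording object
#'
#' A `recording` is the package's in-memory representation of a multichannel
#' EEG segment: a channels-by-samples matrix in microvolts plus its sampling
#' rate and channel labels.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels character vector of channel names (defaults to "Ch1"...).
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, labels = NULL) {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("Ch", seq_len(nrow(data)))
  rec <- structure(list(data = data, fs = fs, labels = labels),
                   class = "recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(is.matrix(rec$data), is.numeric(rec$data))
  if (nrow(rec$data) < 2) stop("recording needs at least 2 channels")
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0)
    stop("fs must be a positive scalar")
  if (length(rec$labels) != nrow(rec$data))
    stop("labels length must equal channel count")
  if (anyNA(rec$data) || any(!is.finite(rec$data)))
    stop("recording data contains NA or non-finite values")
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

# --- minimal EDF (European Data Format, 16-bit) reader/writer -------------
# Standard 256-byte fixed header + 256 bytes per signal, then data records of
# little-endian 2-byte integers, demultiplexed per signal.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Writes a standard 16-bit EDF with one data record per second (a final
#' shorter record is padded with the physical value 0).  Physical range is
#' taken from the data; digital range is the full 16-bit span.
#'
#' @param rec a [recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  validate_recording(rec)
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  fs <- rec$fs
  nr_per_rec <- as.integer(round(fs))       # 1-second records
  n_rec <- ceiling(n / nr_per_rec)
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                         # version
    edf_pad("X X X X", 80),                  # patient id
    edf_pad("Startdate X X X X", 80),        # recording id
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),              # header bytes
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(1, nsmall = 0), 8),       # record duration (s)
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) writeChar(paste0(edf_pad(vals, width), collapse = ""), con, eos = NULL)
  fld(rec$labels, 16)
  fld(rep("", ns), 80)                       # transducer
  fld(rep("uV", ns), 8)                      # physical dimension
  fld(formatC(phys_min, digits = 6, format = "g"), 8)
  fld(formatC(phys_max, digits = 6, format = "g"), 8)
  fld(rep(dig_min, ns), 8)
  fld(rep(dig_max, ns), 8)
  fld(rep("", ns), 80)                       # prefiltering
  fld(rep(nr_per_rec, ns), 8)
  fld(rep("", ns), 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * nr_per_rec + 1):min(r * nr_per_rec, n)
    for (s in seq_len(ns)) {
      seg <- rep(0, nr_per_rec)
      seg[seq_along(idx)] <- rec$data[s, idx]
      dig <- as.integer(round((seg - phys_min[s]) / scale[s]) + dig_min)
      dig <- pmax(pmin(dig, dig_max), dig_min)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Parses a standard 16-bit EDF header, demultiplexes the data records and
#' rescales to physical units.  All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return A [recording].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header")
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  nr <- as.integer(rdv(8)); rdv(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, nr)))
    stop("malformed EDF signal headers")
  if (length(unique(nr)) != 1)
    stop("EDF signals have mismatched samples per record")
  fs <- nr[1] / rec_dur
  dat <- matrix(0, ns, n_rec * nr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nr[s], size = 2L, endian = "little")
      if (length(dig) < nr[s]) stop("malformed EDF: truncated data record")
      phys <- (dig - dig_min[s]) * (phys_max[s] - phys_min[s]) /
        (dig_max[s] - dig_min[s]) + phys_min[s]
      dat[s, ((r - 1) * nr[s] + 1):(r * nr[s])] <- phys
    }
  }
  recording(dat, fs, labels)
}

#' Read an EEG recording from disk
#'
#' Front door for file input; currently EDF only.
#'
#' @param path EDF file path.
#' @return A [recording].
#' @export
read_recording <- function(path) read_edf(path)
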