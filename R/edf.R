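# Minimal EDF (European Data Format) reader/writer.
#
# EDF stores a 256-byte ASCII header, 256 ASCII bytes per signal, then data
# records of little-endian int16 samples scaled by a per-signal physical /
# digital calibration. This implementation covers what polysomnography
# pipelines need: multiple channels with per-channel sampling rates,
# physical units in µV, 1-second data records. EDF+ annotation signals are
# not parsed (they read back as an ordinary int16 trace and are ignored by
# read_recording unless requested).

.edf_pad <- function(s, n) {
  s <- as.character(s)
  if (nchar(s, type = "bytes") > n) s <- substr(s, 1L, n)
  formatC(s, width = -n, flag = " ")
}

.edf_num <- function(x, n = 8L) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > n) s <- formatC(x, format = "g", digits = 4, width = 1)
  if (nchar(s) > n) stop("EDF header: numeric field too wide: ", x)
  .edf_pad(s, n)
}

.edf_read_field <- function(con, n, count = 1L) {
  raw <- readChar(con, rep(n, count), useBytes = TRUE)
  trimws(raw)
}

#' Write a recording to an EDF file
#'
#' Uses 1-second data records; every channel must have an integer sampling
#' rate. The physical range per channel is the symmetric ceiling of the
#' sample extrema, digitized over the full 16-bit range, so a write/read
#' round-trip is exact to within one digital quantization step. Signals are
#' zero-padded to a whole number of records.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  traces <- rec$traces
  ns <- length(traces)
  fs <- vapply(traces, function(t) t$fs, numeric(1))
  if (any(fs != round(fs)))
    stop("write_edf: per-channel sampling rates must be integers")
  n_rec <- as.integer(ceiling(max(vapply(traces, trace_duration, numeric(1)))))
  con <- file(path, "wb")
  on.exit(close(con))

  hdr <- paste0(
    .edf_pad("0", 8L),
    .edf_pad("X X X X", 80L),
    .edf_pad("Startdate 01-JAN-2000 synthetic", 80L),
    .edf_pad("01.01.00", 8L),
    .edf_pad("00.00.00", 8L),
    .edf_pad(as.character(256L * (ns + 1L)), 8L),
    .edf_pad("", 44L),
    .edf_pad(as.character(n_rec), 8L),
    .edf_pad("1", 8L),
    .edf_pad(as.character(ns), 4L)
  )
  writeChar(hdr, con, eos = NULL)

  pmax_v <- vapply(traces, function(t) {
    m <- max(abs(t$samples))
    if (m == 0) 1 else ceiling(m * 1.01)
  }, numeric(1))
  dmin <- -32768; dmax <- 32767

  traces_idx <- seq_len(ns)
  writeChar(paste0(
    paste(vapply(traces_idx, function(i)
      .edf_pad(traces[[i]]$label, 16L), character(1)), collapse = ""),
    paste(rep(.edf_pad("", 80L), ns), collapse = ""),
    paste(rep(.edf_pad("uV", 8L), ns), collapse = ""),
    paste(vapply(traces_idx, function(i)
      .edf_num(-pmax_v[i]), character(1)), collapse = ""),
    paste(vapply(traces_idx, function(i)
      .edf_num(pmax_v[i]), character(1)), collapse = ""),
    paste(rep(.edf_num(dmin), ns), collapse = ""),
    paste(rep(.edf_num(dmax), ns), collapse = ""),
    paste(rep(.edf_pad("", 80L), ns), collapse = ""),
    paste(vapply(traces_idx, function(i)
      .edf_pad(as.character(as.integer(fs[i])), 8L), character(1)),
      collapse = ""),
    paste(rep(.edf_pad("", 32L), ns), collapse = "")
  ), con, eos = NULL)

  # digitize each padded channel once, then interleave per record
  dig <- vector("list", ns)
  for (i in traces_idx) {
    x <- traces[[i]]$samples
    need <- n_rec * as.integer(fs[i])
    if (length(x) < need) x <- c(x, numeric(need - length(x)))
    p_lo <- -pmax_v[i]; p_hi <- pmax_v[i]
    d <- round((x - p_lo) / (p_hi - p_lo) * (dmax - dmin) + dmin)
    dig[[i]] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  spr <- as.integer(fs)
  for (r in seq_len(n_rec)) {
    for (i in traces_idx) {
      sel <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][sel], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF/EDF+ file path.
#' @return A list with `labels`, `fs`, `signals` (list of numeric vectors in
#'   physical units), `n_records`, `record_duration_s`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .edf_read_field(con, 8L)
  if (!identical(version, "0"))
    stop("not an EDF file (bad version field): ", path)
  invisible(.edf_read_field(con, 80L))  # patient
  invisible(.edf_read_field(con, 80L))  # recording
  invisible(.edf_read_field(con, 8L))   # date
  invisible(.edf_read_field(con, 8L))   # time
  invisible(.edf_read_field(con, 8L))   # header bytes
  invisible(.edf_read_field(con, 44L))  # reserved
  n_rec <- as.integer(.edf_read_field(con, 8L))
  rec_dur <- as.numeric(.edf_read_field(con, 8L))
  ns <- as.integer(.edf_read_field(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF: bad signal count")

  labels <- .edf_read_field(con, 16L, ns)
  invisible(.edf_read_field(con, 80L, ns))   # transducer
  invisible(.edf_read_field(con, 8L, ns))    # dimension
  pmin <- as.numeric(.edf_read_field(con, 8L, ns))
  pmx  <- as.numeric(.edf_read_field(con, 8L, ns))
  dmin <- as.numeric(.edf_read_field(con, 8L, ns))
  dmax <- as.numeric(.edf_read_field(con, 8L, ns))
  invisible(.edf_read_field(con, 80L, ns))   # prefiltering
  spr <- as.integer(.edf_read_field(con, 8L, ns))
  invisible(.edf_read_field(con, 32L, ns))   # reserved

  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- integer(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, what = "integer", n = spr[i], size = 2L,
                   signed = TRUE, endian = "little")
      if (length(d) < spr[i]) stop("EDF: truncated data record ", r)
      raw[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- d
    }
  }
  signals <- lapply(seq_len(ns), function(i) {
    (raw[[i]] - dmin[i]) / (dmax[i] - dmin[i]) * (pmx[i] - pmin[i]) + pmin[i]
  })
  list(labels = labels, fs = spr / rec_dur, signals = signals,
       n_records = n_rec, record_duration_s = rec_dur)
}

#' Read selected channels of an EDF polysomnogram into a recording
#'
#' @param path EDF file path.
#' @param channel_map named character vector mapping internal trace names to
#'   EDF channel labels, e.g. `c(leg = "LAT", ecg = "ECG")`. With `NULL`,
#'   every channel is read under its EDF label.
#' @return A [recording()]; amplitudes are in the file's physical units (µV
#'   for traces written by this package).
#' @export
read_recording <- function(path, channel_map = NULL) {
  edf <- read_edf(path)
  if (is.null(channel_map)) {
    channel_map <- stats::setNames(edf$labels, edf$labels)
  }
  missing_ch <- setdiff(unname(channel_map), edf$labels)
  if (length(missing_ch))
    stop(sprintf("channel(s) not found: %s; available: %s",
                 paste(missing_ch, collapse = ", "),
                 paste(edf$labels, collapse = ", ")))
  traces <- lapply(seq_along(channel_map), function(i) {
    j <- match(channel_map[[i]], edf$labels)
    signal_trace(edf$signals[[j]], fs = edf$fs[j], label = edf$labels[j])
  })
  names(traces) <- names(channel_map)
  recording(traces, duration_s = edf$n_records * edf$record_duration_s)
}
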