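#' Continuous multichannel sEEG recording
#'
#' Container for a continuous recording: `data` is a channels x samples
#' matrix in microvolts, `fs` the sampling rate in Hz, `channels` a
#' metadata data.frame (label, patient, probe, contact, x, y, z, region,
#' include), `reference` one of "original" or "common-average". All times
#' in the package are milliseconds from recording start; frequencies are
#' Hz; conversions happen only at I/O boundaries.
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channels channel metadata data.frame; a minimal one is built from
#'   rownames if omitted.
#' @param reference reference descriptor.
#' @return a `seeg_recording` object.
#' @export
seeg_recording <- function(data, fs, channels = NULL,
                           reference = "original") {
  data <- as.matrix(data)
  if (is.null(channels)) {
    channels <- data.frame(label = sprintf("ch%03d", seq_len(nrow(data))),
                           include = TRUE)
  }
  if (!"label" %in% names(channels))
    channels$label <- sprintf("ch%03d", seq_len(nrow(data)))
  if (!"include" %in% names(channels)) channels$include <- TRUE
  if (nrow(channels) != nrow(data))
    stop("channel metadata rows must match data rows")
  if (anyDuplicated(channels$label)) stop("channel labels must be unique")
  structure(list(data = data, fs = fs,
                 channels = as.data.frame(channels),
                 reference = reference),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf(
    "seeg_recording: %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs, x$reference))
  cat(sprintf("  included channels: %d of %d\n",
              sum(x$channels$include), nrow(x$channels)))
  invisible(x)
}

#' Write / read recordings
#'
#' `format = "edf"` writes a minimal European Data Format (EDF) file:
#' 16-bit samples with per-channel physical scaling, so the round trip is
#' exact to within one quantization step of the declared physical range.
#' `format = "rds"` is a lossless native serialization. Channel metadata
#' beyond labels does not survive EDF; pair it with an electrode TSV.
#'
#' @param rec a `seeg_recording`.
#' @param path output file.
#' @param format "edf" or "rds".
#' @export
write_recording <- function(rec, path, format = c("edf", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  write_edf(rec, path)
}

#' @rdname write_recording
#' @return `read_recording` returns a `seeg_recording`.
#' @export
read_recording <- function(path, format = c("edf", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (format == "rds") {
    rec <- readRDS(path)
    if (!inherits(rec, "seeg_recording")) stop("not a seeg_recording RDS")
    return(rec)
  }
  read_edf(path)
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

# minimal EDF writer: one data record holding the whole recording
write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8),
    pad_ascii("synthetic", 80), pad_ascii("seegamma", 80),
    pad_ascii("01.01.20", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 + ns * 256, 8), pad_ascii("", 44),
    pad_ascii(1, 8),                                   # n records
    pad_ascii(format(nsamp / rec$fs, digits = 8), 8),  # record duration s
    pad_ascii(ns, 4))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(pad_ascii(rec$channels$label, 16), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(rep(pad_ascii("sEEG", 80), ns), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(rep(pad_ascii("uV", 8), ns), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad_ascii(format(phys_min, digits = 7), 8),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(pad_ascii(format(phys_max, digits = 7), 8),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_ascii(dig_min, 8), ns), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(rep(pad_ascii(dig_max, 8), ns), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(rep(pad_ascii("", 80), ns), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(pad_ascii(rep(nsamp, ns), 8), collapse = ""), con,
            eos = NULL)
  writeChar(paste0(rep(pad_ascii("", 32), ns), collapse = ""), con,
            eos = NULL)
  for (ci in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (phys_max[ci] - phys_min[ci])
    dig <- round((rec$data[ci, ] - phys_min[ci]) * scale + dig_min)
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (nchar(s, type = "bytes") < w) stop("malformed EDF header (truncated)")
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("malformed EDF header (signal count)")
  if (hdr_bytes != 256 + ns * 256) stop("malformed EDF header (size field)")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)   # transducer
  for (i in seq_len(ns)) rd(8)    # unit
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)   # prefilter
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(nsamp)) != 1L)
    stop("channels disagree on samples per record (fs mismatch)")
  fs <- nsamp[1] / rec_dur
  if (abs(fs - round(fs)) < 1e-6) fs <- round(fs)  # header string rounding
  data <- matrix(0, ns, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ci in seq_len(ns)) {
      dig <- readBin(con, "integer", nsamp[ci], size = 2, endian = "little",
                     signed = TRUE)
      scale <- (phys_max[ci] - phys_min[ci]) / (dig_max[ci] - dig_min[ci])
      data[ci, (r - 1) * nsamp[ci] + seq_len(nsamp[ci])] <-
        (dig - dig_min[ci]) * scale + phys_min[ci]
    }
  }
  seeg_recording(data, fs,
                 channels = data.frame(label = labels, include = TRUE),
                 reference = "original")
}

#' EDF quantization step of a written file
#'
#' Physical range divided by the 16-bit digital range, per channel; the
#' maximum absolute round-trip error of [write_recording()] in EDF format.
#' @param rec the `seeg_recording` that was written.
#' @return numeric vector, one step per channel (microvolts).
#' @export
edf_quantization_step <- function(rec) {
  rng <- apply(rec$data, 1, function(x) diff(range(x)))
  rng[rng < 1e-12] <- 1
  rng / 65535
}

#' Write / read electrode tables as TSV
#'
#' Coordinates are mm; a `# coord_unit: mm` comment records the unit.
#' @param electrodes an electrode table data.frame.
#' @param path TSV path.
#' @export
write_electrodes <- function(electrodes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coord_unit: mm", con)
  utils::write.table(electrodes, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_electrodes
#' @export
read_electrodes <- function(path) {
  if (!file.exists(path)) stop("electrode file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  req <- c("patient", "probe", "contact", "x", "y", "z")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("electrode TSV missing required columns: ",
         paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(d[, c("x", "y", "z")]))))
    stop("electrode coordinates must be finite")
  if (anyDuplicated(d[, c("patient", "probe", "contact")]))
    stop("(patient, probe, contact) must be unique")
  if (!"include" %in% names(d)) d$include <- TRUE
  if (!"label" %in% names(d))
    d$label <- paste(d$patient, d$probe, d$contact, sep = "-")
  extra <- setdiff(names(d), c(req, "label", "region", "include"))
  if (length(extra))
    warning("ignoring unknown electrode columns: ",
            paste(extra, collapse = ", "))
  class(d) <- c("electrode_table", "data.frame")
  d
}

#' Write / read event tables as TSV
#'
#' Times are written in ms with a `# time_unit: ms` header comment; files
#' declaring `# time_unit: s` are converted to ms on read.
#' @param events an event table data.frame.
#' @param path TSV path.
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# time_unit: ms", con)
  utils::write.table(events, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  first <- readLines(path, n = 1)
  unit <- "ms"
  if (grepl("^#\\s*time_unit:", first))
    unit <- trimws(sub("^#\\s*time_unit:", "", first))
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  req <- c("trial", "task", "stim_onset_ms")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("event TSV missing required columns: ", paste(miss, collapse = ", "))
  if (unit == "s") {
    for (col in intersect(c("stim_onset_ms", "speech_onset_ms", "rt_ms"),
                          names(d)))
      d[[col]] <- d[[col]] * 1000
  } else if (unit != "ms") stop("unknown time unit in event TSV: ", unit)
  class(d) <- c("event_table", "data.frame")
  d
}

#' Write a JSON provenance / ground-truth sidecar
#' @param x a list (e.g. a `ground_truth`, or any config).
#' @param path JSON path.
#' @param seed seed to record.
#' @export
write_sidecar <- function(x, path, seed = NULL) {
  payload <- list(content = unclass(x), seed = seed,
                  package_version = as.character(
                    utils::packageVersion("seegamma")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}
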