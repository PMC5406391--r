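#' Write recordings to long-format CSV files
#'
#' One file per recording, named `sub<ID>_cond<I|II>.csv`, with columns
#' `subject`, `condition`, `channel`, `sample_index`, `value`. Exact
#' round-trip via [read_recording_csv()].
#'
#' @param recordings A list of [eeg_recording()] objects (or a single one).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_recordings_csv <- function(recordings, dir) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(recordings, function(rec) {
    path <- file.path(dir, sprintf("sub%s_cond%s.csv",
                                   rec$subject_id, rec$condition))
    long <- tibble::tibble(
      subject = rec$subject_id,
      condition = rec$condition,
      channel = rep(rec$channels$channel, each = ncol(rec$data)),
      sample_index = rep(seq_len(ncol(rec$data)), nrow(rec$data)),
      value = as.vector(t(rec$data))
    )
    utils::write.csv(long, path, row.names = FALSE)
    path
  }, "")
  invisible(paths)
}

#' Read one long-format CSV recording
#'
#' @param path CSV file written by [write_recordings_csv()].
#' @param fs_hz Sampling rate to attach. Default 128.
#' @return An [eeg_recording()].
#' @export
read_recording_csv <- function(path, fs_hz = 128) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject", "condition", "channel", "sample_index", "value")
  if (!all(needed %in% names(long))) {
    stop("CSV ", path, " lacks columns: ",
         paste(setdiff(needed, names(long)), collapse = ", "),
         call. = FALSE)
  }
  mont <- montage_channels()
  chans <- unique(long$channel)
  if (!setequal(chans, mont$channel)) {
    stop("channel set in ", basename(path),
         " does not match the 14-channel montage", call. = FALSE)
  }
  n <- max(long$sample_index)
  data <- matrix(NA_real_, nrow(mont), n)
  for (ci in seq_len(nrow(mont))) {
    rows <- long[long$channel == mont$channel[ci], ]
    data[ci, rows$sample_index] <- rows$value
  }
  eeg_recording(data, unique(long$subject)[1], unique(long$condition)[1],
                fs_hz)
}

# ---- Minimal EDF (European Data Format) support ----------------------------
# ASCII 256-byte header + per-signal 256-byte headers + 16-bit little-endian
# samples, written as a single data record spanning the whole recording.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write one recording as an EDF file
#'
#' Minimal single-record EDF writer: 16-bit samples scaled to each
#' channel's physical range, montage labels as signal labels. Values
#' round-trip through [read_recording_edf()] to within one quantization
#' step of the channel range.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_recording_edf <- function(recording, path) {
  data <- recording$data
  ns <- nrow(data)
  n <- ncol(data)
  dig_min <- -32768; dig_max <- 32767
  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("sub ", recording$subject_id), 80),
    edf_pad(paste0("cond ", recording$condition), 80),
    edf_pad("01.01.17", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(1, 8),                                    # one data record
    edf_pad(format(n / recording$fs_hz, digits = 7), 8),
    edf_pad(ns, 4)
  )
  fields <- c(
    vapply(recording$channels$channel, edf_pad, "", width = 16),  # labels
    rep(edf_pad("", 80), ns),                         # transducer
    rep(edf_pad("uV", 8), ns),                        # physical dimension
    vapply(phys_min, function(v) edf_pad(format(v, digits = 7), 8), ""),
    vapply(phys_max, function(v) edf_pad(format(v, digits = 7), 8), ""),
    rep(edf_pad(dig_min, 8), ns),
    rep(edf_pad(dig_max, 8), ns),
    rep(edf_pad("", 80), ns),                         # prefiltering
    rep(edf_pad(n, 8), ns),                           # samples per record
    rep(edf_pad("", 32), ns)
  )
  writeChar(paste0(header, paste(fields, collapse = "")), con,
            eos = NULL)
  for (ci in seq_len(ns)) {
    scale <- (dig_max - dig_min) / (phys_max[ci] - phys_min[ci])
    dig <- round((data[ci, ] - phys_min[ci]) * scale) + dig_min
    writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_recording_edf()]
#'
#' @param path EDF file path.
#' @param subject_id,condition Metadata overrides; by default parsed from
#'   the EDF patient/recording fields.
#' @return An [eeg_recording()].
#' @export
read_recording_edf <- function(path, subject_id = NULL, condition = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  invisible(rd(8))                       # version
  patient <- rd(80)
  rec_field <- rd(80)
  invisible(rd(8)); invisible(rd(8))     # date, time
  invisible(rd(8))                       # header bytes
  invisible(rd(44))
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  invisible(replicate(ns, rd(80)))
  invisible(replicate(ns, rd(8)))
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  invisible(replicate(ns, rd(80)))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  invisible(replicate(ns, rd(32)))

  mont <- montage_channels()
  if (!setequal(labels, mont$channel)) {
    stop("EDF ", basename(path),
         " channel labels do not match the 14-channel montage",
         call. = FALSE)
  }
  data <- matrix(0, ns, spr[1] * n_records)
  for (r in seq_len(n_records)) {
    for (ci in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ci], size = 2,
                     endian = "little")
      scale <- (phys_max[ci] - phys_min[ci]) / (dig_max[ci] - dig_min[ci])
      at <- (r - 1) * spr[ci] + seq_len(spr[ci])
      data[ci, at] <- (dig - dig_min[ci]) * scale + phys_min[ci]
    }
  }
  # Reorder to montage order.
  data <- data[match(mont$channel, labels), , drop = FALSE]
  fs <- spr[1] / record_dur
  eeg_recording(
    data,
    subject_id %||% sub("^sub\\s*", "", patient),
    condition %||% sub("^cond\\s*", "", rec_field),
    fs
  )
}

#' Write recordings as EDF files
#'
#' One `sub<ID>_cond<I|II>.edf` file per recording.
#'
#' @param recordings List of [eeg_recording()] objects (or a single one).
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_recordings_edf <- function(recordings, dir) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(recordings, function(rec) {
    path <- file.path(dir, sprintf("sub%s_cond%s.edf",
                                   rec$subject_id, rec$condition))
    write_recording_edf(rec, path)
    path
  }, "")
  invisible(paths)
}

#' Ingest a directory of recordings
#'
#' Reads every `sub<ID>_cond<I|II>.csv` or `.edf` file in a directory,
#' parsing subject and condition from the filename. Files that fail to
#' parse, carry unknown channel labels, or disagree on sampling rate are
#' collected into a validation report; the run aborts only if no file
#' is valid.
#'
#' @param path Directory to scan.
#' @param format `"csv"` or `"edf"`.
#' @param fs_hz Expected sampling rate (used for CSV, checked for EDF).
#' @return List of [eeg_recording()] objects with attribute `"report"`
#'   (a tibble of per-file outcomes).
#' @export
ingest_recordings <- function(path, format = c("csv", "edf"), fs_hz = 128) {
  format <- match.arg(format)
  files <- list.files(path, pattern = paste0("\\.", format, "$"),
                      full.names = TRUE)
  pattern <- "^sub(.+)_cond(I{1,2})$"
  recs <- list()
  report <- list()
  for (f in files) {
    base <- sub(paste0("\\.", format, "$"), "", basename(f))
    m <- regmatches(base, regexec(pattern, base))[[1]]
    if (length(m) != 3) {
      report[[f]] <- tibble::tibble(file = basename(f), ok = FALSE,
                                    reason = "unparseable filename")
      next
    }
    rec <- tryCatch(
      if (format == "csv") read_recording_csv(f, fs_hz)
      else read_recording_edf(f, subject_id = m[2], condition = m[3]),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      report[[f]] <- tibble::tibble(file = basename(f), ok = FALSE,
                                    reason = conditionMessage(rec))
      next
    }
    if (abs(rec$fs_hz - fs_hz) > 1e-6) {
      report[[f]] <- tibble::tibble(
        file = basename(f), ok = FALSE,
        reason = sprintf("sampling-rate mismatch: %g != %g",
                         rec$fs_hz, fs_hz))
      next
    }
    rec$subject_id <- m[2]
    rec$condition <- m[3]
    recs[[length(recs) + 1]] <- rec
    report[[f]] <- tibble::tibble(file = basename(f), ok = TRUE,
                                  reason = NA_character_)
  }
  report <- dplyr::bind_rows(report)
  if (length(recs) == 0) {
    stop("no valid recordings in ", path,
         if (nrow(report) > 0) paste0(
           " (", paste(unique(report$reason), collapse = "; "), ")") else "",
         call. = FALSE)
  }
  attr(recs, "report") <- report
  recs
}
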