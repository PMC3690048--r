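# CSV / TSV interchange and frame-stream reassembly.
# CSV dialect: comma-separated, '.' decimal, optional header. The time base is
# implicit (index / fs, 0-based, seconds); an explicit first time column is
# validated for uniformity but never resampled.

read_numeric_table <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    !grepl("^\\s*[-+0-9.eE]+(\\s*[,\t]\\s*[-+0-9.eE]+)*\\s*$", first)
  df <- tryCatch(
    utils::read.table(path, header = has_header, sep = sep, dec = ".",
                      colClasses = "numeric", strip.white = TRUE),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(df)) {
    # locate the first offending line for the error message
    raw <- utils::read.table(path, header = has_header, sep = sep,
                             colClasses = "character", strip.white = TRUE)
    for (i in seq_len(nrow(raw))) {
      if (anyNA(suppressWarnings(as.numeric(unlist(raw[i, ])))))
        stop("non-numeric value on data line ", i, " of ", path)
    }
    stop("could not parse ", path)
  }
  df
}

#' Read an ECG series from CSV
#'
#' Accepts one numeric column (voltage, mV) or two columns (time s, voltage
#' mV). With two columns the timestamps must be uniform at \code{1/fs} within
#' tolerance; they set \code{start_time} but are otherwise discarded in favour
#' of the implicit index/fs time base.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param device_grid validate samples against the acquisition grid.
#' @param tol_s allowed deviation of explicit timestamps from uniformity (s).
#' @return an [ecg_record()].
#' @export
read_ecg_csv <- function(path, fs = ECG_FS_DEFAULT, device_grid = FALSE,
                         tol_s = 1e-6) {
  df <- read_numeric_table(path, sep = ",")
  if (ncol(df) == 1L) {
    ecg_record(df[[1]], fs = fs, device_grid = device_grid)
  } else if (ncol(df) == 2L) {
    tt <- df[[1]]
    if (length(tt) > 1L) {
      expected <- tt[1] + (seq_along(tt) - 1) / fs
      if (max(abs(tt - expected)) > tol_s)
        stop("explicit timestamps in ", path,
             " are not uniform at 1/fs = ", signif(1 / fs, 6), " s")
    }
    ecg_record(df[[2]], fs = fs, start_time = if (length(tt)) tt[1] else 0,
               device_grid = device_grid)
  } else {
    stop("expected 1 or 2 columns in ", path, ", found ", ncol(df))
  }
}

#' Write an ECG series to CSV
#'
#' One or two columns (`time_s` first when `times = TRUE`); values round-trip
#' bit-identically through [read_ecg_csv()].
#'
#' @param record an [ecg_record()].
#' @param path output file path.
#' @param times include an explicit time column.
#' @export
write_ecg_csv <- function(record, path, times = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  if (times) {
    df <- data.frame(time_s = ecg_times(record), ecg_mV = record$samples)
  } else {
    df <- data.frame(ecg_mV = record$samples)
  }
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an SCR series as CSV
#'
#' One column of voltages (V), or two columns with a label column
#' (`scr_V,label`) written by [write_scr_csv()].
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @return an [scr_record()].
#' @export
read_scr_csv <- function(path, fs = SCR_FS_DEFAULT) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, strip.white = TRUE,
                        colClasses = NA, stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]]))
    df <- utils::read.csv(path, header = FALSE, strip.white = TRUE)
  v <- as.numeric(df[[1]])
  if (anyNA(v)) stop("non-numeric SCR value on data line ",
                     which(is.na(v))[1], " of ", path)
  labels <- if (ncol(df) >= 2L) as.character(df[[2]]) else NULL
  scr_record(v, fs = fs, labels = labels)
}

#' @rdname read_scr_csv
#' @param record an [scr_record()].
#' @export
write_scr_csv <- function(record, path) {
  stopifnot(inherits(record, "scr_record"))
  df <- data.frame(scr_V = format(record$samples, digits = 17, trim = TRUE,
                                  scientific = FALSE),
                   label = record$labels)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read beat annotations as TSV
#'
#' Tab-separated columns `time_s`, `class`, `norm_amp`; a header line is always
#' present, so an empty peak list yields a header-only file.
#'
#' @param peaks an [rpeak_list()] with sorted times.
#' @param path file path.
#' @export
write_annotations <- function(peaks, path) {
  stopifnot(inherits(peaks, "rpeak_list"))
  if (nrow(peaks) > 1L && any(diff(peaks$time) <= 0))
    stop("peak times must be sorted strictly ascending")
  df <- data.frame(time_s = format(peaks$time, digits = 17, trim = TRUE,
                                   scientific = FALSE),
                   class = peaks$klass,
                   norm_amp = format(peaks$norm_amp, digits = 17, trim = TRUE,
                                     scientific = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) return(rpeak_list())
  rpeak_list(as.numeric(df$time_s), as.numeric(df$norm_amp),
             as.character(df$class))
}

#' Construct a frame stream
#'
#' An ordered list of telemetry frames as sent by the wearable: ECG waveform
#' frames (63 samples each, one frame per 252 ms at 4 ms/sample), breathing
#' waveform frames (18 samples each, one frame per 1.008 s at 56 ms/sample)
#' and summary frames (raw byte payload carrying, among other fields, the heart
#' rate at byte offsets 12-13).
#'
#' @param frames list of frames, each `list(kind =, payload =)` with kind one
#'   of `"ecg"`, `"breathing"`, `"summary"`; ecg/breathing payloads are numeric
#'   sample vectors, summary payloads raw (or 0-255 integer) vectors.
#' @return an object of class \code{frame_stream}.
#' @export
frame_stream <- function(frames = list()) {
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.list(fr) || is.null(fr$kind) || is.null(fr$payload))
      stop("frame ", i, " must be list(kind =, payload =)")
    if (!fr$kind %in% c("ecg", "breathing", "summary"))
      stop("frame ", i, ": unknown kind '", fr$kind, "'")
  }
  structure(list(frames = frames), class = "frame_stream")
}

#' Reassemble a frame stream into uniform sample series
#'
#' Concatenates ECG frames onto the 4 ms grid and breathing frames onto the
#' 56 ms grid, and decodes the heart rate from each summary frame's payload at
#' byte offsets 12-13 (unsigned 16-bit; little-endian by default, a declared
#' convention that can be flipped).
#'
#' @param stream a [frame_stream()].
#' @param hr_big_endian decode the heart-rate field big-endian instead.
#' @return list with `ecg` ([ecg_record()]), `breathing` (list of `samples`,
#'   `fs`), and `heart_rate` (integer vector, one per summary frame).
#' @export
reassemble_frames <- function(stream, hr_big_endian = FALSE) {
  stopifnot(inherits(stream, "frame_stream"))
  ecg <- list(); breath <- list(); hr <- integer(0)
  for (i in seq_along(stream$frames)) {
    fr <- stream$frames[[i]]
    if (fr$kind == "ecg") {
      if (length(fr$payload) != ECG_SAMPLES_PER_FRAME)
        stop("frame ", i, ": ECG payload has ", length(fr$payload),
             " samples, expected ", ECG_SAMPLES_PER_FRAME)
      ecg[[length(ecg) + 1L]] <- as.numeric(fr$payload)
    } else if (fr$kind == "breathing") {
      if (length(fr$payload) != BREATH_SAMPLES_PER_FRAME)
        stop("frame ", i, ": breathing payload has ", length(fr$payload),
             " samples, expected ", BREATH_SAMPLES_PER_FRAME)
      breath[[length(breath) + 1L]] <- as.numeric(fr$payload)
    } else {
      bytes <- as.integer(fr$payload)
      if (length(bytes) < 14L)
        stop("frame ", i, ": summary payload shorter than 14 bytes")
      if (any(bytes < 0L | bytes > 255L))
        stop("frame ", i, ": summary payload bytes must be 0-255")
      b12 <- bytes[13L]; b13 <- bytes[14L]  # 0-based offsets 12 and 13
      hr <- c(hr, if (hr_big_endian) b12 * 256L + b13 else b13 * 256L + b12)
    }
  }
  list(
    ecg = ecg_record(unlist(ecg) %||% numeric(0), fs = ECG_FS_DEFAULT),
    breathing = list(samples = unlist(breath) %||% numeric(0),
                     fs = 1 / BREATH_DT_S),
    heart_rate = hr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
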