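## EDF (European Data Format) I/O, delimited-text I/O, and the standard
## preprocessing chain (zero-phase band-pass, common average reference,
## FFT-domain resampling, epoch truncation).

.trim <- function(x) sub("[[:space:]]+$", "", sub("^[[:space:]]+", "", x))

.readAscii <- function(con, n) {
  raw <- readChar(con, n, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < n) {
    stop("EDF format error: truncated header", call. = FALSE)
  }
  .trim(raw)
}

#' Read an EDF file
#'
#' Minimal reader for continuous EDF (European Data Format) recordings, the
#' standard interchange format of clinical EEG systems. Digital values are
#' rescaled to physical units using the per-signal calibration in the header;
#' voltages are assumed to be (and returned in) microvolts. All signals must
#' share one sampling rate.
#'
#' @param path path to an `.edf` file.
#' @param subjectId,group optional metadata overrides; by default the subject
#'   identifier is taken from the EDF patient field. A JSON sidecar
#'   `<path>.json` with fields `subject_id` / `group`, if present, is honored.
#' @return An [EEGRecording-class].
#' @seealso [writeEDF()], [readMatrixText()]
#' @export
readEDF <- function(path, subjectId = NULL, group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  version <- .readAscii(con, 8)
  if (version != "0") {
    stop("EDF format error: unsupported version field '", version, "'",
      call. = FALSE
    )
  }
  patient <- .readAscii(con, 80)
  .readAscii(con, 80) # recording id
  .readAscii(con, 8) # start date
  .readAscii(con, 8) # start time
  headerBytes <- suppressWarnings(as.integer(.readAscii(con, 8)))
  .readAscii(con, 44) # reserved
  nRecords <- suppressWarnings(as.integer(.readAscii(con, 8)))
  recDuration <- suppressWarnings(as.numeric(.readAscii(con, 8)))
  ns <- suppressWarnings(as.integer(.readAscii(con, 4)))
  if (anyNA(c(headerBytes, nRecords, ns)) || is.na(recDuration) ||
      ns < 1L || nRecords < 1L || recDuration <= 0) {
    stop("EDF format error: invalid header fields", call. = FALSE)
  }

  labels <- vapply(seq_len(ns), function(i) .readAscii(con, 16), "")
  if (any(!nzchar(labels))) {
    stop("EDF metadata error: missing channel labels", call. = FALSE)
  }
  for (i in seq_len(ns)) .readAscii(con, 80) # transducer
  for (i in seq_len(ns)) .readAscii(con, 8) # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(.readAscii(con, 8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(.readAscii(con, 8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(.readAscii(con, 8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(.readAscii(con, 8)), 0)
  for (i in seq_len(ns)) .readAscii(con, 80) # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(.readAscii(con, 8)), 0L)
  for (i in seq_len(ns)) .readAscii(con, 32) # reserved
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)) ||
      any(spr < 1L) || any(digMax <= digMin)) {
    stop("EDF format error: invalid signal headers", call. = FALSE)
  }
  if (length(unique(spr)) != 1L) {
    stop("EDF format error: heterogeneous sampling rates are not supported",
      call. = FALSE
    )
  }

  fs <- spr[1] / recDuration
  total <- nRecords * sum(spr)
  vals <- readBin(con, "integer", n = total, size = 2, signed = TRUE,
                  endian = "little")
  if (length(vals) < total) {
    stop("EDF format error: truncated data section", call. = FALSE)
  }

  data <- matrix(0, nrow = ns, ncol = nRecords * spr[1])
  gain <- (physMax - physMin) / (digMax - digMin)
  pos <- 0L
  for (r in seq_len(nRecords)) {
    for (i in seq_len(ns)) {
      seg <- vals[(pos + 1L):(pos + spr[i])]
      data[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (seg - digMin[i]) * gain[i] + physMin[i]
      pos <- pos + spr[i]
    }
  }

  sid <- if (!is.null(subjectId)) subjectId else if (nzchar(patient)) patient else "unknown"
  grp <- if (!is.null(group)) group else "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (is.null(subjectId) && !is.null(meta$subject_id)) sid <- meta$subject_id
    if (is.null(group) && !is.null(meta$group)) grp <- meta$group
  }
  EEGRecording(data, fs = fs, labels = labels, subjectId = sid, group = grp)
}

.padAscii <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n, flag = "-")
}

#' Write an EDF file
#'
#' Companion writer used by the simulator and tests. Channels are quantized to
#' 16-bit integers over a symmetric physical range per channel.
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  data <- rec@data
  ns <- nrow(data)
  n <- ncol(data)
  fs <- rec@fs
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0) {
    spr <- as.integer(round(fs))
    nRecords <- n %/% spr
    recDuration <- 1
  } else {
    spr <- n
    nRecords <- 1L
    recDuration <- n / fs
  }
  amax <- pmax(apply(abs(data), 1, max), 1e-6)
  physMin <- -amax
  physMax <- amax
  digMin <- -32768
  digMax <- 32767
  dig <- round((data - physMin) / (physMax - physMin) * (digMax - digMin) + digMin)
  dig <- pmin(pmax(dig, digMin), digMax)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(.padAscii(x, w), con, eos = NULL)
  wr("0", 8)
  wr(rec@subjectId, 80)
  wr("EEGmicrostates export", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(256 + ns * 256, 8)
  wr("", 44)
  wr(nRecords, 8)
  wr(format(recDuration, digits = 7), 8)
  wr(ns, 4)
  for (i in seq_len(ns)) wr(rec@labels[i], 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(physMin[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(format(physMax[i], digits = 7), 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(nRecords)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(ns)) {
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a delimited-text channel matrix
#'
#' Reads a numeric table with one row per channel (comma, tab or whitespace
#' separated) into an [EEGRecording-class]. The sampling rate and channel
#' labels are supplied by the caller; a JSON sidecar `<path>.json` may carry
#' `subject_id` / `group`.
#'
#' @param path path to the text file.
#' @param fs sampling rate (Hz).
#' @param labels channel names, one per row of the table.
#' @param subjectId,group optional metadata overrides.
#' @return An [EEGRecording-class].
#' @export
readMatrixText <- function(path, fs, labels, subjectId = NULL, group = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "numeric", strip.white = TRUE),
    error = function(e) stop("format error reading '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  m <- as.matrix(tab)
  if (anyNA(m) || !all(is.finite(m))) {
    stop("format error: non-numeric or non-finite values in ", path,
      call. = FALSE
    )
  }
  if (nrow(m) != length(labels)) {
    stop(sprintf(
      "metadata error: %d rows but %d channel labels", nrow(m), length(labels)
    ), call. = FALSE)
  }
  dimnames(m) <- NULL
  sid <- if (!is.null(subjectId)) subjectId else "unknown"
  grp <- if (!is.null(group)) group else "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (is.null(subjectId) && !is.null(meta$subject_id)) sid <- meta$subject_id
    if (is.null(group) && !is.null(meta$group)) grp <- meta$group
  }
  EEGRecording(m, fs = fs, labels = labels, subjectId = sid, group = grp)
}

#' Write a recording as delimited text
#'
#' @param rec an [EEGRecording-class].
#' @param path output path.
#' @param sep field separator (default tab).
#' @param digits significant digits to keep.
#' @return `path`, invisibly.
#' @export
writeMatrixText <- function(rec, path, sep = "\t", digits = 15) {
  utils::write.table(
    format(rec@data, digits = digits, scientific = TRUE, trim = TRUE),
    path,
    sep = sep, row.names = FALSE, col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so the
#' channel mean is zero at all times (the reference-free representation all
#' topographic analyses assume).
#'
#' @param rec an [EEGRecording-class].
#' @return The re-referenced [EEGRecording-class].
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  rec@data <- sweep(rec@data, 2, colMeans(rec@data))
  rec
}

.isAverageReferenced <- function(data, tol = 1e-9) {
  max(abs(colMeans(data))) <= tol
}

## FFT-domain resampling: crop or zero-pad the spectrum. Exact for
## band-limited signals and introduces no group delay.
.fftResample <- function(x, targetFs, fs) {
  n <- length(x)
  m <- as.integer(round(n * targetFs / fs))
  if (m == n) return(x)
  X <- stats::fft(x)
  keep <- min(n, m)
  h <- keep %/% 2L
  Y <- complex(m)
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  if (h > 0L) Y[(m - h + 1L):m] <- X[(n - h + 1L):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Preprocess a recording
#'
#' The standard chain before microstate analysis: zero-phase Butterworth
#' band-pass (order `filterOrder` per pass, applied forward and backward),
#' optional FFT-domain resampling, truncation to the analysis epoch, and
#' common-average re-referencing. All steps are configurable; pass `band =
#' NULL` or `epochLength = NULL` to skip a step.
#'
#' @param rec an [EEGRecording-class].
#' @param band numeric `(low, high)` pass band in Hz, or `NULL` to skip
#'   filtering. Must satisfy `low < high < fs/2`.
#' @param targetFs resample to this rate (Hz), or `NULL` to keep the native
#'   rate.
#' @param epochLength keep exactly the first `epochLength` seconds (default
#'   20 s, the standard resting-state analysis epoch); `NULL` keeps all
#'   samples. A recording shorter than the epoch is an error.
#' @param filterOrder Butterworth design order per pass (default 4).
#' @return The preprocessed [EEGRecording-class].
#' @examples
#' rec <- generateEEG(syntheticSpec(nChannels = 8, durationS = 2, seed = 1))$recording
#' out <- preprocessEEG(rec, band = c(1, 30), epochLength = NULL)
#' max(abs(colMeans(eegData(out)))) # common average reference
#' @export
preprocessEEG <- function(rec, band = c(1, 30), targetFs = NULL,
                          epochLength = 20, filterOrder = 4) {
  stopifnot(is(rec, "EEGRecording"))
  data <- rec@data
  fs <- rec@fs

  if (!is.null(band)) {
    if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2] ||
        band[2] >= fs / 2) {
      stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
    }
    bf <- signal::butter(filterOrder, band / (fs / 2), type = "pass")
    for (i in seq_len(nrow(data))) {
      data[i, ] <- signal::filtfilt(bf, data[i, ])
    }
  }

  if (!is.null(targetFs) && abs(targetFs - fs) > 1e-12) {
    if (targetFs > fs) stop("targetFs must not exceed fs", call. = FALSE)
    data <- t(apply(data, 1, .fftResample, targetFs = targetFs, fs = fs))
    fs <- targetFs
  }

  if (!is.null(epochLength)) {
    nKeep <- as.integer(round(epochLength * fs))
    if (ncol(data) < nKeep) {
      stop(sprintf(
        "length error: recording has %.3f s but epoch of %g s requested",
        ncol(data) / fs, epochLength
      ), call. = FALSE)
    }
    data <- data[, seq_len(nKeep), drop = FALSE]
  }

  data <- sweep(data, 2, colMeans(data))
  EEGRecording(data, fs = fs, labels = rec@labels,
               subjectId = rec@subjectId, group = rec@group)
}

#' Down-convert to a clinical montage
#'
#' Restricts a high-density recording to a clinical subset of electrodes (in
#' the given order), resamples to the clinical rate, and re-references to the
#' common average of the retained channels — the spatial and temporal
#' down-conversion needed before features from research-grade (e.g. 64
#' channel / 1000 Hz) and routine clinical (19 channel / 512 Hz) EEG can be
#' compared or a classifier retrained on the clinical format.
#'
#' @param rec an [EEGRecording-class].
#' @param targetLabels channel names to retain, in output order.
#' @param targetFs target sampling rate (Hz), at most `samplingRate(rec)`.
#' @return The down-converted [EEGRecording-class].
#' @export
downsampleToClinical <- function(rec, targetLabels, targetFs) {
  stopifnot(is(rec, "EEGRecording"))
  missing <- setdiff(targetLabels, rec@labels)
  if (length(missing)) {
    stop("metadata error: channels absent from recording: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (targetFs > rec@fs) stop("targetFs must not exceed fs", call. = FALSE)
  idx <- match(targetLabels, rec@labels)
  data <- rec@data[idx, , drop = FALSE]
  if (abs(targetFs - rec@fs) > 1e-12) {
    data <- t(apply(data, 1, .fftResample, targetFs = targetFs, fs = rec@fs))
  }
  data <- sweep(data, 2, colMeans(data))
  EEGRecording(data, fs = targetFs, labels = targetLabels,
               subjectId = rec@subjectId, group = rec@group)
}
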