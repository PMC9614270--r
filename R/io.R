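#' Read a multichannel EEG recording
#'
#' Reads either the plain-text matrix interchange format written by
#' \code{\link{writeEEGcsv}} (one row per channel, header line carrying the
#' sampling rate and channel labels) or a minimal EDF file as written by
#' \code{\link{writeEDF}}. Non-finite samples are rejected with the offending
#' channel and sample index named.
#'
#' @param path file to read.
#' @param format "csv" or "edf"; default guesses from the file extension.
#' @param channels channels that must be present; an input error names any
#'   missing one. NULL accepts whatever the file holds.
#' @return an \code{EEGRecording}.
#' @export
readEEG <- function(path, format = c("auto", "csv", "edf"), channels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input error: file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  rec <- if (format == "edf") readEDF(path) else readEEGcsv(path)
  if (!is.null(channels)) {
    missing <- setdiff(channels, rec@channelLabels)
    if (length(missing))
      stop("input error: ", path, " is missing channel(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    idx <- match(channels, rec@channelLabels)
    rec@signal <- rec@signal[idx, , drop = FALSE]
    rec@channelLabels <- channels
  }
  bad <- which(!is.finite(rec@signal), arr.ind = TRUE)
  if (nrow(bad))
    stop("input error: non-finite sample in ", path, " at channel ",
         rec@channelLabels[bad[1, 1]], ", sample ", bad[1, 2], call. = FALSE)
  rec
}

#' Write an EEG recording as a plain-text matrix
#'
#' One header line (\code{# podeeg fs=<Hz> patient=<id> channels=<labels>})
#' followed by one comma-separated row of samples per channel.
#'
#' @param rec an \code{EEGRecording}.
#' @param path output file.
#' @export
writeEEGcsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# podeeg fs=%.10g patient=%s channels=%s\n",
              rec@samplingRate, rec@patientId,
              paste(rec@channelLabels, collapse = ",")), file = con)
  for (i in seq_len(nrow(rec@signal)))
    cat(paste(formatC(rec@signal[i, ], format = "g", digits = 9),
              collapse = ","), "\n", sep = "", file = con)
  invisible(path)
}

readEEGcsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^# podeeg ", header))
    stop("input error: unreadable header in ", path, call. = FALSE)
  getField <- function(key) {
    m <- regmatches(header, regexec(paste0(key, "=([^ ]+)"), header))[[1]]
    if (length(m) < 2) stop("input error: header of ", path,
                            " lacks field ", key, call. = FALSE)
    m[2]
  }
  fs <- as.numeric(getField("fs"))
  labels <- strsplit(getField("channels"), ",")[[1]]
  pid <- getField("patient")
  lines <- readLines(path)[-1]
  if (length(lines) != length(labels))
    stop("input error: ", path, " is truncated: expected ", length(labels),
         " channel rows, found ", length(lines), call. = FALSE)
  sig <- do.call(rbind, lapply(lines, function(l) {
    tokens <- trimws(strsplit(l, ",", fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(tokens))
    # non-finite tokens (NA/NaN/Inf) pass through so the caller can name
    # their location; anything else is unparseable
    bad <- is.na(vals) & !toupper(tokens) %in% c("NA", "NAN", "INF", "-INF")
    if (any(bad))
      stop("input error: unparseable samples in ", path, call. = FALSE)
    vals
  }))
  new("EEGRecording", signal = sig, samplingRate = fs,
      channelLabels = labels, patientId = pid)
}

#' Write a recording as a minimal EDF file
#'
#' Standard EDF layout: 256-byte global header, 256 bytes per signal, then
#' 1-second data records of little-endian 16-bit integers. The signal is
#' truncated to whole seconds (EDF records are fixed-duration); the sampling
#' rate must be a whole number per second.
#'
#' @param rec an \code{EEGRecording} in microvolts.
#' @param path output file.
#' @export
writeEDF <- function(rec, path) {
  fs <- rec@samplingRate
  stopIfNot(abs(fs - round(fs)) < 1e-9, "EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec@signal)
  nrec <- ncol(rec@signal) %/% fs
  stopIfNot(nrec >= 1, "recording shorter than one EDF data record")
  x <- rec@signal[, seq_len(nrec * fs), drop = FALSE]
  physMax <- pmax(apply(abs(x), 1, max), 1e-6)
  pad <- function(s, n) {
    s <- substr(s, 1, n)
    paste0(s, strrep(" ", n - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad(rec@patientId, 80), pad("podeeg export", 80),
    pad("01.01.20", 8), pad("00.00.00", 8),
    pad(as.character(256 * (1 + ns)), 8), pad("", 44),
    pad(as.character(nrec), 8), pad("1", 8), pad(as.character(ns), 4),
    paste(vapply(rec@channelLabels, pad, "", n = 16), collapse = ""),
    strrep(pad("", 80), ns),
    strrep(pad("uV", 8), ns),
    paste(vapply(sprintf("%.6g", -physMax), pad, "", n = 8), collapse = ""),
    paste(vapply(sprintf("%.6g", physMax), pad, "", n = 8), collapse = ""),
    strrep(pad("-32768", 8), ns),
    strrep(pad("32767", 8), ns),
    strrep(pad("", 80), ns),
    strrep(pad(as.character(fs), 8), ns),
    strrep(pad("", 32), ns)
  ), con, eos = NULL)
  scale <- 65535 / (2 * physMax)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[ch, idx] + physMax[ch]) * scale[ch] - 32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0 || nchar(s, type = "bytes") < n)
      stop("input error: truncated EDF header in ", path, call. = FALSE)
    trimws(s)
  }
  rd(8)                       # version
  pid <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  durRec <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(nrec) || is.na(ns) || ns < 1)
    stop("input error: unreadable EDF header in ", path, call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  sig <- matrix(0, ns, nrec * spr[1])
  gain <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr[ch])
        stop("input error: truncated EDF data in ", path, call. = FALSE)
      sig[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        physMin[ch] + gain[ch] * (dig - digMin[ch])
    }
  }
  new("EEGRecording", signal = sig, samplingRate = spr[1] / durRec,
      channelLabels = labels, patientId = if (nzchar(pid)) pid else "unknown")
}

#' Read / write the per-cohort clinical table
#'
#' Tab-separated table with columns patient_id, age, asa, op_length,
#' benzodiazepine, induction_agent, maintenance_agent and (for training
#' cohorts) pod.
#'
#' @param x clinical data.frame.
#' @param path file path.
#' @export
writeClinicalTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeClinicalTable
#' @export
readClinicalTable <- function(path) {
  need <- c("patient_id", "age", "asa", "op_length", "benzodiazepine",
            "induction_agent", "maintenance_agent")
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("input error: clinical table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x
}

BUNDLE_VERSION <- "podeeg-bundle-1"

#' Save / load a trained model bundle
#'
#' A bundle holds a \code{GroupedModelSet} (or single \code{PodModelStack})
#' together with a configuration echo and version tag, and round-trips to
#' prediction-identical models.
#'
#' @param models the trained model object.
#' @param path bundle file path.
#' @param config configuration list echoed into the bundle.
#' @export
saveBundle <- function(models, path, config = list()) {
  saveRDS(list(version = BUNDLE_VERSION, models = models, config = config),
          path)
  invisible(path)
}

#' @rdname saveBundle
#' @export
loadBundle <- function(path) {
  if (!file.exists(path)) stop("input error: no bundle at ", path, call. = FALSE)
  b <- readRDS(path)
  if (!identical(b$version, BUNDLE_VERSION))
    stop("incompatible bundle version: found '", b$version, "', need '",
         BUNDLE_VERSION, "'", call. = FALSE)
  for (comp in c("models", "config"))
    if (!comp %in% names(b))
      stop("bundle is missing component '", comp, "'", call. = FALSE)
  if (is(b$models, "GroupedModelSet")) {
    for (g in names(b$models@stacks)) {
      st <- b$models@stacks[[g]]
      if (!is.null(st@covEnsemble) && is.null(st@covEnsemble@reference))
        stop("bundle is missing component 'covariance reference point' for group ",
             g, call. = FALSE)
    }
  }
  b
}
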