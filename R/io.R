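# On-disk fixture interface: WAV audio, TSV word boundaries, TSV EEG,
# JSON manifest. A written fixture round-trips through read_fixture().
# The WAV reader/writer is a minimal RIFF implementation (IEEE float-32 and
# PCM int16 chunks) because no WAV package is available in the dependency
# set; it covers exactly the subset this package writes.

#' Write a mono waveform to a WAV file
#'
#' @param x numeric samples.
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @param format `"float32"` (default) or `"int16"`.
#' @export
write_wav <- function(x, fs, path, format = c("float32", "int16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bytes_per <- if (format == "float32") 4L else 2L
  data_bytes <- n * bytes_per
  fmt_tag <- if (format == "float32") 3L else 1L

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, size = 4, endian = "little")
  writeBin(bytes_per, con, size = 2, endian = "little")
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file written by [write_wav()]
#'
#' @param path WAV path.
#' @return list with `samples` and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt_tag <- NULL; fs <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_tag <- readBin(con, integer(), size = 2, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt_tag)) stop("data chunk before fmt chunk")
      if (fmt_tag == 3 && bits == 32) {
        samples <- readBin(con, numeric(), n = size / 4, size = 4,
                           endian = "little")
      } else if (fmt_tag == 1 && bits == 16) {
        samples <- readBin(con, integer(), n = size / 2, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else {
        stop("unsupported WAV encoding (fmt ", fmt_tag, ", ", bits, " bit)")
      }
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(samples)) stop("no data chunk found")
  list(samples = samples, fs = fs)
}

#' Write word boundaries to TSV
#'
#' Columns: `word_index`, `onset_s`, `offset_s`, `token`.
#' @param word_boundaries tibble of boundaries.
#' @param path output path.
#' @export
write_boundaries_tsv <- function(word_boundaries, path) {
  wb <- tibble::as_tibble(word_boundaries)
  if (!"word_index" %in% names(wb)) wb$word_index <- seq_len(nrow(wb))
  if (!"token" %in% names(wb)) wb$token <- NA_character_
  utils::write.table(
    wb[, c("word_index", "onset_s", "offset_s", "token")],
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a word-boundary TSV
#' @param path TSV path with columns `word_index`, `onset_s`, `offset_s`,
#'   `token`.
#' @return tibble of boundaries.
#' @export
read_boundaries_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a simulated recording to disk
#'
#' Writes, under `dir`: `envelope.wav` (the broadband envelope as float-32
#' audio), `words.tsv` (word boundaries), `pauses.tsv` (pause intervals),
#' `eeg.tsv` (channels in columns, full double precision), and
#' `manifest.json` recording the sampling rates, identifiers, seed and
#' generator configuration. The fixture round-trips through
#' [read_fixture()]; re-running the generator from the manifest reproduces
#' the data.
#'
#' @param rec a recording as returned by [simulate_recording()].
#' @param dir output directory (created if needed).
#' @param config the [sim_config()] used (stored in the manifest).
#' @return the manifest, invisibly.
#' @export
write_fixture <- function(rec, dir, config = NULL) {
  if (is.null(rec$envelope) || is.null(rec$eeg) ||
      !length(rec$envelope$values) || !ncol(rec$eeg$data)) {
    stop("empty dataset: nothing to write")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_wav(rec$envelope$values, rec$envelope$fs,
            file.path(dir, "envelope.wav"))
  write_boundaries_tsv(rec$word_boundaries, file.path(dir, "words.tsv"))
  utils::write.table(rec$pause_intervals, file.path(dir, "pauses.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  eeg_df <- as.data.frame(t(rec$eeg$data))
  names(eeg_df) <- rec$eeg$channel_names
  utils::write.table(format(eeg_df, digits = 17, trim = TRUE, scientific = TRUE),
                     file.path(dir, "eeg.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    fs_env = rec$envelope$fs,
    fs_eeg = rec$eeg$fs,
    n_channels = nrow(rec$eeg$data),
    channel_names = rec$eeg$channel_names,
    subject = rec$subject,
    segment = rec$segment,
    condition = rec$condition,
    config = if (!is.null(config)) unclass(config) else NULL
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `envelope`, `eeg`, `word_boundaries`, `pause_intervals`,
#'   `manifest`.
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  wav <- read_wav(file.path(dir, "envelope.wav"))
  wb <- read_boundaries_tsv(file.path(dir, "words.tsv"))
  pauses <- tibble::as_tibble(utils::read.delim(file.path(dir, "pauses.tsv")))
  eeg_df <- utils::read.delim(file.path(dir, "eeg.tsv"), check.names = FALSE)
  eeg <- eeg_recording(t(as.matrix(eeg_df)), manifest$fs_eeg,
                       channel_names = manifest$channel_names,
                       subject_id = as.character(manifest$subject),
                       segment_id = manifest$segment,
                       condition = manifest$condition)
  list(
    envelope = envelope_series(pmax(wav$samples, 0), wav$fs,
                               band = "broadband"),
    eeg = eeg,
    word_boundaries = wb,
    pause_intervals = pauses,
    manifest = manifest
  )
}
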