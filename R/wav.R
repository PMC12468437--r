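# Minimal RIFF/WAVE I/O for 16-bit PCM mono audio.
#
# Heart-sound corpora ship as plain 16-bit PCM mono WAV; the reader walks
# the RIFF chunk list (some encoders insert LIST/fact chunks before data)
# and refuses anything that is not mono integer PCM.

WAV_PCM_SCALE <- 32767

#' Read a mono 16-bit PCM WAV file
#'
#' @param path path to a RIFF/WAVE file containing mono 16-bit PCM audio.
#' @return a [pcg_recording] with samples rescaled to `[-1, 1]`.  Label and
#'   condition are `NA`; attach them from the manifest.
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    stop_pcg("WAV file not found: %s", path, class = "pcgnet_io_error")
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop_pcg("%s is not a RIFF/WAVE file", path, class = "pcgnet_unsupported_format")

  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; audio_format <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", n = size + size %% 2)
      u16 <- function(off) sum(as.integer(body[off + 1:2]) * c(1L, 256L))
      u32 <- function(off) sum(as.double(body[off + 1:4]) * c(1, 256, 65536, 16777216))
      audio_format <- u16(0)
      n_channels   <- u16(2)
      sample_rate  <- u32(4)
      bits         <- u16(14)
    } else if (identical(id, "data")) {
      if (is.null(bits))
        stop_pcg("malformed WAV: data chunk before fmt", class = "pcgnet_unsupported_format")
      samples <- readBin(con, "integer", n = size / 2, size = 2,
                         signed = TRUE, endian = "little")
      break
    } else {
      seek(con, where = size + size %% 2, origin = "current")
    }
  }
  if (is.null(samples))
    stop_pcg("no data chunk found in %s", path, class = "pcgnet_unsupported_format")
  if (audio_format != 1L)
    stop_pcg("unsupported WAV encoding (format tag %d); only integer PCM is supported",
             audio_format, class = "pcgnet_unsupported_format")
  if (n_channels != 1L)
    stop_pcg("unsupported channel count %d; only mono is supported",
             n_channels, class = "pcgnet_unsupported_format")
  if (bits != 16L)
    stop_pcg("unsupported bit depth %d; only 16-bit PCM is supported",
             bits, class = "pcgnet_unsupported_format")

  pcg_recording(samples = samples / WAV_PCM_SCALE, sample_rate = sample_rate,
                label = NA_character_, condition = NA_character_,
                cycle_onsets = numeric(0), seed = NA_integer_)
}

#' Write a recording as a mono 16-bit PCM WAV file
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16-bit integers, so a
#' write/read round trip agrees with the original within one quantization
#' step (`2^-15`).
#'
#' @param recording a [pcg_recording] (or any list with `samples` and
#'   `sample_rate`).
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop_pcg("directory does not exist: %s", dir, class = "pcgnet_io_error")
  x <- pmin(1, pmax(-1, recording$samples))
  pcm <- as.integer(round(x * WAV_PCM_SCALE))
  sr <- as.integer(recording$sample_rate)
  n <- length(pcm)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
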