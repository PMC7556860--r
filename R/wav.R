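#' Write a waveform to a RIFF/WAV file
#'
#' Writes PCM 24-bit integer or IEEE float32 WAV. Sample values are written
#' as-is (full-scale normalized); multi-channel waveforms use one channel
#' per matrix column.
#'
#' @param wave a [waveform()].
#' @param path output file path.
#' @param format `"pcm24"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, format = c("pcm24", "float32")) {
  format <- match.arg(format)
  x <- wave$samples
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n_ch <- ncol(x); n <- nrow(x)
  fs <- as.integer(round(wave$fs))
  bits <- if (format == "pcm24") 24L else 32L
  fmt_code <- if (format == "pcm24") 1L else 3L
  block <- n_ch * bits / 8L
  byte_rate <- fs * block
  data_size <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  inter <- as.numeric(t(x))          # interleave channels
  if (format == "float32") {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    v <- as.integer(round(pmax(pmin(inter, 1), -1) * (2^23 - 1)))
    neg <- v < 0
    v[neg] <- v[neg] + 2^24
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' Supports mono/multichannel PCM-24 and float32 RIFF files.
#'
#' @param path file path.
#' @return A [waveform()] (level metadata is not stored in WAV and comes
#'   back as `NA`).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  fmt_code <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4)
    if (length(id_raw) < 4) stop("no data chunk found")
    id <- rawToChar(id_raw)
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, "integer", 1, 2, endian = "little")
      n_ch <- readBin(con, "integer", 1, 2, endian = "little")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("data chunk before fmt chunk")
      if (fmt_code == 3L && bits == 32L) {
        inter <- readBin(con, "numeric", sz / 4, size = 4, endian = "little")
      } else if (fmt_code == 1L && bits == 24L) {
        raw3 <- readBin(con, "raw", sz)
        b <- matrix(as.integer(raw3), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v[v >= 2^23] <- v[v >= 2^23] - 2^24
        inter <- v / (2^23 - 1)
      } else stop("unsupported WAV format")
      x <- matrix(inter, ncol = n_ch, byrow = TRUE)
      if (n_ch == 1) x <- drop(x)
      tag <- if (n_ch > 1) "binaural" else "target-ear"
      return(waveform(x, fs = fs, level_spl = NA_real_, channel_tag = tag))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}

#' Canonical stimulus file name
#'
#' `<task>_<fc>_<fm>_<depth>_<seed>.wav`, the naming scheme used for
#' exported stimuli.
#'
#' @param task task label (e.g. `"fm"`, `"am"`, `"dyad"`).
#' @param fc carrier (or center) frequency, Hz.
#' @param fm modulation rate, Hz.
#' @param depth modulation depth (task units).
#' @param seed integer seed used for the rendering.
#' @return file name string.
#' @export
stimulus_filename <- function(task, fc, fm, depth, seed) {
  sprintf("%s_%g_%g_%g_%d.wav", task, fc, fm, depth, as.integer(seed))
}
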