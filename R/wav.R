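#' Write a PCM WAV file
#'
#' Minimal RIFF/WAVE writer for 16- or 24-bit integer PCM, the formats used
#' by long-term hydrophone recorders. Samples are clipped to `[-1, 1]` full
#' scale before quantisation.
#'
#' @param x numeric vector (mono) or matrix with one column per channel,
#'   values in `[-1, 1]` full scale.
#' @param fs sample rate in Hz.
#' @param path output file path.
#' @param bits bit depth, 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, fs, path, bits = 16) {
  if (!bits %in% c(16L, 24L)) stop("bits must be 16 or 24")
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n_ch <- ncol(x)
  n <- nrow(x)
  x <- pmin(pmax(x, -1), 1)
  block_align <- n_ch * bits / 8L
  data_size <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")      # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  interleaved <- as.numeric(t(x))          # frame-major
  if (bits == 16L) {
    v <- as.integer(round(interleaved * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- round(interleaved * 8388607)
    v <- ifelse(v < 0, v + 16777216, v)    # two's complement, 24 bit
    b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
    writeBin(as.raw(as.vector(b)), con)
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' @param path file path.
#' @return list with `data` (samples x channels matrix, full scale
#'   `[-1, 1]`), `fs` (Hz), and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; n_ch <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      n_ch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      extra <- size - 16
      if (extra > 0) readBin(con, raw(), n = extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), n = size)
      break
    } else {
      readBin(con, raw(), n = size + size %% 2)
    }
  }
  if (is.null(fs) || is.null(data_raw)) stop("malformed WAV: ", path)
  if (bits == 16L) {
    v <- readBin(data_raw, integer(), n = length(data_raw) / 2,
                 size = 2, signed = TRUE, endian = "little")
    x <- v / 32767
  } else if (bits == 24L) {
    b <- as.integer(data_raw)
    n3 <- length(b) %/% 3
    dim(b) <- c(3, n3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388607
  } else stop("unsupported bit depth: ", bits)
  list(data = matrix(x, ncol = n_ch, byrow = TRUE), fs = fs, bits = bits)
}
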