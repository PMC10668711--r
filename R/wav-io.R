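#' Multichannel WAV I/O (32-bit float)
#'
#' Minimal RIFF/WAVE reader and writer for IEEE float32 PCM, the format used
#' for simulated microphone-array recordings (64 interleaved channels by
#' default). `read_wav()` returns the samples-by-channels matrix and the
#' sample rate; `write_wav()` is its inverse.
#'
#' @param path file path
#' @param x samples-by-channels numeric matrix
#' @param fs sample rate (Hz)
#' @return `read_wav()`: list with `x` (matrix) and `fs`; `write_wav()`:
#'   `path`, invisibly
#' @export
write_wav <- function(x, fs, path) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n_ch <- ncol(x); n <- nrow(x)
  data_bytes <- n * n_ch * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")        # IEEE float
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * n_ch * 4L), con, size = 4, endian = "little")
  writeBin(as.integer(n_ch * 4L), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")       # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(as.numeric(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop(path, ": not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop(path, ": not a WAVE file")
  fs <- NULL; n_ch <- NULL; fmt <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) stop(path, ": no data chunk found")
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1, 2, endian = "little")
      n_ch <- readBin(con, "integer", 1, 2, endian = "little")
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little"))  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little")
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop(path, ": data chunk before fmt chunk")
      if (fmt != 3L || bits != 32L)
        stop(path, ": only 32-bit float WAV is supported")
      vals <- readBin(con, "numeric", sz / 4L, size = 4, endian = "little")
      x <- matrix(vals, ncol = n_ch, byrow = TRUE)
      return(list(x = x, fs = fs))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
  }
}
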