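# Minimal EDF (European Data Format) writer/reader: fixed-layout ASCII
# header + 16-bit little-endian integer data records. One data record per
# epoch for epoched recordings. Physical scaling is per-channel min/max.

pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one data record per epoch. Samples are quantized to the
#' per-channel physical range; round-tripping is exact up to that
#' quantization.
#'
#' @param rec an `epoched_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "epoched_recording"))
  d <- dim(rec$data)
  C <- d[1]; n <- d[2]; E <- d[3]
  labels <- if (!is.null(rec$montage)) rec$montage$labels else
    paste0("Ch", seq_len(C))
  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80),
    pad(paste("Startdate 01-JAN-2000 ganznet synthetic", sep = ""), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + 256 * C, 8), pad("", 44), pad(E, 8),
    pad(format(n / rec$fs, digits = 8), 8), pad(C, 4))
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(labels, pad, "", 16), collapse = ""),
    paste(rep(pad("", 80), C), collapse = ""),
    paste(rep(pad("uV", 8), C), collapse = ""),
    paste(vapply(phys_min, function(v) pad(formatC(v, digits = 6,
                                                   format = "g"), 8), ""),
          collapse = ""),
    paste(vapply(phys_max, function(v) pad(formatC(v, digits = 6,
                                                   format = "g"), 8), ""),
          collapse = ""),
    paste(rep(pad(-32768, 8), C), collapse = ""),
    paste(rep(pad(32767, 8), C), collapse = ""),
    paste(rep(pad("", 80), C), collapse = ""),
    paste(rep(pad(n, 8), C), collapse = ""),
    paste(rep(pad("", 32), C), collapse = ""))
  writeChar(sig, con, eos = NULL)
  for (e in seq_len(E)) {
    for (ci in seq_len(C)) {
      x <- rec$data[ci, , e]
      dig <- round(-32768 + (x - phys_min[ci]) /
                     (phys_max[ci] - phys_min[ci]) * 65535)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads 16-bit EDF written by [write_edf()] (or any EDF with a uniform
#' sampling rate across signals), returning each data record as one epoch.
#'
#' @param path EDF file path.
#' @param montage optional [montage_spec] to attach and validate against
#'   the stored labels.
#' @return an `epoched_recording`.
#' @export
read_edf <- function(path, montage = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) stop("not an EDF file (short header): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    raw <- readChar(con, width, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < width)
      stop("truncated EDF header at byte ", seek(con), " in ", path)
    trimws(raw)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  labels <- vapply(seq_len(C), function(i) rd(16), "")
  for (i in seq_len(C)) rd(80)               # transducer
  for (i in seq_len(C)) rd(8)                # phys dim
  phys_min <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(C), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(C)) rd(80)               # prefiltering
  spr <- vapply(seq_len(C), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(C)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  n <- spr[1]
  fs <- n / dur
  expected <- 2 * as.numeric(n_rec) * C * n
  have <- sz - (256 + 256 * C)
  if (have < expected)
    stop("truncated EDF data: expected ", expected, " bytes after header, ",
         "found ", have, " (offset ", 256 + 256 * C + have, ")")
  data <- array(0, dim = c(C, n, n_rec), dimnames = list(labels, NULL, NULL))
  for (e in seq_len(n_rec)) {
    for (ci in seq_len(C)) {
      dig <- readBin(con, "integer", n = n, size = 2, endian = "little",
                     signed = TRUE)
      data[ci, , e] <- phys_min[ci] + (dig - dig_min[ci]) /
        (dig_max[ci] - dig_min[ci]) * (phys_max[ci] - phys_min[ci])
    }
  }
  if (!is.null(montage)) {
    bad <- setdiff(labels, montage$labels)
    extra <- setdiff(montage$labels, labels)
    if (length(bad) || length(extra))
      stop("channel labels do not match the montage; offending labels: ",
           paste(c(bad, extra), collapse = ", "))
    data <- data[match(montage$labels, labels), , , drop = FALSE]
  }
  structure(list(data = data, fs = fs,
                 montage = montage %||% montage_spec(labels),
                 condition = list(), group = NA_character_),
            class = "epoched_recording")
}
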