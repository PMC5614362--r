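#' Read an MRC volume
#'
#' Minimal reader for the standard MRC2014 layout: 1024-byte header followed
#' by the voxel block. Modes 0 (int8), 1 (int16) and 2 (float32) are
#' supported; data are returned as a numeric array in `(z, y, x)` order
#' (the file stores x fastest). Little-endian files only, which is what
#' practically all tomography packages emit.
#'
#' @param path path to an `.mrc`/`.rec` file.
#' @return numeric 3D array indexed `(z, y, x)`.
#' @seealso [write_mrc()], [load_volume()]
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  if (nx <= 0 || ny <= 0 || nz <= 0)
    stop("invalid MRC header: non-positive dimensions")
  seek(con, 1024)
  n <- nx * ny * nz
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode)
  )
  if (length(vals) < n) stop("truncated MRC file: ", path)
  a <- array(vals, dim = c(nx, ny, nz))
  aperm(a, c(3, 2, 1))
}

#' Write an MRC volume
#'
#' Writes a `(z, y, x)` array as a little-endian MRC file with a standard
#' 1024-byte header. `mode = 2` (float32) is lossless to single precision;
#' modes 0/1 round to the nearest representable integer.
#'
#' @param data numeric 3D array indexed `(z, y, x)`.
#' @param path output path.
#' @param mode on-disk numeric mode: 0 (int8), 1 (int16) or 2 (float32).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path, mode = 2) {
  stopifnot(length(dim(data)) == 3, mode %in% c(0, 1, 2))
  d <- dim(data) # (z, y, x)
  con <- file(path, "wb")
  on.exit(close(con))
  nx <- d[3]; ny <- d[2]; nz <- d[1]
  writeBin(as.integer(c(nx, ny, nz, mode, 0L, 0L, 0L, nx, ny, nz)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz, 90, 90, 90)), con, size = 4,
           endian = "little")                       # cella, cellb
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(data), max(data), mean(data))), con, size = 4,
           endian = "little")                       # dmin dmax dmean
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little")
  writeBin(raw(100), con)                           # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little") # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(data)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")    # nlabl
  writeBin(raw(800), con)                           # labels
  x_fastest <- aperm(data, c(3, 2, 1))
  if (mode == 2) {
    writeBin(as.numeric(x_fastest), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(x_fastest)), con, size = ifelse(mode == 0, 1, 2),
             endian = "little")
  }
  invisible(path)
}
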