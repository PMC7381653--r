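# MRC2014 image/volume I/O (mode 2, 32-bit float), little-endian.
# Data layout: column-major with x fastest, matching R array indexing, so a
# micrograph is a matrix with dim (nx, ny) and [i, j] = pixel (x = i, y = j).

#' Read an MRC2014 image or volume
#'
#' Supports mode 0 (int8), 1 (int16), 2 (float32) and 6 (uint16); the
#' standard 1024-byte header plus any extended header is consumed, and the
#' "MAP " magic is required.
#'
#' @param path file path.
#' @return list with \code{data} (matrix or 3D array) and
#'   \code{voxel_size} (Angstrom per pixel, length 3).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  cella <- hdr_num[11:13]
  nsymbt <- hdr_int[24]
  seek(con, 52 * 4)
  magic <- readBin(con, "raw", n = 4)
  if (!identical(rawToChar(magic), "MAP "))
    stop("not an MRC2014 file (missing MAP magic): ", path)
  if (any(c(nx, ny, nz) <= 0)) stop("invalid MRC dimensions")
  npix <- as.numeric(nx) * ny * nz
  seek(con, 1024 + nsymbt)
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = npix, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = npix, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = npix, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = npix, size = 2,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode: ", mode))
  if (length(data) < npix)
    stop("truncated MRC file: expected ", npix, " pixels, got ",
         length(data))
  dim(data) <- if (nz > 1) c(nx, ny, nz) else c(nx, ny)
  grid <- c(max(mx, 1), max(my, 1), max(mz, 1))
  voxel_size <- ifelse(cella > 0, cella / grid, 1)
  list(data = data, voxel_size = voxel_size)
}

#' Write an MRC2014 image or volume
#'
#' Always writes mode 2 (32-bit float) with the voxel size recorded in the
#' cell dimensions.
#'
#' @param data matrix (image) or 3D array (volume).
#' @param voxel_size Angstrom per pixel; scalar or length 3.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_mrc <- function(data, voxel_size, path) {
  d <- dim(data)
  if (is.null(d) || length(d) < 2 || length(d) > 3)
    stop("data must be a 2D matrix or 3D array")
  if (length(d) == 2) d <- c(d, 1L)
  voxel_size <- rep_len(voxel_size, 3)
  stopifnot(all(voxel_size > 0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  v <- as.numeric(data)
  wi(d)                      # nx ny nz
  wi(2)                      # mode 2: float32
  wi(c(0, 0, 0))             # nxstart nystart nzstart
  wi(d)                      # mx my mz
  wf(d * voxel_size)         # cella
  wf(c(90, 90, 90))          # cellb
  wi(c(1, 2, 3))             # mapc mapr maps
  wf(c(min(v), max(v), mean(v)))   # dmin dmax dmean
  wi(if (d[3] > 1) 1 else 0) # ispg
  wi(0)                      # nsymbt
  wi(rep(0, 25))             # extra
  wf(c(0, 0, 0))             # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machst: little-endian
  wf(stats::sd(v))           # rms
  wi(0)                      # nlabl
  writeBin(raw(800), con)    # labels
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}
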