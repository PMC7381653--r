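# Readers/writers for the on-disk artifacts of a tilt-series workflow:
# IMOD .tlt / .xf, Dynamo-style particle tables, STAR metadata and MRC2014.

#' Read an IMOD .tlt file
#'
#' One tilt angle (degrees) per line, in stack order.
#'
#' @param path file path.
#' @return numeric vector of angles in file order.
#' @export
read_tlt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty .tlt file: ", path)
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals))
    stop("malformed .tlt line ", which(is.na(vals))[1], " in ", path)
  vals
}

#' Write an IMOD .tlt file
#' @param angles numeric vector of tilt angles (degrees).
#' @param path file path.
#' @export
write_tlt <- function(angles, path) {
  writeLines(sprintf("%10.2f", angles), path)
  invisible(path)
}

#' Read an IMOD .xf transform file
#'
#' Each line holds six numbers \code{a11 a12 a21 a22 dx dy}: a row-major 2x2
#' affine matrix plus a shift, mapping raw micrograph coordinates into the
#' aligned stack.
#'
#' @param path file path.
#' @return list of \code{list(A = 2x2 matrix, shift = length-2 numeric)}.
#' @export
read_xf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
    if (length(f) != 6 || anyNA(f))
      stop("malformed .xf line ", i, ": expected 6 numbers")
    list(A = matrix(f[1:4], 2, 2, byrow = TRUE), shift = f[5:6])
  })
}

#' Write an IMOD .xf transform file
#' @param xf list of \code{list(A, shift)} records.
#' @param path file path.
#' @export
write_xf <- function(xf, path) {
  writeLines(vapply(xf, function(r) {
    sprintf("%12.7f %11.7f %11.7f %11.7f %11.3f %11.3f",
            r$A[1, 1], r$A[1, 2], r$A[2, 1], r$A[2, 2],
            r$shift[1], r$shift[2])
  }, character(1)), path)
  invisible(path)
}

#' Assemble a tilt-series alignment
#'
#' Pairs the per-image tilt angles (.tlt) and in-plane affines (.xf) with
#' the stack geometry linking tomogram voxels to micrograph pixels.
#'
#' @param angles numeric vector of tilt angles (degrees), stack order.
#' @param xf list of \code{list(A, shift)} records, same order.
#' @param image_size length-2 integer, micrograph size in pixels.
#' @param tomogram_size length-3 integer, tomogram size in voxels.
#' @param binning micrograph pixels per tomogram voxel edge (>= 1 typical).
#' @return object of class \code{tilt_alignment}.
#' @export
tilt_alignment <- function(angles, xf, image_size, tomogram_size,
                           binning = 1) {
  if (length(angles) != length(xf))
    stop("number of .xf records (", length(xf),
         ") != number of tilt angles (", length(angles), ")")
  for (i in seq_along(xf))
    if (abs(det(xf[[i]]$A)) < 1e-6)
      stop("singular in-plane affine at image ", i)
  stopifnot(length(image_size) == 2, length(tomogram_size) == 3,
            binning > 0)
  structure(list(angles = angles, xf = xf,
                 image_size = as.numeric(image_size),
                 tomogram_size = as.numeric(tomogram_size),
                 binning = binning),
            class = "tilt_alignment")
}

#' @export
print.tilt_alignment <- function(x, ...) {
  cat("tilt_alignment:", length(x$angles), "images,",
      "range", min(x$angles), "to", max(x$angles), "deg\n")
  cat("  micrograph", paste(x$image_size, collapse = " x "),
      "px; tomogram", paste(x$tomogram_size, collapse = " x "),
      "voxels; binning", x$binning, "\n")
  invisible(x)
}

#' Index of the zero-tilt image in an alignment
#'
#' @param align a \code{tilt_alignment}.
#' @param tol tolerance in degrees for "zero" (default 0.5).
#' @return integer index.
#' @export
zero_tilt_index <- function(align, tol = 0.5) {
  i <- which(abs(align$angles) < tol)
  if (length(i) == 0)
    stop("no zero-tilt image in alignment (|angle| < ", tol, " deg)")
  if (length(i) > 1)
    stop("multiple candidate zero-tilt images: ",
         paste(i, collapse = ", "))
  i
}

# Dynamo table column convention used here:
#   1 tag, 2 aligned, 3 averaged, 4:6 dx dy dz (shifts, voxels),
#   7:9 tdrot tilt narot (ZXZ degrees), 10 cc score, 24:26 x y z
#   (particle position, 1-based tomogram voxels).
.tbl_names <- function(ncol) {
  nm <- paste0("c", seq_len(ncol))
  nm[1] <- "tag"; nm[4:6] <- c("dx", "dy", "dz")
  nm[7:9] <- c("tdrot", "tilt", "narot"); nm[10] <- "score"
  nm[24:26] <- c("x", "y", "z")
  nm
}

#' Read a Dynamo-style particle table
#'
#' Whitespace-delimited numeric table, one subtomogram per row, with at
#' least 26 columns. Named accessors are attached for tag (col 1), shifts
#' (4-6), ZXZ Euler angles tdrot/tilt/narot (7-9), cross-correlation score
#' (10) and tomogram position x/y/z (24-26, 1-based voxels). Any extra
#' columns are preserved opaquely and survive a round trip.
#'
#' @param path file path.
#' @return data.frame of class \code{c("dynamo_table", "data.frame")}.
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty particle table: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
    if (anyNA(f)) stop("non-numeric field in table row ", i)
    if (length(f) < 26)
      stop("table row ", i, " has ", length(f),
           " columns; at least 26 required")
    f
  })
  nc <- length(rows[[1]])
  if (any(vapply(rows, length, integer(1)) != nc))
    stop("ragged particle table: rows differ in column count")
  m <- do.call(rbind, rows)
  df <- as.data.frame(m)
  names(df) <- .tbl_names(nc)
  df$tag <- as.integer(df$tag)
  class(df) <- c("dynamo_table", "data.frame")
  df
}

#' Write a Dynamo-style particle table
#' @param table data.frame as returned by \code{\link{read_particle_table}}.
#' @param path file path.
#' @export
write_particle_table <- function(table, path) {
  stopifnot(is.data.frame(table), ncol(table) >= 26)
  m <- as.matrix(as.data.frame(table))
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.6g", r), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an in-memory particle table
#'
#' Builds a minimal 26-column Dynamo-convention table from positions,
#' shifts and ZXZ Euler angles (all other columns zero).
#'
#' @param positions n x 3 matrix, 1-based tomogram voxels.
#' @param shifts n x 3 matrix of refinement shifts (voxels); default 0.
#' @param eulers n x 3 matrix of (tdrot, tilt, narot) degrees; default 0.
#' @param tags integer ids; default 1..n.
#' @param score cross-correlation scores; default 0.
#' @return \code{dynamo_table} data.frame.
#' @export
particle_table <- function(positions, shifts = NULL, eulers = NULL,
                           tags = NULL, score = 0) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (is.null(shifts)) shifts <- matrix(0, n, 3)
  if (is.null(eulers)) eulers <- matrix(0, n, 3)
  if (is.null(tags)) tags <- seq_len(n)
  m <- matrix(0, n, 26)
  m[, 1] <- tags; m[, 2] <- 1; m[, 3] <- 1
  m[, 4:6] <- rbind(shifts); m[, 7:9] <- rbind(eulers)
  m[, 10] <- score; m[, 24:26] <- positions
  df <- as.data.frame(m)
  names(df) <- .tbl_names(26)
  df$tag <- as.integer(df$tag)
  class(df) <- c("dynamo_table", "data.frame")
  df
}
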