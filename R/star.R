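# Minimal STAR (Self-defining Text Archive and Retrieval) I/O for particle
# metadata: named data blocks, loop_ tables, '_tag value' scalar blocks.

#' Read a STAR file
#'
#' Parses every \code{data_} block into a data.frame (for \code{loop_}
#' tables) or a named list (for scalar tag/value blocks). Column names keep
#' the leading underscore stripped.
#'
#' @param path file path.
#' @return named list of data.frames / lists, one per data block.
#' @export
read_star <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  blocks <- list()
  i <- 1; n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "data_")) { i <- i + 1; next }
    bname <- sub("^data_", "", lines[i])
    if (!nzchar(bname)) bname <- sprintf("block%d", length(blocks) + 1)
    i <- i + 1
    if (i <= n && lines[i] == "loop_") {
      i <- i + 1
      cols <- character()
      while (i <= n && startsWith(lines[i], "_")) {
        cols <- c(cols, sub("^_", "", strsplit(lines[i], "\\s+")[[1]][1]))
        i <- i + 1
      }
      rows <- list()
      while (i <= n && !startsWith(lines[i], "data_") &&
             !startsWith(lines[i], "loop_")) {
        f <- strsplit(lines[i], "\\s+")[[1]]
        if (length(f) != length(cols))
          stop("STAR row has ", length(f), " fields; expected ",
               length(cols))
        rows[[length(rows) + 1L]] <- f
        i <- i + 1
      }
      m <- do.call(rbind, rows)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- cols
      for (j in seq_along(df)) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        if (!anyNA(v)) df[[j]] <- v
      }
      blocks[[bname]] <- df
    } else {
      kv <- list()
      while (i <= n && startsWith(lines[i], "_")) {
        f <- strsplit(lines[i], "\\s+")[[1]]
        key <- sub("^_", "", f[1])
        val <- paste(f[-1], collapse = " ")
        vn <- suppressWarnings(as.numeric(val))
        kv[[key]] <- if (!is.na(vn)) vn else val
        i <- i + 1
      }
      blocks[[bname]] <- kv
    }
  }
  blocks
}

.star_fmt <- function(x) {
  if (is.numeric(x)) {
    out <- ifelse(x == round(x) & abs(x) < 1e15,
                  sprintf("%d", as.integer(round(x))),
                  sprintf("%.6f", x))
    format(out, width = 12, justify = "right")
  } else format(as.character(x), width = 12, justify = "right")
}

.write_star_loop <- function(con, name, df) {
  writeLines(c(paste0("data_", name), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  cols <- lapply(df, .star_fmt)
  writeLines(do.call(paste, cols), con)
  writeLines("", con)
}

#' Write exported particles as a STAR file
#'
#' Uses the modern two-block dialect: a \code{data_optics} table holding the
#' microscope/CTF metadata shared by all particles of the tomogram (one
#' optics group), and a \code{data_particles} table with per-particle
#' coordinates (0-based pixels), ZYZ Euler angles, per-particle defocus,
#' micrograph name and half-set membership. Output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param particles data.frame from \code{\link{export_particles}}.
#' @param optics a \code{\link{ctf_model}} supplying voltage, Cs, amplitude
#'   contrast and pixel size.
#' @param path file path.
#' @param optics_group integer optics-group id (default 1).
#' @return the path, invisibly.
#' @export
write_star <- function(particles, optics, path, optics_group = 1L) {
  if (!is.data.frame(particles) || nrow(particles) == 0)
    stop("empty particle list")
  stopifnot(inherits(optics, "ctf_model"))
  odf <- data.frame(
    rlnOpticsGroup = optics_group,
    rlnOpticsGroupName = sprintf("opticsGroup%d", optics_group),
    rlnVoltage = optics$voltage,
    rlnSphericalAberration = optics$cs,
    rlnAmplitudeContrast = optics$amplitude_contrast,
    rlnMicrographPixelSize = optics$pixel_size,
    stringsAsFactors = FALSE)
  pdf <- data.frame(
    rlnCoordinateX = particles$coord_x,
    rlnCoordinateY = particles$coord_y,
    rlnAngleRot = particles$rot,
    rlnAngleTilt = particles$tilt,
    rlnAnglePsi = particles$psi,
    rlnDefocusU = particles$defocus_u,
    rlnDefocusV = particles$defocus_v,
    rlnDefocusAngle = particles$defocus_angle,
    rlnMicrographName = particles$micrograph,
    rlnRandomSubset = particles$halfset,
    rlnOpticsGroup = optics_group,
    hsParticleTag = particles$tag,
    hsZOffsetVoxels = particles$z_offset,
    stringsAsFactors = FALSE)
  if (!is.null(particles$origin_x)) {
    pdf$rlnOriginX <- particles$origin_x
    pdf$rlnOriginY <- particles$origin_y
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  .write_star_loop(con, "optics", odf)
  .write_star_loop(con, "particles", pdf)
  invisible(path)
}

#' Read back a particle STAR file into export form
#'
#' Inverse of \code{\link{write_star}} for the particle fields: returns a
#' data.frame with the same columns \code{\link{export_particles}} emits.
#'
#' @param path file path.
#' @return list with \code{particles} data.frame and \code{optics} list.
#' @export
read_star_particles <- function(path) {
  b <- read_star(path)
  if (is.null(b$particles)) stop("no data_particles block in ", path)
  p <- b$particles
  particles <- data.frame(
    tag = as.integer(p$hsParticleTag),
    coord_x = p$rlnCoordinateX, coord_y = p$rlnCoordinateY,
    rot = p$rlnAngleRot, tilt = p$rlnAngleTilt, psi = p$rlnAnglePsi,
    defocus_u = p$rlnDefocusU, defocus_v = p$rlnDefocusV,
    defocus_angle = p$rlnDefocusAngle,
    z_offset = p$hsZOffsetVoxels,
    halfset = as.integer(p$rlnRandomSubset),
    micrograph = p$rlnMicrographName,
    stringsAsFactors = FALSE)
  if (!is.null(p$rlnOriginX)) {
    particles$origin_x <- p$rlnOriginX
    particles$origin_y <- p$rlnOriginY
  }
  list(particles = particles, optics = as.list(b$optics))
}
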