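# 2D particle-box extraction from the high-dose micrograph and SPA-stack
# conditioning (background normalization, contrast inversion).

#' Extract 2D particle boxes from a micrograph
#'
#' Crops a square box around every exported particle coordinate. The box is
#' centred on the integer-rounded coordinate; the sub-pixel residual is
#' recorded in the particle's \code{origin_x/origin_y} fields (no
#' interpolation at extraction — the residual is handed to the downstream
#' refiner, standard SPA practice). With the 0-based pixel-centre
#' convention, a box of size \code{b} centred on integer coordinate
#' \code{i} covers pixels \code{i - b/2 .. i + b/2 - 1}, so the nominal
#' particle centre sits at local coordinate \code{b/2}. Boxes overlapping
#' the micrograph edge are rejected with a reason; every input particle
#' ends up in exactly one of stack or rejection list.
#'
#' @param micrograph numeric matrix, dim (nx, ny), 0-based coordinates.
#' @param particles data.frame from \code{\link{export_particles}} (columns
#'   \code{coord_x, coord_y, tag} at minimum).
#' @param box_size even box side length in pixels, smaller than the
#'   micrograph.
#' @return list of class \code{particle_stack}: \code{boxes} (list of
#'   matrices), \code{particles} (surviving records with origin offsets),
#'   \code{rejected} (tag + reason), \code{box_size}.
#' @export
extract_boxes <- function(micrograph, particles, box_size = 64) {
  stopifnot(is.matrix(micrograph), box_size %% 2 == 0)
  nx <- nrow(micrograph); ny <- ncol(micrograph)
  if (box_size >= min(nx, ny))
    stop("box_size (", box_size, ") must be smaller than the micrograph")
  h <- box_size / 2
  boxes <- list(); keep <- list(); rej <- list()
  for (k in seq_len(nrow(particles))) {
    p <- particles[k, ]
    ix <- round(p$coord_x); iy <- round(p$coord_y)
    x0 <- ix - h; y0 <- iy - h            # 0-based corner
    if (x0 < 0 || y0 < 0 || x0 + box_size > nx || y0 + box_size > ny) {
      rej[[length(rej) + 1L]] <- data.frame(
        tag = p$tag, reason = "box_overlaps_edge",
        stringsAsFactors = FALSE)
      next
    }
    box <- micrograph[(x0 + 1):(x0 + box_size), (y0 + 1):(y0 + box_size)]
    p$origin_x <- p$coord_x - ix
    p$origin_y <- p$coord_y - iy
    boxes[[length(boxes) + 1L]] <- box
    keep[[length(keep) + 1L]] <- p
  }
  structure(list(
    boxes = boxes,
    particles = if (length(keep)) do.call(rbind, keep) else data.frame(),
    rejected = if (length(rej)) do.call(rbind, rej) else
      data.frame(tag = integer(), reason = character(),
                 stringsAsFactors = FALSE),
    box_size = box_size), class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  cat("particle_stack:", length(x$boxes), "boxes of", x$box_size, "px;",
      nrow(x$rejected), "rejected\n")
  invisible(x)
}

#' Invert the contrast of a particle stack
#'
#' Negates every box; applying it twice restores the input.
#'
#' @param stack a \code{particle_stack}.
#' @return the stack with inverted boxes.
#' @export
invert_contrast <- function(stack) {
  stopifnot(inherits(stack, "particle_stack"))
  stack$boxes <- lapply(stack$boxes, function(b) -b)
  stack
}

#' Normalize particle boxes against their background annulus
#'
#' Standardizes each box so the annulus outside \code{background_radius}
#' (measured from the box centre) has mean 0 and standard deviation 1.
#' Boxes whose background has zero variance are flagged (attribute
#' \code{zero_variance}) and left unscaled rather than dividing by zero.
#'
#' @param stack a \code{particle_stack}.
#' @param background_radius radius in pixels, below \code{box_size/2}.
#' @return the stack with normalized boxes.
#' @export
normalize_boxes <- function(stack, background_radius) {
  stopifnot(inherits(stack, "particle_stack"),
            background_radius < stack$box_size / 2)
  b <- stack$box_size
  ctr <- b / 2           # 0-based box centre
  xs <- matrix(0:(b - 1), b, b) - ctr
  ys <- matrix(0:(b - 1), b, b, byrow = TRUE) - ctr
  annulus <- sqrt(xs^2 + ys^2) >= background_radius
  flags <- logical(length(stack$boxes))
  stack$boxes <- lapply(seq_along(stack$boxes), function(i) {
    box <- stack$boxes[[i]]
    bg <- box[annulus]
    s <- stats::sd(bg)
    if (!is.finite(s) || s == 0) {
      flags[i] <<- TRUE
      return(box - mean(bg))
    }
    (box - mean(bg)) / s
  })
  attr(stack, "zero_variance") <- flags
  stack
}
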