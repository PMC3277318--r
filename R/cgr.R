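# Chaos Game Representation: sequence -> point cloud in the unit square.

#' Default CGR corner assignment
#'
#' The standard genomics convention: A = (0,0), C = (0,1), G = (1,1),
#' T = (1,0).  Dq statistics are invariant to corner permutation (any
#' permutation is a symmetry of the square), so the choice only affects
#' the orientation of rendered images.
#'
#' @return A 4 x 2 numeric matrix with row names A, C, G, T and columns
#'   x, y.
#' @export
default_corners <- function() {
  matrix(c(0, 0, 0, 1, 1, 1, 1, 0), ncol = 2, byrow = TRUE,
         dimnames = list(c("A", "C", "G", "T"), c("x", "y")))
}

.check_corners <- function(corners) {
  if (!is.matrix(corners) || !identical(dim(corners), c(4L, 2L)) ||
      !setequal(rownames(corners), c("A", "C", "G", "T"))) {
    stop("'corners' must be a 4 x 2 matrix with row names A, C, G, T")
  }
  if (!all(corners %in% c(0, 1)) ||
      anyDuplicated(paste(corners[, 1], corners[, 2]))) {
    stop("'corners' must assign the four bases to the four distinct ",
         "unit-square corners")
  }
  corners[c("A", "C", "G", "T"), , drop = FALSE]
}

#' Chaos Game Representation of a DNA sequence
#'
#' Iterates the midpoint rule p <- (p + corner(base)) / 2 from
#' `start_point`, emitting one point per A/C/G/T base in sequence order.
#' N bases emit no point and leave the position unchanged (no reset: a
#' reset would inject start-point density artifacts).  No transient is
#' discarded; with fragment-scale inputs the transient is negligible and
#' the rule stays exactly reproducible.
#'
#' @param residues A residue string over \{A,C,G,T,N\} (case-insensitive).
#' @param corners Corner assignment, see [default_corners()].
#' @param start_point Numeric length-2 starting position (default the
#'   square's center).
#' @param fragment_id Optional label carried through to outputs.
#' @return An object of class `"cgr"`: a list with `fragment_id`,
#'   `points` (n x 2 matrix of coordinates in the unit square) and
#'   `n_points` (number of A/C/G/T bases consumed).
#' @examples
#' cgr_points("ACG")$points
#' @export
cgr_points <- function(residues, corners = default_corners(),
                       start_point = c(0.5, 0.5), fragment_id = NULL) {
  stopifnot(is.character(residues), length(residues) == 1L)
  corners <- .check_corners(corners)
  stopifnot(is.numeric(start_point), length(start_point) == 2L,
            all(start_point >= 0), all(start_point <= 1))
  if (nchar(residues) == 0L) {
    pts <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
    return(structure(list(fragment_id = fragment_id, points = pts,
                          n_points = 0L), class = "cgr"))
  }
  codes <- .encode_residues(residues)
  codes <- codes[codes <= 4L]          # drop N: no point, position unchanged
  if (length(codes) == 0L) {
    pts <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
    return(structure(list(fragment_id = fragment_id, points = pts,
                          n_points = 0L), class = "cgr"))
  }
  # p_t = p_{t-1}/2 + corner_t/2 is a linear recursion; stats::filter
  # (method "recursive") evaluates it in C.
  x <- as.numeric(stats::filter(corners[codes, 1] / 2, 0.5,
                                method = "recursive",
                                init = start_point[1]))
  y <- as.numeric(stats::filter(corners[codes, 2] / 2, 0.5,
                                method = "recursive",
                                init = start_point[2]))
  pts <- cbind(x = x, y = y)
  structure(list(fragment_id = fragment_id, points = pts,
                 n_points = nrow(pts)), class = "cgr")
}

#' @export
print.cgr <- function(x, ...) {
  cat("Chaos Game Representation",
      if (!is.null(x$fragment_id)) paste0(" [", x$fragment_id, "]"),
      "\n", sep = "")
  cat("  points:", x$n_points, "\n")
  if (x$n_points > 0L) {
    cat("  first point: (", format(x$points[1, 1]), ", ",
        format(x$points[1, 2]), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method plot cgr
plot.cgr <- function(x, pch = ".", cex = 1, ...) {
  graphics::plot(x$points, pch = pch, cex = cex, xlim = c(0, 1),
                 ylim = c(0, 1), asp = 1, xlab = "x", ylab = "y",
                 main = if (is.null(x$fragment_id)) "CGR" else x$fragment_id,
                 ...)
  invisible(x)
}

# Accept a cgr object, a 2-column point matrix, or a residue string.
.as_points <- function(x, corners = default_corners()) {
  if (inherits(x, "cgr")) return(x$points)
  if (is.matrix(x) && ncol(x) == 2L) return(x)
  if (is.character(x) && length(x) == 1L) return(cgr_points(x, corners)$points)
  stop("expected a 'cgr' object, a 2-column point matrix, ",
       "or a residue string")
}

#' CGR occupancy image
#'
#' Counts points per half-open grid cell
#' \[i/r, (i+1)/r) x \[j/r, (j+1)/r) at a power-of-two resolution;
#' coordinates exactly equal to 1 fall in the last cell.  The matrix is
#' indexed `[i + 1, j + 1]` with i the x-cell and j the y-cell index.
#'
#' @param point_set A `"cgr"` object (or 2-column point matrix).
#' @param resolution Cells per side; must be a power of two.
#' @return An integer `resolution` x `resolution` count matrix whose sum
#'   equals the number of points.
#' @export
cgr_occupancy_image <- function(point_set, resolution) {
  r <- as.integer(resolution)
  if (is.na(r) || r < 1L || bitwAnd(r, r - 1L) != 0L) {
    stop("'resolution' must be a power of two")
  }
  pts <- .as_points(point_set)
  if (nrow(pts) == 0L) {
    return(matrix(0L, nrow = r, ncol = r))
  }
  ix <- pmin(floor(pts[, 1] * r), r - 1L)
  iy <- pmin(floor(pts[, 2] * r), r - 1L)
  counts <- tabulate(iy * r + ix + 1, nbins = r * r)
  matrix(as.integer(counts), nrow = r, ncol = r)
}

#' Write CGR points as TSV
#'
#' @param point_set A `"cgr"` object.
#' @param path Output path; one `x<TAB>y` line per point, with header.
#' @return `path`, invisibly.
#' @export
write_cgr_points <- function(point_set, path) {
  stopifnot(inherits(point_set, "cgr"))
  utils::write.table(point_set$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
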