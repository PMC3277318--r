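# Box-counting estimation of the generalized dimension spectrum Dq.
#
# For box size eps = 2^-k the partition sum over occupied boxes is
#   S(q, eps) = sum_i (Mi / M0)^q ,
# and Dq is the least-squares slope of ln S(q, eps) against
# (q - 1) ln eps across the scale range.  q = 1 is handled by the entropy
# limit: D1 is the slope of sum_i (Mi/M0) ln(Mi/M0) against ln eps.
# Empty boxes are always excluded (mandatory for q < 0, where Mi = 0
# diverges).

.MAX_K <- 12L  # 4^12 cells = 16.8M tabulate bins; finer grids are never useful

#' Box occupancy of a point set
#'
#' Assigns each point to the half-open box
#' \[i 2^-k, (i+1) 2^-k) per axis (coordinate 1.0 goes to the last box)
#' and reports the per-box counts of the occupied boxes only.
#'
#' @param point_set A `"cgr"` object, 2-column point matrix, or residue
#'   string.
#' @param k Scale index >= 1; box size is 2^-k.
#' @return An object of class `"box_occupancy"`: list with `k`,
#'   `box_size`, `counts` (occupied-box point counts, all >= 1) and `m0`
#'   (total points).
#' @export
box_occupancy <- function(point_set, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("'k' must be an integer >= 1")
  if (k > .MAX_K) stop("'k' > ", .MAX_K, " is not supported")
  pts <- .as_points(point_set)
  if (nrow(pts) == 0L) {
    stop("empty point set: box occupancy (and the spectrum) is undefined")
  }
  r <- 2^k
  ix <- pmin(floor(pts[, 1] * r), r - 1)
  iy <- pmin(floor(pts[, 2] * r), r - 1)
  counts <- tabulate(ix * r + iy + 1, nbins = r * r)
  counts <- counts[counts > 0L]
  structure(list(k = k, box_size = 2^-k, counts = counts,
                 m0 = nrow(pts)), class = "box_occupancy")
}

#' @export
print.box_occupancy <- function(x, ...) {
  cat("Box occupancy at k =", x$k, "(box size", format(x$box_size), ")\n")
  cat("  occupied boxes:", length(x$counts), " points:", x$m0, "\n")
  invisible(x)
}

#' Partition sum of a box occupancy
#'
#' For q != 1 returns `sum((Mi/M0)^q)` over occupied boxes; for q = 1
#' returns the entropy numerator `sum((Mi/M0) * log(Mi/M0))` (natural
#' log), the q -> 1 limit case used by the information-dimension fit.
#'
#' @param occupancy A `"box_occupancy"` object.
#' @param q Moment order (any real).
#' @return A single number.
#' @export
partition_sum <- function(occupancy, q) {
  stopifnot(inherits(occupancy, "box_occupancy"), is.numeric(q),
            length(q) == 1L)
  lp <- log(occupancy$counts) - log(occupancy$m0)
  if (q == 1) sum(exp(lp) * lp) else exp(.lse(q * lp))
}

# ln S(q, eps) (or the entropy numerator at q = 1) for a list of
# occupancies; evaluated in log space so extreme q cannot overflow.
.fit_response <- function(occupancies, q) {
  vapply(occupancies, function(occ) {
    lp <- log(occ$counts) - log(occ$m0)
    if (q == 1) sum(exp(lp) * lp) else .lse(q * lp)
  }, numeric(1))
}

# OLS slope + squared correlation of y on x.
.slope_r2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else (sxy * sxy) / (sxx * syy)
  c(slope = slope, r2 = r2)
}

.dq_fit <- function(occupancies, q, k_range) {
  y <- .fit_response(occupancies, q)
  lneps <- -k_range * log(2)
  x <- if (q == 1) lneps else (q - 1) * lneps
  .slope_r2(x, y)
}

.check_degenerate <- function(occupancies) {
  finest <- occupancies[[length(occupancies)]]
  if (length(finest$counts) == 1L) {
    stop("all points fall in a single box at the finest scale ",
         "(coincident points?); the spectrum is undefined")
  }
}

#' Estimate a single generalized dimension
#'
#' Least-squares fit of the box-counting scaling law across
#' `k_range` scales (box sizes 2^-k).
#'
#' @param point_set A `"cgr"` object, 2-column point matrix, or residue
#'   string.
#' @param q Moment order.
#' @param k_range Integer scale indices (at least 3).
#' @return Named numeric vector `c(dq, fit_r2)` where `fit_r2` is the
#'   squared correlation of the fitted line.
#' @examples
#' pts <- cbind(runif(2000), runif(2000))
#' dq_estimate(pts, q = 2, k_range = 1:4)  # close to 2
#' @export
dq_estimate <- function(point_set, q, k_range = 1:6) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) stop("'k_range' must contain at least 3 scales")
  pts <- .as_points(point_set)
  occs <- lapply(k_range, function(k) box_occupancy(pts, k))
  .check_degenerate(occs)
  fit <- .dq_fit(occs, q, k_range)
  c(dq = unname(fit["slope"]), fit_r2 = unname(fit["r2"]))
}

#' Generalized dimension spectrum of a sequence or point set
#'
#' The package's central fitted object: estimates Dq for every requested
#' moment order by box counting over the CGR point cloud, and derives the
#' mass exponent tau(q) = (q - 1) Dq and the multifractality degree
#' delta_dq = max(Dq) - min(Dq).
#'
#' The default scale range k = 1..6 (coarsest grid 2x2, finest 64x64)
#' keeps the expected occupancy of the finest grid above roughly 70
#' points per box for 300-kb fragments; finer grids starve boxes and
#' corrupt the negative-q moments.  Increase `k_range` only for much
#' larger point sets.
#'
#' @param point_set A residue string, `"cgr"` object, or 2-column point
#'   matrix.
#' @param q Moment orders (default the integers -20..20; non-integer
#'   values are accepted).
#' @param k_range Integer scale indices used in the fit (>= 3 scales).
#' @param corners Corner assignment used when `point_set` is a residue
#'   string.
#' @param fragment_id Optional label carried into the result.
#' @return An object of class `"dq_spectrum"`: list with `q`, `dq`,
#'   `fit_r2`, `tau` (= (q-1) dq, exactly 0 at q = 1), `delta_dq`,
#'   `k_range`, `n_points`, `fragment_id`.  Methods: `print`, `summary`,
#'   `coef` (named Dq vector), `as.data.frame`, `plot`.
#' @examples
#' sp <- dq_spectrum(random_sequence(20000, seed = 1), q = -5:5, k_range = 1:4)
#' sp
#' coef(sp)[c("0", "1", "2")]
#' @export
dq_spectrum <- function(point_set, q = -20:20, k_range = 1:6,
                        corners = default_corners(), fragment_id = NULL) {
  stopifnot(is.numeric(q), length(q) >= 1L, !anyDuplicated(q))
  q <- sort(q)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) stop("'k_range' must contain at least 3 scales")
  if (is.null(fragment_id) && inherits(point_set, "cgr")) {
    fragment_id <- point_set$fragment_id
  }
  pts <- .as_points(point_set, corners)
  if (nrow(pts) == 0L) stop("empty point set: the spectrum is undefined")
  occs <- lapply(k_range, function(k) box_occupancy(pts, k))
  .check_degenerate(occs)
  fits <- vapply(q, function(qq) .dq_fit(occs, qq, k_range), numeric(2))
  dq <- unname(fits["slope", ])
  structure(list(
    q = q, dq = dq, fit_r2 = unname(fits["r2", ]),
    tau = (q - 1) * dq,
    delta_dq = max(dq) - min(dq),
    k_range = k_range, n_points = nrow(pts),
    fragment_id = fragment_id), class = "dq_spectrum")
}

#' @export
print.dq_spectrum <- function(x, ...) {
  cat("Generalized dimension spectrum",
      if (!is.null(x$fragment_id)) paste0(" [", x$fragment_id, "]"),
      "\n", sep = "")
  cat("  points: ", x$n_points, ";  scales k = ",
      paste(range(x$k_range), collapse = ".."),
      ";  q = ", paste(range(x$q), collapse = ".."), "\n", sep = "")
  show <- intersect(c(0, 1, 2), x$q)
  if (length(show) > 0L) {
    v <- x$dq[match(show, x$q)]
    cat("  ", paste(sprintf("D%g = %.4f", show, v), collapse = ",  "),
        "\n", sep = "")
  }
  cat("  multifractality degree (max Dq - min Dq): ",
      sprintf("%.4f", x$delta_dq), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary dq_spectrum
summary.dq_spectrum <- function(object, ...) {
  print(object)
  cat("  worst scaling fit r2 over q: ",
      sprintf("%.4f", min(object$fit_r2)), "\n", sep = "")
  invisible(as.data.frame(object))
}

#' @export
#' @method coef dq_spectrum
coef.dq_spectrum <- function(object, ...) {
  stats::setNames(object$dq, object$q)
}

#' @export
#' @method as.data.frame dq_spectrum
as.data.frame.dq_spectrum <- function(x, ...) {
  data.frame(q = x$q, dq = x$dq, fit_r2 = x$fit_r2, tau = x$tau)
}

#' @export
#' @method plot dq_spectrum
plot.dq_spectrum <- function(x, which = c("dq", "tau"), ...) {
  which <- match.arg(which)
  if (which == "dq") {
    graphics::plot(x$q, x$dq, type = "b", pch = 19, cex = 0.6,
                   xlab = "q", ylab = expression(D[q]),
                   main = if (is.null(x$fragment_id)) "Dq spectrum"
                          else x$fragment_id, ...)
  } else {
    graphics::plot(x$q, x$tau, type = "b", pch = 19, cex = 0.6,
                   xlab = "q", ylab = expression(tau(q)),
                   main = "mass exponent", ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}

#' Mass exponent curve tau(q)
#'
#' tau(q) = (q - 1) Dq; exactly 0 at q = 1.  Linear tau(q) is the
#' monofractal signature; curvature indicates multifractality.
#'
#' @param spectrum A `"dq_spectrum"` object.
#' @return A data frame with columns `q` and `tau`.
#' @export
tau_curve <- function(spectrum) {
  stopifnot(inherits(spectrum, "dq_spectrum"))
  data.frame(q = spectrum$q, tau = spectrum$tau)
}

#' Multifractality degree
#'
#' The spread max(Dq) - min(Dq) of an estimated spectrum; always >= 0.
#'
#' @param spectrum A `"dq_spectrum"` object.
#' @return A single non-negative number.
#' @export
delta_dq <- function(spectrum) {
  stopifnot(inherits(spectrum, "dq_spectrum"))
  spectrum$delta_dq
}

#' Spectra for every retained fragment
#'
#' Runs [cgr_points()] + [dq_spectrum()] on each non-removed fragment of a
#' fragment table.
#'
#' @param fragments Fragment table from [fragment_genome()].
#' @param q,k_range,corners Passed to [dq_spectrum()].
#' @return A named list of `"dq_spectrum"` objects keyed by fragment id.
#' @seealso [spectrum_summary()]
#' @export
fragment_spectra <- function(fragments, q = -20:20, k_range = 1:6,
                             corners = default_corners()) {
  frs <- retained_fragments(fragments)
  out <- lapply(seq_len(nrow(frs)), function(i) {
    dq_spectrum(cgr_points(frs$residues[i], corners,
                           fragment_id = frs$fragment_id[i]),
                q = q, k_range = k_range)
  })
  stats::setNames(out, frs$fragment_id)
}

#' Per-fragment spectrum summary table
#'
#' @param spectra Named list of `"dq_spectrum"` objects
#'   (see [fragment_spectra()]).
#' @return A data frame: `fragment_id`, `n_points`, `delta_dq`, `d1`,
#'   `d_minus1`, `min_fit_r2`.
#' @export
spectrum_summary <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  grab <- function(sp, qq) {
    i <- match(qq, sp$q)
    if (is.na(i)) NA_real_ else sp$dq[i]
  }
  data.frame(
    fragment_id = if (is.null(names(spectra))) {
      vapply(spectra, function(s) s$fragment_id %||% NA_character_,
             character(1))
    } else names(spectra),
    n_points = vapply(spectra, function(s) s$n_points, numeric(1)),
    delta_dq = vapply(spectra, function(s) s$delta_dq, numeric(1)),
    d1 = vapply(spectra, grab, numeric(1), qq = 1),
    d_minus1 = vapply(spectra, grab, numeric(1), qq = -1),
    min_fit_r2 = vapply(spectra, function(s) min(s$fit_r2), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-q spectrum table as TSV
#'
#' @param spectra Named list of `"dq_spectrum"` objects.
#' @param path Output path; columns fragment_id, q, dq, fit_r2, tau.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  rows <- do.call(rbind, lapply(names(spectra), function(id) {
    cbind(fragment_id = id, as.data.frame(spectra[[id]]))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
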