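# Statistical layer: regression of multifractality on feature densities,
# multifractality-range binning, threshold discrimination, chromosome
# averaging + clustering, and region averaging.

#' Simple linear regression of multifractality on a feature
#'
#' Ordinary least squares y = a + b x with the squared Pearson correlation
#' as R2 and the classical two-sided t-test p-value for the slope.
#'
#' @param x Per-fragment predictor (e.g. an Alu count per fragment).
#' @param y Per-fragment response (e.g. delta_dq).
#' @param xname,yname Labels carried into the result.
#' @return An object of class `"mf_regression"`: list with `response`,
#'   `predictors`, `coefficients` (intercept, slope), `r2`, `p_value`,
#'   `n`.
#' @export
simple_regression <- function(x, y, xname = deparse(substitute(x)),
                              yname = deparse(substitute(y))) {
  force(xname); force(yname)  # capture labels before x/y are filtered
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("degenerate predictor: '", xname,
                              "' is constant")
  fit <- stats::lm(y ~ x)
  r2 <- unname(stats::cor(x, y)^2)
  # classical two-sided t-test for the slope, without summary.lm's
  # perfect-fit warning
  tstat <- sqrt(r2) * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  structure(list(
    response = yname, predictors = xname,
    coefficients = stats::setNames(stats::coef(fit),
                                   c("(Intercept)", xname)),
    r2 = r2,
    p_value = 2 * stats::pt(-abs(tstat), df = n - 2),
    n = n), class = "mf_regression")
}

#' @export
print.mf_regression <- function(x, ...) {
  cat("Linear fit: ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "  (n = ", x$n, ")\n",
      sep = "")
  print(round(x$coefficients, 6))
  cat("R2 = ", sprintf("%.4f", x$r2), ",  p = ",
      format.pval(x$p_value, digits = 3), "\n", sep = "")
  if (!is.null(x$top)) {
    cat("largest |coefficient|:", paste(x$top, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Multivariate regression with min-max normalization and top-coefficient
#' selection
#'
#' Normalizes the response and every predictor to \[0, 1\] (min-max), fits
#' all predictors jointly by OLS, and reports the `n_top` predictors with
#' the largest absolute coefficients.  The default predictor set is the
#' twelve molecular variables of the per-fragment feature table.
#'
#' @param features Feature table from [assemble_feature_table()].
#' @param response Response column name (default `"delta_dq"`).
#' @param predictors Predictor column names.
#' @param n_top How many top-|coefficient| predictors to report.
#' @return An `"mf_regression"` object with additional elements `top`
#'   (selected predictor names) and `kappa` (design condition number).
#' @export
multivariate_regression <- function(features, response = "delta_dq",
                                    predictors = c(
                                      "alu_total", "gc_fraction", "cgi",
                                      "line", "mir", "mer", "ltr",
                                      "coding_bases", "noncoding_bases",
                                      "exon", "gene", "snp"),
                                    n_top = 5L) {
  missing_cols <- setdiff(c(response, predictors), names(features))
  if (length(missing_cols) > 0L) {
    stop("columns absent from the feature table: ",
         paste(missing_cols, collapse = ", "))
  }
  dat <- features[, c(response, predictors)]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < length(predictors) + 2L) {
    stop("need at least ", length(predictors) + 2L,
         " complete rows to fit ", length(predictors), " predictors")
  }
  const <- vapply(dat, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    stop("zero-variance column(s) cannot be min-max normalized: ",
         paste(names(dat)[const], collapse = ", "))
  }
  norm <- as.data.frame(lapply(dat, function(v) {
    (v - min(v)) / (max(v) - min(v))
  }))
  X <- as.matrix(norm[, predictors, drop = FALSE])
  kap <- kappa(cbind(1, X))
  fit <- stats::lm(stats::reformulate(predictors, response), data = norm)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; dropped columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  if (kap > 1e8) {
    warning("ill-conditioned design (condition number ",
            format(kap, digits = 3), "); coefficients may be unstable")
  }
  sm <- summary(fit)
  slopes <- cf[-1]
  top <- names(sort(abs(slopes), decreasing = TRUE))[
    seq_len(min(n_top, length(slopes)))]
  structure(list(
    response = response, predictors = predictors,
    coefficients = cf, r2 = unname(sm$r.squared),
    p_value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                               sm$fstatistic[3], lower.tail = FALSE)),
    n = nrow(norm), top = top, kappa = kap), class = "mf_regression")
}

#' Bin fragments by range of multifractality
#'
#' Histograms the per-fragment delta_dq on fixed-width bins anchored at
#' `floor(min(delta_dq) / bin_width) * bin_width`, optionally aggregating
#' a feature per bin.
#'
#' @param table Feature table (needs a `delta_dq` column).
#' @param feature Optional feature column to sum/average per bin.
#' @param bin_width Bin width on the delta_dq axis (default 0.05).
#' @return An object of class `"rm_binning"`: data frame with
#'   `bin_start`, `bin_end`, `n` and, when `feature` is given,
#'   `feature_sum` and `feature_mean`; attribute `"feature"` names it.
#' @export
rm_binning <- function(table, feature = NULL, bin_width = 0.05) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("'bin_width' must be > 0")
  }
  dd <- table$delta_dq
  if (is.null(dd) || length(dd) == 0L) {
    stop("'table' must contain a non-empty 'delta_dq' column")
  }
  origin <- floor(min(dd) / bin_width) * bin_width
  idx <- pmin(floor((dd - origin) / bin_width),
              ceiling((max(dd) - origin) / bin_width))  # top edge inclusive
  nbin <- max(idx) + 1L
  out <- data.frame(
    bin_start = origin + (seq_len(nbin) - 1L) * bin_width,
    bin_end = origin + seq_len(nbin) * bin_width,
    n = as.integer(tabulate(idx + 1L, nbins = nbin)))
  if (!is.null(feature)) {
    if (!feature %in% names(table)) {
      stop("feature column '", feature, "' not found")
    }
    v <- table[[feature]]
    out$feature_sum <- as.numeric(
      tapply(v, factor(idx, levels = 0:(nbin - 1L)), sum, default = 0))
    out$feature_mean <- ifelse(out$n > 0, out$feature_sum / out$n, NA_real_)
  }
  attr(out, "feature") <- feature
  class(out) <- c("rm_binning", "data.frame")
  out
}

#' Classify fragments by multifractality and Alu thresholds
#'
#' A fragment belongs to the `high` group iff delta_dq >= `delta_dq_min`
#' AND alu_total >= `alu_min` (both inclusive); otherwise to `LMM`
#' (low-and-medium multifractality).  The default thresholds are the
#' published cut points 1.159 and 217.9.
#'
#' @param table Feature table with `delta_dq` and `alu_total` columns.
#' @param delta_dq_min,alu_min Inclusive thresholds.
#' @return An object of class `"mf_classification"`: list with
#'   `classification` (fragment_id, delta_dq, alu_total, group),
#'   `thresholds`, and `summary` (per-group n, mean delta_dq, mean Alu).
#' @export
threshold_classify <- function(table, delta_dq_min = 1.159,
                               alu_min = 217.9) {
  stopifnot(all(c("delta_dq", "alu_total") %in% names(table)))
  grp <- ifelse(table$delta_dq >= delta_dq_min &
                  table$alu_total >= alu_min, "high", "LMM")
  cls <- data.frame(fragment_id = table$fragment_id,
                    delta_dq = table$delta_dq,
                    alu_total = table$alu_total,
                    group = factor(grp, levels = c("high", "LMM")),
                    stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(levels(cls$group), function(g) {
    sel <- cls$group == g
    data.frame(group = g, n = sum(sel),
               mean_delta_dq = if (any(sel)) mean(cls$delta_dq[sel])
                               else NA_real_,
               mean_alu = if (any(sel)) mean(cls$alu_total[sel])
                          else NA_real_)
  }))
  structure(list(classification = cls,
                 thresholds = c(delta_dq_min = delta_dq_min,
                                alu_min = alu_min),
                 summary = summ), class = "mf_classification")
}

#' @export
print.mf_classification <- function(x, ...) {
  cat("Fragment classification (delta_dq >= ",
      x$thresholds["delta_dq_min"], " & alu_total >= ",
      x$thresholds["alu_min"], ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Information-dimension discrimination table
#'
#' Tidy (D1, D-1) tuples per fragment, plus the Alu count when present,
#' for the 2-D / 3-D discrimination scatter plots.
#'
#' @param table Feature table with `d1` and `d_minus1` columns.
#' @return A data frame `fragment_id`, `d1`, `d_minus1` (and `alu_total`
#'   if available), in input order.
#' @export
information_dimension_table <- function(table) {
  stopifnot(all(c("d1", "d_minus1") %in% names(table)))
  bad <- table$fragment_id[is.na(table$d1) | is.na(table$d_minus1)]
  if (length(bad) > 0L) {
    stop("missing q = 1 or q = -1 estimates for fragment(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out <- table[, c("fragment_id", "d1", "d_minus1")]
  if ("alu_total" %in% names(table)) out$alu_total <- table$alu_total
  rownames(out) <- NULL
  out
}

#' Chromosome-level averages
#'
#' Means of delta_dq and all numeric feature columns over the retained
#' fragments of each chromosome, plus (when per-fragment spectra are
#' supplied) the per-q mean Dq spectrum per chromosome -- the input to
#' [cluster_chromosomes()].
#'
#' @param table Feature table from [assemble_feature_table()].
#' @param spectra Optional named list of `"dq_spectrum"` objects keyed by
#'   fragment id.
#' @return An object of class `"chromosome_summary"`: list with `summary`
#'   (data frame of per-chromosome means), `spectra` (chromosome x q
#'   matrix of mean Dq, or NULL) and `q`.
#' @export
chromosome_summary <- function(table, spectra = NULL) {
  stopifnot("chromosome" %in% names(table))
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("start", "end"))
  chroms <- unique(table$chromosome)
  summ <- do.call(rbind, lapply(chroms, function(ch) {
    sel <- table$chromosome == ch
    row <- data.frame(chromosome = ch, n_fragments = sum(sel))
    for (col in num_cols) row[[paste0("mean_", col)]] <-
        mean(table[[col]][sel], na.rm = TRUE)
    row
  }))
  spec_mat <- NULL
  qv <- NULL
  if (!is.null(spectra)) {
    miss <- setdiff(table$fragment_id, names(spectra))
    if (length(miss) > 0L) {
      stop("no spectrum for fragment(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    qv <- spectra[[table$fragment_id[1]]]$q
    spec_mat <- t(vapply(chroms, function(ch) {
      ids <- table$fragment_id[table$chromosome == ch]
      rowMeans(vapply(spectra[ids], function(s) s$dq,
                      numeric(length(qv))))
    }, numeric(length(qv))))
    dimnames(spec_mat) <- list(chroms, qv)
  }
  structure(list(summary = summ, spectra = spec_mat, q = qv),
            class = "chromosome_summary")
}

#' @export
print.chromosome_summary <- function(x, ...) {
  cat("Chromosome averages over retained fragments\n")
  cols <- intersect(c("chromosome", "n_fragments", "mean_delta_dq",
                      "mean_alu_total"), names(x$summary))
  print(x$summary[, cols], row.names = FALSE)
  invisible(x)
}

#' Cluster chromosomes by their averaged Dq spectra
#'
#' Rows (chromosomes) are normalized (min-max by default, z-score as
#' alternative), dissimilarity is 1 - Pearson correlation between the
#' normalized averaged Dq vectors, and agglomeration uses complete
#' linkage.  The tree is cut into `n_groups` multifractality groups;
#' merge similarities are reported as 1 - merge height.
#'
#' @param x A `"chromosome_summary"` with spectra, or a numeric matrix of
#'   averaged spectra (rows = chromosomes, columns = q).
#' @param n_groups Number of groups to cut (default 3).
#' @param normalize `"minmax"` (default) or `"zscore"` row normalization.
#' @return An object of class `"chromosome_clustering"`: list with
#'   `hclust`, `groups` (named cut assignment), `similarities`
#'   (1 - merge heights), `n_groups`.
#' @export
cluster_chromosomes <- function(x, n_groups = 3L,
                                normalize = c("minmax", "zscore")) {
  normalize <- match.arg(normalize)
  mat <- if (inherits(x, "chromosome_summary")) x$spectra else x
  if (is.null(mat) || !is.matrix(mat)) {
    stop("need a chromosome x q matrix of averaged spectra")
  }
  if (nrow(mat) < n_groups) {
    stop("fewer chromosomes (", nrow(mat), ") than groups (", n_groups, ")")
  }
  norm <- t(apply(mat, 1, function(v) {
    rng <- max(v) - min(v)
    if (normalize == "minmax") {
      if (rng == 0) rep(0.5, length(v)) else (v - min(v)) / rng
    } else {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
  }))
  cc <- suppressWarnings(stats::cor(t(norm)))
  if (anyNA(cc)) stop("constant normalized spectrum row; ",
                      "correlation dissimilarity is undefined")
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "complete")
  structure(list(hclust = hc,
                 groups = stats::cutree(hc, k = n_groups),
                 similarities = 1 - hc$height,
                 n_groups = as.integer(n_groups)),
            class = "chromosome_clustering")
}

#' @export
print.chromosome_clustering <- function(x, ...) {
  cat("Complete-linkage clustering of", length(x$groups),
      "chromosomes (1 - Pearson correlation)\n")
  cat("cut into", x$n_groups, "groups:\n")
  print(split(names(x$groups), x$groups))
  cat("minimum merge similarity:",
      sprintf("%.3f", min(x$similarities)), "\n")
  invisible(x)
}

#' @export
#' @method plot chromosome_clustering
plot.chromosome_clustering <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "",
                 main = "Chromosome multifractality clustering", ...)
  invisible(x)
}

#' Export a chromosome dendrogram as Newick
#'
#' @param clustering A `"chromosome_clustering"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "chromosome_clustering"))
  ape::write.tree(ape::as.phylo(clustering$hclust), file = path)
  invisible(path)
}

#' Average multifractality over chromosome regions
#'
#' Splits the (position-ordered) retained fragments of each chromosome
#' into `n_regions` runs of consecutive fragments whose sizes differ by
#' at most one (earlier runs take the remainder) and averages delta_dq
#' per run.
#'
#' @param table Feature table with `chromosome`, `start` and `delta_dq`.
#' @param chromosome Chromosome to summarize; `NULL` (default) does all
#'   chromosomes with at least `n_regions` fragments.
#' @param n_regions Number of regions per chromosome (default 4).
#' @return A data frame: `chromosome`, `region`, `n_fragments`, `start`,
#'   `end`, `mean_delta_dq`.
#' @export
region_summary <- function(table, chromosome = NULL, n_regions = 4L) {
  n_regions <- as.integer(n_regions)
  if (is.na(n_regions) || n_regions < 1L) {
    stop("'n_regions' must be a positive integer")
  }
  chroms <- if (is.null(chromosome)) unique(table$chromosome)
            else chromosome
  out <- lapply(chroms, function(ch) {
    tb <- table[table$chromosome == ch, , drop = FALSE]
    tb <- tb[order(tb$start), , drop = FALSE]
    n <- nrow(tb)
    if (n < n_regions) {
      if (!is.null(chromosome)) {
        stop("chromosome '", ch, "' has ", n, " fragments; fewer than ",
             n_regions, " regions")
      }
      return(NULL)
    }
    sizes <- rep(n %/% n_regions, n_regions)
    rem <- n %% n_regions
    if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    stopnd <- cumsum(sizes)
    startnd <- c(1L, utils::head(stopnd, -1L) + 1L)
    data.frame(
      chromosome = ch, region = seq_len(n_regions),
      n_fragments = sizes,
      start = tb$start[startnd], end = tb$end[stopnd],
      mean_delta_dq = vapply(seq_len(n_regions), function(i) {
        mean(tb$delta_dq[startnd[i]:stopnd[i]])
      }, numeric(1)))
  })
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L) stop("no chromosome has >= ", n_regions,
                              " fragments")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
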