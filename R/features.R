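# Per-fragment feature counting and the joined feature table.

# Wide count-column names for the canonical categories.
.COUNT_COLS <- c(alu = "Alu", alu_j = "AluJ", alu_s = "AluS",
                 alu_y = "AluY", line = "LINE", mir = "MIR", mer = "MER",
                 ltr = "LTR", cgi = "CGI", gene = "gene", exon = "exon",
                 intron = "intron", snp = "SNP")

#' Count annotation intervals per fragment
#'
#' Assigns intervals to retained fragments under one of three overlap
#' rules and tallies them per category.  The default `"midpoint"` rule
#' counts an interval exactly once genome-wide, in the fragment containing
#' its midpoint, which avoids double counting across fragment boundaries;
#' `"any"` counts an interval in every fragment it overlaps; `"within"`
#' only when fully contained.  Intervals on chromosomes absent from the
#' fragment table (or falling in no retained fragment) are skipped with a
#' warning and tallied in the `"skipped"` attribute.
#'
#' @param fragments Fragment table from [fragment_genome()]; removed
#'   fragments are excluded.
#' @param intervals Interval table from [read_intervals()] (columns
#'   `chromosome`, `start`, `end`, `category`).
#' @param rule Overlap rule, see above.
#' @return A data frame with one row per retained fragment: `fragment_id`,
#'   one count column per canonical category (`alu`, `alu_j`, `alu_s`,
#'   `alu_y`, `line`, `mir`, `mer`, `ltr`, `cgi`, `gene`, `exon`,
#'   `intron`, `snp`), an `other` column for all remaining categories,
#'   and `alu_total` = alu + alu_j + alu_s + alu_y.  Attribute
#'   `"skipped"` holds the number of unassigned intervals.
#' @export
count_per_fragment <- function(fragments, intervals,
                               rule = c("midpoint", "any", "within")) {
  rule <- match.arg(rule)
  frs <- retained_fragments(fragments)
  if (nrow(frs) == 0L) stop("no retained fragments")
  hit_frag <- character(0)
  hit_cat <- character(0)
  skipped <- 0L
  skipped_chroms <- character(0)
  for (chrom in unique(intervals$chromosome)) {
    iv <- intervals[intervals$chromosome == chrom, , drop = FALSE]
    fr <- frs[frs$chromosome == chrom, , drop = FALSE]
    if (nrow(fr) == 0L) {
      skipped <- skipped + nrow(iv)
      skipped_chroms <- c(skipped_chroms, chrom)
      next
    }
    fr <- fr[order(fr$start), , drop = FALSE]
    if (rule == "midpoint") {
      mid <- (iv$start + iv$end) / 2
      idx <- findInterval(mid, fr$start)
      ok <- idx >= 1L & mid < fr$end[pmax(idx, 1L)]
      skipped <- skipped + sum(!ok)
      hit_frag <- c(hit_frag, fr$fragment_id[idx[ok]])
      hit_cat <- c(hit_cat, iv$category[ok])
    } else {
      for (j in seq_len(nrow(iv))) {
        if (rule == "any") {
          sel <- which(fr$start < iv$end[j] & fr$end > iv$start[j])
        } else {
          sel <- which(fr$start <= iv$start[j] & fr$end >= iv$end[j])
        }
        if (length(sel) == 0L) {
          skipped <- skipped + 1L
        } else {
          hit_frag <- c(hit_frag, fr$fragment_id[sel])
          hit_cat <- c(hit_cat, rep(iv$category[j], length(sel)))
        }
      }
    }
  }
  if (length(skipped_chroms) > 0L) {
    warning("skipped intervals on chromosome(s) absent from fragments: ",
            paste(skipped_chroms, collapse = ", "))
  }
  out <- data.frame(fragment_id = frs$fragment_id, stringsAsFactors = FALSE)
  for (col in names(.COUNT_COLS)) {
    cat_hits <- hit_frag[hit_cat == .COUNT_COLS[[col]]]
    out[[col]] <- as.integer(table(factor(cat_hits,
                                          levels = frs$fragment_id)))
  }
  other_hits <- hit_frag[!(hit_cat %in% .COUNT_COLS)]
  out$other <- as.integer(table(factor(other_hits,
                                       levels = frs$fragment_id)))
  out$alu_total <- out$alu + out$alu_j + out$alu_s + out$alu_y
  attr(out, "skipped") <- skipped
  out
}

# Total bases covered by the union of intervals clipped to [lo, hi).
.union_bases <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo)
  e <- pmin(ends, hi)
  keep <- s < e
  if (!any(keep)) return(0)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else {
      cur_e <- max(cur_e, e[i])
    }
  }
  tot + (cur_e - cur_s)
}

#' Assemble the per-fragment feature table
#'
#' Joins the multifractal summary (delta_dq, D1, D-1) with the
#' per-category counts and fragment metadata into one row per retained
#' fragment.  If `intervals` with an `exon` category are supplied,
#' `coding_bases` is the union of exon bases clipped to the fragment and
#' `noncoding_bases` the remainder of the fragment; otherwise both are
#' `NA`.
#'
#' @param spectra Named list of `"dq_spectrum"` objects from
#'   [fragment_spectra()], or a summary data frame from
#'   [spectrum_summary()].
#' @param counts Count table from [count_per_fragment()].
#' @param fragments Fragment table from [fragment_genome()].
#' @param intervals Optional interval table used for exon base counting.
#' @return A data frame: fragment id and coordinates, `delta_dq`, `d1`,
#'   `d_minus1`, count columns (including `alu_total`), `gc_fraction`,
#'   `coding_bases`, `noncoding_bases`.
#' @export
assemble_feature_table <- function(spectra, counts, fragments,
                                   intervals = NULL) {
  summ <- if (is.data.frame(spectra)) spectra else spectrum_summary(spectra)
  frs <- retained_fragments(fragments)
  miss_sp <- setdiff(frs$fragment_id, summ$fragment_id)
  miss_ct <- setdiff(frs$fragment_id, counts$fragment_id)
  extra <- setdiff(union(summ$fragment_id, counts$fragment_id),
                   frs$fragment_id)
  if (length(miss_sp) || length(miss_ct) || length(extra)) {
    stop("inconsistent fragment ids -- missing spectra: ",
         paste(utils::head(miss_sp, 5), collapse = ", "),
         "; missing counts: ", paste(utils::head(miss_ct, 5), collapse = ", "),
         "; unknown ids: ", paste(utils::head(extra, 5), collapse = ", "))
  }
  out <- frs[, c("fragment_id", "chromosome", "start", "end",
                 "gc_fraction")]
  si <- match(out$fragment_id, summ$fragment_id)
  out$delta_dq <- summ$delta_dq[si]
  out$d1 <- summ$d1[si]
  out$d_minus1 <- summ$d_minus1[si]
  ci <- match(out$fragment_id, counts$fragment_id)
  for (col in setdiff(names(counts), "fragment_id")) {
    out[[col]] <- counts[[col]][ci]
  }
  out$coding_bases <- NA_real_
  out$noncoding_bases <- NA_real_
  if (!is.null(intervals)) {
    ex <- intervals[intervals$category == "exon", , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      exc <- ex[ex$chromosome == out$chromosome[i], , drop = FALSE]
      cb <- .union_bases(exc$start, exc$end, out$start[i], out$end[i])
      out$coding_bases[i] <- cb
      out$noncoding_bases[i] <- (out$end[i] - out$start[i]) - cb
    }
  }
  rownames(out) <- NULL
  out
}

#' Write the feature table as TSV
#'
#' @param features Feature table from [assemble_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
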