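# Reading genomes, fragmenting chromosomes, reading annotation intervals.
#
# Internal coordinate convention: 0-based, half-open [start, end), in bases.

# Byte -> base code lookup: A=1, C=2, G=3, T=4, N=5, anything else 0.
.BASE_CODE <- local({
  m <- integer(256)
  up <- utf8ToInt("A") ; lo <- utf8ToInt("a")
  for (i in seq_along(c("A", "C", "G", "T", "N"))) {
    b <- c("A", "C", "G", "T", "N")[i]
    m[utf8ToInt(b)] <- i
    m[utf8ToInt(tolower(b))] <- i
  }
  m
})

# Encode a residue string to integer codes 1..5; error on symbols outside
# {A,C,G,T,N} (case-insensitive).
.encode_residues <- function(residues) {
  codes <- .BASE_CODE[utf8ToInt(residues)]
  if (any(codes == 0L)) {
    bad <- intToUtf8(utf8ToInt(residues)[codes == 0L][1])
    stop("invalid residue symbol '", bad,
         "'; sequences must use A/C/G/T/N (case-insensitive)")
  }
  codes
}

#' Read a multi-FASTA genome
#'
#' Reads one record per FASTA header (plain or gzipped), normalizes residues
#' to upper case, and maps every symbol outside A/C/G/T (ambiguous IUPAC
#' codes included) to N.  Chaos-game corners exist only for the four
#' unambiguous bases, so N is the single internal ambiguity symbol.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A named character vector of residue strings over
#'   \{A,C,G,T,N\}; names are the first whitespace-delimited token of each
#'   header, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrZ", "acgtn"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  res <- toupper(as.character(set))
  res <- gsub("[^ACGT]", "N", res)
  names(res) <- sub("\\s.*$", "", names(set))
  res
}

#' Cut chromosomes into fixed-length fragments
#'
#' Each record is divided into consecutive, non-overlapping windows of
#' exactly `fragment_length` bases; the trailing partial window is
#' discarded.  Windows whose N fraction exceeds `max_n_fraction` are kept
#' in the table but flagged `removed = TRUE`; downstream functions exclude
#' them by default, which keeps the ambiguity filter auditable.
#'
#' @param records Named character vector of residue strings, as returned by
#'   [read_fasta()].
#' @param fragment_length Window size in bases (default 300,000).
#' @param max_n_fraction Maximum tolerated fraction of N per window
#'   (default 0.10).
#' @return A data frame with one row per window: `fragment_id`,
#'   `chromosome`, `start`, `end` (0-based half-open), `n_count`,
#'   `gc_fraction` (over non-N bases), `removed`, `residues`.
#' @seealso [retained_fragments()], [gc_content()]
#' @export
fragment_genome <- function(records, fragment_length = 300000L,
                            max_n_fraction = 0.10) {
  if (!is.character(records) || is.null(names(records)) ||
      anyNA(names(records)) || any(names(records) == "")) {
    stop("'records' must be a named character vector of residue strings")
  }
  fragment_length <- as.integer(fragment_length)
  if (is.na(fragment_length) || fragment_length < 1L) {
    stop("'fragment_length' must be a positive integer")
  }
  empty <- data.frame(
    fragment_id = character(), chromosome = character(),
    start = numeric(), end = numeric(), n_count = integer(),
    gc_fraction = numeric(), removed = logical(), residues = character(),
    stringsAsFactors = FALSE)
  pieces <- lapply(names(records), function(chrom) {
    len <- nchar(records[[chrom]])
    nf <- len %/% fragment_length
    if (nf == 0L) return(NULL)
    start <- (seq_len(nf) - 1) * as.numeric(fragment_length)
    end <- start + fragment_length
    seqs <- substring(records[[chrom]], start + 1, end)
    freq <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                        c("G", "C", "N"))
    n_count <- as.integer(freq[, "N"])
    non_n <- fragment_length - n_count
    gc <- ifelse(non_n > 0L, (freq[, "G"] + freq[, "C"]) / non_n, 0)
    data.frame(
      fragment_id = sprintf("%s_%05d", chrom, seq_len(nf)),
      chromosome = chrom, start = start, end = end,
      n_count = n_count, gc_fraction = as.numeric(gc),
      removed = n_count / fragment_length > max_n_fraction,
      residues = seqs, stringsAsFactors = FALSE)
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (length(pieces) == 0L) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Retained (non-removed) fragments
#'
#' @param fragments Fragment table from [fragment_genome()].
#' @return The subset with `removed == FALSE`.
#' @export
retained_fragments <- function(fragments) {
  fragments[!fragments$removed, , drop = FALSE]
}

#' G+C fraction of a residue string
#'
#' Computed over non-N bases: (G + C) / (length - N).  All-N or empty input
#' returns 0 with a warning.
#'
#' @param residues A residue string over \{A,C,G,T,N\}.
#' @return A number in \[0, 1\].
#' @examples
#' gc_content("ACGT")  # 0.5
#' gc_content("ANGN")  # 0.5: one G over two non-N bases
#' @export
gc_content <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (nchar(residues) == 0L) {
    warning("empty sequence; returning gc_content = 0")
    return(0)
  }
  codes <- .encode_residues(residues)
  non_n <- sum(codes != 5L)
  if (non_n == 0L) {
    warning("sequence contains only N; returning gc_content = 0")
    return(0)
  }
  sum(codes == 2L | codes == 3L) / non_n
}

#' Default feature-category mapper
#'
#' Maps source annotation labels to the package's closed category set
#' (Alu, AluJ, AluS, AluY, LINE, MIR, MER, LTR, CGI, gene, exon, intron,
#' SNP).  Canonical labels pass through;
#' Alu subfamily names are collapsed to their family by the J/S/Y prefix
#' naming scheme (e.g. AluSx -> AluS, AluYb8 -> AluY); common repeat-class
#' prefixes (L1/L2/L3/CR1 -> LINE, MIR* -> MIR, MER* -> MER,
#' LTR/MLT/MST/THE -> LTR) are recognized.  Unrecognized labels map to
#' `NA`, which [read_intervals()] turns into `other:<label>`.
#'
#' @param labels Character vector of source labels.
#' @return Character vector of categories (`NA` where unrecognized).
#' @export
default_category_map <- function(labels) {
  out <- rep(NA_character_, length(labels))
  hit <- labels %in% CATEGORIES
  out[hit] <- labels[hit]
  rules <- list(
    c("^AluJ", "AluJ"), c("^AluS", "AluS"), c("^AluY", "AluY"),
    c("^Alu", "Alu"),
    c("^(L1|L2|L3|CR1)", "LINE"),
    c("^MIR", "MIR"), c("^MER", "MER"),
    c("^(LTR|MLT|MST|THE)", "LTR"))
  for (r in rules) {
    m <- is.na(out) & grepl(r[1], labels)
    out[m] <- r[2]
  }
  out
}

# Apply a category map (function or named character vector) to labels.
.map_category <- function(labels, category_map) {
  if (is.null(category_map)) {
    cat <- rep(NA_character_, length(labels))
  } else if (is.function(category_map)) {
    cat <- category_map(labels)
  } else {
    cat <- unname(category_map[labels])
  }
  miss <- is.na(cat)
  cat[miss] <- paste0("other:", labels[miss])
  cat
}

#' Read annotation intervals
#'
#' Reads a tab-separated interval file with columns chrom, start, end,
#' label (further columns ignored) and normalizes everything to the
#' internal 0-based half-open convention.  `dialect = "bed"` treats input
#' coordinates as 0-based half-open; `dialect = "one-based"` as 1-based
#' inclusive (as in tabular NCBI annotation dumps).  Point features
#' (e.g. SNPs given as start == end in 1-based input) become
#' single-base intervals.
#'
#' @param path Path to the interval file.
#' @param category_map Either a function mapping label vectors to category
#'   vectors (default [default_category_map()]) or a named character vector
#'   `c(source_label = category)`.  Unmapped labels become
#'   `other:<label>`.
#' @param dialect `"bed"` (default) or `"one-based"`.
#' @return A data frame: `chromosome`, `start`, `end` (0-based half-open),
#'   `category`, `name` (the source label).
#' @export
read_intervals <- function(path, category_map = default_category_map,
                           dialect = c("bed", "one-based")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interval file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) {
    stop("interval file '", path,
         "' needs at least 4 tab-separated columns (chrom, start, end, label)")
  }
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("non-numeric coordinates at line ", bad[1], " of ", path)
  }
  if (dialect == "one-based") {
    start <- start - 1
    # 1-based inclusive point features (start == end) become 1-base runs.
  }
  bad <- which(start >= end)
  if (length(bad) > 0L) {
    stop("empty or inverted interval (start >= end after normalization) ",
         "at line ", bad[1], " of ", path)
  }
  data.frame(chromosome = raw[[1]], start = start, end = end,
             category = .map_category(raw[[4]], category_map),
             name = raw[[4]], stringsAsFactors = FALSE)
}

#' Write a fragment table as TSV
#'
#' Writes fragment metadata (id, coordinates, N count, G+C, removed flag)
#' without the residue column; sequences can be written separately with
#' [write_fragment_fasta()].
#'
#' @param fragments Fragment table from [fragment_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  cols <- c("fragment_id", "chromosome", "start", "end", "n_count",
            "gc_fraction", "removed")
  utils::write.table(fragments[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write fragment sequences as FASTA
#'
#' @param fragments Fragment table from [fragment_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragment_fasta <- function(fragments, path) {
  set <- Biostrings::DNAStringSet(fragments$residues)
  names(set) <- fragments$fragment_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
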