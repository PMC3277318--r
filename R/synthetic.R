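# Synthetic genomes and closed-form multifractal oracles.
#
# The chaos game with i.i.d. letter probabilities p over the four corners
# generates the self-similar measure with contraction ratio 1/2 and
# weights p, whose spectrum is known in closed form:
#   Dq = -log2(sum_i p_i^q) / (q - 1),   D1 = -sum_i p_i log2 p_i.
# This lets every stage of the estimator be validated end-to-end without
# external data.

.BASES <- c("A", "C", "G", "T")

.check_probs <- function(base_probs) {
  if (!is.numeric(base_probs) || length(base_probs) != 4L ||
      any(base_probs < 0) || abs(sum(base_probs) - 1) > 1e-8) {
    stop("'base_probs' must be 4 non-negative numbers summing to 1 ",
         "(order A, C, G, T)")
  }
  base_probs / sum(base_probs)
}

# int codes 1..4 -> residue string
.codes_to_string <- function(codes) {
  intToUtf8(utf8ToInt("ACGT")[codes])
}

#' Random i.i.d. DNA sequence
#'
#' @param length Sequence length (>= 0).
#' @param base_probs Per-base probabilities in A, C, G, T order (default
#'   uniform).
#' @param seed Optional integer seed; identical seeds give identical
#'   sequences.
#' @return A residue string.
#' @examples
#' random_sequence(10, c(1, 0, 0, 0))  # "AAAAAAAAAA"
#' @export
random_sequence <- function(length, base_probs = rep(0.25, 4),
                            seed = NULL) {
  stopifnot(is.numeric(length), length >= 0)
  base_probs <- .check_probs(base_probs)
  if (!is.null(seed)) set.seed(seed)
  if (length == 0) return("")
  .codes_to_string(sample.int(4L, length, replace = TRUE,
                              prob = base_probs))
}

#' Random first-order Markov DNA sequence
#'
#' @param length Sequence length (>= 0).
#' @param transition 4 x 4 row-stochastic transition matrix in
#'   A, C, G, T order.
#' @param init Initial-state probabilities (default uniform).
#' @param seed Optional integer seed.
#' @return A residue string.
#' @export
markov_sequence <- function(length, transition, init = rep(0.25, 4),
                            seed = NULL) {
  stopifnot(is.matrix(transition), identical(dim(transition), c(4L, 4L)),
            all(transition >= 0),
            all(abs(rowSums(transition) - 1) < 1e-8))
  init <- .check_probs(init)
  if (!is.null(seed)) set.seed(seed)
  if (length == 0) return("")
  codes <- integer(length)
  codes[1] <- sample.int(4L, 1L, prob = init)
  if (length > 1) {
    u <- stats::runif(length - 1)
    cum <- t(apply(transition, 1, cumsum))
    for (i in 2:length) {
      codes[i] <- findInterval(u[i - 1], cum[codes[i - 1], ],
                               left.open = TRUE) + 1L
    }
  }
  .codes_to_string(codes)
}

#' Synthetic genome with planted, mutated repeat copies
#'
#' Emulates an interspersed-repeat density gradient: each fragment is
#' i.i.d. background carrying a known number of copies of one
#' seed-derived consensus (default 300 bp, mimicking the Alu element's
#' size), placed at uniform-random non-overlapping positions by rejection
#' sampling and independently mutated per base.  Copies overwrite the
#' background, so fragment length is exact and the emitted annotation
#' intervals cover the insertions exactly.  One contig is emitted per
#' fragment.
#'
#' @param n_fragments Number of fragments/contigs.
#' @param copy_numbers Integer vector (length `n_fragments`) of planted
#'   copies per fragment.
#' @param fragment_length Fragment length in bases (default 300,000).
#' @param base_probs Background base probabilities (default uniform).
#' @param consensus_length Repeat consensus length (default 300).
#' @param mutation_rate Per-base substitution probability applied
#'   independently to each planted copy (default 0.1).
#' @param seed Optional integer seed driving all randomness.
#' @param max_tries Placement rejection-sampling cap per fragment.
#' @return A list: `records` (named character vector, one contig per
#'   fragment), `intervals` (annotation table with category `"Alu"`),
#'   `truth` (data frame `chromosome`, `copies`), `consensus` (the
#'   repeat consensus string).
#' @export
planted_repeat_genome <- function(n_fragments, copy_numbers,
                                  fragment_length = 300000L,
                                  base_probs = rep(0.25, 4),
                                  consensus_length = 300L,
                                  mutation_rate = 0.1,
                                  seed = NULL, max_tries = 10000L) {
  stopifnot(length(copy_numbers) == n_fragments,
            all(copy_numbers >= 0),
            mutation_rate >= 0, mutation_rate <= 1)
  base_probs <- .check_probs(base_probs)
  L <- as.integer(fragment_length)
  cl <- as.integer(consensus_length)
  if (any(copy_numbers * cl > L)) {
    stop("planted repeat bases exceed fragment length; ",
         "reduce the copy number")
  }
  if (!is.null(seed)) set.seed(seed)
  cons <- sample.int(4L, cl, replace = TRUE)
  chroms <- sprintf("frag%03d", seq_len(n_fragments))
  records <- character(n_fragments)
  iv <- list()
  for (i in seq_len(n_fragments)) {
    bg <- sample.int(4L, L, replace = TRUE, prob = base_probs)
    nc <- copy_numbers[i]
    if (nc > 0L) {
      pos <- integer(0)
      tries <- 0L
      while (length(pos) < nc) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("could not place ", nc, " non-overlapping copies in ",
               max_tries, " tries; reduce the copy number")
        }
        s <- sample.int(L - cl + 1L, 1L) - 1L   # 0-based start
        if (length(pos) == 0L || all(abs(s - pos) >= cl)) {
          pos <- c(pos, s)
        }
      }
      pos <- sort(pos)
      for (s in pos) {
        cp <- cons
        mut <- stats::runif(cl) < mutation_rate
        if (any(mut)) {
          # substitute with one of the three other bases, uniformly
          cp[mut] <- ((cp[mut] - 1L +
                         sample.int(3L, sum(mut), replace = TRUE)) %% 4L) + 1L
        }
        bg[(s + 1L):(s + cl)] <- cp
      }
      iv[[length(iv) + 1L]] <- data.frame(
        chromosome = chroms[i], start = pos, end = pos + cl,
        category = "Alu", name = "synthetic_repeat",
        stringsAsFactors = FALSE)
    }
    records[i] <- .codes_to_string(bg)
  }
  intervals <- if (length(iv) > 0L) do.call(rbind, iv) else
    data.frame(chromosome = character(), start = numeric(),
               end = numeric(), category = character(),
               name = character(), stringsAsFactors = FALSE)
  list(records = stats::setNames(records, chroms),
       intervals = intervals,
       truth = data.frame(chromosome = chroms,
                          copies = as.integer(copy_numbers),
                          stringsAsFactors = FALSE),
       consensus = .codes_to_string(cons))
}

#' Closed-form generalized dimensions of the biased chaos-game measure
#'
#' For corner probabilities p (zeros allowed) the chaos-game measure has
#' Dq = -log2(sum over nonzero p of p^q) / (q - 1); at q = 1 the Shannon
#' entropy -sum p log2 p; at q = 0 the support dimension log2(#nonzero).
#'
#' @param base_probs 4 probabilities in A, C, G, T order summing to 1.
#' @param q Moment order(s); vectorized.
#' @return Numeric vector of exact dimensions.
#' @examples
#' analytic_dq(rep(0.25, 4), -5:5)          # all exactly 2
#' analytic_dq(c(0.4, 0.3, 0.2, 0.1), 2)    # -log2(0.30)
#' @export
analytic_dq <- function(base_probs, q) {
  p <- .check_probs(base_probs)
  p <- p[p > 0]
  vapply(q, function(qq) {
    if (qq == 1) -sum(p * log2(p)) else -log2(sum(p^qq)) / (qq - 1)
  }, numeric(1))
}

#' Labelled archetype chromosome spectra
#'
#' Fixture generator for cluster-recovery experiments: each group's
#' spectra are i.i.d. Gaussian perturbations of that group's template Dq
#' curve, the closed-form spectrum of a biased chaos-game measure.  The
#' downstream clustering metric (row normalization + Pearson correlation)
#' is invariant to scaling and shifting a spectrum, so the group
#' templates must differ in curve *shape*: the defaults concentrate the
#' composition bias on one, two, or three corners, which produces three
#' clearly shape-distinct archetypes.
#'
#' @param n_per_group Spectra (chromosomes) per group.
#' @param group_probs List (>= 2) of corner-probability vectors, one per
#'   group.
#' @param noise_sd Gaussian noise standard deviation; when
#'   `relative = TRUE` it is interpreted as a fraction of the mean
#'   template spectrum range (max Dq - min Dq).
#' @param relative Interpret `noise_sd` relative to the template spread?
#' @param q Moment orders (default -20..20).
#' @param seed Optional integer seed.
#' @return A list: `spectra` (matrix, one row per synthetic chromosome),
#'   `labels` (integer group labels), `q`, `templates` (q x group
#'   matrix of exact curves), `spread` (mean template range), `noise_sd`
#'   (the absolute value used).
#' @export
archetype_spectra <- function(n_per_group,
                              group_probs = list(
                                c(0.55, 0.15, 0.15, 0.15),
                                c(0.35, 0.35, 0.15, 0.15),
                                c(0.30, 0.30, 0.30, 0.10)),
                              noise_sd = 0, relative = FALSE,
                              q = -20:20, seed = NULL) {
  stopifnot(is.list(group_probs), length(group_probs) >= 2L,
            n_per_group >= 1L, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  templates <- vapply(group_probs, analytic_dq, numeric(length(q)), q = q)
  spread <- mean(apply(templates, 2, function(v) max(v) - min(v)))
  sd_abs <- if (relative) noise_sd * spread else noise_sd
  n_groups <- length(group_probs)
  n <- n_groups * n_per_group
  labels <- rep(seq_len(n_groups), each = n_per_group)
  spectra <- t(vapply(labels, function(g) {
    templates[, g] + stats::rnorm(length(q), sd = sd_abs)
  }, numeric(length(q))))
  dimnames(spectra) <- list(sprintf("chr%02d", seq_len(n)), q)
  list(spectra = spectra, labels = labels, q = q,
       templates = templates, spread = spread, noise_sd = sd_abs)
}

#' Do two labelings describe the same partition?
#'
#' Compares two cluster assignments up to label permutation.
#'
#' @param a,b Equal-length label vectors.
#' @return `TRUE` iff the induced partitions are identical.
#' @export
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
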