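# Independent oracles, implemented deliberately without reusing package
# internals: a plain-loop chaos game and an exhaustive-grid partition sum.

# Chaos game by explicit loop (reference for the recursive-filter path).
brute_cgr <- function(residues, corners = default_corners(),
                      start = c(0.5, 0.5)) {
  bases <- strsplit(toupper(residues), "")[[1]]
  p <- start
  out <- matrix(NA_real_, nrow = 0, ncol = 2)
  for (b in bases) {
    if (b %in% rownames(corners)) {
      p <- (p + corners[b, ]) / 2
      out <- rbind(out, p)
    }
  }
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

# Partition sum by enumerating every grid cell of the full 2^k x 2^k grid.
brute_partition_sum <- function(points, q, k) {
  r <- 2^k
  grid <- matrix(0L, nrow = r, ncol = r)
  for (i in seq_len(nrow(points))) {
    ix <- min(floor(points[i, 1] * r), r - 1) + 1
    iy <- min(floor(points[i, 2] * r), r - 1) + 1
    grid[ix, iy] <- grid[ix, iy] + 1L
  }
  m0 <- sum(grid)
  total <- 0
  for (ix in seq_len(r)) {
    for (iy in seq_len(r)) {
      mi <- grid[ix, iy]
      if (mi > 0L) {
        p <- mi / m0
        total <- total + if (q == 1) p * log(p) else p^q
      }
    }
  }
  total
}

# Dq by least squares on the brute-force sums (independent of .dq_fit).
brute_dq <- function(points, q, k_range) {
  y <- vapply(k_range, function(k) {
    s <- brute_partition_sum(points, q, k)
    if (q == 1) s else log(s)
  }, numeric(1))
  x <- if (q == 1) -k_range * log(2) else (q - 1) * (-k_range * log(2))
  unname(coef(lm(y ~ x))[2])
}

# Short random DNA helper for property loops.
rand_dna <- function(n, probs = rep(0.25, 4), seed = NULL) {
  random_sequence(n, probs, seed = seed)
}
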