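test_that("box_occupancy handles exact corners, ties and degenerate input", {
  quad <- cbind(c(0.25, 0.25, 0.75, 0.75), c(0.25, 0.75, 0.25, 0.75))
  occ <- box_occupancy(quad, 1)
  expect_equal(sort(occ$counts), rep(1L, 4))
  expect_equal(occ$m0, 4L)

  occ1 <- box_occupancy(cbind(0.3, 0.3), 5)
  expect_equal(occ1$counts, 1L)

  same <- matrix(rep(c(0.123, 0.456), each = 10), ncol = 2)
  occ2 <- box_occupancy(same, 3)
  expect_equal(occ2$counts, 10L)

  # coordinate 1.0 goes into the last box, not a phantom one
  edge <- box_occupancy(cbind(1, 1), 2)
  expect_equal(length(edge$counts), 1L)

  expect_error(box_occupancy(matrix(numeric(0), ncol = 2), 2), "empty")
  expect_error(box_occupancy(quad, 0), ">= 1")
})

test_that("partition_sum reproduces closed forms", {
  quad <- cbind(c(0.25, 0.25, 0.75, 0.75), c(0.25, 0.75, 0.25, 0.75))
  occ <- box_occupancy(quad, 1)
  expect_equal(partition_sum(occ, 2), 0.25)
  expect_equal(partition_sum(occ, 0), 4)          # box count
  expect_equal(partition_sum(occ, 1), -log(4))    # entropy numerator
})

test_that("partition sums and Dq match the exhaustive-grid oracle", {
  set.seed(20)
  for (n in c(37, 500, 1000)) {
    pts <- cbind(runif(n), runif(n))
    for (q in -5:5) {
      for (k in 1:3) {
        occ <- box_occupancy(pts, k)
        expect_equal(partition_sum(occ, q),
                     brute_partition_sum(pts, q, k), tolerance = 1e-9)
      }
      expect_equal(unname(dq_estimate(pts, q, k_range = 1:3)["dq"]),
                   brute_dq(pts, q, 1:3), tolerance = 1e-9)
    }
  }
})

test_that("dq_estimate recovers the uniform plane dimension", {
  set.seed(21)
  pts <- cbind(runif(100000), runif(100000))
  est <- dq_estimate(pts, q = 2, k_range = 1:6)
  expect_lt(abs(est["dq"] - 2), 0.05)
  expect_gt(est["fit_r2"], 0.999)
})

test_that("dq_estimate input validation", {
  pts <- cbind(runif(50), runif(50))
  expect_error(dq_estimate(pts, 2, k_range = 1:2), "3 scales")
  coincident <- matrix(rep(c(0.4, 0.4), each = 40), ncol = 2)
  expect_error(dq_estimate(coincident, 2, k_range = 1:4), "single box")
})

test_that("spectrum on a biased chaos-game measure approaches closed form", {
  probs <- c(0.4, 0.3, 0.2, 0.1)
  s <- random_sequence(150000, probs, seed = 22)
  sp <- dq_spectrum(s, q = -2:10, k_range = 1:6)
  for (q in c(0, 1, 2, 5)) {
    expect_lt(abs(coef(sp)[as.character(q)] - analytic_dq(probs, q)), 0.05)
  }
  # spectrum is non-increasing in q (small estimation slack allowed)
  expect_true(all(diff(sp$dq) < 0.02))
})

test_that("tau identities hold and monofractal tau is a straight line", {
  sp <- dq_spectrum(rand_dna(50000, seed = 23), q = -5:5, k_range = 1:5)
  tc <- tau_curve(sp)
  expect_identical(tc$tau, (tc$q - 1) * sp$dq)
  expect_identical(tc$tau[tc$q == 1], 0)        # exact, by construction
  expect_gte(delta_dq(sp), 0)

  # constant spectrum c => tau = c (q - 1), a perfect line through q = 1
  flat <- sp
  flat$dq <- rep(1.8, length(flat$q))
  flat$tau <- (flat$q - 1) * flat$dq
  fit <- lm(tau ~ q, data = tau_curve(flat))
  expect_equal(unname(coef(fit)[2]), 1.8, tolerance = 1e-12)
  expect_equal(suppressWarnings(summary(fit)$r.squared), 1,
               tolerance = 1e-12)
})

test_that("delta_dq is the spectrum spread", {
  sp <- dq_spectrum(rand_dna(20000, seed = 24), q = -3:3, k_range = 1:4)
  expect_equal(delta_dq(sp), max(sp$dq) - min(sp$dq))
  sp$dq <- c(2, 2, 2, 2, 2, 1.6, 1.6)
  sp$delta_dq <- max(sp$dq) - min(sp$dq)
  expect_equal(delta_dq(sp), 0.4)
})

test_that("Dq statistics are invariant under corner permutation", {
  s <- rand_dna(30000, probs = c(0.4, 0.3, 0.2, 0.1), seed = 25)
  base <- dq_spectrum(s, q = c(-5, -1, 0, 1, 2, 5), k_range = 1:5)
  swapped <- default_corners()[c("T", "G", "C", "A"), ]
  rownames(swapped) <- c("A", "C", "G", "T")
  alt <- dq_spectrum(s, q = c(-5, -1, 0, 1, 2, 5), k_range = 1:5,
                     corners = swapped)
  # square symmetries reverse the half-open direction of one axis, so the
  # few points exactly on dyadic box edges may change bins: near-equality
  expect_equal(alt$dq, base$dq, tolerance = 1e-2)
})

test_that("three-letter sequences give the Sierpinski-type dimension", {
  s <- random_sequence(100000, c(1, 1, 1, 0) / 3, seed = 26)
  sp <- dq_spectrum(s, q = 0:5, k_range = 1:6)
  expect_lt(abs(coef(sp)["0"] - log2(3)), 0.05)
  expect_lt(max(sp$dq) - min(sp$dq), 0.1)
})

test_that("fragment_spectra + spectrum_summary cover retained fragments", {
  rec <- c(c1 = rand_dna(3000, seed = 27), c2 = rand_dna(2000, seed = 28))
  fr <- fragment_genome(rec, fragment_length = 1000)
  sps <- fragment_spectra(fr, q = -2:2, k_range = 1:3)
  expect_identical(names(sps), retained_fragments(fr)$fragment_id)
  summ <- spectrum_summary(sps)
  expect_equal(nrow(summ), 5L)
  expect_identical(summ$d1,
                   vapply(sps, function(s) s$dq[s$q == 1], numeric(1),
                          USE.NAMES = FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(sps, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 5L * 5L)
})
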