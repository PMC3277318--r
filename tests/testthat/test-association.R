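test_that("simple_regression recovers exact linear structure", {
  x <- 1:10
  fit <- simple_regression(x, 2 * x)
  expect_equal(unname(fit$coefficients[2]), 2)
  expect_equal(fit$r2, 1)
  expect_lt(fit$p_value, 1e-10)
  # r2 equals an independently computed squared Pearson correlation
  set.seed(40)
  a <- rnorm(50); b <- 0.3 * a + rnorm(50)
  fit2 <- simple_regression(a, b)
  expect_equal(fit2$r2, cor(a, b)^2)
})

test_that("independent noise gives near-zero r2; degenerate input errors", {
  set.seed(41)
  fit <- simple_regression(rnorm(1000), rnorm(1000))
  expect_lt(fit$r2, 0.05)
  expect_error(simple_regression(rep(1, 10), rnorm(10)), "constant")
  expect_error(simple_regression(1:2, 1:2), "at least 3")
})

test_that("multivariate_regression normalizes, fits, and selects top-5", {
  set.seed(42)
  n <- 200
  ft <- data.frame(alu_total = rpois(n, 100), gc_fraction = runif(n),
                   cgi = rpois(n, 10), line = rpois(n, 50),
                   mir = rpois(n, 20), mer = rpois(n, 20),
                   ltr = rpois(n, 30), coding_bases = rpois(n, 5000),
                   noncoding_bases = rpois(n, 9000), exon = rpois(n, 8),
                   gene = rpois(n, 3), snp = rpois(n, 400))
  alu_norm <- (ft$alu_total - min(ft$alu_total)) /
    (max(ft$alu_total) - min(ft$alu_total))
  ft$delta_dq <- 0.8 * alu_norm + rnorm(n, sd = 0.05)
  fit <- multivariate_regression(ft)
  expect_true("alu_total" %in% fit$top)
  expect_length(fit$top, 5L)
  expect_gt(fit$r2, 0.5)
  # normalization maps every column to [0, 1] -- checked via coefficients:
  # the planted coefficient on the normalized scale is near 0.8
  expect_equal(unname(fit$coefficients["alu_total"]) *
                 (max(ft$delta_dq) - min(ft$delta_dq)), 0.8,
               tolerance = 0.15)
  ft$flat <- 1
  expect_error(multivariate_regression(ft, predictors = c("alu_total", "flat")),
               "zero-variance")
  ft$dup <- ft$alu_total
  expect_error(multivariate_regression(ft, predictors = c("alu_total", "dup")),
               "rank-deficient")
})

test_that("rm_binning partitions fragments into fixed-width ranges", {
  tb <- data.frame(delta_dq = c(0.80, 0.84, 0.91, 1.30))
  b <- rm_binning(tb, bin_width = 0.05)
  occupied <- b[b$n > 0, ]
  expect_equal(occupied$bin_start, c(0.80, 0.90, 1.30), tolerance = 1e-9)
  expect_equal(occupied$n, c(2L, 1L, 1L))
  expect_equal(sum(b$n), 4L)

  single <- rm_binning(data.frame(delta_dq = 1.0))
  expect_equal(sum(single$n > 0), 1L)

  for (w in c(0.03, 0.05, 0.2)) {
    set.seed(43)
    tb2 <- data.frame(delta_dq = runif(100, 0.79, 1.56))
    expect_equal(sum(rm_binning(tb2, bin_width = w)$n), 100L)
  }
  expect_error(rm_binning(tb, bin_width = 0), "> 0")
})

test_that("rm_binning aggregates a feature per bin", {
  tb <- data.frame(delta_dq = c(0.80, 0.84, 1.30), alu_total = c(10, 20, 5))
  b <- rm_binning(tb, feature = "alu_total", bin_width = 0.05)
  occ <- b[b$n > 0, ]
  expect_equal(occ$feature_sum, c(30, 5))
  expect_equal(occ$feature_mean, c(15, 5))
})

test_that("threshold classification is an inclusive conjunction", {
  tb <- data.frame(fragment_id = paste0("f", 1:4),
                   delta_dq = c(1.2, 1.2, 1.159, 1.0),
                   alu_total = c(300, 100, 217.9, 300))
  cl <- threshold_classify(tb)
  expect_equal(as.character(cl$classification$group),
               c("high", "LMM", "high", "LMM"))
  # partition: group sizes add up
  expect_equal(sum(cl$summary$n), nrow(tb))
  expect_equal(cl$summary$mean_alu[cl$summary$group == "high"],
               mean(c(300, 217.9)))
})

test_that("information_dimension_table keeps order and flags missing values", {
  tb <- data.frame(fragment_id = c("a", "b", "c"), d1 = c(1.9, 1.8, 1.7),
                   d_minus1 = c(2.0, 2.1, 2.2), alu_total = c(1, 2, 3))
  out <- information_dimension_table(tb)
  expect_identical(out$fragment_id, c("a", "b", "c"))
  expect_identical(names(out), c("fragment_id", "d1", "d_minus1",
                                 "alu_total"))
  tb$d_minus1[2] <- NA
  expect_error(information_dimension_table(tb), "b")
})

test_that("chromosome_summary averages fragments per chromosome", {
  tb <- data.frame(fragment_id = c("x1", "x2", "y1"),
                   chromosome = c("X", "X", "Y"),
                   start = c(0, 10, 0), end = c(10, 20, 10),
                   delta_dq = c(1.0, 1.2, 0.9), alu_total = c(10, 30, 5))
  cs <- chromosome_summary(tb)
  expect_equal(cs$summary$mean_delta_dq, c(1.1, 0.9))
  expect_equal(cs$summary$mean_alu_total, c(20, 5))
  expect_equal(cs$summary$n_fragments, c(2L, 1L))
  # invariant to fragment order
  cs2 <- chromosome_summary(tb[c(3, 1, 2), ])
  expect_equal(cs2$summary[order(cs2$summary$chromosome), ],
               cs$summary[order(cs$summary$chromosome), ],
               ignore_attr = TRUE)
})

test_that("chromosome_summary builds per-chromosome mean spectra", {
  rec <- c(cA = rand_dna(2000, seed = 44), cB = rand_dna(1000, seed = 45))
  fr <- fragment_genome(rec, fragment_length = 1000)
  sps <- fragment_spectra(fr, q = -2:2, k_range = 1:3)
  ct <- count_per_fragment(fr, data.frame(chromosome = character(),
                                          start = numeric(), end = numeric(),
                                          category = character(),
                                          name = character()))
  ft <- assemble_feature_table(sps, ct, fr)
  cs <- chromosome_summary(ft, sps)
  expect_equal(dim(cs$spectra), c(2L, 5L))
  manual <- colMeans(rbind(sps[[1]]$dq, sps[[2]]$dq))
  expect_equal(unname(cs$spectra["cA", ]), manual)
})

test_that("clustering merges identical spectra first and errors sensibly", {
  m <- rbind(a = c(2, 1.8, 1.6), b = c(2, 1.8, 1.6),
             c = c(1.6, 1.8, 2.0))
  ct <- cluster_chromosomes(m, n_groups = 2)
  expect_equal(ct$groups[["a"]], ct$groups[["b"]])
  expect_false(ct$groups[["a"]] == ct$groups[["c"]])
  # identical pair merges at similarity 1
  expect_equal(max(ct$similarities), 1, tolerance = 1e-12)
  expect_error(cluster_chromosomes(m, n_groups = 5), "fewer chromosomes")
})

test_that("planted archetype groups are recovered exactly at low noise", {
  arch <- archetype_spectra(8, noise_sd = 0.005, relative = TRUE,
                            seed = 46)
  ct <- cluster_chromosomes(arch$spectra, n_groups = 3)
  expect_true(same_partition(ct$groups, arch$labels))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(ct, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, rownames(arch$spectra))
})

test_that("region_summary splits runs as equally as possible", {
  tb <- data.frame(fragment_id = paste0("f", 1:9), chromosome = "c",
                   start = (0:8) * 10, end = (1:9) * 10,
                   delta_dq = c(1, 1, 1, 2, 2, 3, 3, 4, 4))
  rs <- region_summary(tb, "c", n_regions = 4)
  expect_equal(rs$n_fragments, c(3L, 2L, 2L, 2L))  # earlier runs take remainder
  expect_equal(rs$mean_delta_dq, c(1, 2, 3, 4))
  expect_equal(sum(rs$n_fragments), 9L)

  rs8 <- region_summary(tb[1:8, ], "c", n_regions = 4)
  expect_equal(rs8$n_fragments, rep(2L, 4))
  expect_error(region_summary(tb[1:3, ], "c", n_regions = 4), "fewer")
})
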