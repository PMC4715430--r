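test_that("pairwise differences use pairwise deletion", {
  m <- seq_alignment(c(a = "ACGTACGTAC",
                       b = "ACGTACGTAC",
                       c = "ACTTA-GTAC"))
  pd <- pairwise_diffs(m)
  expect_equal(pd$diffs["a", "b"], 0)
  expect_equal(pd$valid["a", "b"], 10)
  expect_equal(pd$valid["a", "c"], 9)     # gap column excluded
  expect_equal(pd$diffs["a", "c"], 1)
  expect_false(any(pd$missing_pairs))
  # N treated as missing
  m2 <- seq_alignment(c(a = "ACGT", b = "NCGT"))
  pd2 <- pairwise_diffs(m2)
  expect_equal(pd2$valid["a", "b"], 3)
})

test_that("K2P distance matches its closed form and ape's implementation", {
  # P = 0.1 (10 transitions), Q = 0.05 (5 transversions) on 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  d <- k2p_distance(seq_alignment(c(x = a, y = b)))
  expect_equal(d["x", "y"], -0.5 * log(0.75) - 0.25 * log(0.9),
               tolerance = 1e-12)
  # zero divergence
  d0 <- k2p_distance(seq_alignment(c(x = a, y = a)))
  expect_equal(d0["x", "y"], 0)
  # random alignments: symmetric and equal to ape::dist.dna(model="K80")
  set.seed(31)
  for (i in 1:4) {
    s <- rand_seq(120)
    rows <- vapply(1:5, function(j) mutate_k(s, sample(0:8, 1)),
                   character(1))
    names(rows) <- paste0("t", 1:5)
    d <- k2p_distance(seq_alignment(rows))
    expect_equal(unclass(d)[1:5, 1:5], t(unclass(d)[1:5, 1:5]))
    bin <- ape::as.DNAbin(t(sapply(strsplit(rows, ""), identity)))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))
    expect_equal(unclass(d)[rownames(ref), colnames(ref)], ref,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # saturation flagged as NA
  sat <- seq_alignment(c(x = "ACGT", y = "GTAC"))
  dsat <- k2p_distance(sat)
  expect_true(is.na(dsat["x", "y"]))
})

test_that("diversity summary matches hand enumeration", {
  s <- strrep("A", 100)
  aln0 <- seq_alignment(setNames(rep(s, 4), paste0("t", 1:4)))
  st0 <- diversity_summary(aln0, d_pvalue = FALSE)
  expect_equal(st0$S, 0)
  expect_equal(st0$pi, 0)
  expect_equal(st0$theta_w, 0)
  expect_true(is.na(st0$D))
  expect_match(st0$D_reason, "segregating")
  # n = 4, one singleton site: k_hat = 3/6 pairs differ, pi = k/L,
  # theta_w = 1/(a1 * 100) with a1 = 1 + 1/2 + 1/3
  s2 <- s; substr(s2, 10, 10) <- "T"
  aln1 <- seq_alignment(setNames(c(s, s, s, s2), paste0("t", 1:4)))
  st1 <- diversity_summary(aln1, d_pvalue = FALSE)
  expect_equal(st1$S, 1)
  expect_equal(st1$k_hat, 0.5)
  expect_equal(st1$pi, 0.005)
  expect_equal(st1$theta_w, 1 / ((1 + 1 / 2 + 1 / 3) * 100),
               tolerance = 1e-12)
  # invariance under row permutation
  set.seed(32)
  rows <- setNames(vapply(1:6, function(i) mutate_k(rand_seq(80), 2),
                          character(1)), paste0("r", 1:6))
  a <- diversity_summary(seq_alignment(rows), d_pvalue = FALSE)
  b <- diversity_summary(seq_alignment(rows[sample(6)]),
                         d_pvalue = FALSE)
  for (f in c("S", "k_hat", "pi", "theta_w", "D")) {
    expect_equal(a[[f]], b[[f]])
  }
})

test_that("Tajima's D equals an independently coded evaluation", {
  expect_equal(tajima_d(10, 5, 1.0), oracle_tajima(10, 5, 1.0),
               tolerance = 1e-12)
  expect_equal(tajima_d(25, 12, 3.3), oracle_tajima(25, 12, 3.3),
               tolerance = 1e-12)
  # k_hat exactly S/a1 gives D = 0
  a1 <- sum(1 / (1:9))
  expect_equal(as.numeric(tajima_d(10, 5, 5 / a1)), 0)
  # undefined cases are missing, never zero
  expect_true(is.na(tajima_d(3, 5, 1)))
  expect_true(is.na(tajima_d(10, 0, 0)))
})

test_that("beta null has the documented support and p-value behaviour", {
  null <- tajima_null(20)
  expect_equal(null$a1, sum(1 / (1:19)))
  expect_lt(null$D_min, 0)
  expect_gt(null$D_max, 0)
  expect_gt(null$beta_alpha, 0)
  expect_gt(null$beta_beta, 0)
  # center of a mean-zero null
  expect_gt(tajima_pvalue(0, 20), 0.5)
  # monotone tail toward the lower bound
  ps <- vapply(c(-1, -1.5, -2, -2.5), tajima_pvalue, numeric(1), n = 20)
  expect_true(all(diff(ps) < 0))
  expect_lt(tajima_pvalue(null$D_min + 1e-9, 20), 1e-4)
})

test_that("beta and simulation nulls agree at moderate sample sizes", {
  # spot check here (the acceptance suite covers the full grid)
  p_beta <- tajima_pvalue(-1.5, 20)
  p_sim <- tajima_pvalue(-1.5, 20, S = 10, mode = "simulation",
                         n_replicates = 4000, seed = 99)
  expect_lt(abs(p_beta - p_sim), 0.03)
})

test_that("G_ST matches fixed-difference and panmixia anchors", {
  # two locales fixed for different haplotypes
  aln <- aln_with_meta(c(rep("AAAA", 5), rep("TTTT", 5)),
                       rep(c("K", "L"), each = 5))
  g <- gst_test(aln, B = 99, seed = 1)
  expect_equal(g$G_ST, 1)
  expect_lt(g$p_value, 0.05)
  # identical haplotype frequencies in all locales: the uncorrected
  # estimator is exactly zero; the small-sample-corrected one is near
  # zero (slightly negative, shrinking as n_p grows)
  haps <- c("AAAA", "TTTT")
  rows <- c(rep(haps, each = 10), rep(haps, each = 10))
  aln2 <- aln_with_meta(rows, rep(c("K", "L"), each = 20))
  g2u <- gst_test(aln2, B = 19, seed = 1, corrected = FALSE)
  expect_equal(g2u$G_ST, 0)
  rows50 <- c(rep(haps, each = 25), rep(haps, each = 25))
  aln2b <- aln_with_meta(rows50, rep(c("K", "L"), each = 50))
  g2c <- gst_test(aln2b, B = 19, seed = 1)
  expect_lt(abs(g2c$G_ST), 0.02)
  # monomorphic: missing
  aln3 <- aln_with_meta(rep("AAAA", 8), rep(c("K", "L"), each = 4))
  g3 <- gst_test(aln3, B = 19, seed = 1)
  expect_true(is.na(g3$G_ST))
  # seed determinism
  aln4 <- sim_panmictic_aln(4, 5, 100)
  r1 <- gst_test(aln4, B = 99, seed = 5)
  r2 <- gst_test(aln4, B = 99, seed = 5)
  expect_identical(r1, r2)
})

test_that("permutation p-values are uniform under the null (KS sanity)", {
  # a continuous statistic gives p-values uniform on the permutation
  # grid: Phi_ST on Gaussian-coordinate distances
  set.seed(33)
  ps <- replicate(400, {
    x <- rnorm(24)
    d2 <- outer(x, x, function(a, b) (a - b)^2)
    loc <- sample(rep(c("K", "L", "A"), each = 8))
    amova(d2, loc, c(K = "west", L = "east", A = "east"), B = 99)$p_st
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # discrete haplotype statistics tie heavily, so their permutation
  # p-values are valid (super-uniform) rather than exactly uniform
  haps <- c("AAAA", "AATT", "TTTT", "TTAA")
  ps2 <- replicate(300, {
    rows <- sample(haps, 24, replace = TRUE)
    aln <- aln_with_meta(rows, sample(rep(c("K", "L", "A"), each = 8)))
    gst_test(aln, B = 99)$p_value
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    band <- exact_binomial_band(length(ps2), alpha)
    expect_lte(sum(ps2 <= alpha), band[2])
  }
})
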