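test_that("chi-squared goodness of fit equals its closed form", {
  g <- chi_squared_gof(7, 29, 0.05)
  e1 <- 0.05 * 29
  expect_equal(g$chi2, (7 - e1)^2 / e1 + (22 - 27.55)^2 / 27.55,
               tolerance = 1e-12)
  expect_equal(g$df, 1L)
  # observed equal to expected gives zero
  expect_equal(chi_squared_gof(1, 20, 0.05)$chi2, 0)
  # property grid against the closed form and chisq.test
  for (total in c(10, 29, 31, 100)) {
    for (obs in c(0, 1, floor(total / 3), total)) {
      for (alpha in c(0.01, 0.05, 0.1)) {
        g <- chi_squared_gof(obs, total, alpha)
        direct <- (obs - alpha * total)^2 / (alpha * total) +
          (total - obs - (1 - alpha) * total)^2 / ((1 - alpha) * total)
        expect_equal(g$chi2, direct, tolerance = 1e-9)
        ref <- suppressWarnings(
          chisq.test(c(obs, total - obs), p = c(alpha, 1 - alpha)))
        expect_equal(g$chi2, unname(ref$statistic), tolerance = 1e-9)
        expect_equal(g$p_value, unname(ref$p.value), tolerance = 1e-9)
      }
    }
  }
  expect_error(chi_squared_gof(5, 0), "total")
  expect_error(chi_squared_gof(5, 4), "observed")
})

test_that("significance counts respect alpha and missing p-values", {
  tbl <- data.frame(p_a = c(0.01, 0.2, NA, 0.04),
                    p_b = c(1, 1, 1, 1))
  sc <- significance_counts(tbl, alpha = 0.05)
  expect_equal(sc$observed[sc$test == "a"], 2)
  expect_equal(sc$total[sc$test == "a"], 3)
  expect_equal(sc$observed[sc$test == "b"], 0)
  # significance is strict p < alpha, so every p below 1 is counted at
  # alpha = 1
  tbl2 <- data.frame(p_a = c(0.2, 0.999, 0.005))
  sc2 <- significance_counts(tbl2, alpha = 1)
  expect_equal(sc2$observed, sc2$total)
  # strict inequality at the boundary
  tbl3 <- data.frame(p_a = c(0.05, 0.049))
  expect_equal(significance_counts(tbl3, alpha = 0.05)$observed, 1)
})

test_that("group aggregates use the standard median convention", {
  tbl <- data.frame(D = c(-2, -1, 0, -3), G_ST = c(0.1, 0.2, 0.3, 0.4))
  grp <- c("f", "f", "f", "m")
  ag <- group_aggregates(tbl, grp)
  expect_equal(ag$median_D[ag$group == "f"], -1)      # odd count
  expect_equal(ag$median_D[ag$group == "overall"], -1.5)  # even count
  expect_equal(ag$mean_G_ST[ag$group == "m"], 0.4)    # single-OTU group
  expect_equal(ag$n[ag$group == "overall"], 4)
})

test_that("rarefaction matches the hypergeometric closed form", {
  # counts (5,5), m = 1: 2 * (1 - choose(5,1)/choose(10,1)) = 1
  rc <- rarefaction_curve(c(5, 5), grid = c(1, 5, 10))
  expect_equal(rc$expected_richness[1], 1)
  expect_equal(rc$expected_richness[3], 2)   # m = N recovers richness
  # against direct evaluation of the formula
  counts <- c(14, 3, 1, 25, 7)
  N <- sum(counts)
  grid <- c(1, 5, 20, N)
  rc2 <- rarefaction_curve(counts, grid = grid)
  direct <- vapply(grid, function(m) {
    sum(1 - exp(lchoose(N - counts, m) - lchoose(N, m)))
  }, numeric(1))
  expect_equal(rc2$expected_richness, direct, tolerance = 1e-9)
  # nondecreasing and concave on a unit-spaced grid
  rc3 <- rarefaction_curve(counts, grid = 1:N)
  expect_true(all(diff(rc3$expected_richness) >= -1e-12))
  expect_true(all(diff(diff(rc3$expected_richness)) <= 1e-9))
  expect_error(rarefaction_curve(c(5, 5), grid = 11), "exceeds")
})

test_that("rarefaction closed form agrees with Monte-Carlo resampling", {
  set.seed(51)
  counts <- c(40, 12, 5, 2, 1)
  N <- sum(counts)
  pool <- rep(seq_along(counts), counts)
  for (m in c(5, 15, 30)) {
    draws <- replicate(4000, length(unique(sample(pool, m))))
    expected <- rarefaction_curve(counts, grid = m)$expected_richness
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - expected), 3 * se + 1e-9)
  }
})

test_that("community table flags are self-consistent and reports rebuild", {
  rows <- list(
    list(otu_id = "OTU_1", n = 20, stats = list(pi = 0.01,
         theta_w = 0.02, D = -2.1, D_pvalue = 0.01),
         gst = list(G_ST = 0.1, p_value = 0.2),
         amova = list(phi_ct = 0.0, phi_sc = 0.1, phi_st = 0.1,
                      p_ct = 0.5, p_sc = 0.04, p_st = 0.02),
         gsi = list(list(gsi = 0.4, p_value = 0.01),
                    list(gsi = 0.2, p_value = 0.3)),
         mantel = list(r = 0.1, p_value = 0.6)),
    list(otu_id = "OTU_2", n = 11, stats = NULL, gst = NULL,
         amova = NULL, gsi = NULL, mantel = NULL))
  tbl <- community_table(rows, alpha = 0.05)
  expect_equal(nrow(tbl), 2)
  expect_true(tbl$sig_phi_sc[1])
  expect_false(tbl$sig_G_ST[1])
  expect_true(is.na(tbl$p_phi_st[2]))
  # flags recomputed from emitted p-values reproduce the emitted flags
  for (pc in grep("^p_", names(tbl), value = TRUE)) {
    expect_equal(!is.na(tbl[[pc]]) & tbl[[pc]] < 0.05,
                 tbl[[sub("^p_", "sig_", pc)]])
  }
  gofs <- community_gof(tbl, alpha = 0.05)
  expect_equal(gofs$total[gofs$test == "phi_st"], 1)
  out <- withr::local_tempdir()
  files <- build_report(tbl, gofs, out, config = pipeline_config())
  expect_true(all(file.exists(files)))
  reread <- read.delim(files[["community_table"]])
  expect_equal(nrow(reread), 2)
  # empty table still produces a report, with a warning
  expect_warning(
    build_report(community_table(list()), community_gof(
      data.frame(test = "phi_st", observed = 0L, total = 0L)),
      withr::local_tempdir()),
    "empty")
})

test_that("published survey tables load with the expected shape", {
  surv <- inquiline_survey()
  expect_equal(nrow(surv), 32)       # 31 OTUs + host
  expect_equal(sum(surv$group == "fungi"), 15)
  expect_equal(sum(surv$group == "mite"), 7)
  expect_equal(sum(surv$D_significant[surv$group != "host"]), 21)
  counts <- inquiline_structure_counts()
  expect_equal(nrow(counts), 6)
  expect_true(all(counts$observed <= counts$total))
})
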