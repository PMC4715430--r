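test_that("AMOVA recovers the two-locale fixed-difference anchor", {
  d2 <- matrix(1, 6, 6)
  d2[1:3, 1:3] <- 0
  d2[4:6, 4:6] <- 0
  res <- amova(d2, rep(c("p1", "p2"), each = 3),
               c(p1 = "west", p2 = "east"), B = 49, seed = 1)
  expect_equal(res$sigma2[["c"]], 0)
  expect_equal(res$phi_st, 1)
  # SSD additivity
  expect_equal(res$ssd[["total"]],
               sum(res$ssd[c("among_regions",
                             "among_locales_within_regions",
                             "within_locales")]))
})

test_that("AMOVA equals the brute-force nested decomposition and aov", {
  set.seed(41)
  for (i in 1:12) {
    inst <- rand_amova_instance()
    d2 <- outer(inst$x, inst$x, function(a, b) (a - b)^2)
    res <- amova(d2, inst$locale, inst$region_of, B = 1)
    ora <- oracle_amova_scalar(inst$x, inst$locale, inst$region_of)
    expect_equal(unname(res$ssd), c(ora$ssd), tolerance = 1e-10)
    expect_equal(res$sigma2, ora$sigma2, tolerance = 1e-10)
    expect_equal(res$phi_st, ora$phi_st, tolerance = 1e-10)
    expect_equal(res$phi_sc, ora$phi_sc, tolerance = 1e-10)
    expect_equal(res$phi_ct, ora$phi_ct, tolerance = 1e-10)
    # SSDs independently from R's nested ANOVA
    dfm <- data.frame(x = inst$x, locale = inst$locale,
                      region = unname(inst$region_of[inst$locale]))
    av <- anova(aov(x ~ region + region:locale, data = dfm))
    expect_equal(unname(res$ssd)[1:3], av[["Sum Sq"]],
                 tolerance = 1e-10)
  }
})

test_that("AMOVA SSD additivity holds exactly on arbitrary inputs", {
  set.seed(42)
  for (i in 1:8) {
    n <- sample(8:16, 1)
    locale <- sample(c("p1", "p2", "p3", "p4"), n, replace = TRUE)
    while (length(unique(locale)) < 3) {
      locale <- sample(c("p1", "p2", "p3", "p4"), n, replace = TRUE)
    }
    x <- matrix(rnorm(2 * n), ncol = 2)
    d2 <- as.matrix(dist(x))^2
    reg <- c(p1 = "west", p2 = "east", p3 = "east", p4 = "west")
    res <- amova(d2, locale, reg[unique(locale)], B = 1)
    expect_equal(res$ssd[["total"]],
                 sum(res$ssd[c("among_regions",
                               "among_locales_within_regions",
                               "within_locales")]),
                 tolerance = 1e-12)
  }
})

test_that("AMOVA permutation engine honours the seed and drops empties", {
  set.seed(43)
  aln <- sim_panmictic_aln(4, 5, 150)
  pd <- pairwise_diffs(aln)
  meta <- attr(aln, "meta")
  reg <- setNames(meta$region, meta$locale)
  reg <- reg[!duplicated(names(reg))]
  r1 <- amova(pd$diffs, meta$locale, reg, B = 99, seed = 17)
  r2 <- amova(pd$diffs, meta$locale, reg, B = 99, seed = 17)
  expect_identical(r1, r2)
  expect_warning(
    amova(pd$diffs, meta$locale, c(reg, zz = "east"), B = 9),
    "dropped")
})

test_that("NJ matches the three-point closed form and additive matrices", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[rownames(dm), colnames(dm)], dm, ignore_attr = TRUE)
  tip_edge <- function(tree, tip) {
    tree$edge.length[tree$edge[, 2] == which(tree$tip.label == tip)]
  }
  expect_equal(tip_edge(tr, "A"), 1)
  expect_equal(tip_edge(tr, "B"), 1)
  expect_equal(tip_edge(tr, "C"), 3)
  # additive matrices from random trees are recovered exactly
  set.seed(44)
  for (i in 1:8) {
    n <- sample(4:12, 1)
    ref <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(ref)
    est <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(ref), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)],
                 d, tolerance = 1e-8)
  }
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
  # negative branch lengths are clamped
  set.seed(45)
  x <- matrix(rnorm(12), ncol = 2)
  dn <- as.matrix(dist(x))
  dimnames(dn) <- list(paste0("t", 1:6), paste0("t", 1:6))
  expect_true(all(nj_tree(dn)$edge.length >= 0))
})

test_that("GSI hits its monophyly and full-dispersal anchors", {
  set.seed(46)
  for (i in 1:6) {
    n <- sample(c(8, 16, 32, 64), 1)
    tr <- ape::rtree(n)
    # monophyletic group: tips of a random internal clade
    repeat {
      node <- sample((n + 2):(n + tr$Nnode), 1)
      tips <- ape::extract.clade(tr, node)$tip.label
      if (length(tips) >= 2 && length(tips) < n) break
    }
    grp <- setNames(ifelse(tr$tip.label %in% tips, "g", "o"),
                    tr$tip.label)
    expect_equal(gsi_test(tr, grp, "g", B = 9, seed = 1)$gsi, 1)
    # maximally dispersed group: one tip from every cherry
    is_cherry <- vapply((n + 1):(n + tr$Nnode), function(v) {
      ch <- tr$edge[tr$edge[, 1] == v, 2]
      all(ch <= n)
    }, logical(1))
    cherry_nodes <- ((n + 1):(n + tr$Nnode))[is_cherry]
    picked <- vapply(cherry_nodes, function(v) {
      tr$edge[tr$edge[, 1] == v, 2][1]
    }, numeric(1))
    grp2 <- setNames(rep("o", n), tr$tip.label)
    grp2[tr$tip.label[picked]] <- "g"
    expect_equal(gsi_test(tr, grp2, "g", B = 9, seed = 1)$gsi, 0)
  }
})

test_that("GSI is a topology-only statistic with a calibrated null", {
  set.seed(47)
  tr <- ape::rtree(32)
  grp <- setNames(sample(rep(c("e", "w"), 16)), tr$tip.label)
  r1 <- gsi_test(tr, grp, "e", B = 99, seed = 3)
  tr2 <- tr
  tr2$edge.length <- runif(length(tr$edge.length), 0.1, 5)
  r2 <- gsi_test(tr2, grp, "e", B = 99, seed = 3)
  expect_equal(r1$gsi, r2$gsi)
  # random labels: observed gsi sits inside its permutation distribution
  expect_gt(r1$p_value, 0.01)
  expect_error(gsi_test(tr, setNames(rep("w", 32), tr$tip.label), "e"),
               "fewer than 2")
})

test_that("Mantel test matches its correlation anchors", {
  set.seed(48)
  co <- data.frame(locale = c("K", "C", "L", "A", "T"),
                   lat = runif(5, 30, 32), lon = runif(5, -93, -89))
  geo <- geo_distances(coords = co)
  r <- mantel_test(unclass(geo), geo, B = 99, seed = 1)
  expect_equal(r$r, 1)
  # affine invariance
  gen <- 3 * unclass(geo) + 2
  diag(gen) <- 0
  r2 <- mantel_test(gen, geo, B = 99, seed = 1)
  expect_equal(r2$r, 1)
  expect_error(mantel_test(geo[1:2, 1:2], geo[1:2, 1:2]),
               "fewer than 3")
})
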