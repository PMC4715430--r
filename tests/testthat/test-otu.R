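make_samples <- function() {
  validate_sample_table(data.frame(
    sample_id = c("k1", "c1", "l1", "a1", "t1"),
    locale = c("K", "C", "L", "A", "T"),
    region = c("west", "west", "east", "east", "east"),
    month = "June", stringsAsFactors = FALSE))
}

test_that("trimming keeps 5'-prefixes of exactly trim_length", {
  set.seed(1)
  reads <- data.frame(read_id = c("a", "b", "c"),
                      sample_id = "k1",
                      bases = c(rand_seq(280), rand_seq(275), rand_seq(270)),
                      stringsAsFactors = FALSE)
  out <- trim_reads(reads, 275)
  expect_equal(nrow(out), 2)
  expect_true(all(nchar(out$bases) == 275))
  expect_equal(out$bases[1], substr(reads$bases[1], 1, 275))
  expect_equal(attr(out, "n_discarded"), 1)
  expect_warning(trim_reads(reads, 300), "no reads")
})

test_that("dereplication conserves abundance and sorts deterministically", {
  samples <- make_samples()
  reads <- data.frame(read_id = sprintf("r%d", 1:5),
                      sample_id = c("k1", "k1", "l1", "l1", "t1"),
                      bases = c("AAA", "AAA", "AAT", "AAT", "AAC"),
                      stringsAsFactors = FALSE)
  u <- dereplicate(reads, samples)
  # tie between AAT (2) and AAA (2): lexicographic
  expect_equal(u$bases, c("AAA", "AAT", "AAC"))
  expect_equal(u$abundance, c(2L, 2L, 1L))
  expect_equal(sum(u$abundance), nrow(reads))
  expect_equal(unname(u$locale_counts[1, c("K", "L")]), c(2L, 0L))
  expect_equal(u$members[[2]], c("r3", "r4"))
  # permuting input reads leaves the dereplicated output invariant
  set.seed(3)
  u2 <- dereplicate(reads[sample(5), ], samples)
  u2$members <- lapply(u2$members, sort)
  u$members <- lapply(u$members, sort)
  expect_equal(u, u2)
  bad <- reads; bad$sample_id[1] <- "zz"
  expect_error(dereplicate(bad, samples), "absent from the sample table")
})

test_that("global identity matches closed forms and the DP score oracle", {
  set.seed(42)
  a <- rand_seq(275)
  expect_equal(global_identity(a, a), 1.0)
  b <- mutate_k(a, 1)
  expect_equal(global_identity(a, b), 274 / 275)
  # internal deletion: identity from the known alignment
  d3 <- paste0(substr(a, 1, 100), substr(a, 104, 275))
  expect_equal(global_identity(a, d3), 272 / 275)
  # symmetry
  expect_equal(global_identity(a, d3), global_identity(d3, a))
  expect_error(global_identity("", a), "empty")
  # score agrees with an independent ends-free affine DP on perturbed
  # pairs
  for (i in 1:6) {
    x <- rand_seq(60)
    y <- mutate_k(x, sample(1:6, 1))
    if (i > 3) y <- paste0(substr(y, 1, 29), substr(y, 33, 60))
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(y), subject = x,
      type = "overlap",
      substitutionMatrix = codiv:::identity_submat(),
      gapOpening = 4, gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle_align_score(y, x))
  }
})

test_that("greedy clustering follows the abundance-sorted contract", {
  samples <- make_samples()
  set.seed(7)
  A <- rand_seq(275)
  A1 <- mutate_k(A, 1)              # 99.6% to A
  B <- mutate_k(A, 22)              # 92% to A
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:18),
    sample_id = rep(c("k1", "l1", "t1"), 6),
    bases = c(rep(A, 10), rep(A1, 5), rep(B, 3)),
    stringsAsFactors = FALSE)
  u <- dereplicate(reads, samples)
  ot <- cluster_otus(u, threshold = 0.97)
  expect_equal(length(ot$otus), 2)
  expect_equal(ot$otus[[1]]$centroid, A)
  expect_equal(ot$otus[[1]]$abundance, 15)
  expect_equal(ot$otus[[2]]$abundance, 3)
  # determinism: byte-identical rerun
  ot2 <- cluster_otus(u, threshold = 0.97)
  expect_identical(ot, ot2)
  # unsorted input rejected
  bad <- u
  bad$bases <- rev(bad$bases); bad$abundance <- rev(bad$abundance)
  bad$members <- rev(bad$members)
  bad$locale_counts <- bad$locale_counts[3:1, , drop = FALSE]
  expect_error(cluster_otus(bad), "sorted")
  # abundance conservation including chimera discards
  expect_equal(sum(vapply(ot$otus, `[[`, numeric(1), "abundance")) +
                 sum(u$abundance[ot$chimeras]), sum(u$abundance))
  # membership identities all above threshold
  for (o in ot$otus) expect_true(all(o$member_identity >= 0.97))
})

test_that("unrelated sequences never merge through chance overlaps", {
  set.seed(11)
  seqs <- replicate(6, rand_seq(275))
  samples <- make_samples()
  reads <- data.frame(read_id = sprintf("r%d", 1:6), sample_id = "k1",
                      bases = seqs, stringsAsFactors = FALSE)
  u <- dereplicate(reads, samples)
  ot <- cluster_otus(u, threshold = 0.97, chimera_check = FALSE)
  expect_equal(length(ot$otus), 6)
})

test_that("chimera screen flags constructed crossovers and spares others", {
  set.seed(13)
  P1 <- rand_seq(275)
  P2 <- mutate_k(P1, 27)            # ~90% mutual identity
  chi <- paste0(substr(P1, 1, 130), substr(P2, 131, 275))
  v <- screen_chimera(chi, c(P1, P2), threshold = 0.97)
  expect_equal(v$verdict, "chimeric")
  expect_true(abs(v$breakpoint - 130) <= 10)
  expect_equal(screen_chimera(P1, c(P1, P2), 0.97)$verdict, "clean")
  # single centroid: always clean
  expect_equal(screen_chimera(chi, P1, 0.97)$verdict, "clean")
  # false-positive rate on unrelated random queries below 1%
  fp <- sum(replicate(1000, {
    screen_chimera(rand_seq(275), c(P1, P2), 0.97)$verdict == "chimeric"
  }))
  expect_lt(fp / 1000, 0.01)
})

test_that("comparative filter applies both thresholds at the boundary", {
  samples <- make_samples()
  mk_otu <- function(west, east) {
    set.seed(east * 100 + west)
    seqs <- c(rep(rand_seq(275), west + east))
    reads <- data.frame(
      read_id = sprintf("x%d_%d_%d", west, east, seq_len(west + east)),
      sample_id = c(rep("k1", west), rep("l1", east)),
      bases = seqs, stringsAsFactors = FALSE)
    reads
  }
  reads <- rbind(mk_otu(7, 3), mk_otu(12, 2), mk_otu(4, 5))
  u <- dereplicate(reads, samples)
  ot <- cluster_otus(u, threshold = 0.97, chimera_check = FALSE)
  ot <- add_region_counts(ot, samples)
  kept <- filter_comparative(ot, min_total = 10, min_per_region = 3)
  rc <- lapply(kept$otus, `[[`, "region_counts")
  # only {west 7, east 3} passes: {12, 2} fails per-region,
  # {4, 5} fails the total
  expect_equal(length(kept$otus), 1)
  expect_equal(unname(rc[[1]][c("east", "west")]), c(3, 7))
  expect_error(filter_comparative(cluster_otus(u, verify = FALSE)),
               "region counts")
})
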