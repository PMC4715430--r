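# Independent oracles and small fixture builders used across the suite.

rand_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# substitute k random sites with a different base
mutate_k <- function(seq, k) {
  L <- nchar(seq)
  pos <- sample.int(L, k)
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  seq
}

# --- exhaustive affine-gap ends-free DP (Gotoh), score only -----------
# match +1, mismatch -1, gap of length L costs 5 + (L - 1); terminal
# gaps free. Independent of the Biostrings-based implementation.
oracle_align_score <- function(a, b) {
  A <- strsplit(a, "")[[1L]]
  B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  open <- 4; ext <- 1
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  M[1L, ] <- 0; M[, 1L] <- 0       # free leading gaps
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (A[i - 1L] == B[j - 1L]) 1 else -1
      M[i, j] <- s + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                         Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext,
                     Y[i - 1L, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext,
                     X[i, j - 1L] - open - ext)
    }
  }
  best_state <- pmax(M, X, Y)
  max(best_state[, m + 1L], best_state[n + 1L, ])  # free trailing gaps
}

# --- second, independently written set of Tajima constants ------------
oracle_tajima <- function(n, S, k_hat) {
  aa1 <- 0; aa2 <- 0
  for (i in 1:(n - 1)) {
    aa1 <- aa1 + 1 / i
    aa2 <- aa2 + 1 / (i * i)
  }
  bb1 <- (n + 1) / (3 * (n - 1))
  bb2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  cc1 <- bb1 - 1 / aa1
  cc2 <- bb2 - (n + 2) / (aa1 * n) + aa2 / (aa1 * aa1)
  ee1 <- cc1 / aa1
  ee2 <- cc2 / (aa1 * aa1 + aa2)
  (k_hat - S / aa1) / sqrt(ee1 * S + ee2 * S * (S - 1))
}

# --- brute-force nested variance decomposition on scalar data ---------
# SSDs via explicit group-mean sums (cross-checked against aov in the
# tests) and variance components from independently coded coefficients.
oracle_amova_scalar <- function(x, locale, region_of_loc) {
  region <- unname(region_of_loc[locale])
  N <- length(x)
  locs <- unique(locale)
  regs <- unique(region)
  P <- length(locs); G <- length(regs)
  ss_total <- sum((x - mean(x))^2)
  ss_wp <- 0
  for (p in locs) ss_wp <- ss_wp + sum((x[locale == p] -
                                          mean(x[locale == p]))^2)
  ss_wg <- 0
  for (g in regs) ss_wg <- ss_wg + sum((x[region == g] -
                                          mean(x[region == g]))^2)
  ssd_ap <- ss_wg - ss_wp
  ssd_ag <- ss_total - ss_wg
  ms_wp <- ss_wp / (N - P)
  ms_ap <- ssd_ap / (P - G)
  ms_ag <- ssd_ag / (G - 1)
  n_p <- sapply(locs, function(p) sum(locale == p))
  names(n_p) <- locs
  N_g <- sapply(regs, function(g) sum(region == g))
  names(N_g) <- regs
  sum_np2_over_Ng <- 0
  for (g in regs) {
    in_g <- locs[sapply(locs, function(p) {
      unname(region_of_loc[p]) == g
    })]
    sum_np2_over_Ng <- sum_np2_over_Ng + sum(n_p[in_g]^2) / N_g[[g]]
  }
  n1 <- (N - sum_np2_over_Ng) / (P - G)
  n2 <- (sum_np2_over_Ng - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(N_g^2) / N) / (G - 1)
  sc <- ms_wp
  sb <- (ms_ap - sc) / n1
  sa <- (ms_ag - sc - n2 * sb) / n3
  tot <- sa + sb + sc
  list(ssd = c(ssd_ag, ssd_ap, ss_wp, ss_total),
       sigma2 = c(a = sa, b = sb, c = sc),
       phi_ct = sa / tot, phi_sc = sb / (sb + sc),
       phi_st = (sa + sb) / tot)
}

# random nested design: 3 locales in 2 regions, n <= 10 individuals
rand_amova_instance <- function(n_max = 10L) {
  repeat {
    sizes <- sample(2:4, 3L, replace = TRUE)
    if (sum(sizes) <= n_max) break
  }
  locale <- rep(c("p1", "p2", "p3"), times = sizes)
  region_of <- c(p1 = "west", p2 = "east", p3 = "east")
  x <- rnorm(sum(sizes), mean = rep(c(0, 1, 3), times = sizes))
  list(x = x, locale = locale, region_of = region_of)
}

# small alignment straight from strings with locale/region metadata
aln_with_meta <- function(strings, locales, regions = NULL) {
  ids <- sprintf("r%02d", seq_along(strings))
  if (is.null(regions)) regions <- rep("east", length(strings))
  meta <- data.frame(id = ids, sample_id = ids, locale = locales,
                     region = regions, stringsAsFactors = FALSE)
  seq_alignment(stats::setNames(strings, ids), meta = meta)
}

# panmictic simulated alignment over the default 5-locale design
sim_panmictic_aln <- function(per_deme = 6L, theta = 5, L = 275L) {
  demes <- default_demes(per_deme)
  region_of <- stats::setNames(demes$region, demes$locale)
  sizes <- stats::setNames(rep(per_deme, nrow(demes)), demes$locale)
  tree <- simulate_genealogy(sizes, region_of, tau = 0)
  aln <- mutate_sequences(tree, theta, L)
  deme <- attr(tree, "deme")
  meta <- data.frame(id = rownames(aln),
                     sample_id = rownames(aln),
                     locale = unname(deme[rownames(aln)]),
                     stringsAsFactors = FALSE)
  meta$region <- unname(region_of[meta$locale])
  seq_alignment(unclass(aln), meta = meta)
}

# structured (clean-barrier) simulated alignment
sim_structured_aln <- function(per_deme = 5L, theta = 5, tau = 10,
                               L = 275L) {
  demes <- default_demes(per_deme)
  region_of <- stats::setNames(demes$region, demes$locale)
  sizes <- stats::setNames(rep(per_deme, nrow(demes)), demes$locale)
  tree <- simulate_genealogy(sizes, region_of, tau = tau, m_within = 1,
                             m_between = 0)
  aln <- mutate_sequences(tree, theta, L)
  deme <- attr(tree, "deme")
  meta <- data.frame(id = rownames(aln),
                     sample_id = rownames(aln),
                     locale = unname(deme[rownames(aln)]),
                     stringsAsFactors = FALSE)
  meta$region <- unname(region_of[meta$locale])
  seq_alignment(unclass(aln), meta = meta)
}

exact_binomial_band <- function(n, p, conf = 0.95) {
  c(qbinom((1 - conf) / 2, n, p), qbinom(1 - (1 - conf) / 2, n, p))
}
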