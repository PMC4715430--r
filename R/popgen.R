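# Per-OTU diversity and differentiation: pairwise differences, K2P
# distances, pi, Watterson's theta, Tajima's D with its beta null, and
# haplotype G_ST with a permutation test.

as_aln_matrix <- function(aln) {
  if (inherits(aln, "seq_alignment")) {
    m <- unclass(aln)
    attr(m, "meta") <- NULL
    return(m)
  }
  if (is.matrix(aln)) return(aln)
  stop("expected a seq_alignment or character matrix")
}

aln_locales <- function(aln) {
  meta <- attr(aln, "meta")
  if (is.null(meta) || is.null(meta$locale)) {
    stop("alignment has no locale metadata")
  }
  meta$locale
}

#' Pairwise difference counts with pairwise deletion
#'
#' For each pair of rows, columns with `-` or `N` in either row are
#' excluded; differences are counted over the remaining (valid) columns.
#'
#' @param aln A `seq_alignment` (or character matrix) with >= 2 rows.
#' @return List with `diffs` (matrix of raw difference counts), `valid`
#'   (matrix of per-pair valid-site counts) and `missing_pairs` (logical
#'   matrix flagging pairs with zero valid columns).
#' @export
pairwise_diffs <- function(aln) {
  m <- as_aln_matrix(aln)
  if (nrow(m) < 2L) stop("pairwise_diffs needs at least 2 sequences")
  known <- (m != "-") & (m != "N")
  storage.mode(known) <- "numeric"
  valid <- tcrossprod(known)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b)
    storage.mode(ind) <- "numeric"
    matches <- matches + tcrossprod(ind)
  }
  diffs <- valid - matches
  dimnames(diffs) <- dimnames(valid) <- list(rownames(m), rownames(m))
  missing_pairs <- valid == 0
  diag(missing_pairs) <- FALSE
  list(diffs = diffs, valid = valid, missing_pairs = missing_pairs)
}

#' Kimura 2-parameter distance matrix
#'
#' Per pair, `P` and `Q` are the transition and transversion proportions
#' over pairwise-valid sites and `d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4`.
#' Saturated pairs (non-positive log arguments) are returned as `NA` and
#' flagged.
#'
#' @param aln A `seq_alignment` or character matrix.
#' @return Symmetric matrix of K2P distances with attributes `kind`
#'   (`"k2p"`) and `saturated` (logical matrix).
#' @export
k2p_distance <- function(aln) {
  m <- as_aln_matrix(aln)
  pd <- pairwise_diffs(m)
  if (any(pd$missing_pairs)) {
    stop("pair(s) with zero valid sites; K2P undefined")
  }
  ts <- matrix(0, nrow(m), nrow(m))
  for (pair in list(c("A", "G"), c("C", "T"))) {
    i1 <- (m == pair[1L]); storage.mode(i1) <- "numeric"
    i2 <- (m == pair[2L]); storage.mode(i2) <- "numeric"
    cross <- tcrossprod(i1, i2)
    ts <- ts + cross + t(cross)
  }
  P <- ts / pd$valid
  Q <- (pd$diffs - ts) / pd$valid
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  sat <- (arg1 <= 0) | (arg2 <= 0)
  diag(sat) <- FALSE
  d <- matrix(NA_real_, nrow(m), nrow(m), dimnames = dimnames(pd$diffs))
  ok <- !sat
  d[ok] <- -0.5 * log(arg1[ok]) - 0.25 * log(arg2[ok])
  diag(d) <- 0
  structure(d, kind = "k2p", saturated = sat,
            P = P, Q = Q)
}

harmonic_number <- function(n) sum(1 / seq_len(n))

#' Tajima's variance constants and beta-null parameters
#'
#' All constants are functions of the sample size `n`: `a1 = sum 1/i`,
#' `a2 = sum 1/i^2` (i = 1..n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`. The null support bounds are
#' `D_min = (2/n - 1/a1)/sqrt(e2)` and
#' `D_max = (n/(2(n-1)) - 1/a1)/sqrt(e2)` for even `n`
#' (`((n+1)/(2n) - 1/a1)/sqrt(e2)` for odd `n`); beta shape parameters
#' are chosen so the rescaled null has mean 0 and variance 1.
#'
#' @param n Number of sequences (>= 4 for a defined D).
#' @return List of class `tajima_null` with the constants, bounds and
#'   beta shapes (`NA` shapes when the mean-0/variance-1 construction is
#'   infeasible).
#' @export
tajima_null <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d_min <- (2 / n - 1 / a1) / sqrt(e2)
  d_max <- if (n %% 2L == 0L) {
    (n / (2 * (n - 1)) - 1 / a1) / sqrt(e2)
  } else {
    ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  }
  # Beta(alpha, beta) on [d_min, d_max] with mean 0, variance 1:
  # total shape s = -d_min*d_max - 1 must be positive.
  s <- -d_min * d_max - 1
  if (s > 0) {
    shape1 <- -d_min / (d_max - d_min) * s   # exponent of (D - d_min)
    shape2 <- d_max / (d_max - d_min) * s    # exponent of (d_max - D)
  } else {
    shape1 <- shape2 <- NA_real_
  }
  structure(list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1,
                 c2 = c2, e1 = e1, e2 = e2, D_min = d_min, D_max = d_max,
                 beta_alpha = shape1, beta_beta = shape2),
            class = "tajima_null")
}

#' Tajima's D from summary quantities
#'
#' `D = (k_hat - S/a1) / sqrt(e1 S + e2 S (S - 1))`. Undefined (returned
#' as `NA` with a `reason` attribute, never as 0) when `n < 4` or
#' `S = 0`.
#'
#' @param n Number of sequences.
#' @param S Number of segregating sites.
#' @param k_hat Mean pairwise difference count.
#' @return Tajima's D, or `NA`.
#' @export
tajima_d <- function(n, S, k_hat) {
  if (n < 4) return(structure(NA_real_, reason = "n < 4"))
  if (S < 1) return(structure(NA_real_, reason = "no segregating sites"))
  cons <- tajima_null(n)
  (k_hat - S / cons$a1) / sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
}

#' Coalescent simulation null for Tajima's D
#'
#' Neutral coalescent genealogies at sample size `n`, conditioned on the
#' observed number of segregating sites: `S` mutations are placed on the
#' genealogy with probability proportional to branch length, and D is
#' recomputed for each replicate.
#'
#' @param n Sample size.
#' @param S Segregating sites to condition on.
#' @param n_replicates Number of replicates.
#' @param seed Optional integer seed.
#' @return Numeric vector of simulated D values.
#' @export
simulate_tajima_null <- function(n, S, n_replicates = 10000L, seed = NULL) {
  stopifnot(n >= 4, S >= 1)
  if (!is.null(seed)) set.seed(seed)
  cons <- tajima_null(n)
  denom <- sqrt(cons$e1 * S + cons$e2 * S * (S - 1))
  n_pairs <- n * (n - 1) / 2
  out <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    # lineage bookkeeping: subtended tip count and branch start time
    counts <- rep(1L, n)
    starts <- numeric(n)
    t <- 0
    branch_len <- numeric(2L * n - 2L)
    branch_cnt <- integer(2L * n - 2L)
    nb <- 0L
    k <- n
    while (k > 1L) {
      t <- t + stats::rexp(1L, rate = k * (k - 1) / 2)
      pair <- sample.int(k, 2L)
      i <- pair[1L]; j <- pair[2L]
      branch_len[nb + 1L] <- t - starts[i]
      branch_cnt[nb + 1L] <- counts[i]
      branch_len[nb + 2L] <- t - starts[j]
      branch_cnt[nb + 2L] <- counts[j]
      nb <- nb + 2L
      counts[i] <- counts[i] + counts[j]
      starts[i] <- t
      counts <- counts[-j]
      starts <- starts[-j]
      k <- k - 1L
    }
    hit <- sample.int(nb, S, replace = TRUE, prob = branch_len[seq_len(nb)])
    ci <- branch_cnt[hit]
    k_hat <- sum(ci * (n - ci)) / n_pairs
    out[r] <- (k_hat - S / cons$a1) / denom
  }
  out
}

#' Two-tailed p-value for Tajima's D
#'
#' In `beta` mode the null is the rescaled beta distribution on
#' `[D_min, D_max]` with mean 0 and variance 1; the two-tailed p-value
#' is `2 min(F(D), 1 - F(D))`. In `simulation` mode an empirical
#' two-tailed p-value is computed from coalescent replicates conditioned
#' on `S`, with +1 smoothing. If the beta shapes are infeasible, beta
#' mode falls back to simulation with a warning.
#'
#' @param D Observed Tajima's D.
#' @param n Sample size.
#' @param S Segregating sites (required for simulation mode).
#' @param mode `"beta"` or `"simulation"`.
#' @param n_replicates Replicates for simulation mode.
#' @param seed Optional seed for simulation mode.
#' @return Two-tailed p-value in (0, 1].
#' @export
tajima_pvalue <- function(D, n, S = NULL, mode = c("beta", "simulation"),
                          n_replicates = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  if (is.na(D)) return(NA_real_)
  if (mode == "beta") {
    null <- tajima_null(n)
    if (is.na(null$beta_alpha) || null$beta_alpha <= 0 ||
        null$beta_beta <= 0) {
      warning("beta null infeasible for n = ", n,
              "; falling back to simulation")
      mode <- "simulation"
    } else {
      x <- (D - null$D_min) / (null$D_max - null$D_min)
      x <- min(max(x, 0), 1)
      lower <- stats::pbeta(x, null$beta_alpha, null$beta_beta)
      return(min(1, 2 * min(lower, 1 - lower)))
    }
  }
  if (is.null(S)) stop("simulation mode requires S")
  sims <- simulate_tajima_null(n, S, n_replicates, seed)
  B <- length(sims)
  p_low <- (1 + sum(sims <= D)) / (B + 1)
  p_high <- (1 + sum(sims >= D)) / (B + 1)
  min(1, 2 * min(p_low, p_high))
}

#' Per-OTU diversity summary
#'
#' Computes the number of sequences `n`, segregating sites `S` (columns
#' with >= 2 distinct non-gap, non-N states), mean pairwise differences
#' `k_hat`, per-site nucleotide diversity `pi` (mean over pairs of
#' differences / pair-valid sites), Watterson's estimator
#' `theta_w = S/(a1 L_eff)` with `L_eff` the number of columns carrying
#' at least one base, and Tajima's D with its beta-null p-value.
#'
#' @param aln A `seq_alignment` with >= 2 rows.
#' @param d_pvalue Compute the D p-value (beta mode).
#' @return A list of class `diversity_stats`.
#' @export
diversity_summary <- function(aln, d_pvalue = TRUE) {
  m <- as_aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("diversity_summary needs at least 2 sequences")
  pd <- pairwise_diffs(m)
  if (any(pd$missing_pairs)) {
    stop("pair(s) with zero valid sites; diversity statistics undefined")
  }
  ut <- upper.tri(pd$diffs)
  k_hat <- mean(pd$diffs[ut])
  pi <- mean(pd$diffs[ut] / pd$valid[ut])
  known <- (m != "-") & (m != "N")
  n_states <- vapply(seq_len(ncol(m)), function(j) {
    length(unique(m[known[, j], j]))
  }, integer(1))
  S <- sum(n_states >= 2L)
  L_eff <- sum(colSums(known) > 0L)
  a1 <- harmonic_number(n - 1L)
  theta_w <- if (L_eff > 0) S / (a1 * L_eff) else 0
  D <- tajima_d(n, S, k_hat)
  p <- if (d_pvalue && !is.na(D)) tajima_pvalue(D, n, S = S) else NA_real_
  structure(list(n = n, S = S, L_eff = L_eff, L_mean = mean(pd$valid[ut]),
                 k_hat = k_hat, pi = pi, theta_w = theta_w,
                 D = as.numeric(D), D_reason = attr(D, "reason"),
                 D_pvalue = p),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf(
    "diversity_stats: n=%d S=%d k_hat=%.4f pi=%.5f theta_w=%.5f D=%s\n",
    x$n, x$S, x$k_hat, x$pi, x$theta_w,
    if (is.na(x$D)) paste0("NA (", x$D_reason, ")") else
      sprintf("%.4f (p=%.4g)", x$D, x$D_pvalue)))
  invisible(x)
}

# Nei-Chesser corrected haplotype G_ST from haplotype and locale labels.
# Locales with fewer than 2 sequences cannot enter the unbiased
# within-locale diversity and are dropped (recorded by the caller).
compute_gst <- function(hap, loc, corrected = TRUE) {
  tab <- table(loc, hap)
  n_p <- rowSums(tab)
  if (corrected) {
    keep <- n_p >= 2L
    tab <- tab[keep, , drop = FALSE]
    n_p <- n_p[keep]
  }
  P <- nrow(tab)
  if (P < 2L) return(NA_real_)
  freq <- tab / n_p
  if (corrected) {
    h_p <- n_p / (n_p - 1) * (1 - rowSums(freq^2))
    H_S <- mean(h_p)
    pbar <- colMeans(freq)
    H_T <- 1 - sum(pbar^2)
    n_tilde <- 1 / mean(1 / n_p)
    H_Tp <- H_T + H_S / (n_tilde * P)
    if (H_Tp <= 0) return(NA_real_)
    (H_Tp - H_S) / H_Tp
  } else {
    h_p <- 1 - rowSums(freq^2)
    H_S <- mean(h_p)
    pbar <- colMeans(freq)
    H_T <- 1 - sum(pbar^2)
    if (H_T <= 0) return(NA_real_)
    (H_T - H_S) / H_T
  }
}

#' Haplotype G_ST with a permutation test
#'
#' Distinct aligned row strings are treated as alleles. Per-locale
#' unbiased gene diversities are averaged into `H_S`; total diversity
#' `H_T` uses unweighted mean haplotype frequencies with the
#' small-sample correction `H_T' = H_T + H_S/(n_tilde P)` (harmonic mean
#' `n_tilde`, `P` locales); `G_ST = (H_T' - H_S)/H_T'`. Significance is
#' by permuting individuals among locales (sizes preserved), with
#' `p = (1 + #{G_perm >= G_obs}) / (B + 1)`. Locales with fewer than two
#' sequences are excluded from the corrected estimator.
#'
#' @param aln A `seq_alignment` with locale metadata, or a character
#'   matrix with `locales` given.
#' @param locales Optional locale label per row.
#' @param B Number of permutations.
#' @param seed Optional integer seed.
#' @param corrected Use the small-sample-corrected estimator (default);
#'   `FALSE` gives the uncorrected haplotype-frequency form.
#' @return A list of class `gst_result` with `G_ST`, `H_S`, `H_T`,
#'   `p_value` and `n_permutations`.
#' @export
gst_test <- function(aln, locales = NULL, B = 999L, seed = NULL,
                     corrected = TRUE) {
  m <- as_aln_matrix(aln)
  if (is.null(locales)) locales <- aln_locales(aln)
  stopifnot(length(locales) == nrow(m))
  if (length(unique(locales)) < 2L) {
    stop("gst_test needs at least 2 locales")
  }
  hap <- apply(m, 1L, paste, collapse = "")
  obs <- compute_gst(hap, locales, corrected)
  # report the diversity components alongside
  tab <- table(locales, hap)
  n_p <- rowSums(tab)
  freq <- tab / n_p
  H_S_raw <- mean(1 - rowSums(freq^2))
  H_T_raw <- 1 - sum(colMeans(freq)^2)
  p <- NA_real_
  if (!is.na(obs)) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(B)) {
      g <- compute_gst(hap, sample(locales), corrected)
      if (!is.na(g) && g >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (B + 1)
  }
  structure(list(G_ST = obs, H_S = H_S_raw, H_T = H_T_raw, p_value = p,
                 n_permutations = B, corrected = corrected),
            class = "gst_result")
}

#' @export
print.gst_result <- function(x, ...) {
  cat(sprintf("gst_result: G_ST=%s H_S=%.4f H_T=%.4f p=%s (B=%d)\n",
              ifelse(is.na(x$G_ST), "NA", sprintf("%.4f", x$G_ST)),
              x$H_S, x$H_T,
              ifelse(is.na(x$p_value), "NA", sprintf("%.4g", x$p_value)),
              x$n_permutations))
  invisible(x)
}
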