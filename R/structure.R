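# Hierarchical AMOVA with three permutation schemes, NJ trees, the
# genealogical sorting index, and the Mantel IBD test.

# Core AMOVA decomposition from a matrix of squared distances and the
# locale/region assignment of each individual. Returns SSDs, variance
# components and Phi statistics (Excoffier-style two-level hierarchy:
# regions / locales within regions / individuals within locales).
amova_components <- function(d2, locale, region_of) {
  locale <- as.character(locale)
  locs <- unique(locale)
  regs <- unname(region_of[locs])
  if (anyNA(regs)) stop("locale(s) with no region mapping")
  groups <- unique(regs)
  N <- nrow(d2)
  P <- length(locs)
  G <- length(groups)
  n_p <- vapply(locs, function(p) sum(locale == p), numeric(1))
  idx_p <- lapply(locs, function(p) which(locale == p))
  idx_g <- lapply(groups, function(g) which(locale %in% locs[regs == g]))
  N_g <- vapply(idx_g, length, numeric(1))

  ssd_total <- sum(d2) / (2 * N)
  ssd_wp <- sum(vapply(seq_len(P), function(i) {
    ix <- idx_p[[i]]
    sum(d2[ix, ix]) / (2 * n_p[i])
  }, numeric(1)))
  ssd_wg <- sum(vapply(seq_len(G), function(i) {
    ix <- idx_g[[i]]
    sum(d2[ix, ix]) / (2 * N_g[i])
  }, numeric(1)))
  ssd_ap_wg <- ssd_wg - ssd_wp
  ssd_ag <- ssd_total - ssd_ap_wg - ssd_wp

  df_a <- G - 1
  df_b <- P - G
  df_c <- N - P
  ms_wp <- ssd_wp / df_c
  ms_ap <- if (df_b > 0) ssd_ap_wg / df_b else NA_real_
  ms_ag <- if (df_a > 0) ssd_ag / df_a else NA_real_

  sum_np2_by_g <- vapply(seq_len(G), function(i) {
    sum(n_p[locs %in% locs[regs == groups[i]]]^2)
  }, numeric(1))
  n_prime <- if (df_b > 0) {
    (N - sum(sum_np2_by_g / N_g)) / df_b
  } else NA_real_
  n_dprime <- (sum(sum_np2_by_g / N_g) - sum(n_p^2) / N) / df_a
  n_tprime <- (N - sum(N_g^2) / N) / df_a

  sigma_c <- ms_wp
  sigma_b <- if (df_b > 0) (ms_ap - sigma_c) / n_prime else 0
  sigma_a <- (ms_ag - sigma_c - n_dprime * sigma_b) / n_tprime
  sigma_tot <- sigma_a + sigma_b + sigma_c

  phi_ct <- if (sigma_tot > 0) sigma_a / sigma_tot else NA_real_
  phi_sc <- if ((sigma_b + sigma_c) > 0) sigma_b / (sigma_b + sigma_c)
            else NA_real_
  phi_st <- if (sigma_tot > 0) (sigma_a + sigma_b) / sigma_tot else NA_real_

  list(ssd = c(among_regions = ssd_ag,
               among_locales_within_regions = ssd_ap_wg,
               within_locales = ssd_wp, total = ssd_total),
       df = c(df_a, df_b, df_c),
       sigma2 = c(a = sigma_a, b = sigma_b, c = sigma_c),
       n_coef = c(n_prime = n_prime, n_dprime = n_dprime,
                  n_tprime = n_tprime),
       phi = c(phi_ct = phi_ct, phi_sc = phi_sc, phi_st = phi_st))
}

#' Hierarchical AMOVA with scheme-specific permutation tests
#'
#' Decomposes squared molecular distances into among-region,
#' among-locale-within-region and within-locale components, with the
#' unequal-sample-size coefficients of the standard two-level nested
#' design, and reports Phi_CT, Phi_SC and Phi_ST. Each Phi statistic has
#' its own permutation null: individuals among locales ignoring regions
#' (Phi_ST), individuals among locales within their region (Phi_SC), and
#' whole locales among regions (Phi_CT). P-values use the
#' `(1 + count)/(B + 1)` estimator. With few locales the Phi_CT null has
#' coarse granularity (there are only `choose(P, P_west)` distinct
#' locale-to-region assignments); the attainable p-value floor is
#' reported as `p_ct_floor`.
#'
#' @param d Distance matrix among individuals (a `dist` or square
#'   matrix). Entries are used as the squared distances of the analysis
#'   when `squared = TRUE` (the convention for raw pairwise difference
#'   counts); set `squared = FALSE` to square them first.
#' @param locale Locale label per individual.
#' @param region_of Named character vector mapping locale to region
#'   (exactly two regions).
#' @param B Number of permutations per scheme.
#' @param seed Optional integer seed.
#' @param squared Are the entries of `d` already squared distances?
#' @return A list of class `amova_result` with SSDs, df, variance
#'   components, Phi statistics and permutation p-values.
#' @export
amova <- function(d, locale, region_of, B = 999L, seed = NULL,
                  squared = TRUE) {
  d2 <- as.matrix(d)
  if (!squared) d2 <- d2^2
  if (anyNA(d2)) stop("distance matrix contains NA (saturated pairs?)")
  locale <- as.character(locale)
  stopifnot(nrow(d2) == length(locale))
  locs <- unique(locale)
  n_p <- table(locale)
  empty <- setdiff(names(region_of), locs)
  if (length(empty)) {
    warning("locale(s) with no individuals dropped: ",
            paste(empty, collapse = ", "))
    region_of <- region_of[setdiff(names(region_of), empty)]
  }
  if (length(locs) < 2L) stop("amova needs at least 2 locales with data")
  regions <- unique(unname(region_of[locs]))
  if (length(regions) != 2L) stop("amova requires exactly two regions")

  obs <- amova_components(d2, locale, region_of)
  if (!is.null(seed)) set.seed(seed)
  hits <- c(st = 0L, sc = 0L, ct = 0L)
  do_scheme <- !is.na(obs$phi[c("phi_st", "phi_sc", "phi_ct")])
  names(do_scheme) <- c("st", "sc", "ct")
  reg_of_loc <- unname(region_of[locs])
  for (b in seq_len(B)) {
    if (do_scheme["st"]) {
      # Phi_ST: individuals among locales ignoring regions
      phi <- amova_components(d2, sample(locale), region_of)$phi["phi_st"]
      if (!is.na(phi) && phi >= obs$phi["phi_st"] - 1e-12) {
        hits["st"] <- hits["st"] + 1L
      }
    }
    if (do_scheme["sc"]) {
      # Phi_SC: individuals among locales within their region
      perm_sc <- locale
      for (g in regions) {
        in_g <- which(unname(region_of[locale]) == g)
        perm_sc[in_g] <- sample(locale[in_g])
      }
      phi <- amova_components(d2, perm_sc, region_of)$phi["phi_sc"]
      if (!is.na(phi) && phi >= obs$phi["phi_sc"] - 1e-12) {
        hits["sc"] <- hits["sc"] + 1L
      }
    }
    if (do_scheme["ct"]) {
      # Phi_CT: whole locales among regions
      perm_map <- stats::setNames(sample(reg_of_loc), locs)
      phi <- amova_components(d2, locale, perm_map)$phi["phi_ct"]
      if (!is.na(phi) && phi >= obs$phi["phi_ct"] - 1e-12) {
        hits["ct"] <- hits["ct"] + 1L
      }
    }
  }
  p <- (1 + hits) / (B + 1)
  p[!do_scheme[names(p)]] <- NA_real_
  n_west <- sum(reg_of_loc == regions[1L])
  p_ct_floor <- 1 / choose(length(locs), n_west)
  structure(list(ssd = obs$ssd, df = obs$df, sigma2 = obs$sigma2,
                 n_coef = obs$n_coef,
                 phi_ct = unname(obs$phi["phi_ct"]),
                 phi_sc = unname(obs$phi["phi_sc"]),
                 phi_st = unname(obs$phi["phi_st"]),
                 p_ct = unname(p["ct"]), p_sc = unname(p["sc"]),
                 p_st = unname(p["st"]),
                 p_ct_floor = p_ct_floor,
                 n_permutations = B),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("amova_result\n")
  cat(sprintf("  Phi_CT = %.4f (p = %.4g, floor %.3g)\n",
              x$phi_ct, x$p_ct, x$p_ct_floor))
  cat(sprintf("  Phi_SC = %.4f (p = %.4g)\n", x$phi_sc, x$p_sc))
  cat(sprintf("  Phi_ST = %.4f (p = %.4g)\n", x$phi_st, x$p_st))
  cat(sprintf("  sigma2: a=%.4f b=%.4f c=%.4f\n",
              x$sigma2["a"], x$sigma2["b"], x$sigma2["c"]))
  invisible(x)
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard NJ on a distance matrix; negative branch lengths are clamped
#' to zero with the deficit moved to the sister branch, preserving path
#' lengths through the parent node. NJ exactly recovers additive
#' matrices. The tree is returned unrooted (as produced by NJ); rooting
#' for the sorting index is handled by [gsi_test()].
#'
#' @param d Distance matrix (`dist` or square matrix) over >= 3 tips.
#' @return An `ape` `phylo` tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) stop("nj_tree needs at least 3 tips")
  if (anyNA(m)) stop("distance matrix contains NA (saturated pairs?)")
  phy <- ape::nj(stats::as.dist(m))
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    parent <- phy$edge[e, 1L]
    siblings <- which(phy$edge[, 1L] == parent & seq_len(nrow(phy$edge)) != e)
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    if (length(siblings)) {
      s <- siblings[1L]
      phy$edge.length[s] <- max(0, phy$edge.length[s] + deficit)
    }
  }
  phy
}

# Per-tree precomputation for fast repeated GSI evaluation.
gsi_prepare <- function(tree) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  edge <- tree$edge
  # postorder edge ordering: children before parents
  po <- ape::reorder.phylo(tree, "postorder")$edge
  deg <- tabulate(c(edge[, 1L], edge[, 2L]), nbins = n_tip + n_node)
  # ancestor lookup: for each node its parent
  parent <- integer(n_tip + n_node)
  parent[edge[, 2L]] <- edge[, 1L]
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  list(tree = tree, n_tip = n_tip, n_node = n_node, po = po, deg = deg,
       parent = parent, root = root,
       internal = (n_tip + 1L):(n_tip + n_node),
       tip_index = stats::setNames(seq_len(n_tip), tree$tip.label))
}

gsi_stat <- function(prep, tip_ids) {
  n <- length(tip_ids)
  n_total <- prep$n_tip + prep$n_node
  cnt <- integer(n_total)
  cnt[tip_ids] <- 1L
  po <- prep$po
  for (e in seq_len(nrow(po))) {
    cnt[po[e, 1L]] <- cnt[po[e, 1L]] + cnt[po[e, 2L]]
  }
  # MRCA: walk up from one group tip until the subtree holds the group
  v <- tip_ids[1L]
  while (cnt[v] < n) v <- prep$parent[v]
  mrca <- v
  # U: internal nodes inside clade(mrca) that carry >= 1 group tip.
  # Membership in clade(mrca) checked by walking parents (trees here are
  # small); only nodes with cnt >= 1 need checking.
  U <- integer(0)
  for (u in prep$internal) {
    if (cnt[u] < 1L) next
    w <- u
    while (w != mrca && w != prep$root) w <- prep$parent[w]
    if (w == mrca) U <- c(U, u)
  }
  denom <- sum(prep$deg[U] - 2L)
  gs <- n / denom
  gs_max <- n / (n - 1)
  gs_min <- n / sum(prep$deg[prep$internal] - 2L)
  if (abs(gs_max - gs_min) < 1e-12) return(NA_real_)
  (gs - gs_min) / (gs_max - gs_min)
}

#' Genealogical sorting index with a permutation test
#'
#' Quantifies the exclusivity of ancestry of a labelled group on a
#' genealogy: 0 for no sorting (the group's minimal connecting subtree
#' spans every internal node), 1 for monophyly. The raw statistic is
#' `gs = n / sum(deg(u) - 2)` over the internal nodes `u` of the minimal
#' subtree connecting the group's tips through their MRCA, normalised
#' between its monophyly maximum and full-dispersal minimum. GSI depends
#' only on topology, not branch lengths. Significance is by permuting
#' group labels over tips (group size preserved):
#' `p = (1 + #{gsi_perm >= gsi_obs}) / (B + 1)`. Unrooted input trees
#' are midpoint rooted.
#'
#' @param tree A `phylo` tree covering all tips.
#' @param group_of Named vector (by tip label) of group labels.
#' @param group The focal group label (>= 2 tips).
#' @param B Number of permutations.
#' @param seed Optional integer seed.
#' @return A list of class `gsi_result` with `gsi`, `p_value`,
#'   `n_permutations`.
#' @export
gsi_test <- function(tree, group_of, group, B = 999L, seed = NULL) {
  prep <- gsi_prepare(tree)
  missing_tips <- setdiff(tree$tip.label, names(group_of))
  if (length(missing_tips)) {
    stop("no group label for tip(s): ",
         paste(utils::head(missing_tips, 3L), collapse = ", "))
  }
  labels <- group_of[tree$tip.label]
  in_group <- which(labels == group)
  n <- length(in_group)
  if (n < 2L) stop("group '", group, "' has fewer than 2 tips")
  obs <- gsi_stat(prep, in_group)
  p <- NA_real_
  if (!is.na(obs)) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(B)) {
      g <- gsi_stat(prep, sample.int(prep$n_tip, n))
      if (!is.na(g) && g >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (B + 1)
  }
  structure(list(group = group, gsi = obs, p_value = p,
                 n_permutations = B),
            class = "gsi_result")
}

#' @export
print.gsi_result <- function(x, ...) {
  cat(sprintf("gsi_result: group=%s gsi=%s p=%s (B=%d)\n", x$group,
              ifelse(is.na(x$gsi), "NA", sprintf("%.4f", x$gsi)),
              ifelse(is.na(x$p_value), "NA", sprintf("%.4g", x$p_value)),
              x$n_permutations))
  invisible(x)
}

#' Aggregate an individual-level distance matrix to locale level
#'
#' Between-locale entries are the mean distance over all cross-locale
#' pairs; the diagonal is zero.
#'
#' @param d Individual-level distance matrix.
#' @param locale Locale label per individual.
#' @return Symmetric locale-level matrix.
#' @export
locale_distance_matrix <- function(d, locale) {
  m <- as.matrix(d)
  locs <- sort(unique(locale))
  out <- matrix(0, length(locs), length(locs),
                dimnames = list(locs, locs))
  for (i in seq_along(locs)) {
    for (j in seq_along(locs)) {
      if (i >= j) next
      ix <- locale == locs[i]
      jx <- locale == locs[j]
      out[i, j] <- out[j, i] <- mean(m[ix, jx])
    }
  }
  out
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the off-diagonal entries of a genetic and
#' a geographic distance matrix, with significance by joint row/column
#' permutation. One-tailed: isolation by distance predicts a positive
#' correlation, so `p = (1 + #{r_perm >= r_obs}) / (B + 1)`.
#'
#' @param gen Genetic distance matrix (locale level).
#' @param geo Geographic distance matrix with matching locales.
#' @param B Number of permutations.
#' @param seed Optional integer seed.
#' @return A list of class `mantel_result` with `r`, `p_value`,
#'   `n_permutations`.
#' @export
mantel_test <- function(gen, geo, B = 999L, seed = NULL) {
  gen <- as.matrix(gen)
  geo <- as.matrix(geo)
  if (nrow(gen) < 3L) stop("mantel test undefined for fewer than 3 locales")
  if (!is.null(rownames(gen)) && !is.null(rownames(geo))) {
    if (!setequal(rownames(gen), rownames(geo))) {
      stop("locale sets of the two matrices differ")
    }
    geo <- geo[rownames(gen), rownames(gen)]
  }
  if (!is.null(seed)) set.seed(seed)
  # with few locales vegan enumerates the complete permutation set,
  # giving an exact p-value
  res <- suppressMessages(
    vegan::mantel(stats::as.dist(gen), stats::as.dist(geo),
                  method = "pearson", permutations = B))
  structure(list(r = unname(res$statistic), p_value = res$signif,
                 n_permutations = B),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("mantel_result: r=%.4f p=%.4g (B=%d)\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}
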