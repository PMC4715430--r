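# Structured-coalescent community simulator: barrier-split communities of
# amplicon OTUs with known truth, for calibration and power analysis.

#' Default simulated sampling design
#'
#' Five locales, two west and three east of the barrier, mirroring a
#' two-region riverine design. Coordinates are synthetic stand-ins laid
#' out on either side of a north-south barrier at realistic
#' between-locale distances (tens to ~250 km).
#'
#' @param samples_per_locale Sequences sampled per locale for each OTU.
#' @return Data frame with `locale`, `region`, `n`, `lat`, `lon`.
#' @export
default_demes <- function(samples_per_locale = 6L) {
  data.frame(
    locale = c("K", "C", "L", "A", "T"),
    region = c("west", "west", "east", "east", "east"),
    n = samples_per_locale,
    lat = c(31.03, 30.80, 30.53, 30.48, 30.45),
    lon = c(-92.65, -92.68, -90.17, -90.03, -89.88),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Time is scaled so that each pair of lineages within a deme coalesces
#' at rate 1; `tau` (the region split time) and the migration rates are
#' in these units. `theta` is the population mutation parameter per
#' locus (expected pairwise differences under panmixia).
#'
#' @param n_otus Number of OTUs in the community.
#' @param demes Data frame `locale`/`region`/`n` (see [default_demes()]).
#' @param theta Per-OTU mutation parameter.
#' @param tau Region split time (coalescent units) for structured OTUs.
#' @param m_within Per-lineage migration rate among demes within a
#'   region.
#' @param m_between Per-lineage migration rate across regions before the
#'   split (0 = clean barrier).
#' @param seq_length Locus length in bp.
#' @param fraction_structured Fraction of OTUs simulated under the
#'   barrier regime; the rest are panmictic.
#' @param abundance Abundance model: `"logseries"` draws per-OTU totals
#'   from a truncated log-series on `[ab_min, ab_max]` (heavy-tailed OTU
#'   size skew); `"fixed"` uses the deme sample sizes as is.
#' @param ab_min,ab_max Abundance bounds.
#' @param ab_p Log-series parameter (default calibrated so the median
#'   OTU size is ~54 sequences).
#' @param seed Root seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_otus = 12L, demes = default_demes(), theta = 5,
                       tau = 0.5, m_within = 1, m_between = 0,
                       seq_length = 275L, fraction_structured = 0.5,
                       abundance = c("logseries", "fixed"),
                       ab_min = 14L, ab_max = 2507L, ab_p = 0.9963,
                       seed = 1L) {
  abundance <- match.arg(abundance)
  stopifnot(theta >= 0, tau >= 0, m_within >= 0, m_between >= 0,
            seq_length >= 1, fraction_structured >= 0,
            fraction_structured <= 1)
  structure(list(n_otus = as.integer(n_otus), demes = demes, theta = theta,
                 tau = tau, m_within = m_within, m_between = m_between,
                 seq_length = as.integer(seq_length),
                 fraction_structured = fraction_structured,
                 abundance = abundance, ab_min = as.integer(ab_min),
                 ab_max = as.integer(ab_max), ab_p = ab_p,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured-coalescent genealogy
#'
#' Backward-in-time coalescent: within a deme each lineage pair
#' coalesces at rate 1; each lineage migrates at rate `m_within` to a
#' uniformly chosen other deme of its region and at rate `m_between` to
#' a uniformly chosen deme of the other region. Looking back past time
#' `tau`, all demes merge into one panmictic ancestral pool. `tau = 0`
#' gives panmixia throughout.
#'
#' @param sample_sizes Named integer vector: sequences sampled per deme.
#' @param region_of Named character vector mapping deme to region.
#' @param tau Split time (coalescent units).
#' @param m_within,m_between Migration rates.
#' @return An `ape` `phylo` tree with coalescent-unit branch lengths;
#'   tip labels are `"<deme>_<i>"` and tip demes are returned in the
#'   `deme` attribute.
#' @export
simulate_genealogy <- function(sample_sizes, region_of, tau = 0,
                               m_within = 0, m_between = 0) {
  n <- sum(sample_sizes)
  if (n < 2L) stop("need at least 2 sampled lineages")
  demes <- names(sample_sizes)
  tip_deme <- rep(demes, times = sample_sizes)
  tip_label <- unlist(lapply(demes[sample_sizes > 0], function(d) {
    paste0(d, "_", seq_len(sample_sizes[[d]]))
  }), use.names = FALSE)
  stopifnot(length(tip_label) == n)

  # active lineages: node id and deme index
  deme_id <- match(tip_deme, demes)
  node <- seq_len(n)
  height <- numeric(2L * n - 1L)
  next_internal <- n + 1L
  edges <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  edge_len <- numeric(2L * n - 2L)
  ne <- 0L
  t <- 0
  merged <- tau <= 0
  if (merged) deme_id[] <- 1L
  n_demes <- length(demes)
  same_region <- outer(region_of[demes], region_of[demes], "==")
  repeat {
    k <- length(node)
    if (k == 1L) break
    kd <- tabulate(deme_id, nbins = n_demes)
    coal_rate <- sum(kd * (kd - 1) / 2)
    # upper bound on the total migration rate; events drawn under it are
    # thinned below when the chosen lineage has no valid destination
    mig_rate <- if (merged || n_demes == 1L) 0 else {
      k * (m_within + m_between)
    }
    total <- coal_rate + mig_rate
    if (total <= 0) {
      if (!merged && is.finite(tau)) {
        t <- tau
        merged <- TRUE
        deme_id[] <- 1L
        next
      }
      stop("non-coalescing configuration: isolated lineages with no ",
           "migration and no merge time")
    }
    dt <- stats::rexp(1L, rate = total)
    if (!merged && t + dt >= tau) {
      t <- tau
      merged <- TRUE
      deme_id[] <- 1L
      next
    }
    t <- t + dt
    if (stats::runif(1L) < coal_rate / total) {
      # coalescence: choose deme weighted by its pair count
      d <- sample.int(n_demes, 1L, prob = kd * (kd - 1) / 2)
      in_d <- which(deme_id == d)
      pair <- in_d[sample.int(length(in_d), 2L)]
      new <- next_internal
      next_internal <- next_internal + 1L
      height[new] <- t
      for (child in node[pair]) {
        ne <- ne + 1L
        edges[ne, ] <- c(new, child)
        edge_len[ne] <- t - height[child]
      }
      node <- c(node[-pair], new)
      deme_id <- c(deme_id[-pair], d)
    } else {
      # migration: uniform lineage, rate class m_within vs m_between,
      # then a uniform destination deme of that class (thinned when the
      # class has no destination)
      i <- sample.int(k, 1L)
      d <- deme_id[i]
      class_within <- stats::runif(1L) < m_within / (m_within + m_between)
      dest <- if (class_within) {
        which(same_region[, d] & seq_len(n_demes) != d)
      } else {
        which(!same_region[, d])
      }
      if (length(dest) == 0L) next
      deme_id[i] <- dest[sample.int(length(dest), 1L)]
    }
  }
  # renumber internals so the root is n+1 (ape convention)
  root_old <- node[1L]
  remap <- function(v) ifelse(v > n, 3L * n - v, v)
  phy <- list(edge = cbind(remap(edges[, 1L]), remap(edges[, 2L])),
              edge.length = edge_len,
              tip.label = tip_label,
              Nnode = n - 1L)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "deme") <- stats::setNames(tip_deme, tip_label)
  phy
}

#' Drop mutations on a genealogy (finite-sites Jukes-Cantor)
#'
#' Mutations arise as a Poisson process at rate `theta/2` per lineage
#' per coalescent unit; each hits a uniformly chosen site and replaces
#' its base with a uniformly chosen different base. The ancestral
#' sequence is uniform random.
#'
#' @param tree A `phylo` genealogy with branch lengths.
#' @param theta Mutation parameter (expected pairwise differences).
#' @param seq_length Sites in the locus.
#' @param seed Optional integer seed.
#' @return A `seq_alignment` (gap-free) with one row per tip.
#' @export
mutate_sequences <- function(tree, theta, seq_length = 275L, seed = NULL) {
  if (theta < 0) stop("theta must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_total <- n_tip + tree$Nnode
  root <- n_tip + 1L
  bases <- c("A", "C", "G", "T")
  seqs <- matrix(NA_integer_, nrow = n_total, ncol = seq_length)
  seqs[root, ] <- sample.int(4L, seq_length, replace = TRUE)
  # preorder: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1L]
    child <- ord$edge[e, 2L]
    s <- seqs[parent, ]
    n_mut <- stats::rpois(1L, theta / 2 * ord$edge.length[e])
    if (n_mut > 0L) {
      sites <- sample.int(seq_length, n_mut, replace = TRUE)
      for (site in sites) {
        s[site] <- sample(setdiff(1:4, s[site]), 1L)
      }
    }
    seqs[child, ] <- s
  }
  m <- matrix(bases[seqs[seq_len(n_tip), ]], nrow = n_tip,
              dimnames = list(tree$tip.label, NULL))
  seq_alignment(m)
}

# draw one abundance from the truncated log-series
draw_abundance <- function(cfg) {
  ks <- cfg$ab_min:cfg$ab_max
  w <- cfg$ab_p^ks / ks
  ks[sample.int(length(ks), 1L, prob = w)]
}

# allocate `total` sequences to demes proportionally to deme sample
# sizes, guaranteeing at least `min_per_region` per region.
allocate_to_demes <- function(total, demes, min_per_region = 3L) {
  prob <- demes$n / sum(demes$n)
  regions <- unique(demes$region)
  need <- min_per_region * length(regions)
  if (total < need) {
    stop("abundance ", total, " cannot satisfy ", min_per_region,
         " sequences per region")
  }
  counts <- as.integer(stats::rmultinom(1L, total, prob))
  names(counts) <- demes$locale
  for (g in regions) {
    in_g <- demes$locale[demes$region == g]
    short <- min_per_region - sum(counts[in_g])
    while (short > 0L) {
      donor_regions <- setdiff(regions, g)
      donors <- demes$locale[demes$region %in% donor_regions]
      donors <- donors[counts[donors] > 0L]
      # take from the largest donor locale whose region stays above the
      # minimum
      ok <- donors[vapply(donors, function(d) {
        gg <- demes$region[demes$locale == d]
        sum(counts[demes$locale[demes$region == gg]]) > min_per_region
      }, logical(1))]
      if (!length(ok)) stop("infeasible deme allocation")
      d <- ok[which.max(counts[ok])]
      counts[d] <- counts[d] - 1L
      recipient <- in_g[which.max(demes$n[match(in_g, demes$locale)])]
      counts[recipient] <- counts[recipient] + 1L
      short <- short - 1L
    }
  }
  counts
}

#' Simulate a barrier-split amplicon community
#'
#' Draws `fraction_structured * n_otus` OTUs under the clean-barrier
#' regime (`tau`, `m_between` from the config) and the remainder as
#' panmictic (`tau = 0`, free migration), with per-OTU totals from the
#' abundance model allocated to demes proportionally to deme sample
#' sizes (respecting `min_per_region`). Returns read-level FASTA-ready
#' data, the sample table (one pitcher sample per locale-month cell,
#' months June and August), locale coordinates and a truth table for
#' scoring.
#'
#' @param config A `sim_config`.
#' @param min_per_region Allocation guarantee per region.
#' @param samples_per_locale Number of pitcher samples per locale.
#' @return List of class `sim_community`: `reads`, `samples`, `coords`,
#'   `truth`, `alignments` (list of per-OTU `seq_alignment`s).
#' @export
simulate_community <- function(config, min_per_region = 3L,
                               samples_per_locale = 6L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  demes <- config$demes
  region_of <- stats::setNames(demes$region, demes$locale)
  months <- c("June", "August")
  samples <- do.call(rbind, lapply(seq_len(nrow(demes)), function(i) {
    data.frame(
      sample_id = sprintf("%s_p%02d", demes$locale[i],
                          seq_len(samples_per_locale)),
      locale = demes$locale[i],
      region = demes$region[i],
      month = rep(months, length.out = samples_per_locale),
      stringsAsFactors = FALSE)
  }))
  samples <- validate_sample_table(samples)
  n_structured <- round(config$fraction_structured * config$n_otus)
  reads_list <- vector("list", config$n_otus)
  truth <- vector("list", config$n_otus)
  alignments <- vector("list", config$n_otus)
  for (o in seq_len(config$n_otus)) {
    structured <- o <= n_structured
    total <- if (config$abundance == "logseries") {
      draw_abundance(config)
    } else {
      sum(demes$n)
    }
    counts <- if (config$abundance == "logseries") {
      allocate_to_demes(total, demes, min_per_region)
    } else {
      stats::setNames(as.integer(demes$n), demes$locale)
    }
    tree <- if (structured) {
      simulate_genealogy(counts, region_of, tau = config$tau,
                         m_within = config$m_within,
                         m_between = config$m_between)
    } else {
      simulate_genealogy(counts, region_of, tau = 0)
    }
    aln <- mutate_sequences(tree, config$theta, config$seq_length)
    tip_deme <- attr(tree, "deme")
    read_id <- sprintf("otu%03d_r%04d", o, seq_len(sum(counts)))
    names(read_id) <- tree$tip.label
    # assign each read to a pitcher sample in its deme
    sample_of <- vapply(tree$tip.label, function(tp) {
      pool <- samples$sample_id[samples$locale == tip_deme[[tp]]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    strings <- alignment_strings(aln)
    reads_list[[o]] <- data.frame(read_id = unname(read_id[names(strings)]),
                                  sample_id = unname(sample_of[names(strings)]),
                                  bases = unname(strings),
                                  stringsAsFactors = FALSE)
    rownames(aln) <- unname(read_id[rownames(aln)])
    meta <- data.frame(id = rownames(aln),
                       sample_id = unname(sample_of[names(read_id)][
                         match(rownames(aln), unname(read_id))]),
                       stringsAsFactors = FALSE)
    meta$locale <- samples$locale[match(meta$sample_id, samples$sample_id)]
    meta$region <- samples$region[match(meta$sample_id, samples$sample_id)]
    alignments[[o]] <- seq_alignment(unclass(aln), meta = meta)
    truth[[o]] <- data.frame(otu = sprintf("sim%03d", o),
                             structured = structured,
                             n = sum(counts),
                             theta = config$theta,
                             tau = if (structured) config$tau else 0,
                             stringsAsFactors = FALSE)
  }
  out <- list(reads = do.call(rbind, reads_list),
              samples = samples,
              coords = demes[, c("locale", "lat", "lon")],
              truth = do.call(rbind, truth),
              alignments = alignments,
              config = config)
  class(out) <- "sim_community"
  out
}

#' @export
print.sim_community <- function(x, ...) {
  cat("sim_community:", x$config$n_otus, "OTUs,", nrow(x$reads),
      "reads,", sum(x$truth$structured), "structured\n")
  invisible(x)
}

#' Write a simulated community to disk
#'
#' Emits reads FASTA, sample table TSV, locale coordinates TSV and the
#' truth TSV, in the same schemas the pipeline consumes.
#'
#' @param community A `sim_community`.
#' @param dir Output directory.
#' @return Named vector of paths, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reads.fasta"),
             samples = file.path(dir, "samples.tsv"),
             coords = file.path(dir, "coords.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_sequences(community$reads, paths["fasta"])
  write_sample_table(community$samples, paths["samples"])
  utils::write.table(community$coords, paths["coords"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(community$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
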