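# Trimming, dereplication, greedy identity clustering and the comparative
# cross-barrier filter.

#' Trim reads to a fixed length
#'
#' Reads are truncated to `trim_length` bases from the 5' end; shorter
#' reads are discarded. Trimming to a common length removes the bias of
#' clustering length-variable pyrosequencing reads.
#'
#' @param reads Read data frame (see [read_sequences()]).
#' @param trim_length Target length in bp.
#' @return The retained reads, all of length `trim_length`, with an
#'   attribute `n_discarded` recording the number removed.
#' @export
trim_reads <- function(reads, trim_length = 275L) {
  stopifnot(trim_length > 0)
  keep <- nchar(reads$bases) >= trim_length
  out <- reads[keep, , drop = FALSE]
  out$bases <- substr(out$bases, 1L, trim_length)
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no reads of length >= ", trim_length, " remain after trimming")
  }
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Restrict reads to samples collected in given months
#'
#' @param reads Read data frame.
#' @param samples Sample table.
#' @param months Character vector of months to keep; `NULL` keeps all.
#' @return The reads whose sample was collected in `months`.
#' @export
filter_by_month <- function(reads, samples, months = NULL) {
  if (is.null(months)) return(reads)
  keep_samples <- samples$sample_id[samples$month %in% months]
  out <- reads[reads$sample_id %in% keep_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse identical reads into unique sequences with abundances
#'
#' One entry per distinct base string, with its total abundance, member
#' read ids and per-locale counts. Output is sorted by abundance
#' (decreasing) with ties broken by the base string (increasing), which
#' makes downstream greedy clustering deterministic and invariant to the
#' input order of reads.
#'
#' @param reads Read data frame; all reads must have equal length.
#' @param samples Sample table covering every `sample_id` in `reads`.
#' @return A list of class `unique_seqs` with elements `bases`,
#'   `abundance`, `members` (list of read-id vectors) and `locale_counts`
#'   (matrix uniques x locales).
#' @export
dereplicate <- function(reads, samples) {
  stopifnot(is.data.frame(reads), nrow(reads) > 0L)
  if (length(unique(nchar(reads$bases))) > 1L) {
    stop("reads must all have equal length; run trim_reads() first")
  }
  missing_samples <- setdiff(reads$sample_id, samples$sample_id)
  if (length(missing_samples)) {
    stop("read sample_id(s) absent from the sample table: ",
         paste(utils::head(missing_samples, 3L), collapse = ", "))
  }
  locales <- sort(unique(samples$locale))
  locale_of <- stats::setNames(samples$locale, samples$sample_id)
  f <- factor(reads$bases)
  abundance <- as.integer(table(f))
  members <- split(reads$read_id, f)
  lc <- table(f, factor(locale_of[reads$sample_id], levels = locales))
  lc <- matrix(as.integer(lc), nrow = nlevels(f),
               dimnames = list(NULL, locales))
  ord <- order(-abundance, levels(f))
  out <- list(bases = levels(f)[ord],
              abundance = abundance[ord],
              members = unname(members[ord]),
              locale_counts = lc[ord, , drop = FALSE])
  class(out) <- "unique_seqs"
  out
}

#' @export
print.unique_seqs <- function(x, ...) {
  cat("unique_seqs:", length(x$bases), "unique sequences,",
      sum(x$abundance), "reads,", ncol(x$locale_counts), "locales\n")
  invisible(x)
}

# substitution matrix for pairwise alignment: match +1, mismatch -1,
# N scored 0 against everything (undetermined base).
identity_submat <- function() {
  m <- matrix(-1, 5L, 5L, dimnames = list(DNA_ALPHABET, DNA_ALPHABET))
  diag(m) <- 1
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

align_to_set <- function(set, query) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(set), subject = query,
    type = "overlap", substitutionMatrix = identity_submat(),
    gapOpening = 4, gapExtension = 1)
}

#' Global pairwise identity between two sequences
#'
#' Needleman-Wunsch global alignment with free terminal gaps
#' (match +1, mismatch -1, a gap of length L costs 5 + (L - 1)).
#' Identity is matching columns over alignment columns, excluding
#' terminal-gap columns; an empty overlap gives identity 0.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity: empty sequence")
  identity_to_set(b, a)
}

# identity of `query` against each sequence in `set` (vectorised).
# With free terminal gaps the optimal alignment of two unrelated
# sequences is a short chance overlap of near-perfect identity; such
# degenerate alignments (covering less than half the shorter sequence)
# are reported as identity 0 rather than as a spuriously high fraction.
identity_to_set <- function(query, set) {
  aln <- align_to_set(set, query)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  min_cols <- ceiling(pmin(nchar(set), nchar(query)) / 2)
  ifelse(cols >= min_cols, Biostrings::nmatch(aln) / cols, 0)
}

#' Single-crossover chimera screen
#'
#' Models a chimera as a prefix of one existing centroid joined to a
#' suffix of another. Breakpoints are scanned on a 5 bp grid with both
#' segments at least 50 bp; segment identities are ungapped equal-length
#' comparisons. A query is called chimeric when its best two-parent
#' identity reaches `threshold` and exceeds its best single-centroid
#' identity by at least 0.01.
#'
#' @param query Candidate sequence (same length as the centroids).
#' @param centroids Character vector of existing OTU centroids.
#' @param threshold Identity threshold used for clustering.
#' @param grid_step Breakpoint grid spacing in bp.
#' @param min_segment Minimum parent segment length in bp.
#' @return A list with `verdict` (`"clean"` or `"chimeric"`) and, when
#'   chimeric, `parent1`, `parent2` (centroid indices) and `breakpoint`.
#' @export
screen_chimera <- function(query, centroids, threshold = 0.97,
                           grid_step = 5L, min_segment = 50L) {
  clean <- list(verdict = "clean")
  if (length(centroids) < 2L) return(clean)
  L <- nchar(query)
  if (any(nchar(centroids) != L)) {
    stop("chimera screen requires centroids of the query's length")
  }
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  cum <- vapply(strsplit(centroids, "", fixed = TRUE),
                function(cc) cumsum(cc == q), numeric(L))
  cum <- matrix(cum, nrow = L)           # L x n_centroids
  total <- cum[L, ]
  best_single <- max(total) / L
  breakpoints <- seq.int(min_segment, L - min_segment, by = grid_step)
  if (length(breakpoints) == 0L) return(clean)
  best <- -Inf
  best_bp <- NA_integer_
  best_parents <- c(NA_integer_, NA_integer_)
  for (b in breakpoints) {
    pre <- cum[b, ]
    suf <- total - pre
    i <- which.max(pre)
    j <- which.max(suf)
    if (i == j) {
      # force distinct parents: best of (top prefix, runner-up suffix)
      # and (runner-up prefix, top suffix)
      suf_alt <- suf; suf_alt[i] <- -Inf
      pre_alt <- pre; pre_alt[j] <- -Inf
      j2 <- which.max(suf_alt)
      i2 <- which.max(pre_alt)
      if (pre[i] + suf_alt[j2] >= pre_alt[i2] + suf[j]) {
        j <- j2
      } else {
        i <- i2
      }
    }
    sc <- (pre[i] + suf[j]) / L
    if (sc > best) {
      best <- sc
      best_bp <- b
      best_parents <- c(i, j)
    }
  }
  if (best >= threshold && best >= best_single + 0.01) {
    list(verdict = "chimeric", parent1 = best_parents[1L],
         parent2 = best_parents[2L], breakpoint = best_bp,
         identity = best)
  } else {
    clean
  }
}

#' Greedy abundance-sorted OTU clustering
#'
#' The most abundant unique sequence founds the first OTU; each
#' subsequent sequence joins the centroid of maximum identity when that
#' identity reaches `threshold` (ties go to the lowest OTU id), is
#' discarded when the chimera screen flags it, and otherwise founds a new
#' OTU. All centroids are pairwise below the threshold by construction;
#' the run re-verifies this and every membership identity.
#'
#' @param uniques A `unique_seqs` object in (abundance desc, bases asc)
#'   order, as produced by [dereplicate()].
#' @param threshold Identity threshold in (0, 1].
#' @param chimera_check Apply [screen_chimera()] to would-be founders.
#' @param verify Re-check centroid separation and membership identities
#'   after clustering (defensive; the greedy pass guarantees both).
#' @return A list of class `otu_set`: per-OTU `otu_id`, `centroid`,
#'   `members` (indices into `uniques`), `member_identity`, `abundance`,
#'   `locale_counts`; plus `chimeras` (discarded unique indices) and the
#'   `uniques` object itself.
#' @export
cluster_otus <- function(uniques, threshold = 0.97, chimera_check = TRUE,
                         verify = TRUE) {
  stopifnot(inherits(uniques, "unique_seqs"))
  n <- length(uniques$bases)
  ord <- order(-uniques$abundance, uniques$bases)
  if (!identical(ord, seq_len(n))) {
    stop("uniques must be sorted by (abundance desc, bases asc); ",
         "use dereplicate()")
  }
  centroid_idx <- integer(0)
  assignment <- integer(n)
  identity <- numeric(n)
  chimeric <- logical(n)
  for (i in seq_len(n)) {
    if (length(centroid_idx)) {
      ids <- identity_to_set(uniques$bases[i], uniques$bases[centroid_idx])
      best <- which.max(ids)
      if (ids[best] >= threshold) {
        assignment[i] <- best
        identity[i] <- ids[best]
        next
      }
      if (chimera_check) {
        verdict <- screen_chimera(uniques$bases[i],
                                  uniques$bases[centroid_idx], threshold)
        if (verdict$verdict == "chimeric") {
          chimeric[i] <- TRUE
          assignment[i] <- NA_integer_
          next
        }
      }
    }
    centroid_idx <- c(centroid_idx, i)
    assignment[i] <- length(centroid_idx)
    identity[i] <- 1
  }
  k <- length(centroid_idx)
  otus <- vector("list", k)
  for (j in seq_len(k)) {
    members <- which(!is.na(assignment) & assignment == j)
    otus[[j]] <- list(
      otu_id = sprintf("OTU_%d", j),
      centroid = uniques$bases[centroid_idx[j]],
      members = members,
      member_identity = identity[members],
      abundance = sum(uniques$abundance[members]),
      locale_counts = colSums(uniques$locale_counts[members, , drop = FALSE]))
  }
  out <- list(otus = otus, chimeras = which(chimeric), uniques = uniques,
              threshold = threshold)
  class(out) <- "otu_set"
  if (verify) verify_otus(out)
  out
}

verify_otus <- function(otu_set) {
  uniques <- otu_set$uniques
  threshold <- otu_set$threshold
  centroids <- vapply(otu_set$otus, `[[`, character(1), "centroid")
  if (length(centroids) > 1L) {
    for (j in seq_along(centroids)[-1L]) {
      ids <- identity_to_set(centroids[j], centroids[seq_len(j - 1L)])
      if (any(ids >= threshold)) {
        stop("internal error: centroid separation violated")
      }
    }
  }
  for (otu in otu_set$otus) {
    if (any(otu$member_identity < threshold)) {
      stop("internal error: member below threshold identity to centroid")
    }
  }
  total <- sum(vapply(otu_set$otus, `[[`, numeric(1), "abundance")) +
    sum(uniques$abundance[otu_set$chimeras])
  if (total != sum(uniques$abundance)) {
    stop("internal error: abundance not conserved across clustering")
  }
  invisible(otu_set)
}

#' @export
print.otu_set <- function(x, ...) {
  cat("otu_set:", length(x$otus), "OTUs at threshold", x$threshold, "\n")
  cat("  sizes:", paste(utils::head(
    vapply(x$otus, `[[`, numeric(1), "abundance"), 10L), collapse = ", "),
    if (length(x$otus) > 10L) "...", "\n")
  if (length(x$chimeras)) {
    cat("  discarded as chimeric:", length(x$chimeras),
        "unique sequence(s)\n")
  }
  invisible(x)
}

#' Add per-region counts to an OTU set
#'
#' @param otu_set An `otu_set`.
#' @param samples Sample table (defines the locale-to-region map; exactly
#'   two regions are required).
#' @return The `otu_set` with a `region_counts` element per OTU.
#' @export
add_region_counts <- function(otu_set, samples) {
  regions <- assert_two_regions(samples)
  map <- region_of_locale(samples)
  for (j in seq_along(otu_set$otus)) {
    lc <- otu_set$otus[[j]]$locale_counts
    rc <- tapply(lc, factor(map[names(lc)], levels = sort(regions)), sum)
    rc[is.na(rc)] <- 0
    otu_set$otus[[j]]$region_counts <- stats::setNames(as.numeric(rc),
                                                       names(rc))
  }
  otu_set
}

#' Comparative cross-barrier filter
#'
#' Keeps OTUs with at least `min_total` sequences overall and at least
#' `min_per_region` on each side of the barrier, preserving order. These
#' thresholds retain enough sequence data for statistical inference both
#' within and across sampling sites, and residual chimeras are expected
#' to fall below them.
#'
#' @param otu_set An `otu_set` with region counts
#'   (see [add_region_counts()]).
#' @param min_total Minimum total sequences per OTU.
#' @param min_per_region Minimum per-region sequences per OTU.
#' @return The filtered `otu_set`; dropped OTU ids are recorded in the
#'   `dropped` attribute-like element `filtered_out`.
#' @export
filter_comparative <- function(otu_set, min_total = 10L, min_per_region = 3L) {
  has_rc <- vapply(otu_set$otus, function(o) !is.null(o$region_counts),
                   logical(1))
  if (!all(has_rc)) {
    stop("region counts missing; call add_region_counts() first")
  }
  keep <- vapply(otu_set$otus, function(o) {
    o$abundance >= min_total && all(o$region_counts >= min_per_region)
  }, logical(1))
  dropped <- vapply(otu_set$otus[!keep], `[[`, character(1), "otu_id")
  otu_set$filtered_out <- dropped
  otu_set$otus <- otu_set$otus[keep]
  otu_set
}

#' OTU membership table
#'
#' @param otu_set An `otu_set`.
#' @param reads Read data frame the OTUs were built from.
#' @param samples Sample table.
#' @return Data frame with one row per clustered read: `read_id`,
#'   `otu_id`, `sample_id`, `locale`, `region`.
#' @export
otu_membership <- function(otu_set, reads, samples) {
  rows <- lapply(otu_set$otus, function(otu) {
    ids <- unlist(otu_set$uniques$members[otu$members], use.names = FALSE)
    if (length(ids) == 0L) return(NULL)
    data.frame(read_id = ids, otu_id = otu$otu_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(read_id = character(0), otu_id = character(0),
                      sample_id = character(0), locale = character(0),
                      region = character(0), stringsAsFactors = FALSE))
  }
  sample_of <- stats::setNames(reads$sample_id, reads$read_id)
  locale_of <- stats::setNames(samples$locale, samples$sample_id)
  region_map <- region_of_locale(samples)
  out$sample_id <- unname(sample_of[out$read_id])
  out$locale <- unname(locale_of[out$sample_id])
  out$region <- unname(region_map[out$locale])
  rownames(out) <- NULL
  out
}
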