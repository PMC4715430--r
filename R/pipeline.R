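# End-to-end orchestration: trim -> dereplicate -> cluster -> filter ->
# align -> per-OTU statistics -> structure tests -> community synthesis.

derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

#' Per-OTU statistical battery
#'
#' Runs the diversity summary, G_ST, AMOVA, GSI (both regions) and
#' Mantel test on one read-level OTU alignment. Tests that are
#' inapplicable (e.g. AMOVA when fewer than two locales hold two or more
#' sequences, Mantel with fewer than three locales, saturated K2P
#' distances for the tree) are reported as `NULL` with the reason
#' recorded in `exclusions`.
#'
#' @param aln A read-level `seq_alignment` with locale/region metadata.
#' @param geo Optional `geo_matrix` of locale distances for the Mantel
#'   test.
#' @param B Permutations for every permutation test.
#' @param seed Integer seed.
#' @param amova_distance `"raw"` pairwise differences or `"k2p"`.
#' @param regions Character vector of the two region labels, in the
#'   order GSI results should be reported (east first by convention when
#'   labels are `east`/`west`).
#' @return List with `stats`, `gst`, `amova`, `gsi`, `mantel`,
#'   `exclusions`.
#' @export
otu_statistics <- function(aln, geo = NULL, B = 999L, seed = 1L,
                           amova_distance = c("raw", "k2p"),
                           regions = NULL) {
  amova_distance <- match.arg(amova_distance)
  meta <- attr(aln, "meta")
  exclusions <- character(0)
  stats <- tryCatch(diversity_summary(aln),
                    error = function(e) {
                      exclusions <<- c(exclusions,
                                       paste("diversity:",
                                             conditionMessage(e)))
                      NULL
                    })
  gst <- tryCatch(gst_test(aln, B = B, seed = derive_seed(seed, 1L)),
                  error = function(e) {
                    exclusions <<- c(exclusions,
                                     paste("gst:", conditionMessage(e)))
                    NULL
                  })
  pd <- pairwise_diffs(aln)
  region_map <- stats::setNames(meta$region, meta$locale)
  region_map <- region_map[!duplicated(names(region_map))]
  d_amova <- if (amova_distance == "raw") pd$diffs else k2p_distance(aln)
  am <- tryCatch({
    # drop locales with a single sequence: within-locale variance needs
    # n_p >= 2 (these exclusions shrink the AMOVA total, as in any
    # nested design)
    keep <- meta$locale %in% names(which(table(meta$locale) >= 2L))
    if (!all(keep)) {
      exclusions <- c(exclusions,
                      paste0("amova: dropped singleton locale(s) ",
                             paste(setdiff(meta$locale[!keep], NULL),
                                   collapse = ",")))
    }
    sub <- which(keep)
    locs_left <- unique(meta$locale[sub])
    if (length(locs_left) < 2L ||
        length(unique(region_map[locs_left])) < 2L) {
      stop("fewer than 2 locales (or 1 region) with >= 2 sequences")
    }
    amova(d_amova[sub, sub, drop = FALSE], meta$locale[sub],
          region_map[locs_left], B = B, seed = derive_seed(seed, 2L))
  }, error = function(e) {
    exclusions <<- c(exclusions, paste("amova:", conditionMessage(e)))
    NULL
  })
  if (is.null(regions)) {
    regions <- sort(unique(meta$region))   # "east" before "west"
  }
  gsi <- tryCatch({
    k2p <- k2p_distance(aln)
    if (anyNA(k2p)) stop("saturated K2P distances")
    # duplicate haplotypes sit at zero distance, and NJ resolves such
    # ties by input position; the input is locale-blocked, so the tip
    # order is shuffled (seeded) to keep tie resolution independent of
    # the group labels
    set.seed(derive_seed(seed, 9L))
    ord <- sample.int(nrow(k2p))
    tree <- nj_tree(k2p[ord, ord, drop = FALSE])
    group_of <- stats::setNames(meta$region, meta$id)
    lapply(seq_along(regions), function(i) {
      gsi_test(tree, group_of, regions[i], B = B,
               seed = derive_seed(seed, 2L + i))
    })
  }, error = function(e) {
    exclusions <<- c(exclusions, paste("gsi:", conditionMessage(e)))
    NULL
  })
  mantel <- if (!is.null(geo)) {
    tryCatch({
      k2p <- k2p_distance(aln)
      if (anyNA(k2p)) stop("saturated K2P distances")
      present <- intersect(rownames(geo), unique(meta$locale))
      if (length(present) < 3L) stop("fewer than 3 locales sampled")
      keep <- meta$locale %in% present
      gen <- locale_distance_matrix(k2p[keep, keep, drop = FALSE],
                                    meta$locale[keep])
      mantel_test(gen, geo[rownames(gen), rownames(gen)], B = B,
                  seed = derive_seed(seed, 5L))
    }, error = function(e) {
      exclusions <<- c(exclusions, paste("mantel:", conditionMessage(e)))
      NULL
    })
  } else NULL
  list(stats = stats, gst = gst, amova = am, gsi = gsi, mantel = mantel,
       exclusions = exclusions)
}

#' Run the full co-diversification pipeline
#'
#' Global mode: trim -> dereplicate -> greedy OTU clustering (with
#' chimera screen) -> comparative cross-barrier filter -> per-OTU
#' center-star alignment -> diversity and structure statistics ->
#' community chi-squared synthesis -> report. Per-locale mode: trim ->
#' optional month filter -> per-locale clustering -> per-locale OTU
#' count matrix and rarefaction curves.
#'
#' @param fasta Path to the reads FASTA (`read_id|sample_id` headers).
#' @param sample_table Path to the sample table TSV.
#' @param out_dir Report directory.
#' @param config A `pipeline_config`.
#' @param coords Optional locale coordinates TSV (`locale`, `lat`,
#'   `lon`) enabling the Mantel test.
#' @param annotations Optional named character vector of OTU taxonomy
#'   annotations (free text, e.g. BLAST hits), keyed by otu_id.
#' @return The report file paths (invisibly); side effect: report files
#'   under `out_dir`.
#' @export
run_pipeline <- function(fasta, sample_table, out_dir,
                         config = pipeline_config(), coords = NULL,
                         annotations = NULL) {
  samples <- read_sample_table(sample_table)
  reads_raw <- read_sequences(fasta)
  stage_counts <- list(input_reads = nrow(reads_raw))
  reads <- trim_reads(reads_raw, config$trim_length)
  stage_counts$trimmed_reads <- nrow(reads)
  stage_counts$discarded_short <- attr(reads, "n_discarded")
  reads <- filter_by_month(reads, samples, config$month_filter)
  stage_counts$after_month_filter <- nrow(reads)

  geo <- NULL
  if (!is.null(coords)) {
    cdf <- utils::read.delim(coords, stringsAsFactors = FALSE)
    geo <- geo_distances(coords = cdf)
  }

  if (config$mode == "per_locale") {
    return(run_per_locale(reads, samples, out_dir, config, stage_counts))
  }

  assert_two_regions(samples)
  uniques <- dereplicate(reads, samples)
  stage_counts$unique_sequences <- length(uniques$bases)
  otus <- cluster_otus(uniques, threshold = config$identity_threshold,
                       chimera_check = config$chimera_check)
  stage_counts$otus_clustered <- length(otus$otus)
  stage_counts$chimeric_uniques <- length(otus$chimeras)
  otus <- add_region_counts(otus, samples)
  otus <- filter_comparative(otus, config$min_otu_size,
                             config$min_per_region)
  stage_counts$otus_comparative <- length(otus$otus)

  rows <- vector("list", length(otus$otus))
  exclusion_log <- list()
  for (j in seq_along(otus$otus)) {
    otu <- otus$otus[[j]]
    aln <- otu_alignment(otu, uniques, reads, samples)
    res <- otu_statistics(aln, geo = geo, B = config$n_permutations,
                          seed = derive_seed(config$seed, 100L + j),
                          amova_distance = config$amova_distance)
    rows[[j]] <- c(list(otu_id = otu$otu_id, n = otu$abundance,
                        annotation = if (!is.null(annotations))
                          annotations[otu$otu_id] else NULL),
                   res[c("stats", "gst", "amova", "gsi", "mantel")])
    if (length(res$exclusions)) {
      exclusion_log[[otu$otu_id]] <- res$exclusions
    }
  }
  tbl <- community_table(rows, alpha = config$alpha)
  gofs <- community_gof(tbl, alpha = config$alpha)
  aggregates <- if (nrow(tbl) > 0L) {
    grp <- if (!is.null(annotations)) {
      ifelse(tbl$annotation == "", "unannotated", tbl$annotation)
    } else rep("all", nrow(tbl))
    group_aggregates(tbl, grp)
  } else NULL
  stage_counts$exclusions <- exclusion_log
  files <- build_report(tbl, gofs, out_dir, aggregates = aggregates,
                        config = config, stage_counts = stage_counts)
  # membership table alongside the report
  memb <- otu_membership(otus, reads, samples)
  f <- file.path(out_dir, "otu_membership.tsv")
  write_tsv(memb, f)
  files["membership"] <- f
  f <- file.path(out_dir, "centroids.fasta")
  centroids <- vapply(otus$otus, `[[`, character(1), "centroid")
  ids <- vapply(otus$otus, `[[`, character(1), "otu_id")
  writeLines(as.vector(rbind(paste0(">", ids), centroids)), f)
  files["centroids"] <- f
  invisible(files)
}

run_per_locale <- function(reads, samples, out_dir, config, stage_counts) {
  locales <- sort(unique(samples$locale))
  counts_list <- list()
  curves <- list()
  otu_counts_per_locale <- list()
  for (loc in locales) {
    ids <- samples$sample_id[samples$locale == loc]
    sub <- reads[reads$sample_id %in% ids, , drop = FALSE]
    if (nrow(sub) == 0L) next
    uniques <- dereplicate(sub, samples)
    otus <- cluster_otus(uniques, threshold = config$identity_threshold,
                         chimera_check = config$chimera_check)
    sizes <- vapply(otus$otus, `[[`, numeric(1), "abundance")
    otu_counts_per_locale[[loc]] <- sizes
    counts_list[[loc]] <- data.frame(locale = loc,
                                     n_reads = nrow(sub),
                                     n_otus = length(sizes),
                                     stringsAsFactors = FALSE)
    curves[[loc]] <- rarefaction_curve(sizes, locale = loc)
  }
  summary_df <- do.call(rbind, counts_list)
  curves_df <- do.call(rbind, curves)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  f <- file.path(out_dir, "per_locale_summary.tsv")
  write_tsv(summary_df, f)
  files["summary"] <- f
  f <- file.path(out_dir, "rarefaction.tsv")
  write_tsv(curves_df, f)
  files["rarefaction"] <- f
  manifest <- list(package_version =
                     as.character(utils::packageVersion("codiv")),
                   config = unclass(config), stage_counts = stage_counts)
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files["manifest"] <- f
  invisible(files)
}
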