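# Community-level synthesis: the per-OTU significance matrix, chi-squared
# goodness-of-fit tests, group aggregates, rarefaction and the report.

#' Chi-squared goodness-of-fit test for an excess of significant OTUs
#'
#' Under the null that no OTU is structured, each test is significant
#' with probability `alpha`. With `O` observed significant OTUs out of
#' `total`, the statistic is
#' `chi2 = (O - E1)^2/E1 + ((total - O) - E2)^2/E2` with
#' `E1 = alpha * total`, `E2 = (1 - alpha) * total`, on 1 df, with an
#' upper-tail p-value.
#'
#' @param observed Number of OTUs significant at `alpha`.
#' @param total Number of OTUs for which the test was computable.
#' @param alpha Significance level.
#' @return A list of class `gof_result`.
#' @export
chi_squared_gof <- function(observed, total, alpha = 0.05) {
  if (total <= 0) stop("total must be positive")
  if (observed < 0 || observed > total) {
    stop("observed must lie in [0, total]")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  e1 <- alpha * total
  e2 <- (1 - alpha) * total
  chi2 <- (observed - e1)^2 / e1 + ((total - observed) - e2)^2 / e2
  structure(list(observed = observed, total = total, alpha = alpha,
                 expected = e1, chi2 = chi2, df = 1L,
                 p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("gof_result: observed=%d/%d (expected %.2f) chi2=%.4f p=%.3g\n",
              x$observed, x$total, x$expected, x$chi2, x$p_value))
  invisible(x)
}

#' Count significant OTUs per test
#'
#' For each p-value column, counts rows with `p < alpha` (strict); the
#' total for a test counts only rows where that test produced a p-value,
#' so tests that were inapplicable for some OTUs (e.g. AMOVA with a
#' locale reduced below two sequences) have smaller totals.
#'
#' @param table Community table (see [community_table()]), or any data
#'   frame with `p_*` columns.
#' @param alpha Significance level.
#' @param tests Character vector of p-value column names; default all
#'   columns starting with `p_`.
#' @return Data frame with `test`, `observed`, `total`.
#' @export
significance_counts <- function(table, alpha = 0.05, tests = NULL) {
  if (is.null(tests)) tests <- grep("^p_", names(table), value = TRUE)
  out <- lapply(tests, function(tst) {
    p <- table[[tst]]
    data.frame(test = sub("^p_", "", tst),
               observed = sum(!is.na(p) & p < alpha),
               total = sum(!is.na(p)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group aggregates of per-OTU statistics
#'
#' Medians of Tajima's D and means of G_ST (and of any other numeric
#' columns supplied) per annotation group and overall. The median is the
#' midpoint element for odd counts and the mean of the central pair for
#' even counts (`stats::median`).
#'
#' @param table Data frame of per-OTU statistics.
#' @param group Group label per row.
#' @param median_cols,mean_cols Columns to aggregate.
#' @return Data frame of aggregates, one row per group plus `overall`.
#' @export
group_aggregates <- function(table, group,
                             median_cols = intersect("D", names(table)),
                             mean_cols = intersect(c("G_ST", "pi", "theta_w"),
                                                   names(table))) {
  agg_one <- function(rows, label) {
    out <- data.frame(group = label, n = length(rows),
                      stringsAsFactors = FALSE)
    for (cl in median_cols) {
      out[[paste0("median_", cl)]] <- stats::median(table[[cl]][rows],
                                                    na.rm = TRUE)
    }
    for (cl in mean_cols) {
      out[[paste0("mean_", cl)]] <- mean(table[[cl]][rows], na.rm = TRUE)
    }
    out
  }
  groups <- unique(group)
  out <- lapply(groups, function(g) agg_one(which(group == g), g))
  out <- c(out, list(agg_one(seq_len(nrow(table)), "overall")))
  do.call(rbind, out)
}

#' Expected OTU richness under rarefaction
#'
#' Hypergeometric expectation of the number of OTUs observed in a random
#' subsample of `m` sequences:
#' `E[S_m] = sum_i (1 - choose(N - N_i, m)/choose(N, m))`, computed via
#' `vegan::rarefy`.
#'
#' @param otu_counts Per-OTU sequence counts (all >= 1).
#' @param grid Subsample sizes (each <= `sum(otu_counts)`).
#' @param locale Optional locale label carried into the result.
#' @return Data frame of class `rarefaction_curve` with `m` and
#'   `expected_richness`.
#' @export
rarefaction_curve <- function(otu_counts, grid = NULL, locale = NA) {
  stopifnot(length(otu_counts) > 0, all(otu_counts >= 1))
  N <- sum(otu_counts)
  if (is.null(grid)) grid <- unique(round(seq(1, N, length.out = 25)))
  if (any(grid > N)) {
    stop("subsample size exceeds the number of sequences (", N, ")")
  }
  if (any(grid < 1)) stop("subsample sizes must be >= 1")
  rich <- vapply(grid, function(m) {
    # rarefy warns about singleton counts; expected here
    suppressWarnings(
      unname(vegan::rarefy(matrix(otu_counts, nrow = 1), sample = m)))
  }, numeric(1))
  out <- data.frame(locale = locale, m = grid, expected_richness = rich)
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Assemble the community table from per-OTU results
#'
#' One row per OTU with its size, annotation, diversity statistics and
#' structure statistics with p-values, plus significance flags at
#' `alpha` (strict `p < alpha`).
#'
#' @param rows List of per-OTU result lists, each with elements `otu_id`,
#'   `n`, `annotation`, `stats` (a `diversity_stats`), `gst`
#'   (`gst_result`), `amova` (`amova_result` or `NULL`), `gsi` (list of
#'   two `gsi_result`), `mantel` (`mantel_result` or `NULL`).
#' @param alpha Significance level for the flags.
#' @return Data frame of class `community_table`.
#' @export
community_table <- function(rows, alpha = 0.05) {
  grab <- function(x, ...) {
    out <- x
    for (nm in c(...)) {
      if (is.null(out)) return(NA_real_)
      out <- out[[nm]]
    }
    if (is.null(out)) NA_real_ else out
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      otu_id = r$otu_id,
      n = r$n,
      annotation = if (is.null(r$annotation)) "" else r$annotation,
      pi = grab(r, "stats", "pi"),
      theta_w = grab(r, "stats", "theta_w"),
      D = grab(r, "stats", "D"),
      p_D = grab(r, "stats", "D_pvalue"),
      G_ST = grab(r, "gst", "G_ST"),
      p_G_ST = grab(r, "gst", "p_value"),
      phi_ct = grab(r, "amova", "phi_ct"),
      phi_sc = grab(r, "amova", "phi_sc"),
      phi_st = grab(r, "amova", "phi_st"),
      p_phi_ct = grab(r, "amova", "p_ct"),
      p_phi_sc = grab(r, "amova", "p_sc"),
      p_phi_st = grab(r, "amova", "p_st"),
      gsi_east = if (is.null(r$gsi)) NA_real_ else r$gsi[[1L]]$gsi,
      p_gsi_east = if (is.null(r$gsi)) NA_real_ else r$gsi[[1L]]$p_value,
      gsi_west = if (is.null(r$gsi)) NA_real_ else r$gsi[[2L]]$gsi,
      p_gsi_west = if (is.null(r$gsi)) NA_real_ else r$gsi[[2L]]$p_value,
      mantel_r = grab(r, "mantel", "r"),
      p_mantel = grab(r, "mantel", "p_value"),
      stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(otu_id = character(0))
  } else {
    for (pc in grep("^p_", names(df), value = TRUE)) {
      df[[sub("^p_", "sig_", pc)]] <- !is.na(df[[pc]]) & df[[pc]] < alpha
    }
  }
  attr(df, "alpha") <- alpha
  class(df) <- c("community_table", "data.frame")
  df
}

#' Community chi-squared synthesis
#'
#' Runs [chi_squared_gof()] on each test's significance counts.
#'
#' @param table A `community_table` (or the output of
#'   [significance_counts()]).
#' @param alpha Significance level.
#' @return Data frame with one row per test: observed, total, chi2, df,
#'   p_value.
#' @export
community_gof <- function(table, alpha = 0.05) {
  counts <- if (all(c("test", "observed", "total") %in% names(table))) {
    table
  } else {
    significance_counts(table, alpha = alpha)
  }
  res <- lapply(seq_len(nrow(counts)), function(i) {
    if (counts$total[i] == 0) {
      return(data.frame(test = counts$test[i], observed = 0L, total = 0L,
                        chi2 = NA_real_, df = 1L, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    g <- chi_squared_gof(counts$observed[i], counts$total[i], alpha)
    data.frame(test = counts$test[i], observed = g$observed,
               total = g$total, chi2 = g$chi2, df = g$df,
               p_value = g$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

format_tsv_num <- function(x) {
  if (is.numeric(x)) {
    ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
  } else {
    x
  }
}

write_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, format_tsv_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the community report bundle
#'
#' Emits the community table, the chi-squared synthesis table, a
#' significance matrix, rarefaction curves (when supplied) and a JSON
#' run manifest with the configuration, seed and stage counts. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param table A `community_table`.
#' @param gofs Output of [community_gof()].
#' @param out_dir Output directory (created if needed).
#' @param curves Optional rarefaction curves (stacked data frame).
#' @param aggregates Optional output of [group_aggregates()].
#' @param config The `pipeline_config` used.
#' @param stage_counts Named list of per-stage input/output counts.
#' @return Named character vector of the files written, invisibly.
#' @export
build_report <- function(table, gofs, out_dir, curves = NULL,
                         aggregates = NULL, config = NULL,
                         stage_counts = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  if (nrow(table) == 0L) {
    warning("community table is empty; writing empty report")
  }
  f <- file.path(out_dir, "community_table.tsv")
  write_tsv(as.data.frame(table), f)
  files["community_table"] <- f
  f <- file.path(out_dir, "chi_squared_tests.tsv")
  write_tsv(gofs, f)
  files["gof"] <- f
  sig_cols <- grep("^sig_", names(table), value = TRUE)
  if (length(sig_cols)) {
    sig <- cbind(table[, "otu_id", drop = FALSE],
                 as.data.frame(lapply(table[sig_cols], as.integer)))
    f <- file.path(out_dir, "significance_matrix.tsv")
    write_tsv(sig, f)
    files["significance_matrix"] <- f
  }
  if (!is.null(aggregates)) {
    f <- file.path(out_dir, "group_aggregates.tsv")
    write_tsv(aggregates, f)
    files["aggregates"] <- f
  }
  if (!is.null(curves)) {
    f <- file.path(out_dir, "rarefaction.tsv")
    write_tsv(as.data.frame(curves), f)
    files["rarefaction"] <- f
  }
  manifest <- list(package_version = as.character(utils::packageVersion("codiv")),
                   config = if (!is.null(config)) unclass(config),
                   stage_counts = stage_counts,
                   n_otus_reported = nrow(table))
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files["manifest"] <- f
  invisible(files)
}

#' Published pitcher-plant inquiline survey tables
#'
#' `inquiline_survey()` returns the per-OTU summary table from a
#' published 454 amplicon survey of the eukaryotes living in
#' *Sarracenia alata* pitcher fluid, sampled from five Louisiana locales
#' on both sides of the Mississippi River: for each of 31 comparative
#' OTUs (and the host plant's chloroplast data) the number of sequences,
#' nearest database hit, nucleotide diversity, Watterson's theta,
#' Tajima's D and G_ST, with reported significance flags at alpha = 0.05.
#' `inquiline_structure_counts()` returns the published counts of OTUs
#' with significant structure per test (AMOVA Phi statistics, G_ST and
#' the east/west genealogical sorting indices), the input to the
#' community chi-squared synthesis.
#'
#' @return A data frame.
#' @export
inquiline_survey <- function() {
  path <- system.file("extdata", "inquiline_survey.tsv", package = "codiv",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname inquiline_survey
#' @export
inquiline_structure_counts <- function() {
  path <- system.file("extdata", "inquiline_structure_counts.tsv",
                      package = "codiv", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
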