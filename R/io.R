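#' Nucleotide alphabets used throughout the package
#'
#' `DNA_ALPHABET` is the read alphabet (A, C, G, T, N); `ALN_ALPHABET`
#' additionally allows the gap character `-` in aligned sequences.
#'
#' @format Character vectors.
#' @export
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' @rdname DNA_ALPHABET
#' @export
ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Read demultiplexed amplicon reads from a FASTA file
#'
#' Each record is one read from one pitcher/sample. Headers are parsed as
#' `"read_id|sample_id"`; alternatively supply `sample_map`, a named
#' character vector mapping `read_id` to `sample_id`, in which case the
#' whole header is taken as the read id. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Allowed characters; any record containing a character
#'   outside this set raises an error naming the record.
#' @param sample_map Optional named character vector `read_id -> sample_id`.
#' @return A data frame with columns `read_id`, `sample_id`, `bases`.
#' @export
read_sequences <- function(path, alphabet = DNA_ALPHABET, sample_map = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  headers <- sub("\\s.*$", "", names(set))
  bases <- toupper(as.character(set))
  if (is.null(sample_map)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop("FASTA header(s) not of the form 'read_id|sample_id' ",
           "(and no sample_map given): '", headers[which(bad)[1L]], "'")
    }
    read_id <- vapply(parts, `[[`, character(1), 1L)
    sample_id <- vapply(parts, `[[`, character(1), 2L)
  } else {
    read_id <- headers
    missing_ids <- setdiff(read_id, names(sample_map))
    if (length(missing_ids)) {
      stop("no sample mapping for read(s): ",
           paste(utils::head(missing_ids, 3L), collapse = ", "))
    }
    sample_id <- unname(sample_map[read_id])
  }
  if (anyDuplicated(read_id)) {
    stop("duplicate read_id in FASTA: '", read_id[duplicated(read_id)][1L], "'")
  }
  if (any(!nzchar(bases))) {
    stop("empty sequence for record '", read_id[!nzchar(bases)][1L], "'")
  }
  cls <- paste0("[^", paste(setdiff(alphabet, "-"), collapse = ""),
                if ("-" %in% alphabet) "-", "]")
  ok <- !grepl(cls, bases)
  if (!all(ok)) {
    stop("sequence contains characters outside {",
         paste(alphabet, collapse = ","), "}: record '", read_id[!ok][1L], "'")
  }
  data.frame(read_id = read_id, sample_id = sample_id, bases = unname(bases),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTA with `read_id|sample_id` headers
#'
#' @param reads Data frame with `read_id`, `sample_id`, `bases`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sample_id", "bases") %in% names(reads)))
  lines <- character(2L * nrow(reads))
  lines[c(TRUE, FALSE)] <- paste0(">", reads$read_id, "|", reads$sample_id)
  lines[c(FALSE, TRUE)] <- reads$bases
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate the sample table
#'
#' The sample table maps each pitcher/sample to its locale, the region
#' (side of the barrier) the locale belongs to, and the collection month.
#' It is the grouping backbone for every hierarchical test.
#'
#' @param path Path to a tab-separated file with header columns
#'   `sample_id`, `locale`, `region`, `month`.
#' @return A validated data frame of class `sample_table`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  tbl <- tryCatch(
    utils::read.delim(path, colClasses = "character", check.names = FALSE),
    error = function(e) stop("cannot parse sample table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  validate_sample_table(tbl)
}

#' @rdname read_sample_table
#' @param tbl A data frame to validate as a sample table.
#' @export
validate_sample_table <- function(tbl) {
  required <- c("sample_id", "locale", "region", "month")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("sample table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tbl) == 0L) stop("sample table has no rows")
  if (anyDuplicated(tbl$sample_id)) {
    stop("duplicate sample_id in sample table: '",
         tbl$sample_id[duplicated(tbl$sample_id)][1L], "'")
  }
  map <- unique(tbl[, c("locale", "region")])
  if (anyDuplicated(map$locale)) {
    bad <- map$locale[duplicated(map$locale)][1L]
    stop("locale '", bad, "' is mapped to more than one region")
  }
  tbl <- tbl[, c(required, setdiff(names(tbl), required)), drop = FALSE]
  class(tbl) <- c("sample_table", "data.frame")
  tbl
}

#' Write a sample table as TSV
#' @param tbl A sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(tbl, path) {
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locale-to-region lookup from a sample table
#' @param samples A sample table.
#' @return Named character vector mapping locale to region.
#' @export
region_of_locale <- function(samples) {
  map <- unique(data.frame(locale = samples$locale, region = samples$region,
                           stringsAsFactors = FALSE))
  stats::setNames(map$region, map$locale)
}

assert_two_regions <- function(samples) {
  regions <- unique(samples$region)
  if (length(regions) != 2L) {
    stop("barrier analyses require exactly two regions; found ",
         length(regions), " (", paste(regions, collapse = ", "), ")")
  }
  invisible(regions)
}

#' Great-circle distance matrix between locales
#'
#' Computes haversine great-circle distances in km (sphere radius 6371 km)
#' from locale coordinates, or validates and ingests a user-supplied
#' distance matrix verbatim.
#'
#' @param coords Data frame with columns `locale`, `lat`, `lon` (degrees).
#' @param matrix Alternatively, a symmetric numeric matrix (km) with locale
#'   dimnames; ingested unchanged after validation.
#' @return Symmetric matrix of distances in km with zero diagonal, class
#'   `geo_matrix`.
#' @export
geo_distances <- function(coords = NULL, matrix = NULL) {
  if (!is.null(matrix)) {
    m <- as.matrix(matrix)
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("distance matrix must have locale dimnames")
    }
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      stop("distance matrix is not symmetric")
    }
    if (any(m < 0)) stop("distance matrix has negative entries")
    if (any(abs(diag(m)) > 1e-8)) stop("distance matrix diagonal is not zero")
    diag(m) <- 0
    class(m) <- c("geo_matrix", class(m))
    return(m)
  }
  stopifnot(is.data.frame(coords),
            all(c("locale", "lat", "lon") %in% names(coords)))
  if (any(abs(coords$lat) > 90)) stop("latitude outside [-90, 90]")
  if (any(abs(coords$lon) > 180)) stop("longitude outside [-180, 180]")
  if (anyDuplicated(coords$locale)) stop("duplicate locale in coords")
  pts <- cbind(coords$lon, coords$lat)
  m <- geosphere::distm(pts, fun = function(x, y) {
    geosphere::distHaversine(x, y, r = 6371)
  })
  dimnames(m) <- list(coords$locale, coords$locale)
  diag(m) <- 0
  class(m) <- c("geo_matrix", class(m))
  m
}

#' Pipeline configuration
#'
#' Pins every threshold of the analysis in one validated object. Defaults
#' reflect the standard settings for ~275 bp 28S amplicons: trim length
#' 275 bp, 97% OTU identity, comparative filter of >= 10 sequences total
#' with >= 3 on each side of the barrier, 10,000 permutations, alpha 0.05.
#'
#' @param trim_length Read trim length in bp.
#' @param identity_threshold OTU clustering identity in (0, 1].
#' @param min_otu_size Minimum total sequences per comparative OTU.
#' @param min_per_region Minimum sequences per region per comparative OTU.
#' @param n_permutations Permutations for every permutation test.
#' @param alpha Significance level.
#' @param seed Integer root seed; every stage derives its stream from it.
#' @param month_filter Optional character vector of months; reads from
#'   samples collected in other months are dropped before clustering.
#' @param chimera_check Run the single-crossover chimera screen during
#'   clustering.
#' @param mode `"global"` (comparative set) or `"per_locale"`
#'   (within-locale survey with rarefaction).
#' @param amova_distance `"raw"` (pairwise differences) or `"k2p"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_length = 275L,
                            identity_threshold = 0.97,
                            min_otu_size = 10L,
                            min_per_region = 3L,
                            n_permutations = 10000L,
                            alpha = 0.05,
                            seed = 1L,
                            month_filter = NULL,
                            chimera_check = TRUE,
                            mode = c("global", "per_locale"),
                            amova_distance = c("raw", "k2p")) {
  mode <- match.arg(mode)
  amova_distance <- match.arg(amova_distance)
  if (!(identity_threshold > 0 && identity_threshold <= 1)) {
    stop("identity_threshold must be in (0, 1]")
  }
  if (trim_length < 1) stop("trim_length must be positive")
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  cfg <- list(trim_length = as.integer(trim_length),
              identity_threshold = identity_threshold,
              min_otu_size = as.integer(min_otu_size),
              min_per_region = as.integer(min_per_region),
              n_permutations = as.integer(n_permutations),
              alpha = alpha,
              seed = as.integer(seed),
              month_filter = month_filter,
              chimera_check = isTRUE(chimera_check),
              mode = mode,
              amova_distance = amova_distance)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read or write a pipeline configuration as JSON
#' @param path JSON file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-19s %s\n", nm,
                if (is.null(val)) "<none>" else paste(val, collapse = ", ")))
  }
  invisible(x)
}
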