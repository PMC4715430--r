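# Per-OTU multiple alignment: built-in center-star aligner plus ingestion
# of externally aligned FASTA.

#' Construct a sequence alignment object
#'
#' An alignment is a character matrix (rows = sequences, columns = sites)
#' over `{A,C,G,T,N,-}` with per-row metadata.
#'
#' @param seqs Named character vector of equal-length (gapped) sequences,
#'   or a character matrix with rownames.
#' @param meta Optional data frame with columns `id`, `sample_id`,
#'   `locale`, `region`, one row per sequence (matched by `id`).
#' @return A matrix of class `seq_alignment` with a `meta` attribute.
#' @export
seq_alignment <- function(seqs, meta = NULL) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
    widths <- unique(nchar(seqs))
    if (length(widths) > 1L) {
      stop("alignment rows have differing lengths: ",
           paste(widths, collapse = ", "))
    }
    m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE,
                dimnames = list(names(seqs), NULL))
  }
  bad <- !(m %in% ALN_ALPHABET)
  if (any(bad)) {
    stop("alignment contains characters outside {",
         paste(ALN_ALPHABET, collapse = ","), "}")
  }
  all_gap <- apply(m == "-", 1L, all)
  if (any(all_gap)) {
    stop("alignment row(s) consist entirely of gaps: ",
         paste(rownames(m)[all_gap], collapse = ", "))
  }
  if (!is.null(meta)) {
    stopifnot(is.data.frame(meta), "id" %in% names(meta))
    if (!setequal(meta$id, rownames(m)) || nrow(meta) != nrow(m)) {
      stop("metadata rows do not match alignment rows")
    }
    meta <- meta[match(rownames(m), meta$id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(m, meta = meta, class = c("seq_alignment", "matrix"))
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", nrow(x), "sequences x", ncol(x), "columns\n")
  meta <- attr(x, "meta")
  if (!is.null(meta) && "locale" %in% names(meta)) {
    cat("  locales:", paste(names(table(meta$locale)), table(meta$locale),
                            sep = ":", collapse = " "), "\n")
  }
  invisible(x)
}

#' Row strings of an alignment
#' @param aln A `seq_alignment`.
#' @return Named character vector of gapped row strings.
#' @export
alignment_strings <- function(aln) {
  stats::setNames(apply(unclass(aln), 1L, paste, collapse = ""),
                  rownames(aln))
}

# full two-row alignment of `seq` against `center`, reconstructing the
# terminal overhangs that the ends-free alignment clips.
pairwise_rows <- function(seq, center) {
  aln <- align_to_set(seq, center)
  p_mid <- as.character(Biostrings::pattern(aln))
  s_mid <- as.character(Biostrings::subject(aln))
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  p_left <- substr(seq, 1L, ps - 1L)
  s_left <- substr(center, 1L, ss - 1L)
  p_right <- substr(seq, pe + 1L, nchar(seq))
  s_right <- substr(center, se + 1L, nchar(center))
  row_seq <- paste0(p_left, strrep("-", nchar(s_left)),
                    p_mid,
                    p_right, strrep("-", nchar(s_right)))
  row_cen <- paste0(strrep("-", nchar(p_left)), s_left,
                    s_mid,
                    strrep("-", nchar(p_right)), s_right)
  c(seq = row_seq, center = row_cen)
}

#' Center-star multiple alignment
#'
#' Aligns every sequence pairwise to the center (the highest-abundance
#' sequence, ties broken by the base string) and merges the pairwise
#' alignments under the "once a gap, always a gap" rule. Suited to short,
#' low-divergence amplicons; externally aligned FASTA remains a
#' first-class alternative via [ingest_alignment()].
#'
#' @param seqs Character vector of sequences (ungapped), or a
#'   `unique_seqs` object.
#' @param ids Row ids; defaults to names or `u1..un`.
#' @param abundance Optional abundances used to pick the center; for a
#'   `unique_seqs` input these are taken from the object.
#' @return A `seq_alignment`. Stripping gaps from any row reproduces the
#'   input sequence exactly.
#' @export
center_star_align <- function(seqs, ids = NULL, abundance = NULL) {
  if (inherits(seqs, "unique_seqs")) {
    abundance <- seqs$abundance
    seqs <- seqs$bases
  }
  n <- length(seqs)
  if (n == 0L) stop("no sequences to align")
  if (is.null(ids)) ids <- if (!is.null(names(seqs))) names(seqs) else
    paste0("u", seq_len(n))
  if (is.null(abundance)) abundance <- rep(1L, n)
  if (n == 1L) return(seq_alignment(stats::setNames(seqs, ids)))
  center_i <- order(-abundance, seqs)[1L]
  center <- seqs[center_i]
  L <- nchar(center)
  others <- setdiff(seq_len(n), center_i)
  # per sequence: characters in each insertion slot (0..L, "before
  # position j+1") and the character aligned to each center position.
  slot_chars <- vector("list", n)
  pos_chars <- vector("list", n)
  ins_len <- matrix(0L, nrow = n, ncol = L + 1L)
  for (i in others) {
    rows <- pairwise_rows(seqs[i], center)
    cen_chars <- strsplit(rows[["center"]], "", fixed = TRUE)[[1L]]
    seq_chars <- strsplit(rows[["seq"]], "", fixed = TRUE)[[1L]]
    slot <- cumsum(cen_chars != "-")        # 0 before first center base
    is_gap <- cen_chars == "-"
    slots <- vector("list", L + 1L)
    if (any(is_gap)) {
      gap_slot <- slot[is_gap] + 1L         # slot index 1..L+1
      slots[unique(gap_slot)] <- split(seq_chars[is_gap], gap_slot)[
        as.character(unique(gap_slot))]
    }
    slot_chars[[i]] <- slots
    pos_chars[[i]] <- seq_chars[!is_gap]
    ins_len[i, ] <- vapply(slots, length, integer(1))
  }
  slot_chars[[center_i]] <- vector("list", L + 1L)
  pos_chars[[center_i]] <- strsplit(center, "", fixed = TRUE)[[1L]]
  ins_glob <- apply(ins_len, 2L, max)
  build_row <- function(i) {
    pieces <- character(0)
    slots <- slot_chars[[i]]
    pos <- pos_chars[[i]]
    for (j in seq_len(L + 1L)) {
      if (ins_glob[j] > 0L) {
        seg <- slots[[j]]
        pad <- ins_glob[j] - length(seg)
        pieces <- c(pieces, seg, rep("-", pad))
      }
      if (j <= L) pieces <- c(pieces, pos[j])
    }
    paste(pieces, collapse = "")
  }
  out <- vapply(seq_len(n), build_row, character(1))
  seq_alignment(stats::setNames(out, ids))
}

#' Read-level alignment for one OTU
#'
#' Aligns the OTU's unique member sequences with [center_star_align()]
#' and expands each unique row to its member reads, attaching sample,
#' locale and region metadata. Statistics downstream therefore weight
#' haplotypes by their observed abundance.
#'
#' @param otu One element of an `otu_set`'s `otus` list.
#' @param uniques The `unique_seqs` object the OTUs were built from.
#' @param reads Read data frame.
#' @param samples Sample table.
#' @return A `seq_alignment` with one row per read.
#' @export
otu_alignment <- function(otu, uniques, reads, samples) {
  idx <- otu$members
  aln_u <- center_star_align(uniques$bases[idx],
                             ids = paste0("u", idx),
                             abundance = uniques$abundance[idx])
  strings <- alignment_strings(aln_u)
  read_ids <- unlist(uniques$members[idx], use.names = FALSE)
  times <- uniques$abundance[idx]
  rows <- rep(strings, times = times)
  names(rows) <- read_ids
  sample_of <- stats::setNames(reads$sample_id, reads$read_id)
  locale_of <- stats::setNames(samples$locale, samples$sample_id)
  region_map <- region_of_locale(samples)
  meta <- data.frame(id = read_ids,
                     sample_id = unname(sample_of[read_ids]),
                     stringsAsFactors = FALSE)
  meta$locale <- unname(locale_of[meta$sample_id])
  meta$region <- unname(region_map[meta$locale])
  seq_alignment(rows, meta = meta)
}

#' Ingest an externally aligned FASTA
#'
#' Accepts alignments produced by any external aligner. Rows must be of
#' uniform length; metadata is joined from the sample table via
#' `read_id|sample_id` headers (or `sample_map`).
#'
#' @inheritParams read_sequences
#' @param samples Sample table.
#' @return A `seq_alignment`.
#' @export
ingest_alignment <- function(path, samples, sample_map = NULL) {
  reads <- read_sequences(path, alphabet = ALN_ALPHABET,
                          sample_map = sample_map)
  widths <- unique(nchar(reads$bases))
  if (length(widths) > 1L) {
    stop("aligned FASTA has rows of differing length: ",
         paste(widths, collapse = ", "))
  }
  missing_samples <- setdiff(reads$sample_id, samples$sample_id)
  if (length(missing_samples)) {
    stop("aligned FASTA references unknown sample(s): ",
         paste(utils::head(missing_samples, 3L), collapse = ", "))
  }
  locale_of <- stats::setNames(samples$locale, samples$sample_id)
  region_map <- region_of_locale(samples)
  meta <- data.frame(id = reads$read_id, sample_id = reads$sample_id,
                     stringsAsFactors = FALSE)
  meta$locale <- unname(locale_of[meta$sample_id])
  meta$region <- unname(region_map[meta$locale])
  seq_alignment(stats::setNames(reads$bases, reads$read_id), meta = meta)
}

#' Write an alignment as FASTA
#'
#' @param aln A `seq_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  strings <- alignment_strings(aln)
  meta <- attr(aln, "meta")
  headers <- if (!is.null(meta) && "sample_id" %in% names(meta)) {
    paste0(">", meta$id, "|", meta$sample_id)
  } else {
    paste0(">", names(strings))
  }
  lines <- character(2L * length(strings))
  lines[c(TRUE, FALSE)] <- headers
  lines[c(FALSE, TRUE)] <- unname(strings)
  writeLines(lines, path)
  invisible(path)
}
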