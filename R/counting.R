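#' Count library spacers in amplicon reads by exact 20-mer matching
#'
#' A read pair increments exactly one spacer's count when exactly one
#' distinct library spacer occurs as an exact substring of read 1 or read 2
#' (each read is searched on both strands by default). Pairs matching zero
#' or two-or-more distinct spacers are discarded and tallied. A spacer
#' occurring several times within a pair — in both mates, or repeated in one
#' read — still counts once: the unit counted is spacer abundance per
#' molecule, not occurrences.
#'
#' @param fastq1 Path to read-1 FASTQ (plain or gzipped).
#' @param fastq2 Optional path to read-2 FASTQ; single-end if `NULL`.
#' @param library Spacer library tibble with spacer_id and 20-nt sequence;
#'   sequences must be unique.
#' @param search_revcomp Also search each read's reverse complement
#'   (default `TRUE`; amplicon orientation is often unknown).
#' @param chunk_size Reads processed per block (memory control).
#' @return A tibble (spacer_id, count) with a `discards` attribute:
#'   tibble(n_pairs, n_counted, n_no_match, n_ambiguous).
#' @export
count_spacers <- function(fastq1, fastq2 = NULL, library,
                          search_revcomp = TRUE, chunk_size = 5000L) {
  check_cols(library, c("spacer_id", "sequence"), "library")
  if (any(nchar(library$sequence) != 20)) {
    abort("all spacer sequences must be exactly 20 nt")
  }
  if (anyDuplicated(library$sequence)) {
    abort("duplicate spacer sequences in library")
  }
  r1 <- read_fastq(fastq1)
  r2 <- if (!is.null(fastq2)) read_fastq(fastq2) else NULL
  if (!is.null(r2) && length(r1) != length(r2)) {
    abort("read-1 and read-2 files have different numbers of records")
  }

  n_spacers <- nrow(library)
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(library$sequence))
  counts <- integer(n_spacers)
  n_no_match <- 0L
  n_ambiguous <- 0L
  n_pairs <- length(r1)

  hit_matrix <- function(reads) {
    m <- Biostrings::vcountPDict(pdict, reads) > 0
    if (search_revcomp) {
      m <- m | (Biostrings::vcountPDict(pdict,
                                        Biostrings::reverseComplement(reads)) > 0)
    }
    m
  }

  idx <- seq_len(n_pairs)
  for (block in split(idx, ceiling(idx / chunk_size))) {
    hits <- hit_matrix(r1[block])
    if (!is.null(r2)) hits <- hits | hit_matrix(r2[block])
    nm <- colSums(hits)
    n_no_match <- n_no_match + sum(nm == 0)
    n_ambiguous <- n_ambiguous + sum(nm >= 2)
    ok <- nm == 1
    if (any(ok)) counts <- counts + rowSums(hits[, ok, drop = FALSE])
  }

  out <- tibble(spacer_id = library$spacer_id, count = as.integer(counts))
  attr(out, "discards") <- tibble(
    n_pairs = n_pairs,
    n_counted = sum(out$count),
    n_no_match = n_no_match,
    n_ambiguous = n_ambiguous
  )
  out
}

#' Merge per-sample count columns into one counts table
#'
#' @param columns Named list of per-sample count tibbles (spacer_id, count),
#'   as produced by [count_spacers()]; names are sample ids.
#' @param sample_sheet Sample sheet tibble; every sample_id must have a
#'   matching column.
#' @return Counts tibble: spacer_id plus one column per sample, missing
#'   spacers filled with 0. Column order follows the sample sheet.
#' @export
merge_count_columns <- function(columns, sample_sheet) {
  check_cols(sample_sheet, "sample_id", "sample sheet")
  missing <- setdiff(sample_sheet$sample_id, names(columns))
  if (length(missing) > 0) {
    abort(sprintf("sample(s) in sheet without a count column: %s",
                  paste(missing, collapse = ", ")))
  }
  spacers <- sort(unique(unlist(lapply(columns, function(x) x$spacer_id))))
  out <- tibble(spacer_id = spacers)
  for (sid in sample_sheet$sample_id) {
    col <- columns[[sid]]
    v <- setNames(as.integer(col$count), col$spacer_id)[spacers]
    v[is.na(v)] <- 0L
    out[[sid]] <- unname(v)
  }
  out
}
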