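# Fixed amplicon flanks around the cloned spacer; mimic a constant vector
# context so every read-1 carries the spacer verbatim at a fixed offset.
AMPLICON_5P <- "GTTTTAGAGCTAGAAATAGCAAGTTAAAAT"                      # 30 nt
AMPLICON_3P <- paste0("AAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTC",
                      "GGTGCTTTTTTTGAAGCTTGGGCCCGAACAAAAACTCATC")   # 81 nt

#' Emit paired FASTQ reads realizing a count column
#'
#' For each spacer, writes exactly `count` read pairs whose read 1 contains
#' the spacer verbatim between fixed amplicon flanks (read 2 is the reverse
#' complement of the amplicon's other end). Used to exercise the counting
#' stage end-to-end; there is no sequencing-error model, so
#' [count_spacers()] recovers the input counts exactly.
#'
#' @param counts Tibble with columns spacer_id and one count column.
#' @param library Spacer library tibble (spacer_id, sequence).
#' @param sample Name of the count column to realize.
#' @param dir Output directory.
#' @param read_length Read length (>= 50 so the spacer fits in read 1).
#' @param seed Seed controlling the read-order shuffle.
#' @return Invisibly, paths to the two FASTQ files.
#' @export
emit_fastq <- function(counts, library, sample, dir, read_length = 150L,
                       seed = 1L) {
  check_cols(counts, c("spacer_id", sample), "counts")
  check_cols(library, c("spacer_id", "sequence"), "library")
  if (read_length < nchar(AMPLICON_5P) + 20L) {
    abort(sprintf("read_length must be >= %d so read 1 spans the spacer",
                  nchar(AMPLICON_5P) + 20L))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- setNames(library$sequence, library$spacer_id)
  nrep <- setNames(as.integer(counts[[sample]]), counts$spacer_id)
  ids <- rep(counts$spacer_id, nrep[counts$spacer_id])

  f1 <- file.path(dir, paste0(sample, "_R1.fastq"))
  f2 <- file.path(dir, paste0(sample, "_R2.fastq"))
  if (length(ids) == 0) {
    file.create(f1); file.create(f2)
    return(invisible(c(f1, f2)))
  }
  set.seed(child_seed(seed, 7L))
  ids <- sample(ids)

  amplicon <- paste0(AMPLICON_5P, seqs[ids], AMPLICON_3P)
  r1 <- substr(amplicon, 1L, read_length)
  alen <- nchar(amplicon)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substr(amplicon, pmax(1L, alen - read_length + 1L), alen))))
  names <- sprintf("read%06d/%s", seq_along(ids), ids)

  write_fastq(f1, names, r1)
  write_fastq(f2, names, r2)
  invisible(c(f1, f2))
}

write_fastq <- function(path, names, seqs) {
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", names, "\n", seqs, "\n+\n", qual), path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that converts parse
#' failures into an error naming the offending file.
#'
#' @param path FASTQ path (plain or gzipped).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  if (!grepl("\\.gz$", path)) {
    n_lines <- length(readLines(path, warn = FALSE))
    if (n_lines %% 4 != 0) {
      abort(sprintf("malformed FASTQ '%s': truncated record near line %d",
                    path, n_lines))
    }
  }
  tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) abort(sprintf("malformed FASTQ '%s': %s",
                                      path, conditionMessage(e)))
  )
}
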