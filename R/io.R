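#' Read and write screen tables
#'
#' Plain-TSV round-trip helpers for the pipeline's tabular interfaces:
#' counts (first column spacer_id, one column per sample), sample sheets,
#' spacer libraries and gene-call tables. All readers return tibbles.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return `read_screen_table()` returns a tibble; writers return `path`
#'   invisibly.
#' @name screen_io
NULL

#' @rdname screen_io
#' @export
write_screen_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname screen_io
#' @export
read_screen_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a gene annotation as GFF3
#'
#' One `gene` feature per row, 1-based inclusive coordinates, `ID=` (and
#' optional `Parent`-free) attributes.
#'
#' @param annotation Tibble (gene_id, replicon, start, end, strand).
#' @param path Output path.
#' @param source Source column value.
#' @param type Feature type (default "gene").
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path, source = "poolscreen", type = "gene") {
  check_cols(annotation, c("gene_id", "replicon", "start", "end", "strand"),
             "annotation")
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$replicon, source, type,
                     as.integer(annotation$start), as.integer(annotation$end),
                     annotation$strand, annotation$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' @param path GFF3 path.
#' @param type Feature type to keep (default "gene").
#' @return Annotation tibble (gene_id, replicon, start, end, strand).
#' @export
read_gff3 <- function(path, type = "gene") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad) > 0) abort(sprintf("malformed GFF3 line %d", bad[1]))
  df <- tibble(
    replicon = map_chr(parts, 1),
    type = map_chr(parts, 3),
    start = as.integer(map_chr(parts, 4)),
    end = as.integer(map_chr(parts, 5)),
    strand = map_chr(parts, 7),
    attr = map_chr(parts, 9)
  ) |>
    filter(.data$type == !!type) |>
    mutate(gene_id = stringr::str_match(.data$attr, "ID=([^;]+)")[, 2]) |>
    select("gene_id", "replicon", "start", "end", "strand")
  df
}

#' Write a genome (or any sequence set) as FASTA
#'
#' @param seqs Named character vector or a [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (methods::is(seqs, "DNAString")) {
    seqs <- Biostrings::DNAStringSet(setNames(list(seqs), "chr"))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read predicted transcripts from TSV or BED6
#'
#' TSV columns: replicon, start, end, strand, source_label (1-based
#' inclusive). BED6 is converted from 0-based half-open at the boundary; the
#' BED name column becomes source_label.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"bed"`.
#' @return Transcript tibble (replicon, start, end, strand, source_label).
#' @export
read_transcripts <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tx <- read_screen_table(path)
    check_cols(tx, c("replicon", "start", "end", "strand"), "transcript table")
    if (!"source_label" %in% names(tx)) tx$source_label <- "unlabelled"
    return(tx)
  }
  bed <- readr::read_tsv(path, col_names = c("chrom", "chromStart", "chromEnd",
                                             "name", "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
  tibble(replicon = bed$chrom,
         start = bed$chromStart + 1L,   # 0-based half-open -> 1-based inclusive
         end = bed$chromEnd,
         strand = bed$strand,
         source_label = bed$name)
}
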