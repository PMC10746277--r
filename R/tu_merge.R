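#' Pseudo-distance between two transcripts
#'
#' `d = max(length(a), length(b)) - overlap(a, b)` in base pairs, with
#' overlap 0 for disjoint intervals. Coordinates are 1-based inclusive.
#' Symmetric, zero iff the intervals are identical; the triangle inequality
#' is not guaranteed (it is a pseudo-distance). Transcripts on different
#' replicons or strands are infinitely far apart and never merged.
#'
#' @param start1,end1,start2,end2 Interval coordinates (vectorized).
#' @return Numeric pseudo-distances.
#' @examples
#' pseudo_distance(100, 1100, 150, 1150) # 50
#' pseudo_distance(100, 1100, 1400, 2400) # 1001
#' @export
pseudo_distance <- function(start1, end1, start2, end2) {
  len1 <- end1 - start1 + 1
  len2 <- end2 - start2 + 1
  overlap <- pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
  pmax(len1, len2) - overlap
}

#' Single-linkage clusters of transcripts at a cophenetic cutoff
#'
#' Transcripts (already restricted to one replicon, strand and covered-gene
#' group) are clustered by single-linkage hierarchical clustering on the
#' pairwise pseudo-distance and the dendrogram is cut at cophenetic height
#' `cutoff`. For single linkage this is equivalent to the connected
#' components of the graph with an edge wherever `d <= cutoff` (the minimax
#' path property), which the test suite uses as an independent oracle.
#'
#' @param transcripts Tibble with start, end columns.
#' @param cutoff Cophenetic cutoff in bp (default 100).
#' @return Integer cluster ids, one per row.
#' @export
cluster_transcripts <- function(transcripts, cutoff = 100) {
  n <- nrow(transcripts)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- pseudo_distance(
      transcripts$start[i], transcripts$end[i],
      transcripts$start[j], transcripts$end[j])
  }
  hc <- hclust(as.dist(d), method = "single")
  unname(cutree(hc, h = cutoff))
}

#' Genes covered by transcripts
#'
#' A gene counts as covered when the transcript overlaps at least
#' `overlap_frac` of the gene's length on the same strand and replicon
#' (default 0.5; `overlap_frac = 0` admits any 1-bp overlap).
#'
#' @param transcripts Tibble (replicon, start, end, strand).
#' @param annotation Gene annotation tibble (gene_id, replicon, start, end,
#'   strand).
#' @param overlap_frac Minimum covered fraction of the gene length.
#' @return List of character vectors (gene ids, annotation order), one per
#'   transcript.
#' @export
covered_genes <- function(transcripts, annotation, overlap_frac = 0.5) {
  check_cols(transcripts, c("replicon", "start", "end", "strand"), "transcripts")
  check_cols(annotation, c("gene_id", "replicon", "start", "end", "strand"),
             "annotation")
  tg <- GenomicRanges::GRanges(transcripts$replicon,
                               IRanges::IRanges(transcripts$start, transcripts$end),
                               strand = transcripts$strand)
  gg <- GenomicRanges::GRanges(annotation$replicon,
                               IRanges::IRanges(annotation$start, annotation$end),
                               strand = annotation$strand)
  hits <- GenomicRanges::findOverlaps(tg, gg)
  ov <- GenomicRanges::pintersect(tg[S4Vectors::queryHits(hits)],
                                  gg[S4Vectors::subjectHits(hits)])
  frac <- GenomicRanges::width(ov) /
    GenomicRanges::width(gg[S4Vectors::subjectHits(hits)])
  keep <- if (overlap_frac <= 0) frac > 0 else frac >= overlap_frac
  out <- rep(list(character(0)), nrow(transcripts))
  if (any(keep)) {
    qh <- S4Vectors::queryHits(hits)[keep]
    sh <- S4Vectors::subjectHits(hits)[keep]
    # keep genes in annotation (genomic) order within each transcript
    for (i in unique(qh)) out[[i]] <- annotation$gene_id[sort(sh[qh == i])]
  }
  out
}

#' Merge predicted transcripts into consensus transcription units
#'
#' Transcript isoforms from one or more per-condition prediction tables are
#' pooled, grouped by the exact set of genes they cover (plus replicon and
#' strand), clustered within each group by single linkage on the
#' pseudo-distance with a cophenetic cutoff, and every cluster is collapsed
#' to one transcription unit spanning the most extreme member boundaries.
#' Grouping by covered-gene set precedes clustering, so isoforms covering
#' different gene sets stay in separate TUs even when they overlap.
#'
#' @param transcripts Tibble (replicon, start, end, strand, source_label) or
#'   a list of such tibbles (one per condition/growth phase).
#' @param annotation Gene annotation tibble.
#' @param cutoff Cophenetic cutoff in bp (default 100).
#' @param overlap_frac Covered-gene threshold, see [covered_genes()].
#' @param grouping `"equal"` (default) groups isoforms covering identical
#'   gene sets; `"containment"` additionally absorbs an isoform whose gene
#'   set is a subset of exactly one other observed set into that superset
#'   group.
#' @return TU tibble: tu_id, replicon, start, end, strand, n_transcripts,
#'   genes (comma-separated, genomic order), source_labels.
#' @export
merge_transcripts <- function(transcripts, annotation, cutoff = 100,
                              overlap_frac = 0.5,
                              grouping = c("equal", "containment")) {
  grouping <- match.arg(grouping)
  if (is.data.frame(transcripts)) transcripts <- list(transcripts)
  tx <- bind_rows(transcripts)
  if (!"source_label" %in% names(tx)) tx$source_label <- "unlabelled"
  check_cols(tx, c("replicon", "start", "end", "strand"), "transcripts")
  if (length(setdiff(unique(tx$replicon), unique(annotation$replicon))) > 0) {
    abort("transcript replicon(s) absent from annotation")
  }

  genes <- covered_genes(tx, annotation, overlap_frac)
  key <- map_chr(genes, function(g) paste(g, collapse = ","))

  if (grouping == "containment") {
    sets <- unique(key)
    setlist <- strsplit(sets, ",", fixed = TRUE)
    for (i in seq_along(sets)) {
      if (sets[i] == "") next
      sup <- which(map_lgl(setlist, function(s)
        all(setlist[[i]] %in% s) && length(s) > length(setlist[[i]])))
      if (length(sup) == 1) key[key == sets[i]] <- sets[sup]
    }
  }

  tx$.group <- paste(tx$replicon, tx$strand, key, sep = "|")
  tx$.genes <- key

  out <- list()
  for (grp in unique(tx$.group)) {
    sub <- tx[tx$.group == grp, ]
    cl <- cluster_transcripts(sub, cutoff)
    for (k in unique(cl)) {
      m <- sub[cl == k, ]
      out[[length(out) + 1]] <- tibble(
        replicon = m$replicon[1],
        start = min(m$start), end = max(m$end),
        strand = m$strand[1],
        n_transcripts = nrow(m),
        genes = m$.genes[1],
        source_labels = paste(sort(unique(m$source_label)), collapse = ",")
      )
    }
  }
  bind_rows(out) |>
    arrange(.data$replicon, .data$start, .data$end, .data$strand) |>
    mutate(tu_id = sprintf("TU%04d", row_number())) |>
    relocate("tu_id")
}

#' Expand a merged TU table into a gene-to-TU assignment
#'
#' Convenience for [annotate_tu()]: one row per (tu_id, gene_id), keeping
#' gene order within each TU. TUs covering no gene are dropped; if a gene
#' belongs to several TUs the table cannot serve as a partition and
#' [annotate_tu()] will refuse it.
#'
#' @param tu_table From [merge_transcripts()].
#' @return Tibble (tu_id, gene_id).
#' @export
tu_gene_map <- function(tu_table) {
  check_cols(tu_table, c("tu_id", "genes"), "TU table")
  tu_table |>
    filter(.data$genes != "") |>
    mutate(gene_id = strsplit(.data$genes, ",", fixed = TRUE)) |>
    select("tu_id", "gene_id") |>
    tidyr::unnest("gene_id")
}
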