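# Independent oracles used across tests. These deliberately avoid the code
# paths they check: clustering is verified against threshold-graph connected
# components (union-find), counting against a naive substring scan.

# connected components of the graph with edges where d <= cutoff
components_oracle <- function(d, cutoff) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && d[i, j] <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# pairwise pseudo-distance matrix computed independently (scalar arithmetic)
pd_matrix_oracle <- function(tx) {
  n <- nrow(tx)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      li <- tx$end[i] - tx$start[i] + 1
      lj <- tx$end[j] - tx$start[j] + 1
      ov <- max(0, min(tx$end[i], tx$end[j]) - max(tx$start[i], tx$start[j]) + 1)
      d[i, j] <- max(li, lj) - ov
    }
  }
  d
}

# brute-force spacer counting: per read pair, scan every spacer with grepl
# on both mates and both strands; count pairs matching exactly one spacer
revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), character(1)))
}

brute_force_counts <- function(r1, r2, spacers) {
  n <- length(r1)
  counts <- setNames(integer(length(spacers)), names(spacers))
  n_ambiguous <- 0L; n_no_match <- 0L
  r1rc <- revcomp_chr(r1)
  r2rc <- if (!is.null(r2)) revcomp_chr(r2) else NULL
  for (i in seq_len(n)) {
    hits <- vapply(spacers, function(sp) {
      grepl(sp, r1[i], fixed = TRUE) || grepl(sp, r1rc[i], fixed = TRUE) ||
        (!is.null(r2) && (grepl(sp, r2[i], fixed = TRUE) ||
                            grepl(sp, r2rc[i], fixed = TRUE)))
    }, logical(1))
    k <- sum(hits)
    if (k == 1) counts[which(hits)] <- counts[which(hits)] + 1L
    else if (k == 0) n_no_match <- n_no_match + 1L
    else n_ambiguous <- n_ambiguous + 1L
  }
  list(counts = counts, n_no_match = n_no_match, n_ambiguous = n_ambiguous)
}

# random stranded transcript tables for clustering property tests
random_transcripts <- function(n, seed) {
  set.seed(seed)
  start <- sample(1:5000, n, replace = TRUE)
  len <- sample(50:1500, n, replace = TRUE)
  tibble::tibble(replicon = "chr", start = start, end = start + len - 1,
                 strand = "+", source_label = "sim")
}

# minimal two-condition screen pieces built directly (no genome needed)
toy_library <- function(n_genes = 4, guides = 4, n_controls = 60, seed = 1,
                        efficiency = NULL) {
  set.seed(seed)
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  n_t <- n_genes * guides
  eff <- if (is.null(efficiency)) stats::rbeta(n_t, 8, 2) else
    rep_len(efficiency, n_t)
  tibble::tibble(
    spacer_id = c(sprintf("%s_sp%d", rep(gene_ids, each = guides),
                          rep(seq_len(guides), n_genes)),
                  sprintf("c%03d", seq_len(n_controls))),
    sequence = replicate(n_t + n_controls,
                         paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                               collapse = "")),
    gene_id = c(rep(gene_ids, each = guides), rep("CONTROL", n_controls)),
    offset_frac = c(rep(seq(0, 1, length.out = guides), n_genes),
                    rep(NA_real_, n_controls)),
    efficiency = c(eff, rep(0, n_controls))
  )
}
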