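#' Simulation configuration for a synthetic CRISPRi screen
#'
#' Bundles every tunable of the synthetic-screen generator. Defaults emulate
#' the design of a genome-wide bacterial CRISPRi essentiality screen: four
#' strong-knockdown guides per gene, 1,000 non-targeting control spacers, and
#' roughly ten population doublings of selection between the initial (Ti) and
#' final (Tf) sampling points.
#'
#' The per-gene selection coefficient `s` used with this config is defined
#' directly on the log2-abundance scale per population doubling, so a spacer
#' with efficiency `e` targeting a gene with coefficient `s` has true log2
#' fold change `G * s * e` after `G` doublings (before library-size
#' renormalization).
#'
#' @param n_genes Number of genes in the synthetic genome.
#' @param genes_per_tu_dist Named numeric vector of probabilities over TU
#'   sizes, e.g. `c("1" = .5, "2" = .3, "3" = .15, "4" = .05)`.
#' @param guides_per_gene Targeting spacers designed per gene (>= 1).
#' @param n_controls Non-targeting control spacers.
#' @param doublings Population doublings of selection `G` (>= 0).
#' @param depth Mean reads per spacer at the initial timepoint (> 0).
#' @param phi Negative-binomial dispersion; counts have variance
#'   `mu + phi * mu^2`. `phi = 0` gives Poisson counts.
#' @param efficiency_alpha,efficiency_beta Beta parameters of the
#'   guide-efficiency distribution on \[0, 1\].
#' @param gene_length,intra_tu_gap,inter_tu_gap Genome geometry in bp.
#' @param polar Simulate polar/reverse-polar effects within TUs?
#' @param reverse_polar_5p,reverse_polar_3p Attenuation of the reverse-polar
#'   (upstream-gene) effect for a spacer at the 5' (offset 0) and 3'
#'   (offset 1) end of its target gene; linearly interpolated in between.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100,
                       genes_per_tu_dist = c("1" = 0.5, "2" = 0.3,
                                             "3" = 0.15, "4" = 0.05),
                       guides_per_gene = 4L,
                       n_controls = 1000L,
                       doublings = 10,
                       depth = 500,
                       phi = 0.05,
                       efficiency_alpha = 8,
                       efficiency_beta = 2,
                       gene_length = 900L,
                       intra_tu_gap = 20L,
                       inter_tu_gap = 200L,
                       polar = FALSE,
                       reverse_polar_5p = 0.49,
                       reverse_polar_3p = 0.17,
                       seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_controls >= 0,
            doublings >= 0, depth > 0, phi >= 0,
            reverse_polar_5p >= 0, reverse_polar_5p <= 1,
            reverse_polar_3p >= 0, reverse_polar_3p <= 1,
            all(genes_per_tu_dist >= 0), sum(genes_per_tu_dist) > 0,
            !is.null(names(genes_per_tu_dist)))
  structure(list(
    n_genes = as.integer(n_genes),
    genes_per_tu_dist = genes_per_tu_dist / sum(genes_per_tu_dist),
    guides_per_gene = as.integer(guides_per_gene),
    n_controls = as.integer(n_controls),
    doublings = doublings,
    depth = depth,
    phi = phi,
    efficiency_alpha = efficiency_alpha,
    efficiency_beta = efficiency_beta,
    gene_length = as.integer(gene_length),
    intra_tu_gap = as.integer(intra_tu_gap),
    inter_tu_gap = as.integer(inter_tu_gap),
    polar = isTRUE(polar),
    reverse_polar_5p = reverse_polar_5p,
    reverse_polar_3p = reverse_polar_3p,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a toy bacterial genome with a known TU structure
#'
#' Lays out `n_genes` non-overlapping, stranded genes along one replicon,
#' grouped into contiguous same-strand transcription units whose sizes are
#' drawn from `genes_per_tu_dist`. The sequence is random but checked to
#' carry at least `guides_per_gene` PAM-adjacent 20-mers per gene so that
#' [build_library()] is always feasible on the result.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a [Biostrings::DNAString]), `annotation`
#'   (tibble: gene_id, replicon, start, end, strand — 1-based inclusive) and
#'   `tu_truth` (tibble: tu_id, gene_id, tu_position).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))

  # draw TU sizes until all genes are placed; truncate the last TU
  sizes <- integer(0)
  tu_opts <- as.integer(names(config$genes_per_tu_dist))
  while (sum(sizes) < config$n_genes) {
    pick <- sample.int(length(tu_opts), 1, prob = config$genes_per_tu_dist)
    sizes <- c(sizes, tu_opts[pick])
  }
  excess <- sum(sizes) - config$n_genes
  sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes <- sizes[sizes > 0]

  gl <- config$gene_length
  ann <- vector("list", length(sizes))
  pos <- config$inter_tu_gap + 1L
  gi <- 0L
  for (t in seq_along(sizes)) {
    strand <- sample(c("+", "-"), 1)
    rows <- vector("list", sizes[t])
    for (k in seq_len(sizes[t])) {
      gi <- gi + 1L
      rows[[k]] <- tibble(
        gene_id = sprintf("gene%04d", gi),
        replicon = "chr",
        start = pos, end = pos + gl - 1L,
        strand = strand,
        tu_id = sprintf("TU%03d", t),
        tu_position = k
      )
      pos <- pos + gl + config$intra_tu_gap
    }
    pos <- pos - config$intra_tu_gap + config$inter_tu_gap
    ann[[t]] <- bind_rows(rows)
  }
  annotation <- bind_rows(ann)
  genome_len <- max(annotation$end) + config$inter_tu_gap

  base <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  genome <- Biostrings::DNAString(paste(base, collapse = ""))

  # feasibility: every gene must expose enough PAM-adjacent spacer sites
  for (i in seq_len(nrow(annotation))) {
    sites <- pam_sites(genome, annotation$start[i], annotation$end[i],
                       annotation$strand[i])
    if (length(sites) < config$guides_per_gene) {
      abort(sprintf(
        "infeasible config: %s has only %d PAM-adjacent sites (< %d); increase gene_length",
        annotation$gene_id[i], length(sites), config$guides_per_gene))
    }
  }

  list(
    genome = genome,
    annotation = select(annotation, "gene_id", "replicon", "start", "end", "strand"),
    tu_truth = select(annotation, "tu_id", "gene_id", "tu_position")
  )
}

# Start positions (on the gene's strand, relative to the genome '+' sense)
# of 20-mer spacers immediately 5' of an NGG PAM, fully inside the gene body.
# Returns genomic start coordinates of the 20-mer on the '+' strand.
pam_sites <- function(genome, start, end, strand) {
  seq <- Biostrings::subseq(genome, start, end)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  s <- as.character(seq)
  gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
  if (gg[1] == -1) return(integer(0))
  # PAM is NGG at positions (p-1, p, p+1); spacer occupies [p-21, p-2]
  p <- gg[gg - 21 >= 1 & gg + 1 <= nchar(s)]
  p - 21L
}

#' Design a spacer library for a simulated genome
#'
#' Picks `guides_per_gene` unique PAM-adjacent 20-mer spacers inside each
#' gene body (evenly spread along the gene) and adds `n_controls`
#' non-targeting spacers: random 20-mers verified to be absent from both
#' strands of the genome. Guide efficiencies are drawn from
#' `Beta(efficiency_alpha, efficiency_beta)`; controls have efficiency 0.
#'
#' @param genome,annotation From [simulate_genome()].
#' @param config The same [sim_config()].
#' @return Tibble: spacer_id, sequence (20 nt), gene_id (`"CONTROL"` for
#'   non-targeting spacers), offset_frac (position within gene on \[0, 1\]),
#'   efficiency.
#' @export
build_library <- function(genome, annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 2L))
  gpg <- config$guides_per_gene
  used <- character(0)

  rows <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    rel <- pam_sites(genome, g$start, g$end, g$strand)  # strand-local 20-mer starts
    if (length(rel) < gpg) {
      abort(sprintf("gene %s: fewer PAM sites than guides_per_gene", g$gene_id))
    }
    glen <- g$end - g$start + 1L
    # spread picks across the gene, skipping sequences already used
    want <- unique(round(quantile(seq_along(rel), probs = seq(0, 1, length.out = gpg))))
    picked <- integer(0)
    cand <- c(want, setdiff(seq_along(rel), want))
    seqs <- character(0)
    for (j in cand) {
      pos <- rel[j]
      if (g$strand == "+") {
        sp <- as.character(Biostrings::subseq(genome, g$start + pos - 1L,
                                              g$start + pos + 18L))
      } else {
        sp <- as.character(Biostrings::reverseComplement(
          Biostrings::subseq(genome, g$end - pos - 18L, g$end - pos + 1L)))
      }
      if (!(sp %in% used) && !(sp %in% seqs)) {
        picked <- c(picked, j)
        seqs <- c(seqs, sp)
      }
      if (length(picked) == gpg) break
    }
    if (length(picked) < gpg) {
      abort(sprintf("gene %s: could not find %d unique spacer sequences",
                    g$gene_id, gpg))
    }
    used <- c(used, seqs)
    rows[[i]] <- tibble(
      spacer_id = sprintf("%s_sp%d", g$gene_id, seq_len(gpg)),
      sequence = seqs,
      gene_id = g$gene_id,
      offset_frac = (rel[picked] - 1) / pmax(glen - 20L, 1L)
    )
  }
  lib <- bind_rows(rows)
  lib$efficiency <- rbeta(nrow(lib), config$efficiency_alpha, config$efficiency_beta)

  # non-targeting controls: random 20-mers absent from the genome (either strand)
  if (config$n_controls > 0) {
    gplus <- as.character(genome)
    gminus <- as.character(Biostrings::reverseComplement(genome))
    ctrl <- character(0)
    tries <- 0L
    while (length(ctrl) < config$n_controls) {
      tries <- tries + 1L
      if (tries > 1e6) abort("could not find non-genomic control sequences after 1e6 retries")
      sp <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
      if (!grepl(sp, gplus, fixed = TRUE) && !grepl(sp, gminus, fixed = TRUE) &&
          !(sp %in% used) && !(sp %in% ctrl)) {
        ctrl <- c(ctrl, sp)
      }
    }
    lib <- bind_rows(lib, tibble(
      spacer_id = sprintf("ctrl%04d", seq_len(config$n_controls)),
      sequence = ctrl,
      gene_id = "CONTROL",
      offset_frac = NA_real_,
      efficiency = 0
    ))
  }
  lib
}

#' Standard sample sheet for a two-condition screen
#'
#' @param conditions Condition labels.
#' @param timepoints Timepoint labels (initial, final).
#' @param replicates Replicates per condition x timepoint.
#' @return Tibble: sample_id, condition, timepoint, replicate.
#' @export
make_sample_sheet <- function(conditions = c("aerobic", "anaerobic"),
                              timepoints = c("Ti", "Tf"),
                              replicates = 2L) {
  tidyr::expand_grid(condition = conditions, timepoint = timepoints,
                     replicate = seq_len(replicates)) |>
    mutate(sample_id = paste(.data$condition, .data$timepoint,
                             paste0("rep", .data$replicate), sep = "_")) |>
    relocate("sample_id")
}

#' Simulate screen counts with known per-gene fitness effects
#'
#' Initial-timepoint counts are negative binomial with mean `depth` and
#' dispersion `phi`. After `G = doublings` of selection, the expected
#' relative abundance of spacer `i` targeting gene `g` is multiplied by
#' `2^(G * s_g * e_i)`, renormalized across the library (fixed sequencing
#' depth), and NB-sampled again. With `polar = TRUE` (and `tu_truth`
#' supplied) a spacer additionally carries the full effect of genes
#' downstream of its target in the same TU, and the attenuated
#' (reverse-polar) effect of upstream genes.
#'
#' @param library Spacer library tibble from [build_library()] (or any tibble
#'   with spacer_id, gene_id, efficiency, offset_frac).
#' @param effects Tibble: gene_id, s_aerobic, s_anaerobic (log2 per doubling;
#'   <= 0 deleterious). Every targeted gene must appear.
#' @param config A [sim_config()].
#' @param sample_sheet Tibble from [make_sample_sheet()].
#' @param tu_truth Optional TU truth tibble (tu_id, gene_id, tu_position);
#'   required when `config$polar` is `TRUE`.
#' @return Counts tibble: spacer_id plus one integer column per sample_id.
#' @export
simulate_counts <- function(library, effects, config, sample_sheet,
                            tu_truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_cols(library, c("spacer_id", "gene_id", "efficiency"), "library")
  check_cols(effects, c("gene_id", "s_aerobic", "s_anaerobic"), "effects")
  check_cols(sample_sheet, c("sample_id", "condition", "timepoint", "replicate"),
             "sample sheet")
  targeted <- setdiff(unique(library$gene_id), "CONTROL")
  missing <- setdiff(targeted, effects$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("missing TrueEffect for targeted gene(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (config$polar && is.null(tu_truth)) {
    abort("polar simulation requires `tu_truth`")
  }

  set.seed(child_seed(config$seed, 3L))
  n <- nrow(library)
  counts <- tibble(spacer_id = library$spacer_id)

  exponent <- function(condition) {
    s <- setNames(effects[[paste0("s_", condition)]], effects$gene_id)
    base <- ifelse(library$gene_id == "CONTROL", 0, s[library$gene_id])
    if (!config$polar) return(config$doublings * base * library$efficiency)
    tu <- tu_truth
    s_tot <- base
    att <- config$reverse_polar_5p +
      (config$reverse_polar_3p - config$reverse_polar_5p) *
      ifelse(is.na(library$offset_frac), 0, library$offset_frac)
    for (i in seq_len(n)) {
      g <- library$gene_id[i]
      if (g == "CONTROL") next
      row <- tu[tu$gene_id == g, ]
      if (nrow(row) == 0) next
      members <- tu[tu$tu_id == row$tu_id[1], ]
      down <- members$gene_id[members$tu_position > row$tu_position[1]]
      up <- members$gene_id[members$tu_position < row$tu_position[1]]
      s_tot[i] <- s_tot[i] + sum(s[down]) + att[i] * sum(s[up])
    }
    config$doublings * s_tot * library$efficiency
  }

  rcounts <- function(mu) {
    if (config$phi == 0) stats::rpois(length(mu), mu) else
      rnbinom(length(mu), mu = mu, size = 1 / config$phi)
  }

  for (cond in unique(sample_sheet$condition)) {
    ex <- exponent(cond)
    w <- 2^ex
    mu_tf <- config$depth * n * (w / sum(w))
    for (j in which(sample_sheet$condition == cond)) {
      sid <- sample_sheet$sample_id[j]
      if (sample_sheet$timepoint[j] == "Ti") {
        counts[[sid]] <- rcounts(rep(config$depth, n))
      } else {
        counts[[sid]] <- rcounts(mu_tf)
      }
    }
  }
  counts[c("spacer_id", sample_sheet$sample_id)]
}

#' Build a TrueEffect table from class labels
#'
#' Assigns per-doubling selection coefficients consistent with a target class
#' label under the convention true LFC = `G * s * e`.
#'
#' @param gene_ids Character vector of genes.
#' @param classes Character vector (same length) in `neutral`,
#'   `generally_essential`, `aerobic_essential`, `anaerobic_essential`,
#'   `fitness_defect`.
#' @param doublings Selection doublings `G` used to scale `s` so that
#'   `G * s` equals `lfc_essential` / `lfc_defect` for affected conditions.
#' @param lfc_essential,lfc_defect Target true LFC at efficiency 1.
#' @return Tibble: gene_id, s_aerobic, s_anaerobic, class_label.
#' @export
true_effects <- function(gene_ids, classes, doublings = 10,
                         lfc_essential = -6, lfc_defect = -1.5) {
  stopifnot(length(gene_ids) == length(classes))
  s_ess <- lfc_essential / doublings
  s_def <- lfc_defect / doublings
  tibble(gene_id = gene_ids, class_label = classes) |>
    mutate(
      s_aerobic = case_when(
        classes == "generally_essential" ~ s_ess,
        classes == "aerobic_essential" ~ s_ess,
        classes == "fitness_defect" ~ s_def,
        .default = 0
      ),
      s_anaerobic = case_when(
        classes == "generally_essential" ~ s_ess,
        classes == "anaerobic_essential" ~ s_ess,
        classes == "fitness_defect" ~ s_def,
        .default = 0
      )
    ) |>
    select("gene_id", "s_aerobic", "s_anaerobic", "class_label")
}
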