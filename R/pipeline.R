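#' Run the full screen analysis
#'
#' Orchestrates the stages end to end: optional FASTQ counting, size-factor
#' normalization, trended dispersion fitting, per-spacer tests for each
#' condition, gene-level aggregation and classification, TU annotation and
#' the screen summary. When the simulator's ground-truth effect table is
#' supplied, recovery metrics (per-class sensitivity, false-essential rate)
#' are computed as well.
#'
#' @param counts Counts tibble (spacer_id + sample columns), or `NULL` to
#'   count from FASTQ.
#' @param sample_sheet Sample sheet tibble (sample_id, condition, timepoint,
#'   replicate).
#' @param library Spacer library tibble.
#' @param fastq Optional named list (by sample_id) of `c(r1, r2)` FASTQ
#'   paths, used when `counts` is `NULL`.
#' @param tu_table Optional TU partition (tu_id, gene_id) for TU-aware
#'   reporting.
#' @param truth Optional ground-truth effects tibble with class_label, for
#'   recovery metrics.
#' @param conditions The two condition labels.
#' @param essential_lfc,defect_lfc,alpha,sensitivity_lfc,pseudocount
#'   Analysis thresholds; see [call_genes()] and [test_spacers()].
#' @param n_protein_coding Genome size used for the summary percentage.
#' @return An object of class `crispri_screen`: list with spacer_stats,
#'   gene_calls, summary, size_factors, trend, params (+ recovery when truth
#'   given). Supports [tidy()], [glance()], `autoplot()` and `print()`.
#' @export
run_screen <- function(counts = NULL, sample_sheet, library, fastq = NULL,
                       tu_table = NULL, truth = NULL,
                       conditions = c("aerobic", "anaerobic"),
                       essential_lfc = -3, defect_lfc = -1, alpha = 0.05,
                       sensitivity_lfc = 1, pseudocount = 0.5,
                       n_protein_coding = NULL) {
  if (is.null(counts)) {
    if (is.null(fastq)) abort("run_screen: supply either counts or fastq")
    cols <- lapply(fastq, function(fp) {
      x <- count_spacers(fp[1], if (length(fp) > 1) fp[2] else NULL, library)
      names(x)[2] <- "count"
      x
    })
    counts <- merge_count_columns(cols, sample_sheet)
  }

  sf <- normalize_counts(counts, library)
  trend <- fit_dispersion(counts, sf, sample_sheet)
  spacer_stats <- bind_rows(lapply(conditions, function(cond) {
    test_spacers(counts, sf, trend, sample_sheet, cond,
                 pseudocount = pseudocount, library = library)
  }))

  gene_calls <- call_genes(spacer_stats, conditions = conditions,
                           essential_lfc = essential_lfc,
                           defect_lfc = defect_lfc, alpha = alpha,
                           sensitivity_lfc = sensitivity_lfc)
  if (!is.null(tu_table)) gene_calls <- annotate_tu(gene_calls, tu_table)

  npc <- n_protein_coding %||% nrow(gene_calls)
  summary <- summarize_screen(gene_calls, npc)

  out <- structure(list(
    spacer_stats = spacer_stats,
    gene_calls = gene_calls,
    summary = summary,
    size_factors = sf,
    trend = trend,
    params = list(conditions = conditions, essential_lfc = essential_lfc,
                  defect_lfc = defect_lfc, alpha = alpha,
                  sensitivity_lfc = sensitivity_lfc,
                  pseudocount = pseudocount)
  ), class = "crispri_screen")

  if (!is.null(truth)) out$recovery <- recovery_metrics(gene_calls, truth)
  out
}

#' Compare gene calls against simulator ground truth
#'
#' Maps simulator class labels onto call labels (`aerobic_essential` ->
#' `conditionally_essential_aerobic`, `fitness_defect` -> any
#' fitness-defect call) and reports per-class sensitivity plus the
#' false-essential rate among truly neutral genes.
#'
#' @param gene_calls Tibble from [call_genes()].
#' @param truth Tibble (gene_id, class_label) from [true_effects()].
#' @return List: `per_class` tibble, `essential_sensitivity`,
#'   `false_essential_rate`, `mean_abs_lfc_error` placeholder `NA` unless
#'   truth carries expected LFC columns.
#' @export
recovery_metrics <- function(gene_calls, truth) {
  check_cols(truth, c("gene_id", "class_label"), "truth")
  map_label <- c(generally_essential = "generally_essential",
                 aerobic_essential = "conditionally_essential_aerobic",
                 anaerobic_essential = "conditionally_essential_anaerobic")
  joined <- truth |>
    rename(true_class = "class_label") |>
    inner_join(select(gene_calls, "gene_id", called = "class_label"),
               by = "gene_id")

  ess_truth <- joined |> filter(.data$true_class %in% names(map_label))
  per_class <- ess_truth |>
    group_by(.data$true_class) |>
    summarise(n = n(),
              n_correct = sum(.data$called ==
                                map_label[first(.data$true_class)]),
              sensitivity = .data$n_correct / n(), .groups = "drop")

  essential_calls <- c("generally_essential",
                       "conditionally_essential_aerobic",
                       "conditionally_essential_anaerobic")
  neutral <- joined |> filter(.data$true_class == "neutral")
  list(
    per_class = per_class,
    essential_sensitivity = if (nrow(ess_truth) > 0)
      sum(per_class$n_correct) / sum(per_class$n) else NA_real_,
    false_essential_rate = if (nrow(neutral) > 0)
      mean(neutral$called %in% essential_calls) else NA_real_
  )
}

#' Build a self-contained miniature dataset
#'
#' Presets:
#' \describe{
#'   \item{tiny}{20 genes, 50 controls, genome + library + FASTQ-capable
#'     counts; end-to-end demo.}
#'   \item{null}{all-neutral counts-only screen (10,000 spacers) for type-I
#'     calibration.}
#'   \item{recovery}{200-gene mixed-effect screen (20 generally essential,
#'     10 aerobic-essential, 10 anaerobic-essential at true LFC -6; 20
#'     fitness-defect at -1.5; 140 neutral) with 4 guides/gene, Beta(8,2)
#'     efficiencies, depth 500, 2 replicates.}
#'   \item{tu_demo}{toy annotation plus per-condition transcript tables for
#'     TU merging.}
#'   \item{conservation_demo}{synthetic orthogroup table, 7 comparators,
#'     with essential-gene catalogs.}
#' }
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, every table is written as TSV
#'   (plus FASTA/GFF3 where applicable) and paths are attached.
#' @return A named list of tibbles/objects for the preset.
#' @export
make_fixture <- function(preset = c("tiny", "null", "recovery", "tu_demo",
                                    "conservation_demo"),
                         seed = 1L, dir = NULL) {
  preset <- tryCatch(match.arg(preset), error = function(e) {
    abort(paste("unknown preset; available:",
                "tiny, null, recovery, tu_demo, conservation_demo"))
  })
  fx <- switch(preset,
    tiny = fixture_screen(n_genes = 20, n_controls = 50, seed = seed,
                          with_genome = TRUE,
                          classes = function(ids) {
                            cl <- rep("neutral", length(ids))
                            cl[1:3] <- "generally_essential"
                            cl[4] <- "aerobic_essential"
                            cl[5] <- "anaerobic_essential"
                            cl
                          }),
    null = fixture_screen(n_genes = 2250, n_controls = 1000, seed = seed,
                          with_genome = FALSE,
                          classes = function(ids) rep("neutral", length(ids))),
    recovery = fixture_screen(n_genes = 200, n_controls = 1000, seed = seed,
                              with_genome = FALSE,
                              classes = function(ids) {
                                cl <- rep("neutral", length(ids))
                                cl[1:20] <- "generally_essential"
                                cl[21:30] <- "aerobic_essential"
                                cl[31:40] <- "anaerobic_essential"
                                cl[41:60] <- "fitness_defect"
                                cl
                              }),
    tu_demo = fixture_tu_demo(seed),
    conservation_demo = fixture_conservation_demo(seed)
  )
  if (!is.null(dir)) fx <- write_fixture(fx, dir)
  fx
}

# counts-level screen fixture; with_genome also builds sequence + FASTQ-able
# library, otherwise spacers get arbitrary unique sequences (counts-only use)
fixture_screen <- function(n_genes, n_controls, seed, classes,
                           with_genome = FALSE) {
  config <- sim_config(n_genes = n_genes, n_controls = n_controls, seed = seed)
  sheet <- make_sample_sheet()
  if (with_genome) {
    gen <- simulate_genome(config)
    lib <- build_library(gen$genome, gen$annotation, config)
    annotation <- gen$annotation
    tu_truth <- gen$tu_truth
    genome <- gen$genome
  } else {
    set.seed(child_seed(seed, 11L))
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    gpg <- config$guides_per_gene
    lib <- tibble(
      spacer_id = c(sprintf("%s_sp%d", rep(gene_ids, each = gpg),
                            rep(seq_len(gpg), n_genes)),
                    sprintf("ctrl%04d", seq_len(n_controls))),
      sequence = random_unique_20mers(n_genes * gpg + n_controls),
      gene_id = c(rep(gene_ids, each = gpg), rep("CONTROL", n_controls)),
      offset_frac = c(rep(seq(0, 1, length.out = gpg), n_genes),
                      rep(NA_real_, n_controls)),
      efficiency = c(rbeta(n_genes * gpg, config$efficiency_alpha,
                           config$efficiency_beta), rep(0, n_controls))
    )
    annotation <- NULL; tu_truth <- NULL; genome <- NULL
  }
  gene_ids <- setdiff(unique(lib$gene_id), "CONTROL")
  effects <- true_effects(gene_ids, classes(gene_ids),
                          doublings = config$doublings)
  counts <- simulate_counts(lib, effects, config, sheet, tu_truth)
  out <- list(config = config, library = lib, effects = effects,
              sample_sheet = sheet, counts = counts)
  if (with_genome) {
    out$genome <- genome
    out$annotation <- annotation
    out$tu_truth <- tu_truth
  }
  out
}

random_unique_20mers <- function(n) {
  seqs <- character(0)
  while (length(seqs) < n) {
    more <- vapply(seq_len(n - length(seqs)), function(i) {
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    }, character(1))
    seqs <- unique(c(seqs, more))
  }
  seqs
}

fixture_tu_demo <- function(seed) {
  set.seed(child_seed(seed, 21L))
  annotation <- tibble(
    gene_id = sprintf("g%d", 1:6),
    replicon = "chr",
    start = c(101L, 1201L, 2301L, 5001L, 6101L, 9001L),
    end = c(1100L, 2200L, 3300L, 6000L, 7100L, 10000L),
    strand = c("+", "+", "+", "-", "-", "+")
  )
  conds <- c("aerobic_exp", "aerobic_stat", "anaerobic_exp", "anaerobic_stat")
  tx <- bind_rows(lapply(conds, function(cl) {
    jitter5 <- sample(-30:30, 1)
    tibble(
      replicon = "chr",
      start = c(81L + jitter5, 4951L, 8981L),
      end = c(3340L, 7120L, 10020L),
      strand = c("+", "-", "+"),
      source_label = cl
    )
  }))
  list(annotation = annotation, transcripts = tx)
}

fixture_conservation_demo <- function(seed) {
  set.seed(child_seed(seed, 31L))
  comparators <- sprintf("alpha%d", 1:7)
  focal <- "focal"
  n_core <- 120; n_core_focal <- 95; n_focal_only <- 20
  rows <- list()
  for (i in seq_len(n_core)) {
    og <- sprintf("OG%04d", i)
    for (sp in comparators) {
      rows[[length(rows) + 1]] <- tibble(orthogroup_id = og, species = sp,
                                         gene_id = sprintf("%s_g%04d", sp, i))
    }
    if (i <= n_core_focal) {
      rows[[length(rows) + 1]] <- tibble(orthogroup_id = og, species = focal,
                                         gene_id = sprintf("focal_g%04d", i))
    }
  }
  for (i in seq_len(n_focal_only)) {
    og <- sprintf("OGU%03d", i)
    rows[[length(rows) + 1]] <- tibble(orthogroup_id = og, species = focal,
                                       gene_id = sprintf("focal_u%03d", i))
  }
  og <- bind_rows(rows)
  # essential catalogs: comparator genes in the first 60 core groups
  catalog <- og |>
    filter(.data$species %in% comparators,
           .data$orthogroup_id %in% sprintf("OG%04d", 1:60))
  focal_essential <- sprintf("focal_g%04d", 1:80)
  list(orthogroups = og,
       catalog = select(catalog, "species", "gene_id"),
       focal = focal, comparators = comparators,
       focal_essential = focal_essential,
       unassigned = sprintf("focal_un%02d", 1:5))
}

write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(fx)) {
    obj <- fx[[nm]]
    if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      write_screen_table(obj, p)
      paths[[nm]] <- p
    } else if (methods::is(obj, "DNAString")) {
      p <- file.path(dir, paste0(nm, ".fasta"))
      write_fasta(obj, p)
      paths[[nm]] <- p
    }
  }
  if (!is.null(fx$annotation)) {
    paths$annotation_gff3 <- write_gff3(fx$annotation,
                                        file.path(dir, "annotation.gff3"))
  }
  fx$paths <- paths
  fx
}
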