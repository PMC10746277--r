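#' Stouffer combination of per-spacer FDR values
#'
#' Combines the guides of one gene into a single significance value:
#' `z_i = qnorm(1 - q_i)`, `Z = sum(z_i) / sqrt(k)`, combined
#' `p = 1 - pnorm(Z)`. Inputs are clamped to `[1e-15, 1 - 1e-15]` before the
#' quantile transform. The combination is one-sided in the "small q =
#' significant" direction and directionless with respect to the sign of the
#' fold change; the median-LFC threshold applied alongside it supplies the
#' directionality.
#'
#' @param q Numeric vector of FDR-adjusted per-spacer values in \[0, 1\].
#' @return Combined p-value.
#' @examples
#' stouffer_combine(0.05)            # 0.05 (k = 1 identity)
#' stouffer_combine(c(0.5, 0.5, 0.5)) # 0.5
#' @export
stouffer_combine <- function(q) {
  if (length(q) == 0) abort("stouffer_combine: empty input")
  if (any(q < 0 | q > 1, na.rm = TRUE)) abort("q values must lie in [0, 1]")
  q <- clamp(q, 1e-15, 1 - 1e-15)
  z <- qnorm(1 - q)
  pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
}

#' Gene-level median log2 fold change
#'
#' The gene score is the exact median of its spacers' LFCs (mean of the two
#' middle values for even n), which neutralizes single ineffective or
#' off-target guides.
#'
#' @param lfc Numeric vector of spacer LFCs (>= 1 value).
#' @return Median LFC.
#' @export
gene_median_lfc <- function(lfc) {
  if (length(lfc) == 0) return(NA_real_)
  median(lfc)
}

#' Aggregate spacer statistics to gene-level calls for two conditions
#'
#' Computes per-gene, per-condition median LFC, Stouffer-combined p (over the
#' spacers' q values) and spacer count, then classifies each gene:
#' \describe{
#'   \item{generally_essential}{p <= alpha and median LFC <= `essential_lfc`
#'     in BOTH conditions.}
#'   \item{conditionally_essential_aerobic / _anaerobic}{the conjunction
#'     holds in exactly one condition.}
#'   \item{fitness_defect_aerobic / _anaerobic / _both}{otherwise, p <= alpha
#'     and median LFC <= `defect_lfc` in one or both conditions.}
#'   \item{non_essential}{none of the above.}
#' }
#' A condition-sensitivity flag is also set: condition X is flagged when
#' `|median LFC| >= sensitivity_lfc` and `p < alpha` in X while the other
#' condition fails either criterion (the magnitude rule is two-sided, so
#' enrichment also qualifies).
#'
#' @param spacer_stats Tibble of per-spacer stats for both conditions
#'   (columns spacer_id, gene_id, condition, lfc, q), e.g. two
#'   [test_spacers()] results row-bound.
#' @param conditions Character(2): the two condition labels, first is
#'   "aerobic"-like. Defaults to `c("aerobic", "anaerobic")`.
#' @param essential_lfc,defect_lfc,alpha,sensitivity_lfc Classification
#'   thresholds (defaults -3, -1, 0.05, 1). Thresholds are inclusive
#'   (<= -3, <= 0.05); the sensitivity p cutoff is strict (< alpha).
#' @param conditional_rule How a conditional call treats the non-qualifying
#'   condition: `"conjunction"` (default) requires the full p-and-LFC
#'   conjunction to fail there; `"lfc_only"` only requires the LFC criterion
#'   to fail.
#' @param min_spacers Genes with fewer targeting spacers are flagged
#'   (`few_spacers`), never dropped.
#' @return Tibble: gene_id, median_lfc_<cond>, p_<cond>, n_spacers_<cond>,
#'   class_label, sensitivity_flag, few_spacers.
#' @export
call_genes <- function(spacer_stats,
                       conditions = c("aerobic", "anaerobic"),
                       essential_lfc = -3, defect_lfc = -1, alpha = 0.05,
                       sensitivity_lfc = 1,
                       conditional_rule = c("conjunction", "lfc_only"),
                       min_spacers = 4L) {
  conditional_rule <- match.arg(conditional_rule)
  check_cols(spacer_stats, c("spacer_id", "gene_id", "condition", "lfc", "q"),
             "spacer stats")
  stopifnot(length(conditions) == 2)
  missing_cond <- setdiff(conditions, unique(spacer_stats$condition))
  if (length(missing_cond) > 0) {
    abort(sprintf("spacer stats lack condition(s): %s",
                  paste(missing_cond, collapse = ", ")))
  }

  stats <- spacer_stats |>
    filter(.data$gene_id != "CONTROL", !is.na(.data$gene_id),
           .data$condition %in% conditions)

  per <- stats |>
    group_by(.data$gene_id, .data$condition) |>
    summarise(median_lfc = gene_median_lfc(.data$lfc),
              p = stouffer_combine(.data$q),
              n_spacers = n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("median_lfc", "p", "n_spacers"))

  c1 <- conditions[1]; c2 <- conditions[2]
  m1 <- per[[paste0("median_lfc_", c1)]]; m2 <- per[[paste0("median_lfc_", c2)]]
  p1 <- per[[paste0("p_", c1)]]; p2 <- per[[paste0("p_", c2)]]
  if (anyNA(m1) || anyNA(m2)) {
    abort("every gene must be scored in both conditions")
  }

  ess1 <- p1 <= alpha & m1 <= essential_lfc
  ess2 <- p2 <= alpha & m2 <= essential_lfc
  ess_other_fails1 <- if (conditional_rule == "conjunction") !ess2 else
    m2 > essential_lfc
  ess_other_fails2 <- if (conditional_rule == "conjunction") !ess1 else
    m1 > essential_lfc
  def1 <- p1 <= alpha & m1 <= defect_lfc
  def2 <- p2 <= alpha & m2 <= defect_lfc

  class_label <- case_when(
    ess1 & ess2 ~ "generally_essential",
    ess1 & ess_other_fails1 ~ paste0("conditionally_essential_", c1),
    ess2 & ess_other_fails2 ~ paste0("conditionally_essential_", c2),
    def1 & def2 ~ "fitness_defect_both",
    def1 ~ paste0("fitness_defect_", c1),
    def2 ~ paste0("fitness_defect_", c2),
    .default = "non_essential"
  )

  sens1 <- abs(m1) >= sensitivity_lfc & p1 < alpha
  sens2 <- abs(m2) >= sensitivity_lfc & p2 < alpha
  sensitivity_flag <- case_when(
    sens1 & !sens2 ~ paste0(c1, "_sensitive"),
    sens2 & !sens1 ~ paste0(c2, "_sensitive"),
    .default = "none"
  )

  per |>
    mutate(class_label = class_label,
           sensitivity_flag = sensitivity_flag,
           few_spacers = pmin(per[[paste0("n_spacers_", c1)]],
                              per[[paste0("n_spacers_", c2)]]) < min_spacers)
}

#' Attach transcription-unit context to gene calls
#'
#' Each gene gets its TU id and the ordered list of co-transcribed genes.
#' CRISPRi knockdown is polar within a TU, so a gene's phenotype should be
#' read together with its operon partners. Genes absent from the TU table
#' fall back to singleton TUs (a warning lists them); a gene mapped to more
#' than one TU is an error — TUs must partition the annotation.
#'
#' @param gene_calls Tibble from [call_genes()].
#' @param tu_table Tibble (tu_id, gene_id) with rows in genomic order, e.g.
#'   the simulator's `tu_truth` or a [merge_transcripts()]-derived partition.
#' @return `gene_calls` with tu_id and tu_members (comma-separated, genomic
#'   order) columns.
#' @export
annotate_tu <- function(gene_calls, tu_table) {
  check_cols(tu_table, c("tu_id", "gene_id"), "TU table")
  if (anyDuplicated(tu_table$gene_id)) {
    dup <- tu_table$gene_id[duplicated(tu_table$gene_id)]
    abort(sprintf("gene(s) mapped to more than one TU: %s (TUs must partition)",
                  paste(unique(dup), collapse = ", ")))
  }
  members <- tu_table |>
    group_by(.data$tu_id) |>
    summarise(tu_members = paste(.data$gene_id, collapse = ","),
              .groups = "drop")
  map <- left_join(tu_table, members, by = "tu_id")

  out <- left_join(gene_calls, map, by = "gene_id")
  orphan <- is.na(out$tu_id)
  if (any(orphan)) {
    warn(sprintf("%d gene(s) absent from TU table; treated as singleton TUs",
                 sum(orphan)))
    out$tu_id[orphan] <- out$gene_id[orphan]
    out$tu_members[orphan] <- out$gene_id[orphan]
  }
  out
}

#' Summarize a screen's gene calls
#'
#' Counts genes per class label and reports the percentage of protein-coding
#' genes called generally essential, rounded to the nearest integer for
#' display (half away from zero).
#'
#' @param gene_calls Tibble from [call_genes()].
#' @param n_protein_coding Total protein-coding genes in the genome
#'   (defaults to the number of called genes).
#' @return List with `class_counts` (tibble class_label, n) and
#'   `pct_generally_essential` (integer percent).
#' @export
summarize_screen <- function(gene_calls, n_protein_coding = nrow(gene_calls)) {
  cc <- gene_calls |> count(.data$class_label, name = "n") |>
    arrange(dplyr::desc(.data$n))
  n_ess <- sum(gene_calls$class_label == "generally_essential")
  list(
    class_counts = cc,
    n_generally_essential = n_ess,
    n_protein_coding = n_protein_coding,
    pct_generally_essential = if (n_protein_coding > 0)
      percent_round(n_ess, n_protein_coding) else 0L
  )
}
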