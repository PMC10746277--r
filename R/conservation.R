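#' Read an orthogroup table (Orthogroups.tsv dialect)
#'
#' First column: orthogroup id; one column per species; cells hold
#' comma-separated gene ids, empty when the species is absent from the
#' group.
#'
#' @param path TSV path.
#' @return Long tibble: orthogroup_id, species, gene_id.
#' @export
read_orthogroups <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  names(wide)[1] <- "orthogroup_id"
  wide |>
    tidyr::pivot_longer(-"orthogroup_id", names_to = "species",
                        values_to = "gene_id") |>
    filter(!is.na(.data$gene_id), .data$gene_id != "") |>
    mutate(gene_id = strsplit(.data$gene_id, ",\\s*")) |>
    tidyr::unnest("gene_id")
}

#' Core-conserved orthogroups and focal coverage
#'
#' The conserved core is the set of orthogroups with at least one member
#' gene in EVERY comparator species. Focal coverage reports how many core
#' groups also contain a gene of the focal species, as a count and an
#' integer-rounded percentage. Adding a comparator can only shrink the core
#' (antitone in the comparator set).
#'
#' @param orthogroups Long tibble from [read_orthogroups()] (orthogroup_id,
#'   species, gene_id).
#' @param comparators Character vector of comparator species (non-empty).
#' @param focal Focal species name (optional; coverage reported when given).
#' @return One-row tibble: n_core, n_core_with_focal, pct_core_with_focal,
#'   with the core orthogroup ids in attribute `core_ids`.
#' @export
core_conserved <- function(orthogroups, comparators, focal = NULL) {
  check_cols(orthogroups, c("orthogroup_id", "species", "gene_id"),
             "orthogroup table")
  if (length(comparators) == 0) abort("comparator set must be non-empty")
  present <- orthogroups |>
    filter(.data$species %in% comparators) |>
    distinct(.data$orthogroup_id, .data$species) |>
    count(.data$orthogroup_id, name = "n_sp")
  core <- present$orthogroup_id[present$n_sp == length(comparators)]

  n_with_focal <- NA_integer_
  pct <- NA_integer_
  if (!is.null(focal)) {
    focal_ogs <- unique(orthogroups$orthogroup_id[orthogroups$species == focal])
    n_with_focal <- sum(core %in% focal_ogs)
    pct <- if (length(core) > 0) percent_round(n_with_focal, length(core)) else 0L
  }
  out <- tibble(n_core = length(core),
                n_core_with_focal = n_with_focal,
                pct_core_with_focal = pct)
  attr(out, "core_ids") <- core
  out
}

#' Genes unique to the focal species
#'
#' Focal genes lying in orthogroups that contain no comparator genes, plus
#' focal genes assigned to no orthogroup at all. Removing a comparator can
#' only grow this set.
#'
#' @param orthogroups Long orthogroup tibble.
#' @param focal Focal species name.
#' @param comparators Comparator species.
#' @param unassigned Optional character vector of focal genes absent from
#'   every orthogroup.
#' @return Character vector of unique focal gene ids.
#' @export
unique_genes <- function(orthogroups, focal, comparators, unassigned = NULL) {
  check_cols(orthogroups, c("orthogroup_id", "species", "gene_id"),
             "orthogroup table")
  shared_ogs <- unique(
    orthogroups$orthogroup_id[orthogroups$species %in% comparators])
  focal_rows <- orthogroups[orthogroups$species == focal, ]
  uniq <- focal_rows$gene_id[!(focal_rows$orthogroup_id %in% shared_ogs)]
  unique(c(uniq, unassigned))
}

#' Essentiality-sharing tiers across comparator species
#'
#' For each focal essential gene, counts the comparator species whose
#' members of the gene's orthogroup intersect that species' essential-gene
#' set, then bins: `most` (>= 4 comparators), `some` (1-3), `none` (0).
#' Focal essential genes absent from the orthogroup table fall in tier
#' `none` and are flagged. A focal gene whose orthogroup has comparator
#' members but no essential ones also counts as `none`.
#'
#' @param orthogroups Long orthogroup tibble.
#' @param catalog Tibble (species, gene_id) of published essential genes
#'   covering every comparator.
#' @param focal Focal species name.
#' @param focal_essential Character vector of focal essential gene ids.
#' @param comparators Comparator species.
#' @param most_min Minimum comparators for the `most` tier (default 4).
#' @return List: `per_gene` tibble (gene_id, n_essential_comparators, tier,
#'   in_table) and `summary` tibble (tier, n, pct) with tiers ordered
#'   most/some/none.
#' @export
essentiality_tiers <- function(orthogroups, catalog, focal, focal_essential,
                               comparators, most_min = 4L) {
  check_cols(catalog, c("species", "gene_id"), "essentiality catalog")
  missing <- setdiff(comparators, unique(catalog$species))
  if (length(missing) > 0) {
    abort(sprintf("catalog lacks comparator(s): %s",
                  paste(missing, collapse = ", ")))
  }
  ess <- split(catalog$gene_id, catalog$species)

  focal_map <- orthogroups |>
    filter(.data$species == focal, .data$gene_id %in% focal_essential) |>
    distinct(.data$gene_id, .data$orthogroup_id)

  comp_rows <- orthogroups |> filter(.data$species %in% comparators)

  n_ess <- map_int(focal_essential, function(g) {
    og <- focal_map$orthogroup_id[focal_map$gene_id == g]
    if (length(og) == 0) return(NA_integer_)
    members <- comp_rows[comp_rows$orthogroup_id %in% og, ]
    sum(map_lgl(comparators, function(sp) {
      any(members$gene_id[members$species == sp] %in% ess[[sp]])
    }))
  })

  per_gene <- tibble(
    gene_id = focal_essential,
    in_table = !is.na(n_ess),
    n_essential_comparators = ifelse(is.na(n_ess), 0L, n_ess)
  ) |>
    mutate(tier = case_when(
      .data$n_essential_comparators >= most_min ~ "most",
      .data$n_essential_comparators >= 1 ~ "some",
      .default = "none"
    ))

  total <- nrow(per_gene)
  summary <- tibble(tier = c("most", "some", "none")) |>
    left_join(count(per_gene, .data$tier, name = "n"), by = "tier") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
           pct = percent_round(.data$n, max(total, 1L)))

  list(per_gene = per_gene, summary = summary)
}
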