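#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a screen result
#'
#' @param x A `crispri_screen` from [run_screen()].
#' @param level `"gene"` (default) returns the gene-call table, `"spacer"`
#'   the per-spacer statistics.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.crispri_screen <- function(x, level = c("gene", "spacer"), ...) {
  level <- match.arg(level)
  if (level == "gene") as_tibble(x$gene_calls) else as_tibble(x$spacer_stats)
}

#' One-row summary of a screen result
#'
#' @param x A `crispri_screen`.
#' @param ... Unused.
#' @return One-row tibble with class counts and the generally-essential
#'   percentage.
#' @export
glance.crispri_screen <- function(x, ...) {
  cc <- setNames(as.list(x$summary$class_counts$n),
                 paste0("n_", x$summary$class_counts$class_label))
  bind_cols(
    tibble(n_genes = nrow(x$gene_calls),
           n_spacers = length(unique(x$spacer_stats$spacer_id)),
           pct_generally_essential = x$summary$pct_generally_essential),
    as_tibble(cc)
  )
}

#' @export
print.crispri_screen <- function(x, ...) {
  cat("<crispri_screen>\n")
  cat(sprintf("  %d genes, %d spacers, conditions: %s\n",
              nrow(x$gene_calls),
              length(unique(x$spacer_stats$spacer_id)),
              paste(x$params$conditions, collapse = " vs ")))
  cc <- x$summary$class_counts
  for (i in seq_len(nrow(cc))) {
    cat(sprintf("  %-35s %d\n", cc$class_label[i], cc$n[i]))
  }
  cat(sprintf("  generally essential: %d of %d protein-coding (%d%%)\n",
              x$summary$n_generally_essential, x$summary$n_protein_coding,
              x$summary$pct_generally_essential))
  if (!is.null(x$recovery)) {
    cat(sprintf("  recovery: essential sensitivity %.3f, false-essential rate %.3f\n",
                x$recovery$essential_sensitivity,
                x$recovery$false_essential_rate))
  }
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes x %d guides + %d controls; G = %g doublings\n",
              x$n_genes, x$guides_per_gene, x$n_controls, x$doublings))
  cat(sprintf("  depth %g, phi %g, efficiency Beta(%g, %g), polar %s, seed %d\n",
              x$depth, x$phi, x$efficiency_alpha, x$efficiency_beta,
              x$polar, x$seed))
  invisible(x)
}
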