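#' Per-sample size factors anchored on non-targeting controls
#'
#' Median-of-ratios size factors (relative to the per-spacer geometric mean
#' across samples), rescaled so their geometric mean is 1. When a spacer
#' library is supplied and at least `min_controls` non-targeting controls
#' have a nonzero median count, only control spacers enter the calculation:
#' controls are fitness-neutral by construction, whereas heavily depleted
#' essential-gene spacers bias whole-library scaling. Otherwise all spacers
#' are used.
#'
#' @param counts Counts tibble (spacer_id + one column per sample).
#' @param library Optional library tibble; rows with `gene_id == "CONTROL"`
#'   mark non-targeting spacers.
#' @param min_controls Minimum controls with nonzero median count needed to
#'   anchor on controls (default 50).
#' @return Named numeric vector of positive size factors (one per sample),
#'   geometric mean 1.
#' @export
normalize_counts <- function(counts, library = NULL, min_controls = 50L) {
  check_cols(counts, "spacer_id", "counts")
  mat <- as.matrix(counts[, setdiff(names(counts), "spacer_id")])
  rownames(mat) <- counts$spacer_id
  if (any(colSums(mat) == 0)) abort("every sample must have a positive total count")

  use <- rep(TRUE, nrow(mat))
  if (!is.null(library) && "gene_id" %in% names(library)) {
    is_ctrl <- counts$spacer_id %in%
      library$spacer_id[library$gene_id == "CONTROL"]
    med_nonzero <- is_ctrl & apply(mat, 1, median) > 0
    if (sum(med_nonzero) >= min_controls) use <- med_nonzero
  }

  sub <- mat[use, , drop = FALSE]
  allpos <- rowSums(sub > 0) == ncol(sub)
  if (!any(allpos)) abort("no spacer has positive counts in every sample; cannot normalize")
  sub <- sub[allpos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  sf <- apply(sub / ref, 2, median)
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Trended negative-binomial dispersion from initial-timepoint replicates
#'
#' Method-of-moments per-spacer dispersions are computed from replicate
#' variance at the initial timepoint (Ti), within each condition's replicate
#' group, on the normalized scale: `phi = (var - mu) / mu^2`, negative
#' estimates floored at 0. Estimates are pooled into at least `n_bins`
#' mean-ordered, equal-occupancy bins and smoothed by isotone (non-increasing
#' in the mean) regression, the usual shape of count dispersion trends.
#' Evaluation outside the fitted mean range is clamped to the nearest bin.
#'
#' @param counts Counts tibble.
#' @param size_factors From [normalize_counts()].
#' @param sample_sheet Sample sheet; needs >= 2 Ti replicates in some
#'   condition.
#' @param n_bins Minimum number of bins (default 20).
#' @return An object of class `dispersion_trend` (fields `mu`, `phi`),
#'   evaluable with [phi_at()].
#' @export
fit_dispersion <- function(counts, size_factors, sample_sheet, n_bins = 20L) {
  check_cols(sample_sheet, c("sample_id", "condition", "timepoint"), "sample sheet")
  mat <- as.matrix(counts[, setdiff(names(counts), "spacer_id")])
  norm <- sweep(mat, 2, size_factors[colnames(mat)], "/")

  ti <- sample_sheet[sample_sheet$timepoint == "Ti", ]
  groups <- split(ti$sample_id, ti$condition)
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) {
    abort(paste("need >= 2 initial-timepoint replicates to estimate dispersion;",
                "supply a constant trend via dispersion_trend(phi) instead"))
  }

  mus <- phis <- numeric(0)
  for (g in groups) {
    y <- norm[, g, drop = FALSE]
    mu <- rowMeans(y)
    v <- apply(y, 1, var)
    keep <- mu > 0
    mus <- c(mus, mu[keep])
    phis <- c(phis, pmax((v[keep] - mu[keep]) / mu[keep]^2, 0))
  }

  ord <- order(mus)
  mus <- mus[ord]; phis <- phis[ord]
  k <- max(as.integer(n_bins), 1L)
  bin <- ceiling(seq_along(mus) / (length(mus) / k))
  bmu <- as.numeric(tapply(mus, bin, mean))
  bphi <- as.numeric(tapply(phis, bin, mean))
  # collapse bins with tied means (e.g. near-constant libraries)
  bphi <- as.numeric(tapply(bphi, bmu, mean))
  bmu <- sort(unique(bmu))
  if (length(bmu) == 1) {
    return(structure(list(mu = bmu, phi = bphi), class = "dispersion_trend"))
  }
  # isotone non-increasing smoothing of phi against mu
  iso <- isoreg(bmu, -bphi)
  structure(list(mu = bmu, phi = pmax(-iso$yf, 0)),
            class = "dispersion_trend")
}

#' Constant dispersion trend
#'
#' @param phi Non-negative dispersion used at every mean.
#' @return A `dispersion_trend`.
#' @export
dispersion_trend <- function(phi) {
  stopifnot(phi >= 0)
  structure(list(mu = c(1, 2), phi = c(phi, phi)), class = "dispersion_trend")
}

#' Evaluate a dispersion trend at given means
#'
#' @param trend A `dispersion_trend`.
#' @param mu Numeric means.
#' @return Dispersions `phi(mu)`, clamped constant outside the fitted range.
#' @export
phi_at <- function(trend, mu) {
  stopifnot(inherits(trend, "dispersion_trend"))
  if (length(trend$mu) == 1) return(rep(trend$phi, length(mu)))
  approx(trend$mu, trend$phi, xout = mu, rule = 2, ties = mean)$y
}

#' Per-spacer log2 fold-change tests for one condition
#'
#' Replicates are averaged on the normalized scale;
#' `lfc = log2((mean Tf + c) / (mean Ti + c))` with pseudocount `c`. The
#' standard error comes from the delta method under the negative-binomial
#' variance `mu + phi(mu) * mu^2` (per-sample size factors propagated) and a
#' Wald z is referred to a two-sided, kurtosis-matched t distribution: with
#' few replicates the log-ratio of NB means has heavier-than-normal tails,
#' so the reference's degrees of freedom are set by matching the statistic's
#' excess kurtosis, computed from the NB fourth cumulant at the observed
#' means (`df = 4 + 6 / kurtosis`; a plain normal reference is measurably
#' anti-conservative in the far tail at genome scale). q is
#' Benjamini-Hochberg adjusted across all spacers within the condition.
#' Spacers with zero counts at both timepoints report `lfc = 0, p = 1` and
#' are flagged low-count.
#'
#' @param counts Counts tibble.
#' @param size_factors From [normalize_counts()].
#' @param trend A `dispersion_trend`.
#' @param sample_sheet Sample sheet.
#' @param condition Condition to test (needs Ti and Tf samples).
#' @param pseudocount Added to both normalized means (default 0.5).
#' @param library Optional library tibble to carry gene_id along.
#' @return Tibble: spacer_id, gene_id (if available), condition, base_mean,
#'   lfc, se, p, q, low_count.
#' @export
test_spacers <- function(counts, size_factors, trend, sample_sheet, condition,
                         pseudocount = 0.5, library = NULL) {
  sheet <- sample_sheet[sample_sheet$condition == condition, ]
  ti <- sheet$sample_id[sheet$timepoint == "Ti"]
  tf <- sheet$sample_id[sheet$timepoint == "Tf"]
  if (length(ti) == 0 || length(tf) == 0) {
    abort(sprintf("condition '%s' needs both Ti and Tf samples", condition))
  }
  mat <- as.matrix(counts[, setdiff(names(counts), "spacer_id")])
  norm <- sweep(mat, 2, size_factors[colnames(mat)], "/")

  m_ti <- rowMeans(norm[, ti, drop = FALSE])
  m_tf <- rowMeans(norm[, tf, drop = FALSE])
  c0 <- pseudocount
  lfc <- log2((m_tf + c0) / (m_ti + c0))

  # delta-method variance of the mean of normalized NB counts
  var_mean <- function(m, samples) {
    phi <- phi_at(trend, m)
    v <- outer(m, 1 / size_factors[samples]) + phi * m^2
    rowSums(v) / length(samples)^2
  }
  v_lfc <- (var_mean(m_tf, tf) / (m_tf + c0)^2 +
            var_mean(m_ti, ti) / (m_ti + c0)^2) / log(2)^2
  se <- sqrt(v_lfc)

  # kurtosis-matched t reference: 2nd/4th cumulants of each group's
  # log-mean under NB(mu, phi), averaged over r replicates
  log_cumulants <- function(m, r) {
    mm <- pmax(m, c0)
    phi <- phi_at(trend, mm)
    k2x <- mm + phi * mm^2
    k4x <- mm + 7 * phi * mm^2 + 12 * phi^2 * mm^3 + 6 * phi^3 * mm^4
    list(k2 = (k2x / r) / mm^2, k4 = (k4x / r^3) / mm^4)
  }
  c_tf <- log_cumulants(m_tf, length(tf))
  c_ti <- log_cumulants(m_ti, length(ti))
  g2 <- (c_tf$k4 + c_ti$k4) / (c_tf$k2 + c_ti$k2)^2
  df <- 4 + 6 / pmax(g2, 1e-6)

  low <- m_ti == 0 & m_tf == 0
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(z) * sqrt(df / (df - 2)), df)
  p[low] <- 1
  lfc[low] <- 0

  out <- tibble(
    spacer_id = counts$spacer_id,
    condition = condition,
    base_mean = (m_ti + m_tf) / 2,
    lfc = lfc, se = se, p = p,
    q = p.adjust(p, method = "BH"),
    low_count = low
  )
  if (!is.null(library) && all(c("spacer_id", "gene_id") %in% names(library))) {
    out <- left_join(out, select(library, "spacer_id", "gene_id"),
                     by = "spacer_id") |>
      relocate("gene_id", .after = "spacer_id")
  }
  out
}
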