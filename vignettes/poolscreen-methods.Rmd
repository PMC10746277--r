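---
title: "Methods: models and design choices in poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

poolscreen analyzes pooled CRISPRi fitness screens with a two-condition
(aerobic vs anaerobic) conditional-essentiality design. This vignette is
the package's account of its statistical models, the tunable parameters
that matter, the synthetic-data generator that backs the test suite, and
the design decisions taken where the design was genuinely open.

## The screen model

A guide library — several 20-nt spacers per gene plus non-targeting
controls — is propagated under induced knockdown for `G` population
doublings. We parameterize each gene's fitness effect by a selection
coefficient `s`, defined directly on the log2-relative-abundance scale per
doubling, so a spacer with knockdown efficiency `e` targeting a gene with
coefficient `s` has true log2 fold change

    LFC_true = G * s * e

after selection. This sidesteps any explicit growth-rate model: `s` is the
quantity the screen actually measures, and efficiency acts as a
multiplicative attenuation of the achievable effect. Deleterious effects
have `s < 0`; an essential gene under full knockdown has `G*s` around -6
or lower, far past the -3 call threshold.

## Per-spacer statistics

**Normalization.** Size factors are median-of-ratios (relative to the
per-spacer geometric mean across samples), rescaled to geometric mean 1.
When at least 50 non-targeting controls have nonzero median counts, only
controls are used: essential-gene spacers deplete strongly by Tf, so
whole-library scaling would absorb real signal into the size factors.
Anchoring on controls — neutral by construction — leaves true depletion in
the fold changes. With fewer usable controls the estimator falls back to
all spacers.

**Dispersion.** Counts are treated as negative binomial with variance
`mu + phi(mu) mu^2`. The trend `phi(mu)` is fitted from initial-timepoint
replicates only (selection has not yet acted there): per-spacer
method-of-moments estimates `(var - mu)/mu^2`, negative values floored at
0, pooled into at least 20 equal-occupancy mean-ordered bins, then smoothed
by isotone non-increasing regression — the shape count dispersion trends
take in practice. Evaluation outside the fitted range is clamped to the
nearest bin; a constant trend can be supplied with `dispersion_trend(phi)`
when only one replicate exists (the fitter refuses single replicates rather
than guessing).

**Testing.** Replicates are averaged on the normalized scale and

    lfc = log2((mean_Tf + c) / (mean_Ti + c)),   c = 0.5

with a delta-method standard error under the NB variance, propagating each
sample's size factor. The pseudocount keeps `lfc` finite; spacers with zero
counts at both timepoints report `lfc = 0, p = 1` and carry a low-count
flag rather than being dropped.

The Wald statistic `z = lfc/se` is *not* referred to a normal. With two
replicates per timepoint the log-ratio of NB means has measurable excess
kurtosis, and at genome scale (10^4 spacers) the normal far tail is
anti-conservative — on fully null simulated screens the family-wise
Benjamini-Hochberg rejection rate at q <= 0.05 ran near 0.10 instead of
0.05. We therefore match the reference distribution's kurtosis to the
statistic's: the excess kurtosis of each group's log-mean is computed from
the NB fourth cumulant at the observed mean
(`k4 = mu + 7 phi mu^2 + 12 phi^2 mu^3 + 6 phi^3 mu^4`), the two groups'
cumulants add, and the t reference gets `df = 4 + 6/kurtosis` (with a
variance-matching scale factor). There are no tuned constants; the df is a
function of the observed means, the dispersion trend, and the replicate
counts. The test suite verifies the resulting calibration: null type-I
fraction inside [0.035, 0.065] and realized null FDP at q <= 0.05 within
its band. The original analysis this design emulates used a
quasi-likelihood NB F-test, which moderates the same far-tail problem by a
different route; we do not attempt to reproduce its numbers, only its
calibration contract.

## Gene-level calls

Per condition, the gene score is the **median spacer LFC** (mean of middle
two for even counts) — robust to a single ineffective or off-target guide —
and gene significance is **Stouffer's combination of the spacers' FDR
values**: `z_i = qnorm(1 - q_i)`, `Z = sum(z_i)/sqrt(k)`, combined
`p = 1 - pnorm(Z)`, inputs clamped to `[1e-15, 1 - 1e-15]`. Combining the
q-values (not the raw p-values) follows the screen convention this package
replicates; the combination is directionless, so a gene with
discordant-sign guides can be significant — the median-LFC threshold
supplies the directionality. All targeting spacers enter the median,
including low-count-flagged ones; genes with fewer than 4 spacers are
called but flagged.

Classification uses inclusive thresholds (defaults: essential LFC -3,
defect LFC -1, alpha 0.05): generally essential when the p-and-LFC
conjunction holds in both conditions, conditionally essential when it
holds in exactly one, fitness defect at the -1 threshold otherwise, else
non-essential. The labels partition the gene set. For a conditional call
the non-qualifying condition must fail the *conjunction* (our default
reading); requiring only the LFC criterion to fail is available via
`conditional_rule = "lfc_only"`, since the defining sentence is ambiguous
on this point. Condition sensitivity is a separate flag
(|median LFC| >= 1 and p < 0.05 in one condition only); the magnitude rule
is deliberately two-sided so enrichment also qualifies.

Display percentages round half away from zero (`percent_round()`), the
convention behind summary figures like "essential genes are ~15% of the
genome"; `base::round()`'s round-to-even would print 14% for some inputs.

## Transcription units

CRISPRi is polar within an operon, so gene calls carry TU context.
Predicted transcript isoforms are merged in two stages:

1. **Grouping** by the exact set of covered genes (a gene is covered when
   the transcript overlaps at least `overlap_frac = 0.5` of its length on
   the same strand; "covered" had no published definition, so the fraction
   is a parameter, with 0 admitting any overlap). Grouping precedes
   clustering, so isoforms covering different gene sets never merge even
   when they overlap. We pool the per-condition tables before grouping:
   identical transcripts observed in four conditions must become one TU,
   which per-table clustering would not produce. A containment mode
   (`grouping = "containment"`) absorbs a gene set into its unique
   superset, for predictors that emit nested isoforms.
2. **Single-linkage clustering** within each group on the pseudo-distance
   `d = max(len_a, len_b) - overlap(a, b)` (symmetric, `d = 0` iff
   identical; the triangle inequality is not guaranteed and not needed),
   cut at a cophenetic height of 100 bp. For single linkage this cut
   equals the connected components of the `d <= 100` threshold graph — the
   minimax-path property — which gives a tie-break-free specification and
   an independent oracle the tests exploit. Merged TUs take the most
   extreme member boundaries.

Cross-strand and cross-replicon merging is never allowed (infinite
distance): merging across strands would be biologically incoherent.
Coordinates are 1-based inclusive internally; BED6 input converts from
0-based half-open at the boundary.

## Phenotype models

* **Growth-curve fitness**: trapezoidal AUC after subtracting the initial
  OD (floored at 0), so inoculum offsets and lag baselines do not inflate
  the area; whether the original AUC convention subtracted baseline is not
  recorded, so the convention is fixed here and documented. Relative
  fitness double-normalizes: treated/vehicle within strain, then to the
  non-targeting control strain.
* **Interactions**: the multiplicative (Bliss-like) model — predicted
  combined fitness is the product of single-perturbation fitness values;
  the interaction is reported both as difference (measured - predicted,
  negative = synergy) and ratio, since the plotted comparison defines no
  single statistic.
* **Spot dilutions**: score = visible dilutions of strain minus control
  (5 vs 6 scores -1); median across scorers, modal colony-size call.
* **Mutation frequency**: RifR CFU / cells plated per replicate; fold of
  means; two-tailed t-test, Welch's unequal-variance form by default
  (`var_equal = TRUE` restores the pooled Student form the assay
  description names); zero-variance and zero-control degeneracies are
  guarded (p = 1 / NA fold) and flagged.

## Conservation summaries

The orthogroup table is an input (orthology inference is out of scope).
The conserved core counts *orthogroups* with members in every comparator —
not summed genes — which is the reading consistent with reporting focal
coverage as a fraction of core groups; gene-level counting remains
available by expanding the table. A focal gene in an orthogroup whose
comparator members are never essential counts toward tier `none`, the same
as a gene with no comparator homologs; tiers are `most` (>= 4 of 7
comparators), `some` (1-3), `none` (0).

## The synthetic-data generator

`sim_config()` + `simulate_genome()` + `build_library()` +
`simulate_counts()` generate screens with known truth. Defaults are the
study conditions the package is tested under, chosen once:

* 4 targeting guides per gene, 1,000 non-targeting controls, `G = 10`
  doublings — the screen design being emulated;
* mean depth 500 reads/spacer at Ti; NB dispersion `phi = 0.05`, constant
  in the simulator (typical of amplicon count data; the *estimator*, not
  the simulator, handles mean-dependence);
* guide efficiency ~ Beta(8, 2) (mean 0.8): strong-knockdown designs
  mostly work, some guides underperform; no published variance exists for
  full-complement guides, so this is flagged as tunable;
* Ti counts ~ NB(depth, phi); Tf expected abundances are multiplied by
  `2^(G*s*e)`, renormalized across the library (fixed sequencing depth,
  a rescaling approximation to multinomial conditioning), and NB-sampled.
  Control-anchored normalization in the analysis undoes the
  renormalization exactly, which is why recovery tests can compare
  estimates to `G*s*e` directly;
* polarity is OFF by default. When on, a spacer inherits the full `s` of
  genes downstream of its target in the TU and an attenuated reverse-polar
  effect of upstream genes, interpolated linearly in the spacer's position
  from 0.49 (5' end) to 0.17 (3' end) — factors derived from a two-gene
  reporter observation (5.4-fold upstream knockdown when targeting the 5'
  end of the downstream gene, 1.8-fold at the 3' end, against an assumed
  ~32-fold full knockdown), offered as defaults rather than asserted as
  truth;
* control spacers are uniform random 20-mers rejected against both genome
  strands (bounded at 10^6 retries); `emit_fastq()` writes read pairs with
  the spacer verbatim inside fixed amplicon flanks, so counting recovers
  the input counts exactly (there is no sequencing-error model).

What the generator does **not** emulate: sequencing error, PCR jackpotting,
mismatch-guide titration sublibraries, batch/day structure, and
genuinely mean-dependent dispersion. Passing recovery tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to those real-data pathologies.

## Problem sizes and fixtures

The test fixtures are sized to exercise the statistics honestly while
keeping the default suite fast: the `recovery` fixture uses 200 genes
(20 generally essential, 10 + 10 conditionally essential at true LFC -6,
20 fitness-defect at -1.5, 140 neutral), 4 guides/gene, depth 500, 2
replicates; the `null` fixture uses 10,000 all-neutral spacers, with
calibration measured over 20 seeded runs; oracle-equivalence checks run
100 random instances of up to 200 transcripts and 10^4 read pairs. The
acceptance script (`scripts/acceptance.R`) re-runs all of these from
scratch under a caller-supplied seed.

## Known limitations

* The spacer test assumes exchangeable same-condition replicates; no
  batch or day covariates.
* Exact matching only: a sequencing error in the spacer loses the read
  (the counting contract is exact 20-mers; there is no fuzzy mode).
* The kurtosis-matched t reference corrects the far tail to first order;
  it is mildly conservative at |z| > 4.5, which costs little power at the
  effect sizes essential genes show.
* TU merging trusts the upstream transcript predictions; it cannot split
  a falsely joined isoform.
* `merge_transcripts()` output need not partition the genes (nested gene
  sets yield nested TUs); `annotate_tu()` demands a partition and will
  refuse such a table rather than guess.
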