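#' Empirical area under a growth curve
#'
#' Trapezoidal integral of optical density over time after subtracting the
#' curve's initial OD (negative baseline-subtracted values are floored at
#' zero), so inoculum offsets and lag-phase baselines do not inflate the
#' area. Exact for piecewise-linear curves and additive over time
#' subintervals.
#'
#' @param time Strictly increasing times (hours), >= 2 points.
#' @param od Optical density readings (>= 0), same length.
#' @param baseline `"initial"` (default) subtracts `od[1]`; `"none"`
#'   integrates the raw readings.
#' @return The empirical AUC (OD x hours).
#' @export
auc_empirical <- function(time, od, baseline = c("initial", "none")) {
  baseline <- match.arg(baseline)
  if (length(time) < 2) abort("need >= 2 time points for an AUC")
  if (length(time) != length(od)) abort("time and od lengths differ")
  if (any(diff(time) <= 0)) abort("times must be strictly increasing")
  y <- if (baseline == "initial") pmax(od - od[1], 0) else od
  pracma::trapz(time, y)
}

#' Relative fitness from four growth curves
#'
#' `f = [auc(test) / auc(test-strain vehicle)] /
#'      [auc(control treated) / auc(control vehicle)]`:
#' the treated/vehicle AUC ratio of the test strain, re-expressed relative
#' to the same ratio in a non-targeting control strain. Invariant to
#' rescaling all four curves' OD by a common constant.
#'
#' @param auc_test,auc_vehicle AUCs for the test strain, treated and
#'   vehicle-only.
#' @param auc_control_treated,auc_control_vehicle The control strain's pair.
#' @return Relative fitness `f >= 0`.
#' @export
relative_fitness <- function(auc_test, auc_vehicle,
                             auc_control_treated = 1,
                             auc_control_vehicle = 1) {
  if (any(c(auc_vehicle, auc_control_vehicle) == 0)) {
    abort("vehicle AUC of zero: relative fitness undefined")
  }
  (auc_test / auc_vehicle) / (auc_control_treated / auc_control_vehicle)
}

#' Fitness of strains across treatments from long-format growth data
#'
#' Computes per-strain relative fitness for each non-vehicle treatment from
#' a long tibble of growth curves, normalizing each strain to its vehicle
#' curve and then to the control strain.
#'
#' @param data Tibble: strain_id, treatment, time, od.
#' @param control_strain The non-targeting control strain id.
#' @param vehicle Label of the vehicle-only treatment (default "vehicle").
#' @return Tibble: strain_id, treatment, auc, f.
#' @export
growth_fitness <- function(data, control_strain, vehicle = "vehicle") {
  check_cols(data, c("strain_id", "treatment", "time", "od"), "growth data")
  aucs <- data |>
    arrange(.data$strain_id, .data$treatment, .data$time) |>
    group_by(.data$strain_id, .data$treatment) |>
    summarise(auc = auc_empirical(.data$time, .data$od), .groups = "drop")
  veh <- aucs |> filter(.data$treatment == vehicle) |>
    select("strain_id", veh_auc = "auc")
  ctrl <- aucs |> filter(.data$strain_id == control_strain) |>
    select("treatment", ctrl_auc = "auc")
  ctrl_veh <- veh$veh_auc[veh$strain_id == control_strain]
  if (length(ctrl_veh) != 1) abort("control strain needs a vehicle curve")
  aucs |>
    filter(.data$treatment != vehicle) |>
    left_join(veh, by = "strain_id") |>
    left_join(ctrl, by = "treatment") |>
    mutate(f = relative_fitness(.data$auc, .data$veh_auc,
                                .data$ctrl_auc, ctrl_veh)) |>
    select("strain_id", "treatment", "auc", "f")
}

#' Multiplicative prediction for a knockdown x treatment combination
#'
#' Under the multiplicative (Bliss-like) theory for fitness interactions, the
#' expected fitness of combining a partial knockdown with a chemical
#' treatment is the product of the single-perturbation fitness values.
#' Measured fitness below the prediction indicates synergy/sensitization.
#'
#' @param f_knockdown,f_treatment Single-perturbation relative fitness
#'   values (>= 0).
#' @return Predicted combined fitness `f_knockdown * f_treatment`.
#' @export
predicted_combined_fitness <- function(f_knockdown, f_treatment) {
  if (any(c(f_knockdown, f_treatment) < 0)) abort("fitness values must be >= 0")
  f_knockdown * f_treatment
}

#' Interaction between measured and predicted combination fitness
#'
#' @param f_measured Measured fitness of the combination.
#' @param f_knockdown,f_treatment Single-perturbation fitness values.
#' @return Tibble: predicted, measured, interaction_diff
#'   (measured - predicted; negative = synergy) and interaction_ratio
#'   (measured / predicted; NA when predicted is 0).
#' @export
fitness_interaction <- function(f_measured, f_knockdown, f_treatment) {
  pred <- predicted_combined_fitness(f_knockdown, f_treatment)
  tibble(
    predicted = pred,
    measured = f_measured,
    interaction_diff = f_measured - pred,
    interaction_ratio = ifelse(pred > 0, f_measured / pred, NA_real_)
  )
}

#' Spot-dilution fitness score
#'
#' The score is the number of serial dilutions producing a visible spot for
#' the strain minus the same count for the non-targeting control spotted
#' alongside (a knockdown visible for 5 dilutions against a control visible
#' for 6 scores -1). Antisymmetric under swapping strain and control.
#'
#' @param strain_spots,control_spots Visible-spot counts (vectorized).
#' @return Integer fitness score(s).
#' @examples
#' spot_score(5, 6) # -1
#' @export
spot_score <- function(strain_spots, control_spots) {
  as.integer(strain_spots) - as.integer(control_spots)
}

#' Consensus spot score and colony-size call across scorers
#'
#' Plates are scored independently by several people; the reported fitness
#' score is the median across scorers/replicates and the colony-size call is
#' the most prevalent category (first-seen category wins ties).
#'
#' @param scores Tibble: scorer, strain_spots, control_spots, and optionally
#'   size (one of "small", "large", "control_like").
#' @return One-row tibble: fitness_score (median), size_call (mode or NA).
#' @export
spot_summary <- function(scores) {
  check_cols(scores, c("strain_spots", "control_spots"), "spot scores")
  if (nrow(scores) == 0) abort("no scorer input")
  sc <- spot_score(scores$strain_spots, scores$control_spots)
  size_call <- NA_character_
  if ("size" %in% names(scores)) {
    tab <- table(scores$size)
    size_call <- names(tab)[which.max(tab)]
  }
  tibble(fitness_score = median(sc), size_call = size_call)
}

#' Mutation frequency from rifampicin-resistance plating
#'
#' Per-replicate frequency is resistant CFU divided by cells plated; the
#' fold change is the ratio of mean frequencies (test over control) and
#' significance comes from a two-tailed two-sample t-test on the
#' per-replicate frequencies (Welch's unequal-variance form by default;
#' `var_equal = TRUE` gives the pooled-variance Student form). Degenerate
#' inputs with zero variance in both groups are reported with p = 1 and
#' flagged.
#'
#' @param test,control Tibbles with columns rif_cfu and cells_plated; the
#'   test needs >= 2 replicates.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @return One-row tibble: freq_test, freq_control, fold, p, flag.
#' @export
mutation_frequency <- function(test, control, var_equal = FALSE) {
  check_cols(test, c("rif_cfu", "cells_plated"), "test assay")
  check_cols(control, c("rif_cfu", "cells_plated"), "control assay")
  if (nrow(test) < 2) abort("need >= 2 test replicates")
  ft <- test$rif_cfu / test$cells_plated
  fc <- control$rif_cfu / control$cells_plated
  flag <- NA_character_
  fold <- if (mean(fc) > 0) mean(ft) / mean(fc) else {
    flag <- "zero_control_frequency"
    NA_real_
  }
  p <- if (var(ft) == 0 && (length(fc) < 2 || var(fc) == 0)) {
    if (is.na(flag)) flag <- "zero_variance"
    1
  } else {
    t.test(ft, fc, var.equal = var_equal)$p.value
  }
  tibble(freq_test = mean(ft), freq_control = mean(fc),
         fold = fold, p = p, flag = flag)
}
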