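#' Annual drug acquisition cost for one adherence category
#'
#' Daily acquisition cost prorated by the category's representative
#' medication possession ratio over the horizon:
#' `daily_drug_cost * horizon_days * mpr(category)`.
#'
#' @param strategy a `cea_strategy`.
#' @param category adherence category.
#' @param config engine configuration.
#' @return MAD.
#' @export
drug_cost <- function(strategy, category, config = default_config()) {
  if (!category %in% names(strategy$adherence$mpr)) {
    stopf("unknown adherence category '%s'", category)
  }
  strategy$daily_drug_cost * config$horizon_days *
    strategy$adherence$mpr[[category]]
}

#' Cost of one usage column of the resource-use matrix
#'
#' Sums `quantity(resource, column) * unit_cost(resource)` over all
#' resources. Hospitalisation quantities are bed-days costed at the per-day
#' rate.
#'
#' @param column one of the five usage columns (see `RU_COLUMNS`).
#' @param resource_use resource-use matrix.
#' @param unit_costs named unit-cost vector.
#' @return MAD per event (or per patient-month for `stable_per_month`).
#' @export
event_cost <- function(column, resource_use, unit_costs) {
  if (!column %in% colnames(resource_use)) {
    stopf("unknown usage column '%s'", column)
  }
  res <- rownames(resource_use)
  missing_uc <- setdiff(res, names(unit_costs))
  if (length(missing_uc)) {
    stopf("no unit cost for resource(s): %s",
          paste(missing_uc, collapse = ", "))
  }
  sum(resource_use[, column] * unit_costs[res])
}

#' Routine care cost of stable time
#'
#' The stable-state monthly outpatient basket applied over the stable days
#' of the year, scaled by the global stable-care fraction:
#' `(stable_days / (365/12)) * monthly_basket * scale`.
#'
#' @param stable_days days spent in the stable state.
#' @param resource_use resource-use matrix.
#' @param unit_costs named unit-cost vector.
#' @param scale stable-care scale fraction (see the methods vignette for why
#'   this reconciliation factor exists).
#' @return MAD.
#' @export
stable_care_cost <- function(stable_days, resource_use, unit_costs,
                             scale = 1) {
  stopifnot(stable_days >= 0)
  (stable_days / DAYS_PER_MONTH) *
    event_cost("stable_per_month", resource_use, unit_costs) * scale
}

# Cost of one adverse event by type. EPS and weight gain consume their
# per-event resource columns; the diabetes event consumes one unit of
# "other medication" (the residual medication line of the unit-cost table).
ae_event_cost <- function(ae, resource_use, unit_costs) {
  switch(ae,
    eps = event_cost("eps_per_event", resource_use, unit_costs),
    weight_gain = event_cost("weight_gain_per_event", resource_use,
                             unit_costs),
    diabetes = {
      if (!"other_medication" %in% names(unit_costs)) {
        stopf("no unit cost for resource(s): other_medication")
      }
      unname(unit_costs[["other_medication"]])
    },
    stopf("unknown adverse event '%s'", ae))
}

#' Expected annual direct cost of a treatment arm
#'
#' Probability-weighted accrual over (adherence category x annual outcome):
#' MPR-prorated drug acquisition, stable-time routine care over the
#' occupancy stable days, per-event relapse resource costs, and annual
#' Bernoulli adverse-event costs.
#'
#' @param strategy a `cea_strategy`.
#' @param params a `cea_parameters` object.
#' @return a `cost_breakdown`: list with components `drug`, `stable_care`,
#'   `outpt_relapse`, `hosp_relapse`, `adverse_events` and their `total`.
#' @export
expected_cost <- function(strategy, params) {
  cfg <- params$config
  ru <- params$resource_use
  uc <- params$unit_costs
  out <- annual_outcomes(strategy, cfg)$per_stratum
  a <- strategy$adherence$p

  drug <- adherence_weighted(vapply(ADHERENCE_CATEGORIES, function(cat)
    drug_cost(strategy, cat, cfg), numeric(1L)), strategy$adherence)

  stable_care <- 0
  outpt_relapse <- 0
  hosp_relapse <- 0
  ev_outpt <- event_cost("outpt_relapse_per_event", ru, uc)
  ev_hosp <- event_cost("hosp_relapse_per_event", ru, uc)
  for (cat in ADHERENCE_CATEGORIES) {
    for (o in OUTCOMES) {
      w <- a[[cat]] * out[cat, o]
      if (w == 0) next
      occ <- occupancy(o, cfg)
      stable_care <- stable_care +
        w * stable_care_cost(occ[["stable"]], ru, uc,
                             cfg$stable_care_scale)
      if (o == "outpt") outpt_relapse <- outpt_relapse + w * ev_outpt
      if (o == "hosp") hosp_relapse <- hosp_relapse + w * ev_hosp
    }
  }
  adverse <- sum(vapply(AE_TYPES, function(ae)
    strategy$ae_probs[[ae]] * ae_event_cost(ae, ru, uc), numeric(1L)))

  structure(list(
    drug = drug, stable_care = stable_care, outpt_relapse = outpt_relapse,
    hosp_relapse = hosp_relapse, adverse_events = adverse,
    total = drug + stable_care + outpt_relapse + hosp_relapse + adverse
  ), class = "cost_breakdown")
}

#' Calibrate the stable-care scale against a target annual total
#'
#' Expected total cost is affine in the stable-care scale, so the scale
#' reproducing a target total for one anchor arm has a closed form. The
#' result is clamped to be non-negative: if the non-stable-care components
#' (drug, relapse events, adverse events) already exceed the target, the
#' scale is 0 and the residual is reported in the returned attributes.
#'
#' @param params a `cea_parameters` object.
#' @param target_total target mean annual cost (MAD) for the anchor arm.
#' @param strategy name of the anchor arm.
#' @return the calibrated scale (numeric scalar) with attributes
#'   `residual` (achieved minus target, MAD) and `clamped` (logical).
#' @export
calibrate_stable_care_scale <- function(params, target_total,
                                        strategy = "olanzapine_sot") {
  s <- params$strategies[[strategy]]
  if (is.null(s)) stopf("unknown strategy '%s'", strategy)
  p0 <- params
  p0$config$stable_care_scale <- 0
  base <- expected_cost(s, p0)$total
  p1 <- params
  p1$config$stable_care_scale <- 1
  slope <- expected_cost(s, p1)$total - base
  scale <- if (slope > 0) (target_total - base) / slope else 0
  clamped <- scale < 0
  scale <- max(scale, 0)
  achieved <- base + scale * slope
  structure(scale, residual = achieved - target_total, clamped = clamped)
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "<cost_breakdown> total %.2f MAD (drug %.2f, stable care %.2f, outpatient relapse %.2f, hospitalised relapse %.2f, adverse events %.2f)\n",
    x$total, x$drug, x$stable_care, x$outpt_relapse, x$hosp_relapse,
    x$adverse_events))
  invisible(x)
}
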