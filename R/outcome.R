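#' Adherence-weighted average of a per-category value
#'
#' @param values named numeric, one value per adherence category.
#' @param adherence adherence component of a strategy (list with element
#'   `p`) or a named probability triple.
#' @return `sum(p(category) * value(category))`.
#' @export
adherence_weighted <- function(values, adherence) {
  p <- if (is.list(adherence)) adherence$p else adherence
  if (is.null(names(values)) && length(values) == 3L) {
    names(values) <- ADHERENCE_CATEGORIES
  }
  if (!setequal(names(values), names(p))) {
    stopf("category mismatch: values (%s) vs adherence (%s)",
          paste(names(values), collapse = ","),
          paste(names(p), collapse = ","))
  }
  sum(p[names(p)] * values[names(p)])
}

#' One-year outcome distribution of a treatment arm
#'
#' Converts the per-cycle relapse probabilities of each adherence stratum
#' into annual outcome probabilities under a continuous-hazard cycle
#' exponent `K` (`config$cycle_exponent_K`): the probability of remaining
#' stable over the year is `(1 - ph - po)^K`, and the complementary
#' first-relapse mass is split between hospitalised and outpatient relapse
#' in the ratio `ph : po` of the stratum. The marginal distribution is the
#' adherence-weighted average of the strata.
#'
#' @param strategy a `cea_strategy`.
#' @param config engine configuration (see [default_config()]).
#' @return an `outcome_distribution`: list with `per_stratum` (3x3 matrix,
#'   rows = categories, columns = `stable`/`outpt`/`hosp`) and `marginal`
#'   (named length-3 vector).
#' @export
annual_outcomes <- function(strategy, config = default_config()) {
  K <- config$cycle_exponent_K
  per <- matrix(0, nrow = 3L, ncol = 3L,
                dimnames = list(ADHERENCE_CATEGORIES, OUTCOMES))
  for (cat in ADHERENCE_CATEGORIES) {
    ph <- strategy$p_relapse_hosp[[cat]]
    po <- strategy$p_relapse_outpt[[cat]]
    if (ph + po >= 1) {
      stopf("per-cycle relapse probabilities sum to >= 1 in stratum '%s' of '%s'",
            cat, strategy$name)
    }
    p_stable <- (1 - ph - po)^K
    relapse <- 1 - p_stable
    if (ph + po > 0) {
      per[cat, "hosp"] <- relapse * ph / (ph + po)
      per[cat, "outpt"] <- relapse * po / (ph + po)
    }
    per[cat, "stable"] <- p_stable
  }
  marginal <- vapply(OUTCOMES, function(o)
    adherence_weighted(per[, o], strategy$adherence), numeric(1L))
  structure(list(per_stratum = per, marginal = marginal),
            class = "outcome_distribution")
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat("<outcome_distribution> marginal:",
      sprintf("%s = %.4f", names(x$marginal), x$marginal), "\n")
  invisible(x)
}

#' Calibrate the cycle exponent against annual outcome targets
#'
#' The input tables give per-cycle relapse probabilities but no cycle
#' structure; the published annual outcome table pins it down. This finds
#' the single exponent `K` minimising the sum of squared differences
#' between the model's marginal annual outcome probabilities and the
#' targets, over all targeted strategies and the three outcome classes
#' (bounded 1-D minimisation on `K` in `[0.5, 12]`, tolerance 1e-6).
#'
#' @param params a `cea_parameters` object.
#' @param targets data frame with columns `strategy`, `stable`, `hosp`,
#'   `outpt` (fractions), e.g. [morocco_outcome_targets()].
#' @return the calibrated exponent `K` (numeric scalar).
#' @export
calibrate_cycle_exponent <- function(params,
                                     targets = morocco_outcome_targets()) {
  if (is.null(targets) || !nrow(targets)) stopf("empty calibration targets")
  unknown <- setdiff(targets$strategy, names(params$strategies))
  if (length(unknown)) {
    stopf("calibration target(s) for unknown strategies: %s",
          paste(unknown, collapse = ", "))
  }
  stats::optimize(function(K)
    outcome_sse(params, targets, K), interval = c(0.5, 12),
    tol = 1e-6)$minimum
}

outcome_sse <- function(params, targets, K) {
  cfg <- params$config
  cfg$cycle_exponent_K <- K
  sse <- 0
  for (i in seq_len(nrow(targets))) {
    m <- annual_outcomes(params$strategies[[targets$strategy[i]]],
                         cfg)$marginal
    sse <- sse + (m[["stable"]] - targets$stable[i])^2 +
      (m[["hosp"]] - targets$hosp[i])^2 +
      (m[["outpt"]] - targets$outpt[i])^2
  }
  sse
}

#' State-occupancy profile of an annual outcome
#'
#' Allocates the horizon across health states: a stable year is spent
#' entirely stable; a relapse year spends one episode
#' (`outpt_episode_days` or `hosp_episode_days`) in the relapse state and
#' the remainder stable.
#'
#' @param outcome one of `"stable"`, `"outpt"`, `"hosp"`.
#' @param config engine configuration.
#' @return named numeric vector `c(stable, outpt, hosp)` of days, summing
#'   to `horizon_days`.
#' @export
occupancy <- function(outcome = OUTCOMES, config = default_config()) {
  outcome <- match.arg(outcome)
  h <- config$horizon_days
  switch(outcome,
    stable = c(stable = h, outpt = 0, hosp = 0),
    outpt = c(stable = h - config$outpt_episode_days,
              outpt = config$outpt_episode_days, hosp = 0),
    hosp = c(stable = h - config$hosp_episode_days, outpt = 0,
             hosp = config$hosp_episode_days))
}

#' Quality-adjusted time of one (category, outcome) cell
#'
#' Utility-weighted years for a patient of the given adherence category
#' whose annual outcome is known: days in each state (from [occupancy()])
#' valued at the category's state utility, divided by 365.
#'
#' @param category adherence category.
#' @param outcome annual outcome (`"stable"`, `"outpt"`, `"hosp"`).
#' @param utilities 3x3 utility matrix.
#' @param config engine configuration.
#' @return QALYs (numeric scalar, years).
#' @export
state_qaly <- function(category, outcome, utilities,
                       config = default_config()) {
  occ <- occupancy(outcome, config)
  u <- utilities[category, HEALTH_STATES]
  sum(occ * u) / DAYS_PER_YEAR
}

#' Expected annual QALYs of a treatment arm
#'
#' Probability-weighted quality-adjusted time: over adherence categories and
#' annual outcomes, the occupancy-weighted state utilities of each cell,
#' minus the expected adverse-event decrements
#' (`config$ae_qaly_decrement`, zero by default since no event disutilities
#' are published).
#'
#' @param strategy a `cea_strategy`.
#' @param utilities 3x3 utility matrix.
#' @param config engine configuration.
#' @return expected QALYs (numeric scalar).
#' @export
expected_qaly <- function(strategy, utilities, config = default_config()) {
  out <- annual_outcomes(strategy, config)$per_stratum
  per_cat <- vapply(ADHERENCE_CATEGORIES, function(cat) {
    sum(vapply(OUTCOMES, function(o)
      out[cat, o] * state_qaly(cat, o, utilities, config), numeric(1L)))
  }, numeric(1L))
  dec <- config$ae_qaly_decrement %||%
    c(eps = 0, weight_gain = 0, diabetes = 0)
  adherence_weighted(per_cat, strategy$adherence) -
    sum(strategy$ae_probs * dec[AE_TYPES])
}
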