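new_cohort_result <- function(strategy, mean_cost, mean_qaly, proportions,
                              ae_incidence, se_cost = 0, se_qaly = 0,
                              n = NA_integer_, seed = NA_integer_) {
  structure(list(
    strategy = strategy, mean_cost = mean_cost, mean_qaly = mean_qaly,
    p_stable = proportions[["stable"]], p_outpt = proportions[["outpt"]],
    p_hosp = proportions[["hosp"]], ae_incidence = ae_incidence,
    se_cost = se_cost, se_qaly = se_qaly, n = n, seed = seed
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> %s: cost %.2f MAD, QALY %.4f, outcomes %.1f%%/%.1f%%/%.1f%% (stable/outpatient/hospitalised)\n",
    x$strategy, x$mean_cost, x$mean_qaly, 100 * x$p_stable, 100 * x$p_outpt,
    100 * x$p_hosp))
  invisible(x)
}

#' Turn cohort results into a data frame
#'
#' @param results a `cohort_result` or list of them.
#' @return data frame, one row per result.
#' @export
cohort_results_df <- function(results) {
  if (inherits(results, "cohort_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    ae <- as.list(r$ae_incidence)
    names(ae) <- paste0("ae_", names(ae))
    cbind(data.frame(strategy = r$strategy, cost = r$mean_cost,
                     qaly = r$mean_qaly, p_stable = r$p_stable,
                     p_outpt = r$p_outpt, p_hosp = r$p_hosp,
                     se_cost = r$se_cost, se_qaly = r$se_qaly,
                     n = r$n, seed = r$seed),
          as.data.frame(ae))
  }))
}

#' Expected-value evaluation of one treatment arm
#'
#' Exact probability-weighted composition of the outcome engine and the
#' costing module; deterministic, standard errors are zero.
#'
#' @param strategy a `cea_strategy` or the name of an arm in `params`.
#' @param params a `cea_parameters` object.
#' @return a `cohort_result`.
#' @export
evaluate_expected <- function(strategy, params) {
  if (is.character(strategy)) {
    s <- params$strategies[[strategy]]
    if (is.null(s)) stopf("unknown strategy '%s'", strategy)
    strategy <- s
  }
  out <- annual_outcomes(strategy, params$config)
  new_cohort_result(
    strategy = strategy$name,
    mean_cost = expected_cost(strategy, params)$total,
    mean_qaly = expected_qaly(strategy, params$utilities, params$config),
    proportions = out$marginal,
    ae_incidence = strategy$ae_probs
  )
}

# Per-(category, outcome) lookup tables of cost and QALY used by both the
# microsimulation and expected-value cross-checks.
cell_tables <- function(strategy, params) {
  cfg <- params$config
  ru <- params$resource_use
  uc <- params$unit_costs
  qaly <- outer(ADHERENCE_CATEGORIES, OUTCOMES,
                Vectorize(function(cat, o)
                  state_qaly(cat, o, params$utilities, cfg)))
  dimnames(qaly) <- list(ADHERENCE_CATEGORIES, OUTCOMES)
  ev <- c(stable = 0,
          outpt = event_cost("outpt_relapse_per_event", ru, uc),
          hosp = event_cost("hosp_relapse_per_event", ru, uc))
  cost <- outer(ADHERENCE_CATEGORIES, OUTCOMES,
                Vectorize(function(cat, o) {
                  occ <- occupancy(o, cfg)
                  drug_cost(strategy, cat, cfg) +
                    stable_care_cost(occ[["stable"]], ru, uc,
                                     cfg$stable_care_scale) + ev[[o]]
                }))
  dimnames(cost) <- list(ADHERENCE_CATEGORIES, OUTCOMES)
  ae_costs <- vapply(AE_TYPES, function(ae) ae_event_cost(ae, ru, uc),
                     numeric(1L))
  list(qaly = qaly, cost = cost, ae_costs = ae_costs)
}

#' Patient-level Monte Carlo simulation of one treatment arm
#'
#' Mirrors the cohort-level model patient by patient. Each patient consumes
#' a fixed block of five uniform variates: one for the adherence category,
#' one classifying the annual outcome against the cumulative
#' `[0, p_hosp)`, `[p_hosp, p_hosp + p_outpt)` intervals of their stratum,
#' and three independent Bernoulli draws for the adverse events. Results
#' are reproducible given `seed` and independent of iteration order.
#'
#' @param strategy a `cea_strategy` or arm name.
#' @param params a `cea_parameters` object.
#' @param n number of simulated patients (default
#'   `params$config$n_patients`).
#' @param seed integer RNG seed.
#' @return a `cohort_result` with Monte Carlo standard errors.
#' @export
simulate_cohort <- function(strategy, params, n = params$config$n_patients,
                            seed = 1L) {
  if (is.character(strategy)) strategy <- params$strategies[[strategy]]
  stopifnot(n >= 1)
  set.seed(seed)
  u <- matrix(stats::runif(n * 5L), ncol = 5L)

  a <- strategy$adherence$p
  cat_idx <- findInterval(u[, 1L], cumsum(a), left.open = TRUE) + 1L
  per <- annual_outcomes(strategy, params$config)$per_stratum
  p_hosp <- per[, "hosp"][cat_idx]
  p_outpt <- per[, "outpt"][cat_idx]
  # single uniform: [0, p_hosp) -> hosp, [p_hosp, p_hosp + p_outpt) -> outpt
  out_idx <- ifelse(u[, 2L] < p_hosp, 3L,
                    ifelse(u[, 2L] < p_hosp + p_outpt, 2L, 1L))

  tabs <- cell_tables(strategy, params)
  cell <- cbind(cat_idx, out_idx)
  qaly <- tabs$qaly[cell]
  cost <- tabs$cost[cell]
  dec <- params$config$ae_qaly_decrement %||%
    c(eps = 0, weight_gain = 0, diabetes = 0)
  for (k in seq_along(AE_TYPES)) {
    ae <- AE_TYPES[[k]]
    hit <- u[, 2L + k] < strategy$ae_probs[[ae]]
    cost <- cost + hit * tabs$ae_costs[[ae]]
    qaly <- qaly - hit * dec[[ae]]
  }
  ae_inc <- vapply(seq_along(AE_TYPES), function(k)
    mean(u[, 2L + k] < strategy$ae_probs[[AE_TYPES[[k]]]]), numeric(1L))
  names(ae_inc) <- AE_TYPES

  props <- c(stable = mean(out_idx == 1L), outpt = mean(out_idx == 2L),
             hosp = mean(out_idx == 3L))
  new_cohort_result(
    strategy = strategy$name,
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    proportions = props, ae_incidence = ae_inc,
    se_cost = stats::sd(cost) / sqrt(n),
    se_qaly = stats::sd(qaly) / sqrt(n),
    n = as.integer(n), seed = as.integer(seed)
  )
}

#' Aggregate member arms into an ODT+SOT group result
#'
#' Group cost and QALY are the *sums* over the member arms (the published
#' group totals equal the sum of their ODT and SOT arm totals); outcome
#' proportions and adverse-event incidences are unweighted means of the
#' member values; standard errors combine in quadrature.
#'
#' @param members list of `cohort_result`s.
#' @param name group identifier (default: member names joined by `+`).
#' @return a `cohort_result`.
#' @export
aggregate_group <- function(members, name = NULL) {
  if (!length(members)) stopf("cannot aggregate an empty group")
  if (inherits(members, "cohort_result")) members <- list(members)
  name <- name %||% paste(vapply(members, `[[`, "", "strategy"),
                          collapse = "+")
  grab <- function(f) vapply(members, `[[`, numeric(1L), f)
  ae <- rowMeans(vapply(members, `[[`, numeric(length(AE_TYPES)),
                        "ae_incidence"))
  new_cohort_result(
    strategy = name,
    mean_cost = sum(grab("mean_cost")),
    mean_qaly = sum(grab("mean_qaly")),
    proportions = c(stable = mean(grab("p_stable")),
                    outpt = mean(grab("p_outpt")),
                    hosp = mean(grab("p_hosp"))),
    ae_incidence = ae,
    se_cost = sqrt(sum(grab("se_cost")^2)),
    se_qaly = sqrt(sum(grab("se_qaly")^2)),
    n = if (all(!is.na(grab("n")))) as.integer(sum(grab("n"))) else
      NA_integer_
  )
}

#' Evaluate every arm and group of a parameter set
#'
#' @param params a `cea_parameters` object.
#' @param mode `"expected"` for the deterministic evaluator or
#'   `"microsim"` for the patient-level engine.
#' @param n,seed microsimulation size and seed (microsim mode only); `seed`
#'   is advanced by one per arm.
#' @return named list of `cohort_result`s: one per arm, then one per group.
#' @export
evaluate_all <- function(params, mode = c("expected", "microsim"),
                         n = params$config$n_patients, seed = 1L) {
  mode <- match.arg(mode)
  arms <- lapply(seq_along(params$strategies), function(i) {
    s <- params$strategies[[i]]
    if (mode == "expected") evaluate_expected(s, params)
    else simulate_cohort(s, params, n = n, seed = seed + i - 1L)
  })
  names(arms) <- names(params$strategies)
  groups <- lapply(names(params$groups), function(g)
    aggregate_group(arms[params$groups[[g]]], name = g))
  names(groups) <- names(params$groups)
  c(arms, groups)
}
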