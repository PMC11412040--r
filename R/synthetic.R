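#' Generate a random, valid parameter set with known ground truth
#'
#' Builds a synthetic parameter set with the same structure as the Moroccan
#' fixtures (adherence triples summing to one, ordered utilities, competing
#' relapse risks below one per cycle, non-negative costs) and a structural
#' ground truth against which the whole pipeline can be checked without the
#' published tables.
#'
#' Plans:
#' * `one_dominant` — strategy 1 has strictly lower relapse probabilities
#'   in every stratum, a larger compliant share, and a lower daily drug
#'   cost than every other strategy, so it strictly dominates (lower cost,
#'   higher QALY) under the expected-value engine.
#' * `frontier_chain` — strategies trade off: drug cost rises and relapse
#'   probabilities fall with the strategy index.
#' * `all_equal` — with `effect_scale = 0` all strategies are identical and
#'   all pairwise comparisons are `equal_effect`.
#'
#' @param n_strategies number of arms (>= 2).
#' @param seed integer RNG seed; generation is deterministic given the
#'   seed.
#' @param dominance_plan `"one_dominant"`, `"frontier_chain"` or
#'   `"all_equal"`.
#' @param effect_scale non-negative fraction controlling the separation
#'   between strategies.
#' @return list with elements `params` (a validated `cea_parameters`) and
#'   `ground_truth` (list: `plan`, `dominant` arm name or `NA`,
#'   `cost_order` for chains).
#' @export
generate_parameter_set <- function(n_strategies = 4L, seed = 1L,
                                   dominance_plan = c("one_dominant",
                                                      "frontier_chain",
                                                      "all_equal"),
                                   effect_scale = 0.3) {
  dominance_plan <- match.arg(dominance_plan)
  stopifnot(n_strategies >= 2L, effect_scale >= 0)
  set.seed(seed)

  base_adh <- c(compliant = 0.3, partial = 0.4, non = 0.3)
  base_ph <- c(compliant = 0.03, partial = 0.06, non = 0.09)
  base_po <- c(compliant = 0.03, partial = 0.05, non = 0.08)
  base_ae <- c(eps = 0.15, weight_gain = 0.15, diabetes = 0.03)
  base_drug <- 12

  jitter3 <- function(x, f) {
    y <- x * (1 + f * stats::runif(length(x), -1, 1))
    pmin(pmax(y, 1e-4), 0.95)
  }
  strategies <- lapply(seq_len(n_strategies), function(i) {
    if (dominance_plan == "all_equal") {
      adh <- base_adh
      ph <- base_ph
      po <- base_po
      drug <- base_drug
      if (effect_scale > 0) {
        adh <- jitter3(base_adh, effect_scale)
        adh <- adh / sum(adh)
        ph <- jitter3(base_ph, effect_scale)
        po <- jitter3(base_po, effect_scale)
        drug <- base_drug * (1 + effect_scale * stats::runif(1, -1, 1))
      }
    } else if (dominance_plan == "one_dominant") {
      # strategy 1 strictly better on every margin that moves cost & QALY
      better <- i == 1L
      mult <- if (better) 1 - effect_scale else
        1 + effect_scale * (0.5 + 0.5 * stats::runif(1))
      ph <- pmin(base_ph * mult, 0.45)
      po <- pmin(base_po * mult, 0.45)
      shift <- if (better) effect_scale * 0.3 else
        -effect_scale * 0.3 * stats::runif(1)
      adh <- base_adh + c(shift, 0, -shift)
      adh <- pmin(pmax(adh, 0.01), 0.98)
      adh <- adh / sum(adh)
      drug <- if (better) base_drug * (1 - effect_scale) else
        base_drug * (1 + effect_scale * stats::runif(1))
    } else { # frontier_chain: cost up, relapse down along the index
      frac <- (i - 1) / (n_strategies - 1)
      mult <- 1 + effect_scale * (1 - frac) - effect_scale * frac
      ph <- pmin(base_ph * mult, 0.45)
      po <- pmin(base_po * mult, 0.45)
      adh <- base_adh
      drug <- base_drug * (1 + 2 * effect_scale * frac)
    }
    names(adh) <- ADHERENCE_CATEGORIES
    new_strategy(sprintf("strategy_%02d", i),
                 formulation = if (i %% 2L) "ODT" else "SOT",
                 daily_drug_cost = drug, adherence = adh,
                 p_relapse_hosp = ph, p_relapse_outpt = po,
                 ae_probs = base_ae)
  })

  u <- rbind(compliant = c(0.88, 0.74, 0.53),
             partial = c(0.75, 0.63, 0.53),
             non = c(0.75, 0.63, 0.42))
  colnames(u) <- HEALTH_STATES
  ru <- rbind(
    hospitalisation = c(0, 0, 10 + 5 * stats::runif(1), 0, 0),
    doctor_visits = c(1, 1, 1, 1, 0.5),
    clinic_visits = c(1.5, 2, 2, 1, 2.5),
    counselling = c(0.5, 1.5, 1.5, 0, 5),
    other_medication = c(0, 0, 0, 0, 0))
  colnames(ru) <- RU_COLUMNS
  uc <- c(hospitalisation = 1000 * (1 + stats::runif(1)),
          doctor_visits = 500, clinic_visits = 500, counselling = 700,
          other_medication = 200)

  params <- new_parameters(strategies, groups = list(), utilities = u,
                           resource_use = ru, unit_costs = uc,
                           config = default_config(cycle_exponent_K = 2))
  stop_if_invalid(params)
  gt <- list(
    plan = dominance_plan,
    dominant = if (dominance_plan == "one_dominant" && effect_scale > 0)
      "strategy_01" else NA_character_,
    cost_order = if (dominance_plan == "frontier_chain")
      names(params$strategies) else NULL)
  list(params = params, ground_truth = gt)
}

#' Perturb the built-in parameter set
#'
#' Multiplies every probability, utility and cost of the Moroccan fixture
#' set by independent `1 + U(-magnitude, magnitude)` noise, then restores
#' all structural invariants (triples renormalised, utilities re-ordered
#' within category, probabilities clamped, competing risks kept below one).
#' Used for robustness checks of calibration and frontier stability.
#'
#' @param magnitude noise half-width in `[0, 0.5]`; 0 returns the fixture
#'   set unchanged.
#' @param seed integer RNG seed.
#' @param params base parameter set (default [morocco_parameters()]).
#' @return a validated `cea_parameters` object.
#' @export
perturb_parameters <- function(magnitude, seed = 1L,
                               params = morocco_parameters()) {
  stopifnot(magnitude >= 0, magnitude <= 0.5)
  if (magnitude == 0) return(params)
  set.seed(seed)
  noise <- function(x) x * (1 + magnitude * stats::runif(length(x), -1, 1))
  clamp01 <- function(x) pmin(pmax(x, 0), 1)

  for (arm in names(params$strategies)) {
    s <- params$strategies[[arm]]
    p <- clamp01(noise(s$adherence$p))
    s$adherence$p[] <- p / sum(p)
    s$p_relapse_hosp[] <- clamp01(noise(s$p_relapse_hosp))
    s$p_relapse_outpt[] <- clamp01(noise(s$p_relapse_outpt))
    for (cat in ADHERENCE_CATEGORIES) {
      tot <- s$p_relapse_hosp[[cat]] + s$p_relapse_outpt[[cat]]
      if (tot >= 1) {
        s$p_relapse_hosp[[cat]] <- s$p_relapse_hosp[[cat]] * 0.99 / tot
        s$p_relapse_outpt[[cat]] <- s$p_relapse_outpt[[cat]] * 0.99 / tot
      }
    }
    s$ae_probs[] <- clamp01(noise(s$ae_probs))
    s$daily_drug_cost <- noise(s$daily_drug_cost)
    params$strategies[[arm]] <- s
  }
  u <- params$utilities
  for (cat in ADHERENCE_CATEGORIES) {
    u[cat, ] <- sort(clamp01(noise(u[cat, ])), decreasing = TRUE)
  }
  params$utilities <- u
  params$unit_costs[] <- noise(params$unit_costs)
  params$resource_use[] <- noise(params$resource_use)
  params$resource_use["hospitalisation",
                      setdiff(RU_COLUMNS, "hosp_relapse_per_event")] <- 0
  stop_if_invalid(params)
  params
}
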