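# Resolve an arm or group name to a cohort_result under the expected-value
# engine. Groups are aggregated from their member arms.
evaluate_named <- function(name, params) {
  if (name %in% names(params$strategies)) {
    return(evaluate_expected(name, params))
  }
  if (name %in% names(params$groups)) {
    members <- lapply(params$groups[[name]], evaluate_expected,
                      params = params)
    return(aggregate_group(members, name = name))
  }
  stopf("unknown strategy or group '%s'", name)
}

# Incremental comparison (intervention vs comparator, arm or group names)
# under the expected-value engine.
evaluate_comparison <- function(params, intervention, comparator) {
  i <- evaluate_named(intervention, params)
  c_ <- evaluate_named(comparator, params)
  icer(i$mean_cost, i$mean_qaly, c_$mean_cost, c_$mean_qaly,
       intervention = intervention, comparator = comparator,
       wtp = params$config$wtp)
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-evaluates the expected-value model with each parameter set to
#' `base * (1 - f)` and `base * (1 + f)` (probabilities and utilities are
#' clamped to `[0, 1]`; adherence triples are renormalised), recomputes
#' the incremental comparison, and records both ICER endpoints. Entries
#' are sorted by tornado spread `|icer_high - icer_low|`, descending.
#'
#' @param params a `cea_parameters` object.
#' @param intervention,comparator arm or group names.
#' @param parameter_ids parameter paths to sweep (default:
#'   [default_parameter_ids()] for the arms involved).
#' @param range_fraction half-width of the sweep as a fraction of the base
#'   value (default `config$owsa_range_fraction`).
#' @return data frame of tornado entries: `parameter`, `base_value`,
#'   `low_value`, `high_value`, `icer_low`, `icer_high`, `spread`.
#' @export
owsa <- function(params, intervention, comparator, parameter_ids = NULL,
                 range_fraction = params$config$owsa_range_fraction) {
  arms <- expand_members(params, c(intervention, comparator))
  parameter_ids <- parameter_ids %||% default_parameter_ids(params, arms)
  rows <- lapply(parameter_ids, function(id) {
    loc <- resolve_param_path(params, id)
    base <- param_get(params, id)
    lo <- base * (1 - range_fraction)
    hi <- base * (1 + range_fraction)
    if (loc$kind %in% c("probability", "utility")) {
      lo <- min(max(lo, 0), 1)
      hi <- min(max(hi, 0), 1)
    }
    icer_at <- function(v) {
      evaluate_comparison(param_set(params, id, v), intervention,
                          comparator)$icer
    }
    data.frame(parameter = id, base_value = base, low_value = lo,
               high_value = hi, icer_low = icer_at(lo),
               icer_high = icer_at(hi), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  out
}

expand_members <- function(params, names_) {
  unique(unlist(lapply(names_, function(nm) {
    if (nm %in% names(params$groups)) params$groups[[nm]] else nm
  })))
}

#' Sequential-bifurcation screening of cost-influential parameters
#'
#' Group-screening for parameters whose one-at-a-time perturbation moves
#' the total expected cost of a comparison by more than a threshold.
#' Parameter blocks are perturbed jointly (each parameter scaled by
#' `1 + range_fraction`, clamped to validity) and a block is bisected only
#' when its joint cost effect exceeds the threshold; leaves are evaluated
#' individually. Assumes the screened parameters have non-negative cost
#' effects (costs, resource quantities, relapse and adverse-event
#' probabilities all qualify), under which the shortlist equals brute-force
#' one-at-a-time screening at the same threshold.
#'
#' @param params a `cea_parameters` object.
#' @param comparison character vector of arm or group names whose summed
#'   expected cost is the screening response.
#' @param threshold cost threshold (MAD), non-negative.
#' @param parameter_ids parameter paths to screen.
#' @param range_fraction perturbation fraction (default
#'   `config$owsa_range_fraction`).
#' @return data frame `parameter`, `effect` (MAD) of the parameters whose
#'   individual effect exceeds the threshold, sorted by effect descending.
#' @export
screen_parameters <- function(params, comparison, threshold,
                              parameter_ids = NULL,
                              range_fraction =
                                params$config$owsa_range_fraction) {
  stopifnot(threshold >= 0)
  arms <- expand_members(params, comparison)
  parameter_ids <- parameter_ids %||% default_parameter_ids(params, arms)
  base_cost <- sum(vapply(arms, function(a)
    evaluate_expected(a, params)$mean_cost, numeric(1L)))
  perturb <- function(p, ids) {
    for (id in ids) {
      p <- param_set(p, id, param_get(p, id) * (1 + range_fraction),
                     renormalize = FALSE)
    }
    p
  }
  block_effect <- function(ids) {
    pc <- sum(vapply(arms, function(a)
      evaluate_expected(a, perturb(params, ids))$mean_cost, numeric(1L)))
    pc - base_cost
  }
  found <- list()
  recurse <- function(ids) {
    eff <- block_effect(ids)
    if (eff <= threshold) return(invisible(NULL))
    if (length(ids) == 1L) {
      found[[ids]] <<- eff
      return(invisible(NULL))
    }
    half <- ceiling(length(ids) / 2)
    recurse(ids[seq_len(half)])
    recurse(ids[-seq_len(half)])
  }
  if (length(parameter_ids)) recurse(parameter_ids)
  out <- data.frame(parameter = as.character(names(found)),
                    effect = as.numeric(unlist(found)),
                    stringsAsFactors = FALSE)
  if (nrow(out)) out <- out[order(-out$effect), ]
  rownames(out) <- NULL
  out
}

# Method-of-moments beta quantile; degenerate means and zero spread return
# the mean. Infeasible moments (SE too large for the beta support) are
# clamped with a warning. Driving the quantile with an externally supplied
# uniform lets arms that share a clinical parameter receive the same draw.
qbeta_mom <- function(u, mean, sd) {
  if (mean <= 0 || mean >= 1 || sd <= 0) return(mean)
  vmax <- mean * (1 - mean)
  if (sd^2 >= vmax) {
    warning(sprintf(
      "beta SE %.4g infeasible for mean %.4g; clamped", sd, mean),
      call. = FALSE)
    sd <- 0.95 * sqrt(vmax)
  }
  nu <- vmax / sd^2 - 1
  stats::qbeta(u, mean * nu, (1 - mean) * nu)
}

rbeta_mom <- function(n, mean, sd) {
  vapply(stats::runif(n), qbeta_mom, numeric(1L), mean = mean, sd = sd)
}

# Method-of-moments gamma quantile (shape 1/f^2 for SE = f * mean).
qgamma_mom <- function(u, mean, sd) {
  if (mean <= 0 || sd <= 0) return(mean)
  shape <- (mean / sd)^2
  stats::qgamma(u, shape = shape, rate = shape / mean)
}

rgamma_mom <- function(n, mean, sd) {
  vapply(stats::runif(n), qgamma_mom, numeric(1L), mean = mean, sd = sd)
}

# Dirichlet draw preserving the base means; the concentration matches the
# relative SE of the largest component to se_fraction.
rdirichlet_mean <- function(p, se_fraction) {
  if (se_fraction <= 0) return(p)
  i <- which.max(p)
  s0 <- (1 - p[i]) / (se_fraction^2 * p[i]) - 1
  if (s0 <= 0) return(p)
  g <- vapply(p * s0, function(a)
    if (a > 0) stats::rgamma(1L, shape = a) else 0, numeric(1L))
  g / sum(g)
}

#' Draw a random parameter set for probabilistic sensitivity analysis
#'
#' Second-order uncertainty draw: probabilities and utilities from beta
#' distributions (method of moments, SE = `psa_se_fraction_prob` x mean),
#' costs (daily drug costs and unit costs) from gamma distributions
#' (SE = `psa_se_fraction_cost` x mean), and adherence triples from a
#' Dirichlet preserving the base means. Utility draws are re-ordered within
#' each adherence category so the stable >= outpatient >= hospitalised
#' ordering holds; relapse draws are rescaled in the rare case the
#' per-cycle competing risks reach one. Resource quantities, MPRs and the
#' engine configuration are held fixed. With both SE fractions zero the
#' draw equals the base set. Uses the current RNG state; seed via
#' `set.seed()` or [run_psa()].
#'
#' ODT and SOT formulations of the same molecule are assumed clinically
#' equivalent apart from adherence, so arms that belong to the same group
#' share their relapse and adverse-event draws (one quantile per clinical
#' parameter per group, mapped through each arm's own moments); adherence
#' and drug-cost draws remain arm-specific, and utilities and unit costs
#' are global parameters drawn once.
#'
#' @param params a `cea_parameters` object.
#' @return a `cea_parameters` object that passes [validate_parameters()].
#' @export
psa_draw_parameters <- function(params) {
  fp <- params$config$psa_se_fraction_prob
  fc <- params$config$psa_se_fraction_cost
  if (fp == 0 && fc == 0) return(params)
  draw_prob <- function(m) qbeta_mom(stats::runif(1L), m, fp * m)
  draw_cost <- function(m) qgamma_mom(stats::runif(1L), m, fc * m)

  # one block of clinical-parameter quantiles per molecule group; arms
  # outside any group get their own block (variate count is fixed per arm
  # order, so results do not depend on evaluation order)
  cluster_of <- stats::setNames(names(params$strategies),
                                names(params$strategies))
  for (g in names(params$groups)) {
    cluster_of[params$groups[[g]]] <- g
  }
  n_clin <- 2L * length(ADHERENCE_CATEGORIES) + length(AE_TYPES)
  clin_u <- lapply(unique(cluster_of), function(cl) stats::runif(n_clin))
  names(clin_u) <- unique(cluster_of)

  for (arm in names(params$strategies)) {
    s <- params$strategies[[arm]]
    u_clin <- clin_u[[cluster_of[[arm]]]]
    s$adherence$p[] <- rdirichlet_mean(s$adherence$p, fp)
    s$p_relapse_hosp[] <- vapply(seq_along(ADHERENCE_CATEGORIES),
                                 function(k) qbeta_mom(
                                   u_clin[k], s$p_relapse_hosp[[k]],
                                   fp * s$p_relapse_hosp[[k]]),
                                 numeric(1L))
    s$p_relapse_outpt[] <- vapply(seq_along(ADHERENCE_CATEGORIES),
                                  function(k) qbeta_mom(
                                    u_clin[3L + k], s$p_relapse_outpt[[k]],
                                    fp * s$p_relapse_outpt[[k]]),
                                  numeric(1L))
    for (cat in ADHERENCE_CATEGORIES) {
      tot <- s$p_relapse_hosp[[cat]] + s$p_relapse_outpt[[cat]]
      if (tot >= 1) {
        s$p_relapse_hosp[[cat]] <- s$p_relapse_hosp[[cat]] * 0.99 / tot
        s$p_relapse_outpt[[cat]] <- s$p_relapse_outpt[[cat]] * 0.99 / tot
      }
    }
    s$ae_probs[] <- vapply(seq_along(AE_TYPES), function(k)
      qbeta_mom(u_clin[6L + k], s$ae_probs[[k]], fp * s$ae_probs[[k]]),
      numeric(1L))
    s$daily_drug_cost <- draw_cost(s$daily_drug_cost)
    params$strategies[[arm]] <- s
  }
  u <- params$utilities
  for (cat in ADHERENCE_CATEGORIES) {
    draws <- vapply(u[cat, ], draw_prob, numeric(1L))
    u[cat, ] <- sort(draws, decreasing = TRUE)
  }
  params$utilities <- u
  params$unit_costs[] <- vapply(params$unit_costs, draw_cost, numeric(1L))
  params
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: per iteration, draw a parameter set with
#' [psa_draw_parameters()], evaluate every compared strategy (arms via the
#' expected-value engine, groups aggregated from their members), and record
#' cost and QALYs. The cost-effectiveness acceptability curve (CEAC) is the
#' frequency with which each strategy attains the highest net monetary
#' benefit over a willingness-to-pay grid; ties split probability equally.
#'
#' @param params a `cea_parameters` object.
#' @param strategies character vector of arm or group names to compare
#'   (default: all arms).
#' @param n_iterations number of Monte Carlo iterations (default
#'   `config$psa_iterations`).
#' @param seed integer RNG seed.
#' @param wtp_grid willingness-to-pay grid; the configured threshold is
#'   always inserted exactly.
#' @return a `psa_result`: list with `draws` (data frame `iteration`,
#'   `strategy`, `cost`, `qaly`), `ceac` (data frame `wtp`, `strategy`,
#'   `probability`), `n_iterations`, `seed`, `wtp`.
#' @export
run_psa <- function(params, strategies = names(params$strategies),
                    n_iterations = params$config$psa_iterations, seed = 1L,
                    wtp_grid = seq(0, 400000, length.out = 101L)) {
  stopifnot(n_iterations >= 1)
  for (nm in strategies) {
    if (!nm %in% c(names(params$strategies), names(params$groups))) {
      stopf("unknown strategy or group '%s'", nm)
    }
  }
  wtp_grid <- sort(unique(c(wtp_grid, params$config$wtp)))
  set.seed(seed)
  n_s <- length(strategies)
  cost <- matrix(NA_real_, n_iterations, n_s,
                 dimnames = list(NULL, strategies))
  qaly <- cost
  for (it in seq_len(n_iterations)) {
    p <- psa_draw_parameters(params)
    arm_res <- lapply(expand_members(p, strategies), evaluate_expected,
                      params = p)
    names(arm_res) <- vapply(arm_res, `[[`, "", "strategy")
    for (j in seq_len(n_s)) {
      nm <- strategies[[j]]
      r <- if (nm %in% names(p$groups)) {
        aggregate_group(arm_res[p$groups[[nm]]], name = nm)
      } else {
        arm_res[[nm]]
      }
      cost[it, j] <- r$mean_cost
      qaly[it, j] <- r$mean_qaly
    }
  }
  ceac <- ceac_from_draws(cost, qaly, wtp_grid)
  draws <- data.frame(
    iteration = rep(seq_len(n_iterations), times = n_s),
    strategy = rep(strategies, each = n_iterations),
    cost = as.vector(cost), qaly = as.vector(qaly),
    stringsAsFactors = FALSE)
  structure(list(draws = draws, ceac = ceac, n_iterations = n_iterations,
                 seed = seed, wtp = params$config$wtp),
            class = "psa_result")
}

ceac_from_draws <- function(cost, qaly, wtp_grid) {
  n_it <- nrow(cost)
  out <- lapply(wtp_grid, function(w) {
    b <- qaly * w - cost
    best <- apply(b, 1L, max)
    win <- b >= best - 1e-9  # ties split equally
    prob <- colSums(win / rowSums(win)) / n_it
    data.frame(wtp = w, strategy = colnames(cost), probability = prob,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' CEAC probability of a strategy at a willingness-to-pay value
#'
#' @param psa a `psa_result`.
#' @param strategy strategy name.
#' @param wtp threshold (must be on the grid; the configured threshold
#'   always is).
#' @return probability in `[0, 1]`.
#' @export
ceac_probability <- function(psa, strategy, wtp = psa$wtp) {
  rows <- psa$ceac[psa$ceac$strategy == strategy &
                     abs(psa$ceac$wtp - wtp) < 1e-6, ]
  if (!nrow(rows)) stopf("wtp %.2f not on the CEAC grid", wtp)
  rows$probability[[1L]]
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, seed %s, %d strategies\n",
              x$n_iterations, x$seed,
              length(unique(x$draws$strategy))))
  at <- x$ceac[abs(x$ceac$wtp - x$wtp) < 1e-6, ]
  cat(sprintf("  CEAC at WTP %.2f: %s\n", x$wtp,
              paste(sprintf("%s %.3f", at$strategy, at$probability),
                    collapse = ", ")))
  invisible(x)
}
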