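# Small in-code fixtures shared across test files.

# An arm with no relapses, no adverse events, fully compliant patients.
degenerate_strategy <- function(name = "degenerate", daily_drug_cost = 0,
                                mpr = c(compliant = 0, partial = 0,
                                        non = 0)) {
  new_strategy(name, "SOT", daily_drug_cost,
               adherence = c(compliant = 1, partial = 0, non = 0),
               p_relapse_hosp = c(0, 0, 0), p_relapse_outpt = c(0, 0, 0),
               ae_probs = c(eps = 0, weight_gain = 0, diabetes = 0),
               mpr = mpr)
}

# A two-arm toy parameter set with round numbers for hand arithmetic.
toy_params <- function(stable_care_scale = 0, cycle_exponent_K = 1) {
  s1 <- new_strategy("alpha", "ODT", 10,
                     adherence = c(0.5, 0.3, 0.2),
                     p_relapse_hosp = c(0.02, 0.04, 0.06),
                     p_relapse_outpt = c(0.02, 0.03, 0.05),
                     ae_probs = c(eps = 0.1, weight_gain = 0.2,
                                  diabetes = 0.05))
  s2 <- new_strategy("beta", "SOT", 8,
                     adherence = c(0.3, 0.4, 0.3),
                     p_relapse_hosp = c(0.04, 0.06, 0.10),
                     p_relapse_outpt = c(0.04, 0.06, 0.08),
                     ae_probs = c(eps = 0.2, weight_gain = 0.1,
                                  diabetes = 0.05))
  u <- rbind(compliant = c(0.9, 0.7, 0.5),
             partial = c(0.8, 0.6, 0.5),
             non = c(0.7, 0.6, 0.4))
  colnames(u) <- c("stable", "relapse_outpt", "relapse_hosp")
  ru <- rbind(hospitalisation = c(0, 0, 10, 0, 0),
              doctor_visits = c(1, 2, 2, 1, 0.5),
              other_medication = c(0, 0, 0, 0, 0))
  colnames(ru) <- c("stable_per_month", "outpt_relapse_per_event",
                    "hosp_relapse_per_event", "eps_per_event",
                    "weight_gain_per_event")
  uc <- c(hospitalisation = 1000, doctor_visits = 500,
          other_medication = 200)
  new_parameters(list(s1, s2), groups = list(both = c("alpha", "beta")),
                 utilities = u, resource_use = ru, unit_costs = uc,
                 config = default_config(
                   cycle_exponent_K = cycle_exponent_K,
                   stable_care_scale = stable_care_scale))
}

expect_no_violations <- function(params) {
  expect_identical(nrow(validate_parameters(params)), 0L)
}
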