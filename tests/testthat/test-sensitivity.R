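test_that("tornado sweeps degenerate and irrelevant parameters to zero spread", {
  p <- toy_params()
  tor0 <- owsa(p, "alpha", "beta", range_fraction = 0)
  expect_true(all(tor0$spread == 0))

  pm <- morocco_parameters()
  tor <- owsa(pm, "olanzapine_odt", "risperidone_odt",
              parameter_ids = c("strategies.aripiprazole_odt.daily_drug_cost",
                                "strategies.olanzapine_odt.daily_drug_cost"))
  untouched <- tor[tor$parameter ==
                     "strategies.aripiprazole_odt.daily_drug_cost", ]
  expect_equal(untouched$spread, 0)
  touched <- tor[tor$parameter ==
                   "strategies.olanzapine_odt.daily_drug_cost", ]
  expect_gt(touched$spread, 0)
  # sorted by spread, descending
  expect_identical(tor$parameter[1],
                   "strategies.olanzapine_odt.daily_drug_cost")
})

test_that("stable-state utilities dominate relapse-state utilities in the group tornado", {
  pm <- morocco_parameters()
  u_ids <- as.vector(outer(c("compliant", "partial", "non"),
                           c("stable", "relapse_outpt", "relapse_hosp"),
                           function(a, b) sprintf("utilities.%s.%s", a, b)))
  tor <- owsa(pm, "olanzapine", "risperidone", parameter_ids = u_ids)
  stable_spreads <- tor$spread[grepl("\\.stable$", tor$parameter)]
  relapse_spreads <- tor$spread[!grepl("\\.stable$", tor$parameter)]
  expect_gt(min(stable_spreads), max(relapse_spreads))
})

test_that("sequential bifurcation reproduces one-at-a-time screening", {
  p <- toy_params()
  # response: summed expected cost of both arms; oracle by brute force
  ids16 <- c(sprintf("strategies.alpha.p_relapse_hosp.%s",
                     c("compliant", "partial", "non")),
             sprintf("strategies.beta.p_relapse_hosp.%s",
                     c("compliant", "partial", "non")),
             sprintf("strategies.alpha.ae_probs.%s",
                     c("eps", "weight_gain", "diabetes")),
             sprintf("strategies.beta.ae_probs.%s",
                     c("eps", "weight_gain", "diabetes")),
             "unit_costs.hospitalisation", "unit_costs.doctor_visits",
             "strategies.alpha.daily_drug_cost",
             "strategies.beta.daily_drug_cost")
  expect_length(ids16, 16)
  oracle <- function(threshold) {
    base <- sum(vapply(c("alpha", "beta"), function(a)
      evaluate_expected(a, p)$mean_cost, numeric(1)))
    eff <- vapply(ids16, function(id) {
      p2 <- param_set(p, id, param_get(p, id) * 1.2, renormalize = FALSE)
      sum(vapply(c("alpha", "beta"), function(a)
        evaluate_expected(a, p2)$mean_cost, numeric(1))) - base
    }, numeric(1))
    sort(names(eff)[eff > threshold])
  }
  for (threshold in c(0, 200, 1000, 1e9)) {
    got <- screen_parameters(p, c("alpha", "beta"), threshold,
                             parameter_ids = ids16)
    expect_identical(sort(got$parameter), oracle(threshold),
                     label = sprintf("threshold %g", threshold))
  }
  # a very high threshold yields an empty shortlist
  expect_identical(nrow(screen_parameters(p, c("alpha", "beta"), 1e9,
                                          parameter_ids = ids16)), 0L)

  # exhaustive agreement on a 32-parameter instance of the Moroccan set
  pm <- morocco_parameters()
  ids32 <- c(sprintf("unit_costs.%s", names(pm$unit_costs)),
             sprintf("strategies.olanzapine_odt.p_relapse_hosp.%s",
                     c("compliant", "partial", "non")),
             sprintf("strategies.olanzapine_odt.p_relapse_outpt.%s",
                     c("compliant", "partial", "non")),
             sprintf("strategies.olanzapine_sot.p_relapse_hosp.%s",
                     c("compliant", "partial", "non")),
             sprintf("strategies.olanzapine_sot.p_relapse_outpt.%s",
                     c("compliant", "partial", "non")),
             sprintf("strategies.olanzapine_odt.ae_probs.%s",
                     c("eps", "weight_gain", "diabetes")),
             sprintf("strategies.olanzapine_sot.ae_probs.%s",
                     c("eps", "weight_gain", "diabetes")),
             "strategies.olanzapine_odt.daily_drug_cost",
             "strategies.olanzapine_sot.daily_drug_cost",
             "resource_use.hospitalisation.hosp_relapse_per_event",
             "resource_use.doctor_visits.stable_per_month")
  expect_length(ids32, 32)
  base <- sum(vapply(c("olanzapine_odt", "olanzapine_sot"), function(a)
    evaluate_expected(a, pm)$mean_cost, numeric(1)))
  eff <- vapply(ids32, function(id) {
    p2 <- param_set(pm, id, param_get(pm, id) * 1.2, renormalize = FALSE)
    sum(vapply(c("olanzapine_odt", "olanzapine_sot"), function(a)
      evaluate_expected(a, p2)$mean_cost, numeric(1))) - base
  }, numeric(1))
  for (threshold in c(0, 100, 500)) {
    got <- screen_parameters(pm, "olanzapine", threshold,
                             parameter_ids = ids32)
    expect_identical(sort(got$parameter),
                     sort(names(eff)[eff > threshold]),
                     label = sprintf("threshold %g", threshold))
  }
})

test_that("moment-matched distributions hit their means and respect their supports", {
  set.seed(10)
  draws <- odtcea:::rbeta_mom(10000, 0.23, 0.023)
  expect_lt(abs(mean(draws) - 0.23), 3 * 0.023 / sqrt(10000))
  expect_true(all(draws > 0 & draws < 1))

  gd <- odtcea:::rgamma_mom(10000, 550, 110)
  expect_lt(abs(mean(gd) - 550), 3 * 110 / sqrt(10000))
  expect_true(all(gd > 0))

  expect_warning(odtcea:::rbeta_mom(1, 0.5, 0.6), "infeasible")

  # Dirichlet preserves the base means
  set.seed(11)
  dd <- t(replicate(5000, odtcea:::rdirichlet_mean(c(0.23, 0.43, 0.34),
                                                   0.1)))
  expect_equal(colMeans(dd), c(0.23, 0.43, 0.34), tolerance = 0.01)
  expect_equal(rowSums(dd), rep(1, 5000))
})

test_that("parameter draws are valid, seed-stable and collapse at zero spread", {
  p <- morocco_parameters()
  p0 <- p
  p0$config$psa_se_fraction_prob <- 0
  p0$config$psa_se_fraction_cost <- 0
  expect_identical(psa_draw_parameters(p0), p0)

  set.seed(3)
  for (i in 1:25) {
    expect_no_violations(psa_draw_parameters(p))
  }

  set.seed(4)
  d1 <- psa_draw_parameters(p)
  set.seed(4)
  d2 <- psa_draw_parameters(p)
  expect_identical(d1, d2)

  # ODT and SOT arms of one molecule share their clinical draws
  expect_identical(d1$strategies$olanzapine_odt$p_relapse_hosp,
                   d1$strategies$olanzapine_sot$p_relapse_hosp)
  expect_identical(d1$strategies$olanzapine_odt$ae_probs,
                   d1$strategies$olanzapine_sot$ae_probs)
  expect_false(identical(d1$strategies$olanzapine_odt$p_relapse_hosp,
                         d1$strategies$risperidone_odt$p_relapse_hosp))
  # adherence stays arm-specific
  expect_false(identical(d1$strategies$olanzapine_odt$adherence$p,
                         d1$strategies$olanzapine_sot$adherence$p))
})

test_that("the PSA is reproducible and its CEAC is a proper probability profile", {
  p <- morocco_parameters()
  psa1 <- run_psa(p, n_iterations = 40, seed = 21)
  psa2 <- run_psa(p, n_iterations = 40, seed = 21)
  expect_identical(psa1$draws, psa2$draws)
  expect_identical(psa1$ceac, psa2$ceac)

  expect_true(all(psa1$ceac$probability >= 0 & psa1$ceac$probability <= 1))
  sums <- tapply(psa1$ceac$probability, psa1$ceac$wtp, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)))
  # the configured threshold is always on the grid
  expect_true(any(abs(unique(psa1$ceac$wtp) - p$config$wtp) < 1e-6))

  # zero spread collapses the scatter onto the base case
  p0 <- p
  p0$config$psa_se_fraction_prob <- 0
  p0$config$psa_se_fraction_cost <- 0
  psa0 <- run_psa(p0, n_iterations = 1, seed = 1)
  base <- evaluate_expected("olanzapine_odt", p0)
  d <- psa0$draws[psa0$draws$strategy == "olanzapine_odt", ]
  expect_equal(d$cost, base$mean_cost)
  expect_equal(d$qaly, base$mean_qaly)

  expect_error(run_psa(p, strategies = "nobody", n_iterations = 1),
               "unknown strategy")
})

test_that("PSA means converge to the base case as spreads shrink", {
  p <- morocco_parameters()
  base <- evaluate_expected("olanzapine_odt", p)
  dev <- vapply(c(0.10, 0.04, 0.01), function(f) {
    pf <- p
    pf$config$psa_se_fraction_prob <- f
    pf$config$psa_se_fraction_cost <- 2 * f
    psa <- run_psa(pf, strategies = "olanzapine_odt", n_iterations = 60,
                   seed = 31)
    d <- psa$draws
    abs(mean(d$cost) - base$mean_cost) / base$mean_cost +
      abs(mean(d$qaly) - base$mean_qaly) / base$mean_qaly
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 0.01)
})
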