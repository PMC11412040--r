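test_that("every cell of the published Moroccan input tables is loaded exactly", {
  p <- morocco_parameters()

  adherence <- list(
    olanzapine_sot = c(23, 43, 34), risperidone_sot = c(21, 39, 40),
    aripiprazole_sot = c(19, 35, 46), olanzapine_odt = c(37, 29, 34),
    risperidone_odt = c(35, 25, 40), aripiprazole_odt = c(33, 21, 46))
  relapse_hosp <- list(
    olanzapine = c(2, 4, 5), risperidone = c(4, 6, 9),
    aripiprazole = c(5, 9, 12))
  relapse_outpt <- list(
    olanzapine = c(2, 3, 5), risperidone = c(4, 6, 9),
    aripiprazole = c(5, 8, 11))
  ae <- list(olanzapine = c(16, 30, 3), risperidone = c(25, 14, 3),
             aripiprazole = c(21, 7, 2))
  drug_costs <- c(olanzapine_sot = 9.7, risperidone_sot = 9.6,
                  aripiprazole_sot = 10.6, olanzapine_odt = 11,
                  risperidone_odt = 19.4, aripiprazole_odt = 13.7)

  expect_setequal(names(p$strategies), names(adherence))
  for (arm in names(adherence)) {
    s <- p$strategies[[arm]]
    drug <- sub("_(odt|sot)$", "", arm)
    expect_equal(unname(s$adherence$p), adherence[[arm]] / 100)
    expect_equal(unname(s$p_relapse_hosp), relapse_hosp[[drug]] / 100)
    expect_equal(unname(s$p_relapse_outpt), relapse_outpt[[drug]] / 100)
    expect_equal(unname(s$ae_probs), ae[[drug]] / 100)
    expect_equal(s$daily_drug_cost, unname(drug_costs[[arm]]))
    expect_equal(unname(s$adherence$mpr), c(0.90, 0.70, 0.40))
  }

  u <- rbind(compliant = c(0.88, 0.74, 0.53),
             partial = c(0.75, 0.63, 0.53),
             non = c(0.75, 0.63, 0.42))
  colnames(u) <- colnames(p$utilities)
  expect_equal(p$utilities, u)

  ru_expected <- rbind(
    hospitalisation = c(0, 0, 11.7, 0, 0),
    ambulatory_care_centre = c(0, 1.25, 1.25, 0, 0),
    emergency_department = c(0, 1, 1, 0, 0),
    doctor_visits = c(1, 1, 1, 1, 0.5),
    psychiatric_clinic_visits = c(1.5, 2, 2, 1, 2.5),
    home_care_hours = c(0, 2.75, 2.75, 0, 0),
    group_counselling_hours = c(0.5, 1.5, 1.5, 0, 5),
    nutritionist_visits = c(0, 0, 0, 0, 2.5),
    extra_admission_day = c(0, 0, 0, 0, 0),
    other_medication = c(0, 0, 0, 0, 0))
  colnames(ru_expected) <- colnames(p$resource_use)
  expect_equal(p$resource_use[rownames(ru_expected), ], ru_expected)

  uc_expected <- c(hospitalisation = 1058.30, ambulatory_care_centre = 5220.42,
                   emergency_department = 550, doctor_visits = 571,
                   psychiatric_clinic_visits = 550, home_care_hours = 854,
                   group_counselling_hours = 740, nutritionist_visits = 250,
                   extra_admission_day = 265, other_medication = 229)
  expect_equal(p$unit_costs[names(uc_expected)], uc_expected)

  expect_equal(p$groups, list(
    olanzapine = c("olanzapine_odt", "olanzapine_sot"),
    risperidone = c("risperidone_odt", "risperidone_sot"),
    aripiprazole = c("aripiprazole_odt", "aripiprazole_sot")))
  expect_equal(p$config$wtp, 250832.40)
  expect_equal(p$config$n_patients, 1000000L)
  expect_equal(p$config$hosp_episode_days, 11.7)
})

test_that("the built-in set is valid and invariant breaches are reported as coded violations", {
  p <- morocco_parameters()
  expect_no_violations(p)

  bad <- p
  bad$utilities["compliant", "stable"] <- 1.2
  rep <- validate_parameters(bad)
  expect_true("UTILITY_RANGE" %in% rep$code)

  bad <- p
  bad$strategies$olanzapine_sot$p_relapse_hosp[["compliant"]] <- 0.6
  bad$strategies$olanzapine_sot$p_relapse_outpt[["compliant"]] <- 0.5
  expect_true("COMPETING_RISK_SUM" %in% validate_parameters(bad)$code)

  bad <- p
  bad$strategies$olanzapine_sot$adherence$p <-
    c(compliant = 0.5, partial = 0.5, non = 0.5)
  rep <- validate_parameters(bad)
  expect_true("ADHERENCE_SUM" %in% rep$code)
  expect_match(rep$message[rep$code == "ADHERENCE_SUM"],
               "adherence must sum to 1")

  bad <- p
  bad$strategies$olanzapine_sot$adherence$mpr <-
    c(compliant = 0.4, partial = 0.7, non = 0.9)
  expect_true("MPR_ORDER" %in% validate_parameters(bad)$code)

  bad <- p
  bad$unit_costs <- bad$unit_costs[names(bad$unit_costs) != "doctor_visits"]
  expect_true("MISSING_UNIT_COST" %in% validate_parameters(bad)$code)

  bad <- p
  bad$groups$olanzapine <- c("olanzapine_odt", "no_such_arm")
  expect_true("GROUP_UNKNOWN_ARM" %in% validate_parameters(bad)$code)

  bad <- p
  bad$resource_use["hospitalisation", "stable_per_month"] <- 2
  expect_true("RESOURCE_HOSP_COL" %in% validate_parameters(bad)$code)
})

test_that("save/load round-trips are the identity in both formats", {
  p <- morocco_parameters()

  dir <- withr::local_tempdir()
  save_parameters(p, dir, format = "bundle")
  expect_equal(load_parameters(dir), p)

  f <- withr::local_tempfile(fileext = ".yaml")
  save_parameters(p, f, format = "yaml")
  expect_equal(load_parameters(f), p, tolerance = 1e-9)

  # and for a synthetic set with non-round numbers
  gen <- generate_parameter_set(3, seed = 11)$params
  dir2 <- withr::local_tempdir()
  save_parameters(gen, dir2, format = "bundle")
  expect_equal(load_parameters(dir2), gen, tolerance = 1e-9)
})

test_that("loading errors name the offending table, cell or key", {
  p <- morocco_parameters()
  dir <- withr::local_tempdir()
  save_parameters(p, dir, format = "bundle")

  file.remove(file.path(dir, "resources.csv"))
  expect_error(load_parameters(dir), "resource/unit-cost table")

  dir2 <- withr::local_tempdir()
  save_parameters(p, dir2, format = "bundle")
  adh <- readLines(file.path(dir2, "adherence.csv"))
  adh[2] <- sub("23", "twenty-three", adh[2])
  writeLines(adh, file.path(dir2, "adherence.csv"))
  err <- expect_error(load_parameters(dir2), "malformed number")
  expect_match(conditionMessage(err), "row 1")

  dir3 <- withr::local_tempdir()
  save_parameters(p, dir3, format = "bundle")
  yml <- readLines(file.path(dir3, "params.yaml"))
  writeLines(c(yml, "surprise: 1"), file.path(dir3, "params.yaml"))
  expect_error(load_parameters(dir3), "unknown key.*surprise")

  dir4 <- withr::local_tempdir()
  save_parameters(p, dir4, format = "bundle")
  adh <- utils::read.csv(file.path(dir4, "adherence.csv"))
  adh[1, c("compliant", "partial", "non")] <- c(50, 50, 50)
  utils::write.csv(adh, file.path(dir4, "adherence.csv"), row.names = FALSE)
  expect_error(load_parameters(dir4), "adherence must sum to 1")
})

test_that("parameter paths read and write the addressed value", {
  p <- toy_params()
  expect_equal(param_get(p, "strategies.alpha.daily_drug_cost"), 10)
  expect_equal(param_get(p, "utilities.non.relapse_hosp"), 0.4)
  expect_equal(param_get(p, "unit_costs.hospitalisation"), 1000)
  expect_equal(param_get(p, "resource_use.hospitalisation.hosp_relapse_per_event"),
               10)

  p2 <- param_set(p, "strategies.alpha.p_relapse_hosp.partial", 0.1)
  expect_equal(param_get(p2, "strategies.alpha.p_relapse_hosp.partial"), 0.1)

  # adherence writes renormalise the triple
  p3 <- param_set(p, "strategies.alpha.adherence.compliant", 0.6)
  expect_equal(sum(p3$strategies$alpha$adherence$p), 1)
  expect_equal(param_get(p3, "strategies.alpha.adherence.compliant"), 0.6)

  # probabilities clamp to [0, 1]
  p4 <- param_set(p, "utilities.compliant.stable", 1.4)
  expect_equal(param_get(p4, "utilities.compliant.stable"), 1)

  expect_error(param_get(p, "strategies.nobody.daily_drug_cost"),
               "unknown strategy")
  expect_error(param_get(p, "utilities.compliant.bogus"), "cannot resolve")
})
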