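#' Engine configuration defaults
#'
#' Builds the engine configuration used by the outcome, costing and
#' sensitivity modules. Defaults reflect the one-year Moroccan base case:
#' 365-day horizon, hospitalised-relapse episodes of 11.7 days (the
#' per-event hospitalisation quantity of the resource-use table), 30-day
#' outpatient-relapse episodes, a willingness-to-pay threshold of
#' MAD 250,832.40 per QALY, 1,000,000 simulated patients, and 1000
#' probabilistic-sensitivity iterations with standard errors of 10% of the
#' mean for probabilities/utilities and 20% for costs.
#'
#' @param ... named overrides of any configuration field.
#' @return a named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    horizon_days = 365,
    cycle_exponent_K = 3.2,
    hosp_episode_days = 11.7,
    outpt_episode_days = 30,
    n_patients = 1000000L,
    seed = NULL,
    wtp = 250832.40,
    psa_iterations = 1000L,
    psa_se_fraction_prob = 0.10,
    psa_se_fraction_cost = 0.20,
    owsa_range_fraction = 0.20,
    stable_care_scale = 0,
    mpr = c(compliant = 0.90, partial = 0.70, non = 0.40),
    # per-event QALY decrements; no published disutilities, so all zero
    ae_qaly_decrement = c(eps = 0, weight_gain = 0, diabetes = 0)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg$mpr <- unlist(cfg$mpr)[ADHERENCE_CATEGORIES]
  cfg$ae_qaly_decrement <- unlist(cfg$ae_qaly_decrement)[AE_TYPES]
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$psa_iterations <- as.integer(cfg$psa_iterations)
  cfg
}

#' Construct a treatment arm
#'
#' @param name arm identifier.
#' @param formulation `"ODT"` or `"SOT"`.
#' @param daily_drug_cost drug acquisition cost, MAD per day.
#' @param adherence named probabilities (`compliant`, `partial`, `non`)
#'   summing to one.
#' @param p_relapse_hosp,p_relapse_outpt per-cycle probabilities of a relapse
#'   requiring / not requiring hospitalisation, one per adherence category.
#' @param ae_probs annual probabilities of the three treatment-emergent
#'   adverse events (`eps`, `weight_gain`, `diabetes`).
#' @param mpr representative medication possession ratio per category, used
#'   to prorate drug acquisition cost.
#' @return a `cea_strategy` list.
#' @export
new_strategy <- function(name, formulation, daily_drug_cost, adherence,
                         p_relapse_hosp, p_relapse_outpt, ae_probs,
                         mpr = c(compliant = 0.90, partial = 0.70,
                                 non = 0.40)) {
  as_cat <- function(x, what) {
    x <- unlist(x)
    if (is.null(names(x)) && length(x) == 3L) names(x) <- ADHERENCE_CATEGORIES
    if (!setequal(names(x), ADHERENCE_CATEGORIES)) {
      stopf("%s for '%s' must be named %s", what, name,
            paste(ADHERENCE_CATEGORIES, collapse = "/"))
    }
    x[ADHERENCE_CATEGORIES]
  }
  ae <- unlist(ae_probs)
  if (is.null(names(ae)) && length(ae) == 3L) names(ae) <- AE_TYPES
  structure(list(
    name = name,
    formulation = match.arg(formulation, c("ODT", "SOT")),
    daily_drug_cost = as.numeric(daily_drug_cost),
    adherence = list(p = as_cat(adherence, "adherence"),
                     mpr = as_cat(mpr, "mpr")),
    p_relapse_hosp = as_cat(p_relapse_hosp, "p_relapse_hosp"),
    p_relapse_outpt = as_cat(p_relapse_outpt, "p_relapse_outpt"),
    ae_probs = ae[AE_TYPES]
  ), class = "cea_strategy")
}

#' Assemble a full model parameter set
#'
#' @param strategies list of [new_strategy()] arms.
#' @param groups named list mapping group names to member arm names.
#' @param utilities 3x3 numeric matrix, rows = adherence categories, columns
#'   = health states (`stable`, `relapse_outpt`, `relapse_hosp`).
#' @param resource_use numeric matrix, one row per resource, columns =
#'   usage columns (per patient-month for `stable_per_month`, per event
#'   otherwise).
#' @param unit_costs named numeric vector, MAD per unit; must cover every
#'   resource in `resource_use`.
#' @param config list from [default_config()].
#' @return a `cea_parameters` object.
#' @export
new_parameters <- function(strategies, groups = list(), utilities,
                           resource_use, unit_costs,
                           config = default_config()) {
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  utilities <- as.matrix(utilities)
  if (is.null(rownames(utilities))) rownames(utilities) <- ADHERENCE_CATEGORIES
  if (is.null(colnames(utilities))) colnames(utilities) <- HEALTH_STATES
  utilities <- utilities[ADHERENCE_CATEGORIES, HEALTH_STATES, drop = FALSE]
  resource_use <- as.matrix(resource_use)
  structure(list(
    strategies = strategies,
    groups = groups,
    utilities = utilities,
    resource_use = resource_use[, RU_COLUMNS, drop = FALSE],
    unit_costs = unlist(unit_costs),
    config = config
  ), class = "cea_parameters")
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("<cea_parameters>\n")
  cat("  arms:  ", paste(names(x$strategies), collapse = ", "), "\n")
  if (length(x$groups)) {
    cat("  groups:", paste(sprintf("%s=[%s]", names(x$groups),
                                   vapply(x$groups, paste, "",
                                          collapse = "+")),
                           collapse = ", "), "\n")
  }
  cat(sprintf("  horizon %s d, K = %.4f, WTP = %.2f MAD/QALY\n",
              x$config$horizon_days, x$config$cycle_exponent_K,
              x$config$wtp))
  invisible(x)
}

# ---- validation --------------------------------------------------------

violation <- function(code, where, message) {
  data.frame(code = code, where = where, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of the parameter set and returns the
#' violations as data, not errors: adherence triples sum to one, all
#' probabilities and MPRs lie in `[0, 1]` with MPRs ordered across
#' categories, per-category competing relapse risks sum to less than one,
#' utilities lie in `[0, 1]` and are ordered stable >= outpatient relapse >=
#' hospitalised relapse, costs and resource quantities are non-negative,
#' hospitalisation days appear only in the hospitalised-relapse column,
#' every resource has a unit cost, and group definitions reference existing
#' arms.
#'
#' @param params a `cea_parameters` object.
#' @return a `cea_validation` data frame with columns `code`, `where`,
#'   `message`; zero rows means the set is valid.
#' @export
validate_parameters <- function(params) {
  v <- list()
  add <- function(code, where, msg) v[[length(v) + 1L]] <<-
    violation(code, where, msg)

  arms <- names(params$strategies)
  if (anyDuplicated(arms)) {
    add("DUPLICATE_ARM", "strategies", "arm names must be unique")
  }
  for (s in params$strategies) {
    w <- function(f) sprintf("strategies.%s.%s", s$name, f)
    p <- s$adherence$p
    if (abs(sum(p) - 1) > 1e-9) {
      add("ADHERENCE_SUM", w("adherence"), "adherence must sum to 1")
    }
    if (any(p < 0 | p > 1)) {
      add("PROB_RANGE", w("adherence"), "adherence outside [0,1]")
    }
    mpr <- s$adherence$mpr
    if (any(mpr < 0 | mpr > 1)) {
      add("MPR_RANGE", w("mpr"), "MPR outside [0,1]")
    }
    if (!(mpr[["compliant"]] >= mpr[["partial"]] &&
          mpr[["partial"]] >= mpr[["non"]])) {
      add("MPR_ORDER", w("mpr"), "MPR must decrease with adherence category")
    }
    for (cat in ADHERENCE_CATEGORIES) {
      ph <- s$p_relapse_hosp[[cat]]
      po <- s$p_relapse_outpt[[cat]]
      if (ph < 0 || ph > 1 || po < 0 || po > 1) {
        add("PROB_RANGE", w(paste0("p_relapse.", cat)),
            "relapse probability outside [0,1]")
      }
      if (ph + po >= 1) {
        add("COMPETING_RISK_SUM", w(paste0("p_relapse.", cat)),
            "per-cycle relapse probabilities must sum to < 1")
      }
    }
    if (any(s$ae_probs < 0 | s$ae_probs > 1)) {
      add("PROB_RANGE", w("ae_probs"), "AE probability outside [0,1]")
    }
    if (s$daily_drug_cost < 0) {
      add("NEG_COST", w("daily_drug_cost"), "drug cost must be >= 0")
    }
  }

  u <- params$utilities
  if (any(u < 0 | u > 1)) {
    add("UTILITY_RANGE", "utilities", "utility outside [0,1]")
  }
  for (cat in ADHERENCE_CATEGORIES) {
    if (!(u[cat, "stable"] >= u[cat, "relapse_outpt"] &&
          u[cat, "relapse_outpt"] >= u[cat, "relapse_hosp"])) {
      add("UTILITY_ORDER", paste0("utilities.", cat),
          "utilities must satisfy stable >= outpatient >= hospitalised")
    }
  }

  ru <- params$resource_use
  if (any(ru < 0)) {
    add("RESOURCE_NEG", "resource_use", "resource quantities must be >= 0")
  }
  if ("hospitalisation" %in% rownames(ru)) {
    other <- setdiff(RU_COLUMNS, "hosp_relapse_per_event")
    if (any(ru["hospitalisation", other] != 0)) {
      add("RESOURCE_HOSP_COL", "resource_use.hospitalisation",
          "hospitalisation days only accrue in the hospitalised-relapse column")
    }
  }
  if (any(params$unit_costs < 0)) {
    add("NEG_COST", "unit_costs", "unit costs must be >= 0")
  }
  missing_uc <- setdiff(rownames(ru), names(params$unit_costs))
  if (length(missing_uc)) {
    add("MISSING_UNIT_COST", "unit_costs",
        sprintf("no unit cost for resource(s): %s",
                paste(missing_uc, collapse = ", ")))
  }

  for (g in names(params$groups)) {
    unknown <- setdiff(params$groups[[g]], arms)
    if (length(unknown)) {
      add("GROUP_UNKNOWN_ARM", paste0("groups.", g),
          sprintf("group member(s) not defined as arms: %s",
                  paste(unknown, collapse = ", ")))
    }
  }

  cfg <- params$config
  if (cfg$horizon_days <= 0) add("CONFIG_RANGE", "config.horizon_days",
                                 "horizon must be positive")
  if (cfg$cycle_exponent_K <= 0) add("CONFIG_RANGE", "config.cycle_exponent_K",
                                     "cycle exponent must be positive")
  for (f in c("hosp_episode_days", "outpt_episode_days")) {
    if (cfg[[f]] < 0 || cfg[[f]] > cfg$horizon_days) {
      add("CONFIG_RANGE", paste0("config.", f),
          "episode days must lie in [0, horizon_days]")
    }
  }
  if (cfg$n_patients < 1) add("CONFIG_RANGE", "config.n_patients",
                              "n_patients must be >= 1")
  if (cfg$wtp < 0) add("CONFIG_RANGE", "config.wtp", "WTP must be >= 0")

  out <- if (length(v)) do.call(rbind, v) else
    violation(character(0), character(0), character(0))
  class(out) <- c("cea_validation", "data.frame")
  out
}

#' @export
print.cea_validation <- function(x, ...) {
  if (!nrow(x)) {
    cat("parameter set valid: no violations\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

stop_if_invalid <- function(params) {
  rep <- validate_parameters(params)
  if (nrow(rep)) {
    stopf("invalid parameter set: %s",
          paste(sprintf("[%s] %s: %s", rep$code, rep$where, rep$message),
                collapse = "; "))
  }
  invisible(params)
}

# ---- fixture / file IO -------------------------------------------------

fixture_dir <- function() {
  system.file("extdata", "morocco2022", package = "odtcea", mustWork = TRUE)
}

#' Built-in Moroccan parameter set (2022 MAD)
#'
#' Loads the packaged input tables of the Moroccan base case: adherence
#' distributions, per-cycle relapse probabilities and adverse-event
#' probabilities for the six arms (olanzapine, risperidone and aripiprazole,
#' each as ODT and SOT), the nine health-state utilities, daily drug costs,
#' the resource-use matrix and unit costs, and the engine configuration with
#' the calibrated cycle exponent.
#'
#' @return a validated `cea_parameters` object.
#' @export
morocco_parameters <- function() {
  load_parameters(fixture_dir())
}

#' Published annual outcome targets used for calibration
#'
#' The published base-case relapse table: per strategy, the percentage of
#' patients stable at one year and the percentages with a hospitalised or
#' ambulatory relapse. Used as the target of
#' [calibrate_cycle_exponent()].
#'
#' @param path CSV with columns `strategy`, `stable`, `hosp`, `outpt`
#'   (percent); defaults to the packaged fixture.
#' @return data frame with columns `strategy`, `stable`, `hosp`, `outpt` as
#'   fractions.
#' @export
morocco_outcome_targets <- function(path = file.path(fixture_dir(),
                                                     "targets.csv")) {
  tab <- read_numeric_csv(path, "strategy", c("stable", "hosp", "outpt"),
                          "outcome-target table")
  tab[c("stable", "hosp", "outpt")] <- tab[c("stable", "hosp", "outpt")] / 100
  tab
}

#' Published base-case cost and QALY totals
#'
#' The published base-case results table (mean annual cost in MAD and QALYs
#' per strategy and per ODT+SOT group), shipped as an external anchor for
#' incremental analyses on the published numbers.
#'
#' @return data frame with columns `strategy`, `type` (`arm`/`group`),
#'   `cost`, `qaly`.
#' @export
morocco_reference_results <- function() {
  path <- file.path(fixture_dir(), "reference_base_case.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_numeric_cols(tab, c("cost", "qaly"), "reference base-case table", path)
  tab
}

read_numeric_csv <- function(path, key_cols, num_cols, table_name) {
  if (!file.exists(path)) {
    stopf("missing %s: file '%s' not found", table_name, path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c(key_cols, num_cols)
  absent <- setdiff(need, names(tab))
  if (length(absent)) {
    stopf("%s ('%s') lacks column(s): %s", table_name, basename(path),
          paste(absent, collapse = ", "))
  }
  for (col in num_cols) {
    parsed <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(parsed) & !is.na(tab[[col]]) & nzchar(tab[[col]]))
    if (length(bad)) {
      stopf("%s ('%s'): malformed number '%s' at row %d, column '%s'",
            table_name, basename(path), tab[[col]][bad[1L]], bad[1L], col)
    }
    tab[[col]] <- parsed
  }
  tab
}

check_numeric_cols <- function(tab, cols, table_name, path) {
  for (col in cols) {
    if (!col %in% names(tab) || !is.numeric(tab[[col]])) {
      stopf("%s ('%s') lacks numeric column '%s'", table_name, path, col)
    }
  }
  invisible(tab)
}

#' Load a model parameter set
#'
#' Two on-disk layouts are supported. A *bundle* is a directory holding
#' `params.yaml` (engine configuration, arm definitions with formulation and
#' daily drug cost, group definitions, and file pointers) plus five CSVs:
#' `adherence.csv`, `relapse.csv` and `adverse_events.csv` in percent as
#' published, `utilities.csv` as decimals, and `resources.csv` holding both
#' the usage quantities and the MAD unit costs. A *single YAML file*
#' (`format = "yaml"`) holds the complete set with probabilities as
#' fractions, as written by [save_parameters()].
#'
#' Unknown keys are rejected; a missing table or malformed number produces
#' an error naming the table and cell. The loaded set must pass
#' [validate_parameters()].
#'
#' @param path directory (bundle) or YAML file.
#' @param format `"auto"` (default, by path type), `"bundle"` or `"yaml"`.
#' @return a validated `cea_parameters` object.
#' @export
load_parameters <- function(path, format = c("auto", "bundle", "yaml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "bundle" else "yaml"
  }
  params <- if (format == "bundle") load_bundle(path) else load_yaml_doc(path)
  stop_if_invalid(params)
  params
}

load_bundle <- function(dir) {
  yaml_path <- file.path(dir, "params.yaml")
  if (!file.exists(yaml_path)) {
    stopf("missing configuration document: '%s' not found", yaml_path)
  }
  doc <- yaml::read_yaml(yaml_path)
  unknown <- setdiff(names(doc), c("config", "strategies", "groups", "files"))
  if (length(unknown)) {
    stopf("unknown key(s) in params.yaml: %s", paste(unknown, collapse = ", "))
  }
  cfg <- do.call(default_config, doc$config %||% list())
  files <- doc$files %||% list()
  needed <- c("adherence", "relapse", "adverse_events", "utilities",
              "resources")
  absent <- setdiff(needed, names(files))
  if (length(absent)) {
    stopf("params.yaml names no file for table(s): %s",
          paste(absent, collapse = ", "))
  }
  fpath <- function(key) file.path(dir, files[[key]])

  adh <- read_numeric_csv(fpath("adherence"), "strategy",
                          ADHERENCE_CATEGORIES, "adherence table")
  rel <- read_numeric_csv(fpath("relapse"), c("strategy", "category"),
                          c("hosp", "outpt"), "relapse table")
  ae <- read_numeric_csv(fpath("adverse_events"), "strategy", AE_TYPES,
                         "adverse-event table")
  uti <- read_numeric_csv(fpath("utilities"), "category", HEALTH_STATES,
                          "utility table")
  res <- read_numeric_csv(fpath("resources"), "resource",
                          c(RU_COLUMNS, "unit_cost"),
                          "resource/unit-cost table")

  mpr <- unlist(cfg$mpr)[ADHERENCE_CATEGORIES]
  strategies <- lapply(names(doc$strategies), function(arm) {
    meta <- doc$strategies[[arm]]
    row <- adh[adh$strategy == arm, , drop = FALSE]
    if (nrow(row) != 1L) {
      stopf("adherence table must have exactly one row for arm '%s'", arm)
    }
    rrows <- rel[rel$strategy == arm, , drop = FALSE]
    if (!setequal(rrows$category, ADHERENCE_CATEGORIES)) {
      stopf("relapse table must cover all categories for arm '%s'", arm)
    }
    aerow <- ae[ae$strategy == arm, , drop = FALSE]
    if (nrow(aerow) != 1L) {
      stopf("adverse-event table must have exactly one row for arm '%s'", arm)
    }
    rh <- stats::setNames(rrows$hosp, rrows$category)[ADHERENCE_CATEGORIES]
    ro <- stats::setNames(rrows$outpt, rrows$category)[ADHERENCE_CATEGORIES]
    new_strategy(
      name = arm,
      formulation = meta$formulation,
      daily_drug_cost = meta$daily_drug_cost,
      adherence = unlist(row[ADHERENCE_CATEGORIES]) / 100,
      p_relapse_hosp = rh / 100,
      p_relapse_outpt = ro / 100,
      ae_probs = unlist(aerow[AE_TYPES]) / 100,
      mpr = mpr
    )
  })

  u <- as.matrix(uti[HEALTH_STATES])
  rownames(u) <- uti$category
  ru <- as.matrix(res[RU_COLUMNS])
  rownames(ru) <- res$resource
  uc <- stats::setNames(res$unit_cost, res$resource)

  new_parameters(strategies, groups = lapply(doc$groups %||% list(), unlist),
                 utilities = u, resource_use = ru, unit_costs = uc,
                 config = cfg)
}

load_yaml_doc <- function(path) {
  if (!file.exists(path)) stopf("parameter file '%s' not found", path)
  doc <- yaml::read_yaml(path)
  needed <- c("config", "strategies", "utilities", "resource_use",
              "unit_costs")
  absent <- setdiff(needed, names(doc))
  if (length(absent)) {
    stopf("parameter document lacks section(s): %s",
          paste(absent, collapse = ", "))
  }
  unknown <- setdiff(names(doc), c(needed, "groups"))
  if (length(unknown)) {
    stopf("unknown key(s) in parameter document: %s",
          paste(unknown, collapse = ", "))
  }
  cfg <- do.call(default_config, doc$config %||% list())
  strategies <- lapply(names(doc$strategies), function(arm) {
    s <- doc$strategies[[arm]]
    new_strategy(arm, s$formulation, s$daily_drug_cost,
                 adherence = unlist(s$adherence),
                 p_relapse_hosp = unlist(s$relapse_hosp),
                 p_relapse_outpt = unlist(s$relapse_outpt),
                 ae_probs = unlist(s$adverse_events),
                 mpr = unlist(s$mpr))
  })
  u <- do.call(rbind, lapply(doc$utilities, function(r)
    unlist(r)[HEALTH_STATES]))
  rownames(u) <- names(doc$utilities)
  ru <- do.call(rbind, lapply(doc$resource_use, function(r)
    unlist(r)[RU_COLUMNS]))
  rownames(ru) <- names(doc$resource_use)
  new_parameters(strategies, groups = lapply(doc$groups %||% list(), unlist),
                 utilities = u, resource_use = ru,
                 unit_costs = unlist(doc$unit_costs), config = cfg)
}

#' Save a model parameter set
#'
#' Writes either the CSV bundle layout (directory with `params.yaml` and
#' five CSVs, percentages as published) or a single self-contained YAML
#' document with fractions. `load_parameters(save_parameters(p))` is the
#' identity on valid sets.
#'
#' @param params a `cea_parameters` object.
#' @param path target directory (bundle) or file (yaml).
#' @param format `"bundle"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path, format = c("bundle", "yaml")) {
  format <- match.arg(format)
  cfg <- params$config
  cfg$mpr <- as.list(params$strategies[[1L]]$adherence$mpr)
  cfg$ae_qaly_decrement <- as.list(cfg$ae_qaly_decrement %||%
                                     c(eps = 0, weight_gain = 0,
                                       diabetes = 0))
  if (format == "yaml") {
    doc <- list(
      config = cfg,
      groups = lapply(params$groups, as.list),
      strategies = lapply(params$strategies, function(s) list(
        formulation = s$formulation,
        daily_drug_cost = s$daily_drug_cost,
        adherence = as.list(s$adherence$p),
        mpr = as.list(s$adherence$mpr),
        relapse_hosp = as.list(s$p_relapse_hosp),
        relapse_outpt = as.list(s$p_relapse_outpt),
        adverse_events = as.list(s$ae_probs)
      )),
      utilities = apply(params$utilities, 1L, as.list, simplify = FALSE),
      resource_use = apply(params$resource_use, 1L, as.list,
                           simplify = FALSE),
      unit_costs = as.list(params$unit_costs)
    )
    yaml::write_yaml(doc, path, precision = 15L)
    return(invisible(path))
  }

  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  pct <- function(x) round(x * 100, 9)
  adh <- data.frame(strategy = names(params$strategies),
                    t(vapply(params$strategies,
                             function(s) pct(s$adherence$p), numeric(3L))),
                    row.names = NULL, check.names = FALSE)
  rel <- do.call(rbind, lapply(params$strategies, function(s)
    data.frame(strategy = s$name, category = ADHERENCE_CATEGORIES,
               hosp = pct(s$p_relapse_hosp),
               outpt = pct(s$p_relapse_outpt), row.names = NULL)))
  ae <- data.frame(strategy = names(params$strategies),
                   t(vapply(params$strategies,
                            function(s) pct(s$ae_probs), numeric(3L))),
                   row.names = NULL, check.names = FALSE)
  uti <- data.frame(category = rownames(params$utilities), params$utilities,
                    row.names = NULL, check.names = FALSE)
  res <- data.frame(resource = rownames(params$resource_use),
                    params$resource_use,
                    unit_cost = params$unit_costs[rownames(params$resource_use)],
                    row.names = NULL, check.names = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(path, f),
                                          row.names = FALSE, quote = FALSE)
  wcsv(adh, "adherence.csv")
  wcsv(rel, "relapse.csv")
  wcsv(ae, "adverse_events.csv")
  wcsv(uti, "utilities.csv")
  wcsv(res, "resources.csv")
  doc <- list(
    config = cfg,
    strategies = lapply(params$strategies, function(s) list(
      formulation = s$formulation, daily_drug_cost = s$daily_drug_cost)),
    groups = lapply(params$groups, as.list),
    files = list(adherence = "adherence.csv", relapse = "relapse.csv",
                 adverse_events = "adverse_events.csv",
                 utilities = "utilities.csv", resources = "resources.csv")
  )
  yaml::write_yaml(doc, file.path(path, "params.yaml"), precision = 15L)
  invisible(path)
}
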