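# Shared vocabularies for the model. Adherence categories follow the MPR
# convention (compliant: MPR >= 80%, partial: 60-80%, non: <= 60%); health
# states and the five resource-use columns mirror the input tables.

ADHERENCE_CATEGORIES <- c("compliant", "partial", "non")
HEALTH_STATES <- c("stable", "relapse_outpt", "relapse_hosp")
OUTCOMES <- c("stable", "outpt", "hosp")
AE_TYPES <- c("eps", "weight_gain", "diabetes")
RU_COLUMNS <- c("stable_per_month", "outpt_relapse_per_event",
                "hosp_relapse_per_event", "eps_per_event",
                "weight_gain_per_event")

DAYS_PER_YEAR <- 365
DAYS_PER_MONTH <- 365 / 12

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Read a model parameter by path
#'
#' Parameters are addressed by dot-separated paths, the same addressing used
#' by [owsa()] and [screen_parameters()]. Supported roots:
#' `strategies.<arm>.daily_drug_cost`, `strategies.<arm>.adherence.<category>`,
#' `strategies.<arm>.p_relapse_hosp.<category>`,
#' `strategies.<arm>.p_relapse_outpt.<category>`,
#' `strategies.<arm>.ae_probs.<ae>`, `utilities.<category>.<state>`,
#' `unit_costs.<resource>` and `resource_use.<resource>.<column>`.
#'
#' @param params a `cea_parameters` object.
#' @param id character scalar, dot-separated parameter path.
#' @return numeric scalar.
#' @export
param_get <- function(params, id) {
  loc <- resolve_param_path(params, id)
  loc$get()
}

#' Set a model parameter by path
#'
#' Writes a value at a parameter path (see [param_get()] for the path
#' grammar). When an adherence component is written the remaining two
#' components of that arm's adherence triple are rescaled so the triple still
#' sums to one; probabilities and utilities are clamped to `[0, 1]`, costs
#' and quantities to non-negative values.
#'
#' @inheritParams param_get
#' @param value numeric scalar to write.
#' @param renormalize logical; rescale the rest of an adherence triple after
#'   writing one of its components (default `TRUE`).
#' @return the modified `cea_parameters` object.
#' @export
param_set <- function(params, id, value, renormalize = TRUE) {
  loc <- resolve_param_path(params, id)
  if (loc$kind %in% c("probability", "utility")) {
    value <- min(max(value, 0), 1)
  } else {
    value <- max(value, 0)
  }
  params <- loc$set(params, value)
  if (renormalize && loc$kind == "probability" &&
      length(loc$parts) == 4L && loc$parts[[3L]] == "adherence") {
    arm <- loc$parts[[2L]]
    p <- params$strategies[[arm]]$adherence$p
    cat <- loc$parts[[4L]]
    rest <- setdiff(ADHERENCE_CATEGORIES, cat)
    remainder <- 1 - p[[cat]]
    rest_sum <- sum(p[rest])
    if (rest_sum > 0) {
      p[rest] <- p[rest] * remainder / rest_sum
    } else {
      p[rest] <- remainder / length(rest)
    }
    params$strategies[[arm]]$adherence$p <- p
  }
  params
}

# Resolve a parameter path into an accessor (get/set closures plus the value
# kind used for clamping). Errors name the failing path.
resolve_param_path <- function(params, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
  bad <- function() stopf("cannot resolve parameter path '%s'", id)
  root <- parts[[1L]]
  if (root == "strategies") {
    if (length(parts) < 3L) bad()
    arm <- parts[[2L]]
    if (is.null(params$strategies[[arm]])) {
      stopf("unknown strategy '%s' in parameter path '%s'", arm, id)
    }
    field <- parts[[3L]]
    if (field == "daily_drug_cost") {
      if (length(parts) != 3L) bad()
      return(list(
        parts = parts, kind = "cost",
        get = function() params$strategies[[arm]]$daily_drug_cost,
        set = function(p, v) {
          p$strategies[[arm]]$daily_drug_cost <- v
          p
        }))
    }
    if (length(parts) != 4L) bad()
    key <- parts[[4L]]
    if (field == "adherence") {
      if (!key %in% ADHERENCE_CATEGORIES) bad()
      return(list(
        parts = parts, kind = "probability",
        get = function() params$strategies[[arm]]$adherence$p[[key]],
        set = function(p, v) {
          p$strategies[[arm]]$adherence$p[[key]] <- v
          p
        }))
    }
    if (field %in% c("p_relapse_hosp", "p_relapse_outpt")) {
      if (!key %in% ADHERENCE_CATEGORIES) bad()
      return(list(
        parts = parts, kind = "probability",
        get = function() params$strategies[[arm]][[field]][[key]],
        set = function(p, v) {
          p$strategies[[arm]][[field]][[key]] <- v
          p
        }))
    }
    if (field == "ae_probs") {
      if (!key %in% AE_TYPES) bad()
      return(list(
        parts = parts, kind = "probability",
        get = function() params$strategies[[arm]]$ae_probs[[key]],
        set = function(p, v) {
          p$strategies[[arm]]$ae_probs[[key]] <- v
          p
        }))
    }
    bad()
  }
  if (root == "utilities") {
    if (length(parts) != 3L || !parts[[2L]] %in% ADHERENCE_CATEGORIES ||
        !parts[[3L]] %in% HEALTH_STATES) bad()
    return(list(
      parts = parts, kind = "utility",
      get = function() params$utilities[parts[[2L]], parts[[3L]]],
      set = function(p, v) {
        p$utilities[parts[[2L]], parts[[3L]]] <- v
        p
      }))
  }
  if (root == "unit_costs") {
    if (length(parts) != 2L) bad()
    if (!parts[[2L]] %in% names(params$unit_costs)) bad()
    return(list(
      parts = parts, kind = "cost",
      get = function() params$unit_costs[[parts[[2L]]]],
      set = function(p, v) {
        p$unit_costs[[parts[[2L]]]] <- v
        p
      }))
  }
  if (root == "resource_use") {
    if (length(parts) != 3L ||
        !parts[[2L]] %in% rownames(params$resource_use) ||
        !parts[[3L]] %in% RU_COLUMNS) bad()
    return(list(
      parts = parts, kind = "quantity",
      get = function() params$resource_use[parts[[2L]], parts[[3L]]],
      set = function(p, v) {
        p$resource_use[parts[[2L]], parts[[3L]]] <- v
        p
      }))
  }
  bad()
}

#' Default one-way sensitivity parameter paths for a comparison
#'
#' Enumerates the parameter paths that can influence an incremental
#' comparison: every adherence, relapse and adverse-event probability and the
#' daily drug cost of the arms involved, all nine utilities, and every unit
#' cost.
#'
#' @param params a `cea_parameters` object.
#' @param arms character vector of arm names involved in the comparison.
#' @return character vector of parameter paths.
#' @export
default_parameter_ids <- function(params, arms = names(params$strategies)) {
  ids <- character(0)
  for (arm in arms) {
    ids <- c(ids,
             sprintf("strategies.%s.daily_drug_cost", arm),
             sprintf("strategies.%s.adherence.%s", arm, ADHERENCE_CATEGORIES),
             sprintf("strategies.%s.p_relapse_hosp.%s", arm,
                     ADHERENCE_CATEGORIES),
             sprintf("strategies.%s.p_relapse_outpt.%s", arm,
                     ADHERENCE_CATEGORIES),
             sprintf("strategies.%s.ae_probs.%s", arm, AE_TYPES))
  }
  for (cat in ADHERENCE_CATEGORIES) {
    ids <- c(ids, sprintf("utilities.%s.%s", cat, HEALTH_STATES))
  }
  ids <- c(ids, sprintf("unit_costs.%s", names(params$unit_costs)))
  ids
}
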