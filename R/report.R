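# Run manifest: identifies a run by its inputs (parameter content digest,
# seed, package version). Output files carry the manifest id so any CSV can
# be traced to the run that produced it; the id does not depend on the
# timestamp, so re-runs with the same inputs are byte-identical apart from
# the manifest's own timestamp field.
build_manifest <- function(params, seed, extra = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_parameters(params, tmp, format = "yaml")
  digest <- unname(tools::md5sum(tmp))
  id <- substr(digest, 1L, 12L)
  c(list(
    manifest_id = id,
    parameter_digest = digest,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("odtcea")),
    config = params$config
  ), extra)
}

write_report_csv <- function(df, path, manifest_id) {
  df$manifest_id <- manifest_id
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

resolve_params <- function(params) {
  if (inherits(params, "cea_parameters")) return(params)
  if (!file.exists(params) && !dir.exists(params)) {
    stopf("parameter file or bundle '%s' not found", params)
  }
  load_parameters(params)
}

#' Run the base case and write the result files
#'
#' Evaluates every arm and ODT+SOT group (expected-value engine or
#' microsimulation), then writes `results.csv` (per-strategy cost, QALYs,
#' outcome proportions, adverse-event incidence, standard errors),
#' `cea.csv` (incremental comparisons of the configured intervention
#' against every other arm, and of its group against the other groups),
#' `frontier.csv`, and `manifest.json`.
#'
#' @param params a `cea_parameters` object or a path accepted by
#'   [load_parameters()].
#' @param out_dir output directory (created if needed).
#' @param mode `"expected"` or `"microsim"`.
#' @param seed RNG seed (microsim mode).
#' @param n_patients patients per arm (microsim mode).
#' @param intervention reference arm for the pairwise table.
#' @return invisibly, the list of `cohort_result`s.
#' @export
write_base_case <- function(params, out_dir, mode = c("expected",
                                                      "microsim"),
                            seed = 1L, n_patients = NULL,
                            intervention = "olanzapine_odt") {
  mode <- match.arg(mode)
  params <- resolve_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_patients %||% params$config$n_patients
  results <- evaluate_all(params, mode = mode, n = n, seed = seed)
  man <- build_manifest(params, seed, list(mode = mode))

  write_report_csv(cohort_results_df(results),
                   file.path(out_dir, "results.csv"), man$manifest_id)

  pairs <- list()
  if (intervention %in% names(results)) {
    ref <- results[[intervention]]
    for (nm in setdiff(names(params$strategies), intervention)) {
      r <- results[[nm]]
      pairs[[length(pairs) + 1L]] <-
        icer(ref$mean_cost, ref$mean_qaly, r$mean_cost, r$mean_qaly,
             intervention, nm, params$config$wtp)
    }
    own_group <- names(which(vapply(params$groups, function(g)
      intervention %in% g, logical(1L))))
    if (length(own_group) == 1L) {
      gref <- results[[own_group]]
      for (g in setdiff(names(params$groups), own_group)) {
        r <- results[[g]]
        pairs[[length(pairs) + 1L]] <-
          icer(gref$mean_cost, gref$mean_qaly, r$mean_cost, r$mean_qaly,
               own_group, g, params$config$wtp)
      }
    }
  }
  cea_df <- do.call(rbind, lapply(pairs, function(p)
    data.frame(intervention = p$intervention, comparator = p$comparator,
               delta_cost = p$delta_cost, delta_qaly = p$delta_qaly,
               icer = p$icer, flag = p$flag,
               cost_effective_at_wtp = p$cost_effective_at_wtp)))
  write_report_csv(cea_df, file.path(out_dir, "cea.csv"), man$manifest_id)

  fr <- frontier(results[names(params$strategies)])
  write_report_csv(fr, file.path(out_dir, "frontier.csv"), man$manifest_id)

  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}

#' Calibrate the engine against annual outcome targets and report
#'
#' Fits the cycle exponent `K` against the annual outcome targets and the
#' stable-care scale against a target mean annual cost for the anchor arm,
#' and writes `calibration.json` with the fitted values, per-cell outcome
#' residuals (model minus target, percentage points) and the cost residual
#' (MAD).
#'
#' @param params parameter set or path.
#' @param targets data frame of annual outcome targets (fractions), or a
#'   CSV path with percent columns `stable`, `hosp`, `outpt`.
#' @param out_dir output directory.
#' @param cost_target,cost_anchor target total (MAD) and anchor arm for the
#'   stable-care scale; `NULL` skips cost calibration.
#' @return invisibly, the calibration list.
#' @export
write_calibration <- function(params, targets = morocco_outcome_targets(),
                              out_dir, cost_target = 3106,
                              cost_anchor = "olanzapine_sot") {
  params <- resolve_params(params)
  if (is.character(targets)) targets <- morocco_outcome_targets(targets)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  K <- calibrate_cycle_exponent(params, targets)
  cfg <- params$config
  cfg$cycle_exponent_K <- K
  residuals <- lapply(seq_len(nrow(targets)), function(i) {
    m <- annual_outcomes(params$strategies[[targets$strategy[i]]],
                         cfg)$marginal
    list(strategy = targets$strategy[i],
         stable_pp = 100 * (m[["stable"]] - targets$stable[i]),
         hosp_pp = 100 * (m[["hosp"]] - targets$hosp[i]),
         outpt_pp = 100 * (m[["outpt"]] - targets$outpt[i]))
  })
  out <- list(cycle_exponent_K = K, outcome_residuals_pp = residuals)
  if (!is.null(cost_target)) {
    pk <- params
    pk$config$cycle_exponent_K <- K
    scale <- calibrate_stable_care_scale(pk, cost_target, cost_anchor)
    out$stable_care_scale <- as.numeric(scale)
    out$cost_residual_mad <- attr(scale, "residual")
    out$cost_scale_clamped <- attr(scale, "clamped")
  }
  jsonlite::write_json(out, file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Run the one-way sensitivity analysis and write the tornado table
#'
#' @param params parameter set or path.
#' @param intervention,comparator arm or group names.
#' @param out_dir output directory.
#' @param range_fraction sweep half-width (default from config).
#' @param parameter_ids optional explicit parameter paths.
#' @return invisibly, the tornado data frame.
#' @export
write_owsa <- function(params, intervention, comparator, out_dir,
                       range_fraction = NULL, parameter_ids = NULL) {
  params <- resolve_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tor <- owsa(params, intervention, comparator,
              parameter_ids = parameter_ids,
              range_fraction = range_fraction %||%
                params$config$owsa_range_fraction)
  man <- build_manifest(params, NA,
                        list(intervention = intervention,
                             comparator = comparator))
  write_report_csv(tor, file.path(out_dir, "tornado.csv"), man$manifest_id)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(tor)
}

#' Run the probabilistic sensitivity analysis and write its files
#'
#' Writes `psa_scatter.csv` (iteration, strategy, cost, qaly) and
#' `ceac.csv` (wtp, strategy, probability); the configured
#' willingness-to-pay threshold is always a grid point.
#'
#' @param params parameter set or path.
#' @param strategies arm or group names to compare (default: all arms).
#' @param out_dir output directory.
#' @param n_iterations iterations (default from config).
#' @param seed RNG seed.
#' @return invisibly, the `psa_result`.
#' @export
write_psa <- function(params, strategies = NULL, out_dir,
                      n_iterations = NULL, seed = 1L) {
  params <- resolve_params(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(params,
                 strategies = strategies %||% names(params$strategies),
                 n_iterations = n_iterations %||%
                   params$config$psa_iterations,
                 seed = seed)
  man <- build_manifest(params, seed,
                        list(n_iterations = psa$n_iterations))
  write_report_csv(psa$draws, file.path(out_dir, "psa_scatter.csv"),
                   man$manifest_id)
  write_report_csv(psa$ceac, file.path(out_dir, "ceac.csv"),
                   man$manifest_id)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(psa)
}
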