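#' Default AUC variants
#'
#' The four variants reported by the workbench: the standard 12-hour AUC,
#' a half-range (first 6 hours) AUC, and early-/late-emphasis weighted
#' AUCs with linearly decreasing/increasing weights.
#'
#' @param t_max window upper bound, minutes.
#' @return named list of [auc_spec()]s.
#' @export
default_auc_specs <- function(t_max = 720) {
  kinds <- c("uniform", "half_range", "linear_decreasing", "linear_increasing")
  setNames(lapply(kinds, function(k) auc_spec(t_max, k)), kinds)
}

#' Default utility specifications
#'
#' U1: elliptical with mid-acuity weighting `lambda = 1.5` and overshoot
#' credit `delta = 0.3`; U2: linear with low-acuity down-weight
#' `alpha = 0.6`. Goals default to full low-acuity attainment and 90%
#' mid-acuity attainment. These are demonstration values, not elicited
#' stakeholder preferences.
#'
#' @param goal_low,goal_mid target attainment proportions.
#' @return named list of [utility_params()].
#' @export
default_utility_params <- function(goal_low = 1, goal_mid = 0.9) {
  list(
    U1 = utility_params("elliptical", goal_low, goal_mid, lambda = 1.5, delta = 0.3),
    U2 = utility_params("linear", goal_low, goal_mid, alpha = 0.6)
  )
}

#' Experiment configuration
#'
#' Bundles everything one comparison run needs: the simulation scenario,
#' the strategies, the cohorts, the threshold grid, the AUC variants, the
#' utility specifications and the fixed thresholds for scatter/cross-utility
#' analysis.
#'
#' @param sim a [sim_config()].
#' @param policies named list of [policy_spec()]s (default: all nine
#'   strategies).
#' @param cohorts named list of [cohort_spec()]s; must include cohorts
#'   named as in `low_cohort`/`mid_cohort` for the utility analyses.
#' @param grid threshold grid.
#' @param auc_specs named list of [auc_spec()]s.
#' @param utilities named list of [utility_params()].
#' @param t_stars fixed thresholds for scatter and cross-utility plots;
#'   each must lie on `grid`.
#' @param low_cohort,mid_cohort names of the cohorts paired in the
#'   utility analyses.
#' @param output_dir directory for CSV/JSON artifacts (`NULL`: in-memory
#'   bundle only).
#' @param seed root seed for the whole experiment.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(sim = sim_config(),
                              policies = lapply(setNames(nm = strategy_names()), make_policy),
                              cohorts = default_cohorts(),
                              grid = default_grid(),
                              auc_specs = default_auc_specs(),
                              utilities = default_utility_params(),
                              t_stars = c(180, 300, 420),
                              low_cohort = "Low Acuity",
                              mid_cohort = "Mid-Acuity",
                              output_dir = NULL,
                              seed = sim$seed) {
  validate_sim_config(sim)
  if (length(policies) < 1) abort("experiment_config: need at least one policy")
  if (length(cohorts) < 1) abort("experiment_config: need at least one cohort")
  for (ts in t_stars) {
    if (!any(abs(grid - ts) < 1e-9))
      abort(sprintf("experiment_config: t* = %g does not lie on the threshold grid", ts))
  }
  if (!low_cohort %in% names(cohorts) || !mid_cohort %in% names(cohorts))
    abort("experiment_config: `low_cohort`/`mid_cohort` must name entries of `cohorts`")
  structure(list(sim = sim, policies = policies, cohorts = cohorts,
                 grid = grid, auc_specs = auc_specs, utilities = utilities,
                 t_stars = as.numeric(t_stars),
                 low_cohort = low_cohort, mid_cohort = mid_cohort,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a full strategy-comparison experiment
#'
#' Simulates (or ingests) one patient log per strategy and applies all
#' three evaluation techniques, producing the full report bundle:
#'
#' * `summary` — tail-aware summary statistics per (strategy, cohort);
#' * `curves` — long-format attainment curves per (strategy, cohort);
#' * `auc` — all AUC variants per (strategy, cohort);
#' * `t_x` — speed to 50/75/90/95% attainment per (strategy, cohort);
#' * `utility_sweep` — utility-vs-threshold curves per strategy and family;
#' * `utility_scatter` — per-strategy attainment pairs and utilities at
#'   each fixed threshold;
#' * `cross_utility` — pairwise utility-family agreement at each fixed
#'   threshold;
#' * `manifest` — seed, configuration hash, cohort sizes, runtime.
#'
#' When `config$output_dir` is set, each element is also written as CSV
#' (manifest as JSON) into that directory.
#'
#' @param config an [experiment_config()].
#' @param logs optional named list of pre-existing patient logs (one per
#'   policy name) to evaluate instead of simulating.
#' @param kpi KPI column to analyse, default `"los"`.
#' @return the report bundle (named list of tibbles plus `manifest`),
#'   invisibly when written to disk.
#' @export
run_experiment <- function(config, logs = NULL, kpi = "los") {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  if (is.null(logs)) {
    logs <- lapply(config$policies, function(p)
      ed_simulate(config$sim, p, seed = config$seed))
  } else {
    missing <- setdiff(names(config$policies), names(logs))
    if (length(missing))
      abort(sprintf("run_experiment: no log supplied for strategy: %s",
                    paste(missing, collapse = ", ")))
    logs <- logs[names(config$policies)]
  }

  summary_tbl <- summary_table(logs, config$cohorts, kpi = kpi)

  curve_rows <- list(); auc_rows <- list(); tx_rows <- list()
  curves_by_strategy <- list()
  for (s in names(logs)) {
    curves_by_strategy[[s]] <- list()
    for (cn in names(config$cohorts)) {
      cv <- attainment_curve(logs[[s]], config$cohorts[[cn]], config$grid,
                             kpi = kpi, strategy = s)
      curve_rows[[paste(s, cn)]] <- tibble::tibble(
        strategy = s, cohort = cn, t = cv$t, value = cv$value)
      for (an in names(config$auc_specs)) {
        auc_rows[[paste(s, cn, an)]] <- tibble::tibble(
          strategy = s, cohort = cn, variant = an,
          auc = auc(cv, config$auc_specs[[an]]))
      }
      tx <- time_to_attainment(cv, c(50, 75, 90, 95))
      tx_rows[[paste(s, cn)]] <- tibble::tibble(
        strategy = s, cohort = cn,
        t50 = tx[["t50"]], t75 = tx[["t75"]], t90 = tx[["t90"]], t95 = tx[["t95"]])
      if (cn == config$low_cohort) curves_by_strategy[[s]]$low <- cv
      if (cn == config$mid_cohort) curves_by_strategy[[s]]$mid <- cv
    }
  }

  sweep_rows <- list(); scatter_rows <- list(); cross_rows <- list()
  for (un in names(config$utilities)) {
    up <- config$utilities[[un]]
    for (s in names(logs)) {
      uc <- utility_curve(curves_by_strategy[[s]]$low,
                          curves_by_strategy[[s]]$mid, up)
      sweep_rows[[paste(un, s)]] <- tibble::tibble(
        strategy = s, family = un, t = uc$t, u = uc$u)
    }
    for (ts in config$t_stars) {
      sc <- utility_scatter(curves_by_strategy, ts, up)
      sc$family <- un
      scatter_rows[[paste(un, ts)]] <- tibble::as_tibble(sc)
    }
  }
  if (length(config$utilities) >= 2) {
    u1 <- config$utilities[[1]]; u2 <- config$utilities[[2]]
    for (ts in config$t_stars) {
      # strategies can tie exactly (e.g. identical fixture logs); the fit is
      # undefined there and the threshold is skipped rather than fatal
      xr <- tryCatch(cross_utility(curves_by_strategy, ts, u1, u2),
                     edflow_degenerate_fit = function(e) NULL)
      if (is.null(xr)) next
      cross_rows[[as.character(ts)]] <- dplyr::mutate(
        xr$points, t_star = ts, slope = xr$slope, intercept = xr$intercept,
        r_squared = xr$r_squared, n_discordant = xr$n_discordant)
    }
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    strategies = names(logs),
    kpi = kpi,
    n_records = vapply(logs, nrow, integer(1)),
    n_censored = vapply(logs, function(l)
      sum(attr(l, "n_censored") %||% NA_integer_), integer(1)),
    runtime_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  bundle <- list(
    logs = logs,
    summary = summary_tbl,
    curves = dplyr::bind_rows(curve_rows),
    auc = dplyr::bind_rows(auc_rows),
    t_x = dplyr::bind_rows(tx_rows),
    utility_sweep = dplyr::bind_rows(sweep_rows),
    utility_scatter = dplyr::bind_rows(scatter_rows),
    cross_utility = dplyr::bind_rows(cross_rows),
    manifest = manifest
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(x, file.path(config$output_dir, f),
                                          row.names = FALSE)
    wr(bundle$summary, "summary.csv")
    wr(bundle$curves, "curves.csv")
    wr(bundle$auc, "auc.csv")
    wr(bundle$t_x, "t_x.csv")
    wr(bundle$utility_sweep, "utility_sweep.csv")
    wr(bundle$utility_scatter, "utility_scatter.csv")
    if (nrow(bundle$cross_utility %||% tibble::tibble()))
      wr(bundle$cross_utility, "cross_utility.csv")
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(bundle))
  }
  bundle
}
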