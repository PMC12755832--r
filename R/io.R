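log_columns <- c("patient_id", "replication_id", "esi", "arrival_time",
                 "service_start", "departure_time", "physician_id")

#' Write / read a patient event log
#'
#' CSV schema: `patient_id,replication_id,esi,arrival_time,service_start,`
#' `departure_time,physician_id`, times in minutes as decimals (preserved
#' to better than 1e-6 min). The reader validates per-record time ordering
#' (`arrival <= service_start <= departure`) and reports the offending row
#' on failure; derived `wait` and `los` columns are recomputed on read, so
#' a write/read round trip is lossless for every stored field. An empty
#' file with a header reads as an empty log.
#'
#' @param records patient-log tibble (extra columns are dropped on write).
#' @param path file path.
#' @return `read_patient_log()` returns the log tibble; `write_patient_log()`
#'   returns `path` invisibly.
#' @export
write_patient_log <- function(records, path) {
  missing <- setdiff(log_columns, names(records))
  if (length(missing))
    abort(sprintf("write_patient_log: missing column(s): %s",
                  paste(missing, collapse = ", ")))
  df <- as.data.frame(records[, log_columns])
  for (col in c("arrival_time", "service_start", "departure_time"))
    df[[col]] <- sprintf("%.8f", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_patient_log
#' @export
read_patient_log <- function(path) {
  if (!file.exists(path)) abort(sprintf("read_patient_log: no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(log_columns, names(df))
  if (length(missing))
    abort(sprintf("read_patient_log: missing column(s): %s",
                  paste(missing, collapse = ", ")))
  if (nrow(df)) {
    bad <- which(df$arrival_time > df$service_start + 1e-9 |
                   df$service_start > df$departure_time + 1e-9)
    if (length(bad))
      abort(sprintf("read_patient_log: non-monotone times (arrival <= start <= departure) at row %d",
                    bad[1]))
    if (!all(df$esi %in% 1:5))
      abort(sprintf("read_patient_log: invalid ESI level at row %d",
                    which(!df$esi %in% 1:5)[1]))
  }
  out <- tibble::as_tibble(df[, log_columns])
  out$wait <- out$service_start - out$arrival_time
  out$los <- out$departure_time - out$arrival_time
  out
}

# ---- scenario files -------------------------------------------------------

sim_config_keys <- c("n_beds", "n_physicians", "physician_capacity",
                     "arrival_rate", "rate_profile", "esi_mix",
                     "service_params", "service_floor", "workload_sensitivity",
                     "warmup", "horizon", "replications", "seed")
policy_keys <- c("name", "base", "addons", "acuity_weights", "aapq_epsilon",
                 "lwp_delta", "pft_physician")
top_keys <- c("sim", "policies", "cohorts", "grid", "auc", "utilities",
              "t_stars", "output_dir", "seed")

reject_unknown <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    abort(sprintf("config error in `%s`: unknown key(s): %s",
                  where, paste(unknown, collapse = ", ")),
          class = "edflow_config_error")
}

parse_service_params <- function(lst) {
  if (length(lst) != 5)
    abort("config error in `sim.service_params`: need 5 entries (ESI 1..5)",
          class = "edflow_config_error")
  lapply(lst, function(sp) do.call(service_spec, sp))
}

parse_policy_entry <- function(p) {
  if (is.character(p)) return(make_policy(p))
  reject_unknown(p, policy_keys, "policies")
  if (!is.null(p$acuity_weights)) p$acuity_weights <- unlist(p$acuity_weights)
  if (!is.null(p$addons)) p$addons <- unlist(p$addons)
  if (!is.null(p$name) && is.null(p$base)) {
    nm <- p$name; p$name <- NULL
    return(do.call(make_policy, c(list(nm), p)))
  }
  do.call(policy_spec, p)
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file into an [experiment_config()]. Recognized
#' top-level keys: `sim` ([sim_config()] fields), `policies` (strategy
#' names or full policy specs), `cohorts` (name -> ESI levels), `grid`
#' (`from`/`to`/`by`), `auc` (`t_max`, `kinds`), `utilities` (name ->
#' [utility_params()] fields), `t_stars`, `output_dir`, `seed`. Unknown
#' keys are rejected with the offending key named; defaults fill every
#' omitted field.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("load_config: no such file: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  reject_unknown(raw, top_keys, "top level")
  sim_args <- raw$sim %||% list()
  reject_unknown(sim_args, sim_config_keys, "sim")
  if (!is.null(sim_args$esi_mix)) sim_args$esi_mix <- unlist(sim_args$esi_mix)
  if (!is.null(sim_args$rate_profile)) sim_args$rate_profile <- unlist(sim_args$rate_profile)
  if (!is.null(sim_args$service_params))
    sim_args$service_params <- parse_service_params(sim_args$service_params)
  sim <- do.call(sim_config, sim_args)

  policies <- if (is.null(raw$policies)) {
    lapply(setNames(nm = strategy_names()), make_policy)
  } else {
    pl <- lapply(raw$policies, parse_policy_entry)
    setNames(pl, vapply(pl, function(p) p$name, character(1)))
  }
  cohorts <- if (is.null(raw$cohorts)) default_cohorts() else {
    lapply(setNames(nm = names(raw$cohorts)),
           function(nm) cohort_spec(nm, unlist(raw$cohorts[[nm]])))
  }
  grid <- if (is.null(raw$grid)) default_grid() else {
    reject_unknown(raw$grid, c("from", "to", "by"), "grid")
    seq(raw$grid$from %||% 0, raw$grid$to %||% 720, by = raw$grid$by %||% 5)
  }
  aucs <- if (is.null(raw$auc)) default_auc_specs() else {
    reject_unknown(raw$auc, c("t_max", "kinds"), "auc")
    t_max <- raw$auc$t_max %||% 720
    kinds <- unlist(raw$auc$kinds %||% c("uniform", "half_range",
                                         "linear_decreasing", "linear_increasing"))
    setNames(lapply(kinds, function(k) auc_spec(t_max, k)), kinds)
  }
  utilities <- if (is.null(raw$utilities)) default_utility_params() else {
    lapply(setNames(nm = names(raw$utilities)),
           function(nm) do.call(utility_params, raw$utilities[[nm]]))
  }
  experiment_config(sim = sim, policies = policies, cohorts = cohorts,
                    grid = grid, auc_specs = aucs, utilities = utilities,
                    t_stars = unlist(raw$t_stars %||% c(180, 300, 420)),
                    output_dir = raw$output_dir,
                    seed = raw$seed %||% sim$seed)
}

#' Write an experiment configuration as YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(cfg, path))`
#' reproduces `cfg` exactly.
#'
#' @param config an [experiment_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  sim <- config$sim
  sp <- lapply(sim$service_params, function(s) unclass(s))
  pol <- lapply(unname(config$policies), function(p) {
    list(name = p$name, base = p$base, addons = as.list(p$addons),
         acuity_weights = as.list(setNames(unname(p$acuity_weights),
                                           names(p$acuity_weights))),
         aapq_epsilon = p$aapq_epsilon, lwp_delta = p$lwp_delta,
         pft_physician = p$pft_physician)
  })
  out <- list(
    sim = list(n_beds = sim$n_beds, n_physicians = sim$n_physicians,
               physician_capacity = sim$physician_capacity,
               arrival_rate = sim$arrival_rate,
               rate_profile = sim$rate_profile,
               esi_mix = as.list(sim$esi_mix), service_params = sp,
               service_floor = sim$service_floor,
               workload_sensitivity = sim$workload_sensitivity,
               warmup = sim$warmup,
               horizon = sim$horizon, replications = sim$replications,
               seed = sim$seed),
    policies = pol,
    cohorts = lapply(config$cohorts, function(co) as.list(co$esi_levels)),
    grid = list(from = min(config$grid), to = max(config$grid),
                by = config$grid[2] - config$grid[1]),
    auc = list(t_max = config$auc_specs[[1]]$t_max,
               kinds = as.list(vapply(config$auc_specs, function(a) a$weight_kind,
                                      character(1)))),
    utilities = lapply(config$utilities, function(u) unclass(u)),
    t_stars = as.list(config$t_stars),
    output_dir = config$output_dir,
    seed = config$seed
  )
  out$sim$rate_profile <- sim$rate_profile # NULL drops the key
  yaml::write_yaml(out, path)
  invisible(path)
}
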