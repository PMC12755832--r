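#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one root seed through named
#' substreams (arrivals/service share the simulation stream; bootstrap and
#' fixture generation use their own), so that e.g. adding bootstrap
#' replicates never perturbs the simulated logs.
#'
#' @param root integer root seed.
#' @param name substream label.
#' @param index replication index (>= 0).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(root, name, index = 0L) {
  m <- 2147483647
  h <- as.numeric(root) %% m
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% m
  h <- (h * 31 + as.numeric(index) + 7) %% m
  as.integer(max(h, 1))
}

#' Simulate the ED under one prioritization policy
#'
#' Runs the discrete-event model for `config$replications` independent
#' replications and returns the patient event log of every patient who
#' arrived after the warmup window and departed before the horizon.
#' Patients still waiting or in service when the clock stops are censored:
#' they are counted (see attributes) but excluded from the log, so KPI
#' analyses are never contaminated by truncated stays. ESI-1 patients are
#' present in the log but are conventionally excluded from cohort analyses
#' downstream.
#'
#' @param config a [sim_config()].
#' @param policy an [policy_spec()] / [make_policy()] object.
#' @param seed root seed; defaults to `config$seed`. Replication `r` uses
#'   the substream seed `substream_seed(seed, "sim", r)`.
#' @return a tibble with columns `patient_id`, `replication_id`, `esi`,
#'   `arrival_time`, `service_start`, `departure_time`, `physician_id`,
#'   `wait`, `los` (all times in minutes), and attributes `n_arrivals`,
#'   `n_censored`, `n_warmup` (per-replication integer vectors).
#' @examples
#' cfg <- sim_config(horizon = 3000, warmup = 500, replications = 1)
#' log <- ed_simulate(cfg, make_policy("FCFS"), seed = 42)
#' head(log)
#' @export
ed_simulate <- function(config, policy, seed = config$seed) {
  validate_sim_config(config)
  stopifnot(inherits(policy, "ed_policy"))
  eps_reach <- policy$aapq_epsilon * config$horizon
  min_gap <- min(abs(diff(policy$acuity_weights)))
  if (policy$base == "AAPQ" && eps_reach >= min_gap)
    abort(paste0("policy error: `aapq_epsilon` x horizon = ", signif(eps_reach, 3),
                 " reaches the smallest acuity-weight gap (", min_gap,
                 "); the elapsed term would override acuity order"),
          class = "edflow_config_error")
  if (!is.null(policy$pft_physician) && policy$pft_physician >= config$n_physicians)
    abort(sprintf("policy error: `pft_physician` = %d but only %d physicians exist",
                  policy$pft_physician, config$n_physicians),
          class = "edflow_config_error")
  ccfg <- config_to_cpp(config)
  cpol <- policy_to_cpp(policy)

  out <- vector("list", config$replications)
  n_arrivals <- n_censored <- n_warmup <- integer(config$replications)
  for (r in seq_len(config$replications)) {
    set.seed(substream_seed(seed, "sim", r))
    raw <- cpp_simulate(ccfg, cpol)
    rec <- tibble::tibble(
      patient_id = raw$patient_id,
      replication_id = r,
      esi = raw$esi,
      arrival_time = raw$arrival_time,
      service_start = raw$service_start,
      departure_time = raw$departure_time,
      physician_id = raw$physician_id
    )
    n_arrivals[r] <- raw$n_arrivals
    censored <- is.na(rec$departure_time)
    n_censored[r] <- sum(censored)
    warm <- rec$arrival_time < config$warmup
    n_warmup[r] <- sum(warm & !censored)
    rec <- rec[!censored & !warm, , drop = FALSE]
    rec$wait <- rec$service_start - rec$arrival_time
    rec$los <- rec$departure_time - rec$arrival_time
    out[[r]] <- rec
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_arrivals") <- n_arrivals
  attr(res, "n_censored") <- n_censored
  attr(res, "n_warmup") <- n_warmup
  attr(res, "strategy") <- policy$name
  res
}

#' Simulate all strategies of a comparison
#'
#' @param config a [sim_config()].
#' @param policies named list of policies; default all nine of
#'   [strategy_names()]. Every policy is run from the same root seed, so a
#'   comparison is reproducible end to end.
#' @param seed root seed; defaults to `config$seed`.
#' @return named list of patient-log tibbles.
#' @export
ed_simulate_all <- function(config,
                            policies = lapply(setNames(nm = strategy_names()), make_policy),
                            seed = config$seed) {
  lapply(policies, function(p) ed_simulate(config, p, seed = seed))
}

#' Realize the arrival process
#'
#' Draws one stream of (time, ESI) arrivals over `[0, horizon]` from the
#' configured stationary or 24-hour-profile Poisson process.
#'
#' @inheritParams ed_simulate
#' @return tibble with columns `time` (minutes) and `esi`.
#' @export
generate_arrivals <- function(config, seed = config$seed) {
  validate_sim_config(config)
  ccfg <- config_to_cpp(config)
  set.seed(substream_seed(seed, "arrivals"))
  tibble::as_tibble(cpp_generate_arrivals(
    ccfg$arrival_rate_per_min, ccfg$rate_profile_per_min,
    ccfg$esi_mix, ccfg$horizon))
}

#' Draw service times for one ESI level
#'
#' @inheritParams ed_simulate
#' @param esi ESI level 1..5.
#' @param n number of draws.
#' @return numeric vector of durations (minutes), each at least
#'   `config$service_floor`.
#' @export
sample_service_time <- function(config, esi, n = 1, seed = NULL) {
  validate_sim_config(config)
  if (!esi %in% 1:5) abort("sample_service_time: `esi` must be in 1..5")
  ccfg <- config_to_cpp(config)
  if (!is.null(seed)) set.seed(substream_seed(seed, "service", esi))
  cpp_sample_service(as.integer(n), ccfg$service_family[esi],
                     ccfg$service_p1[esi], ccfg$service_p2[esi],
                     ccfg$service_floor)
}
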