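#' Service-time specification for one ESI level
#'
#' @param family one of `"lognormal"`, `"exponential"`, `"fixed"`.
#' @param mean mean duration in minutes (lognormal, exponential). For the
#'   lognormal family the `meanlog` parameter is derived as
#'   `log(mean) - sdlog^2/2`, so `mean` is the distribution mean before the
#'   minimum-duration floor is applied.
#' @param sdlog log-scale standard deviation (lognormal only).
#' @param value point mass in minutes (fixed only).
#' @return a `service_spec` list.
#' @export
service_spec <- function(family = c("lognormal", "exponential", "fixed"),
                         mean = NULL, sdlog = 0.55, value = NULL) {
  family <- match.arg(family)
  if (family == "fixed") {
    if (is.null(value) || value <= 0) abort("service_spec: `value` must be > 0 for the fixed family")
    out <- list(family = family, value = value)
  } else if (family == "exponential") {
    if (is.null(mean) || mean <= 0) abort("service_spec: `mean` must be > 0")
    out <- list(family = family, mean = mean)
  } else {
    if (is.null(mean) || mean <= 0) abort("service_spec: `mean` must be > 0")
    if (sdlog <= 0) abort("service_spec: `sdlog` must be > 0")
    out <- list(family = family, mean = mean, sdlog = sdlog)
  }
  structure(out, class = "service_spec")
}

# default per-ESI service calibration: lognormal, minutes.
# Means are chosen so that, with the default arrival process and staffing,
# the simulated FCFS low-acuity mean LOS lands near 170 min in a
# moderately congested 30-bed ED; see the methods vignette.
default_service_params <- function() {
  list(
    service_spec("lognormal", mean = 230, sdlog = 0.55),
    service_spec("lognormal", mean = 192, sdlog = 0.55),
    service_spec("lognormal", mean = 177, sdlog = 0.55),
    service_spec("lognormal", mean = 101, sdlog = 0.55),
    service_spec("lognormal", mean = 87,  sdlog = 0.55)
  )
}

#' Simulation configuration for the mixed-acuity ED model
#'
#' Defines the resources, arrival process, per-ESI service-time
#' distributions and run lengths of the discrete-event model. Defaults
#' describe a moderately congested 30-bed mixed-acuity ED.
#'
#' @param n_beds number of treatment beds.
#' @param n_physicians number of physicians on shift (at least 2; the
#'   workload-balancing and fast-track add-ons need peers).
#' @param physician_capacity maximum concurrent patients per physician.
#' @param arrival_rate stationary Poisson arrival rate, patients per hour.
#' @param rate_profile optional length-24 vector of per-hour arrival rates
#'   (patients per hour, indexed by hour of day starting at hour 0);
#'   overrides `arrival_rate` when supplied.
#' @param esi_mix probability vector over ESI levels 1 to 5 (must sum to 1).
#' @param service_params list of 5 [service_spec()] objects, one per ESI level.
#' @param service_floor minimum service duration in minutes applied to every
#'   draw (a fixed overhead of rooming, assessment and discharge paperwork).
#' @param workload_sensitivity how strongly a physician's concurrent
#'   caseload slows each patient's progress: a patient starting service
#'   with a physician already caring for `L` others takes
#'   `1 + workload_sensitivity * L / (physician_capacity - 1)` times the
#'   drawn duration. 0 disables the effect (pure slot semantics), in which
#'   case physician identity is a label and workload-balancing rules have
#'   no outcome effect.
#' @param warmup minutes discarded from the start of each replication.
#' @param horizon minutes simulated per replication (`warmup < horizon`).
#' @param replications number of independent replications.
#' @param seed default root seed used when none is passed to [ed_simulate()].
#' @return a validated `sim_config` object.
#' @examples
#' cfg <- sim_config(horizon = 4000, replications = 2)
#' cfg$n_beds
#' @export
sim_config <- function(n_beds = 30,
                       n_physicians = 4,
                       physician_capacity = 10,
                       arrival_rate = 7,
                       rate_profile = NULL,
                       esi_mix = c(0.03, 0.08, 0.13, 0.45, 0.31),
                       service_params = default_service_params(),
                       service_floor = 32,
                       workload_sensitivity = 1.2,
                       warmup = 2880,
                       horizon = 13680,
                       replications = 10,
                       seed = 1L) {
  cfg <- structure(list(
    n_beds = n_beds, n_physicians = n_physicians,
    physician_capacity = physician_capacity,
    arrival_rate = arrival_rate, rate_profile = rate_profile,
    esi_mix = esi_mix, service_params = service_params,
    service_floor = service_floor,
    workload_sensitivity = workload_sensitivity,
    warmup = warmup, horizon = horizon,
    replications = replications, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(key, msg) {
    abort(sprintf("invalid simulation config: `%s` %s", key, msg),
          class = "edflow_config_error")
  }
  if (!is.numeric(cfg$n_beds) || cfg$n_beds < 1) stop_cfg("n_beds", "must be >= 1")
  if (!is.numeric(cfg$n_physicians) || cfg$n_physicians < 2)
    stop_cfg("n_physicians", "must be >= 2")
  if (cfg$physician_capacity < 1) stop_cfg("physician_capacity", "must be >= 1")
  if (is.null(cfg$rate_profile)) {
    if (cfg$arrival_rate <= 0) stop_cfg("arrival_rate", "must be > 0")
  } else {
    if (length(cfg$rate_profile) != 24 || any(cfg$rate_profile < 0) ||
        all(cfg$rate_profile == 0))
      stop_cfg("rate_profile", "must be 24 non-negative hourly rates, not all zero")
  }
  if (length(cfg$esi_mix) != 5 || any(cfg$esi_mix < 0))
    stop_cfg("esi_mix", "must be 5 non-negative probabilities")
  if (abs(sum(cfg$esi_mix) - 1) > 1e-9)
    stop_cfg("esi_mix", sprintf("must sum to 1 (got %.12f)", sum(cfg$esi_mix)))
  if (length(cfg$service_params) != 5 ||
      !all(vapply(cfg$service_params, inherits, logical(1), "service_spec")))
    stop_cfg("service_params", "must be a list of 5 service_spec objects")
  if (cfg$service_floor < 0) stop_cfg("service_floor", "must be >= 0")
  if (cfg$workload_sensitivity < 0)
    stop_cfg("workload_sensitivity", "must be >= 0")
  if (cfg$warmup < 0) stop_cfg("warmup", "must be >= 0")
  if (cfg$horizon <= cfg$warmup) stop_cfg("horizon", "must exceed `warmup`")
  if (cfg$replications < 1) stop_cfg("replications", "must be >= 1")
  invisible(cfg)
}

# flatten to the representation the C++ engine consumes (rates per minute)
config_to_cpp <- function(cfg) {
  fam_code <- c(lognormal = 0L, exponential = 1L, fixed = 2L)
  fams <- integer(5); p1 <- numeric(5); p2 <- numeric(5)
  for (i in 1:5) {
    sp <- cfg$service_params[[i]]
    fams[i] <- fam_code[[sp$family]]
    if (sp$family == "lognormal") {
      p1[i] <- log(sp$mean) - sp$sdlog^2 / 2
      p2[i] <- sp$sdlog
    } else if (sp$family == "exponential") {
      p1[i] <- sp$mean; p2[i] <- 0
    } else {
      p1[i] <- sp$value; p2[i] <- 0
    }
  }
  list(
    n_beds = as.integer(cfg$n_beds),
    n_physicians = as.integer(cfg$n_physicians),
    physician_capacity = as.integer(cfg$physician_capacity),
    arrival_rate_per_min = cfg$arrival_rate / 60,
    rate_profile_per_min = if (is.null(cfg$rate_profile)) numeric(0)
                           else cfg$rate_profile / 60,
    esi_mix = as.numeric(cfg$esi_mix),
    service_family = fams, service_p1 = p1, service_p2 = p2,
    service_floor = cfg$service_floor,
    workload_sensitivity = cfg$workload_sensitivity,
    horizon = cfg$horizon
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  beds: %d | physicians: %d x capacity %d\n",
              x$n_beds, x$n_physicians, x$physician_capacity))
  if (is.null(x$rate_profile)) {
    cat(sprintf("  arrivals: stationary Poisson %.2f/h\n", x$arrival_rate))
  } else {
    cat("  arrivals: 24-h rate profile\n")
  }
  cat(sprintf("  ESI mix: %s\n", paste(x$esi_mix, collapse = " / ")))
  cat(sprintf("  warmup %g min, horizon %g min, %d replication(s)\n",
              x$warmup, x$horizon, x$replications))
  invisible(x)
}
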