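# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# M/M/c mean waiting time (Erlang-C closed form)
erlang_c_wq <- function(c, lambda, mean_service) {
  a <- lambda * mean_service
  rho <- a / c
  stopifnot(rho < 1)
  p0_inv <- sum(a^(0:(c - 1)) / factorial(0:(c - 1))) +
    a^c / (factorial(c) * (1 - rho))
  C <- (a^c / (factorial(c) * (1 - rho))) / p0_inv
  C / (c / mean_service - lambda)
}

# type-7 (linear interpolation) quantile computed from first principles
quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  }, numeric(1))
}

# dense-grid trapezoid integral of the piecewise-linear curve, the AUC oracle
riemann_auc <- function(t, v, t_max, w = function(x) rep(1 / t_max, length(x)),
                        step = 0.1) {
  g <- seq(0, t_max, by = step)
  vg <- approx(t, v, xout = g, rule = 2)$y * w(g)
  sum((vg[-1] + vg[-length(vg)]) / 2 * diff(g))
}

# brute-force lexicographic (acuity, elapsed, id) pick for AAPQ equivalence
lex_pick <- function(waiting, now) {
  ord <- order(waiting$esi, -(now - waiting$arrival_time), waiting$patient_id)
  waiting$patient_id[ord[1]]
}

# random queue snapshot generator for policy property tests
random_snapshot <- function(n_wait, n_phys = 4, capacity = 10, seed = NULL,
                            esi_range = 2:5) {
  if (!is.null(seed)) set.seed(seed)
  waiting <- data.frame(
    patient_id = sample.int(1000, n_wait),
    esi = sample(esi_range, n_wait, replace = TRUE),
    arrival_time = round(runif(n_wait, 0, 500), 3)
  )
  queue_snapshot(
    now = 600,
    waiting = waiting,
    physician_loads = sample(0:capacity, n_phys, replace = TRUE),
    capacity = capacity,
    free_beds = sample(1:5, 1)
  )
}

# tiny uncalibrated config for fast simulator tests
small_config <- function(...) {
  args <- utils::modifyList(list(warmup = 200, horizon = 2200, replications = 2),
                            list(...))
  do.call(sim_config, args)
}
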