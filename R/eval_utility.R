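#' Stakeholder utility parameters
#'
#' Maps a pair of cohort attainment proportions (low- and mid-acuity) to a
#' scalar utility in `[0, 1]` under stated goals. Two families:
#'
#' * `elliptical` (U1): with overshoot-credited attainment
#'   `v' = min(v, g) + delta * max(0, v - g)` and relative deficit
#'   `e = max(0, (g - v') / g)` per cohort,
#'   `u = 1 - sqrt((e_L^2 + lambda^2 e_M^2) / (1 + lambda^2))`.
#'   Iso-utility loci are ellipse arcs in deficit space; `lambda > 1`
#'   penalizes mid-acuity shortfall more than low-acuity shortfall, and
#'   `delta` grants partial credit for overshooting a goal (never pushing
#'   utility above 1).
#' * `linear` (U2):
#'   `u = (alpha * min(v_L, g_L)/g_L + min(v_M, g_M)/g_M) / (alpha + 1)`.
#'   `alpha < 1` down-weights the low-acuity cohort; attainment beyond a
#'   goal earns no extra credit.
#'
#' Both families give `u = 1` exactly when both goals are met and `u = 0`
#' at zero attainment.
#'
#' @param family `"elliptical"` or `"linear"`.
#' @param goal_low,goal_mid target attainment proportions in `(0, 1]`.
#' @param lambda mid-acuity weighting, elliptical family (> 0).
#' @param delta overshoot credit factor, elliptical family, in `[0, 1]`.
#' @param alpha low-acuity down-weight, linear family, in `(0, 1]`.
#' @return a `utility_params` object.
#' @export
utility_params <- function(family = c("elliptical", "linear"),
                           goal_low = 1, goal_mid = 0.9,
                           lambda = 1.5, delta = 0.3, alpha = 0.6) {
  family <- match.arg(family)
  if (goal_low <= 0 || goal_low > 1 || goal_mid <= 0 || goal_mid > 1)
    abort("utility_params: goals must lie in (0, 1]")
  if (lambda <= 0) abort("utility_params: `lambda` must be > 0")
  if (delta < 0 || delta > 1) abort("utility_params: `delta` must lie in [0, 1]")
  if (alpha <= 0 || alpha > 1) abort("utility_params: `alpha` must lie in (0, 1]")
  structure(list(family = family, goal_low = goal_low, goal_mid = goal_mid,
                 lambda = lambda, delta = delta, alpha = alpha),
            class = "utility_params")
}

check_attain <- function(v, what) {
  if (any(v < -1e-12 | v > 1 + 1e-12))
    abort(sprintf("utility: `%s` must lie in [0, 1]", what))
  pmin(pmax(v, 0), 1)
}

#' Linear stakeholder utility (U2)
#'
#' @param v_low,v_mid attainment proportions in `[0, 1]` (vectorised).
#' @param params a [utility_params()] with `family = "linear"`.
#' @return utilities in `[0, 1]`.
#' @export
utility_linear <- function(v_low, v_mid, params) {
  stopifnot(inherits(params, "utility_params"))
  if (params$family != "linear") abort("utility_linear: params family is not \"linear\"")
  v_low <- check_attain(v_low, "v_low"); v_mid <- check_attain(v_mid, "v_mid")
  (params$alpha * pmin(v_low, params$goal_low) / params$goal_low +
     pmin(v_mid, params$goal_mid) / params$goal_mid) / (params$alpha + 1)
}

#' Elliptical stakeholder utility (U1)
#'
#' @inheritParams utility_linear
#' @param params a [utility_params()] with `family = "elliptical"`.
#' @return utilities in `[0, 1]`.
#' @export
utility_elliptical <- function(v_low, v_mid, params) {
  stopifnot(inherits(params, "utility_params"))
  if (params$family != "elliptical")
    abort("utility_elliptical: params family is not \"elliptical\"")
  v_low <- check_attain(v_low, "v_low"); v_mid <- check_attain(v_mid, "v_mid")
  eff <- function(v, g) pmin(v, g) + params$delta * pmax(0, v - g)
  e_l <- pmax(0, (params$goal_low - eff(v_low, params$goal_low)) / params$goal_low)
  e_m <- pmax(0, (params$goal_mid - eff(v_mid, params$goal_mid)) / params$goal_mid)
  1 - sqrt((e_l^2 + params$lambda^2 * e_m^2) / (1 + params$lambda^2))
}

#' Evaluate a utility family
#'
#' Dispatches to [utility_elliptical()] or [utility_linear()] per
#' `params$family`.
#'
#' @inheritParams utility_linear
#' @export
utility_value <- function(v_low, v_mid, params) {
  switch(params$family,
         elliptical = utility_elliptical(v_low, v_mid, params),
         linear = utility_linear(v_low, v_mid, params))
}

#' Utility along the threshold grid
#'
#' Tracks `U(T_low(t), T_mid(t))` along the shared grid of two attainment
#' curves, revealing how the stakeholder value of each strategy evolves
#' with the time target.
#'
#' @param curve_low,curve_mid [attainment_curve()]s for the low- and
#'   mid-acuity cohorts of the same strategy, on an identical grid.
#' @param params a [utility_params()].
#' @return tibble with columns `t`, `u` and attributes `strategy`, `family`.
#' @export
utility_curve <- function(curve_low, curve_mid, params) {
  if (length(curve_low$t) != length(curve_mid$t) ||
      any(curve_low$t != curve_mid$t))
    abort("utility_curve: curves must share an identical threshold grid")
  s1 <- attr(curve_low, "strategy"); s2 <- attr(curve_mid, "strategy")
  if (!is.na(s1) && !is.na(s2) && !identical(s1, s2))
    abort("utility_curve: curves belong to different strategies")
  out <- tibble::tibble(t = curve_low$t,
                        u = utility_value(curve_low$value, curve_mid$value, params))
  attr(out, "strategy") <- s1
  attr(out, "family") <- params$family
  out
}

curve_value_at <- function(curve, t_star) {
  i <- which(abs(curve$t - t_star) < 1e-9)
  if (length(i) == 0)
    abort(sprintf("threshold t* = %g is not a point of the curve grid", t_star))
  curve$value[i[1]]
}

#' Strategy scatter at a fixed threshold
#'
#' For each strategy, the point `(T_low(t*), T_mid(t*))` with its utility,
#' plus the contour levels at which `U(.) = c` iso-lines would be drawn.
#' The axes stay raw attainment proportions; utility enters only through
#' point colouring and contours.
#'
#' @param curves named list (one element per strategy), each a list with
#'   components `low` and `mid` holding that strategy's
#'   [attainment_curve()]s.
#' @param t_star threshold, must be a grid point of every curve.
#' @param params a [utility_params()].
#' @param contour_levels utility levels for contour drawing.
#' @return tibble of class `utility_scatter` with columns `strategy`,
#'   `t_star`, `v_low`, `v_mid`, `u`; attribute `contour_levels`.
#' @export
utility_scatter <- function(curves, t_star, params,
                            contour_levels = seq(0.1, 0.9, by = 0.1)) {
  if (length(curves) == 0) abort("utility_scatter: no strategies supplied")
  rows <- lapply(names(curves), function(s) {
    vl <- curve_value_at(curves[[s]]$low, t_star)
    vm <- curve_value_at(curves[[s]]$mid, t_star)
    tibble::tibble(strategy = s, t_star = t_star, v_low = vl, v_mid = vm,
                   u = utility_value(vl, vm, params))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "contour_levels") <- contour_levels
  attr(out, "family") <- params$family
  class(out) <- c("utility_scatter", class(out))
  out
}

#' Cross-utility robustness comparison
#'
#' Scores every strategy under two utility specifications at a fixed
#' threshold and quantifies their agreement: an ordinary-least-squares fit
#' of `u2` on `u1` (slope, intercept, R^2) and the number of discordant
#' strategy pairs (pairs ranked in opposite order by the two
#' specifications). Near-linear, positively sloped alignment with no
#' discordant pairs means the strategy ordering is robust to the utility
#' choice.
#'
#' @inheritParams utility_scatter
#' @param params_1,params_2 two [utility_params()] objects.
#' @return list with `points` (tibble: `strategy`, `u1`, `u2`), `slope`,
#'   `intercept`, `r_squared`, `n_discordant`, `n_pairs`.
#' @export
cross_utility <- function(curves, t_star, params_1, params_2) {
  if (length(curves) < 2) abort("cross_utility: need at least 2 strategies")
  s1 <- utility_scatter(curves, t_star, params_1)
  s2 <- utility_scatter(curves, t_star, params_2)
  pts <- tibble::tibble(strategy = s1$strategy, u1 = s1$u, u2 = s2$u)
  if (max(pts$u1) - min(pts$u1) < 1e-12)
    abort("cross_utility: all `u1` values identical; least-squares fit undefined",
          class = "edflow_degenerate_fit")
  fit <- lm(u2 ~ u1, data = pts)
  n <- nrow(pts)
  disc <- 0L; npair <- 0L
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    d1 <- pts$u1[i] - pts$u1[j]; d2 <- pts$u2[i] - pts$u2[j]
    npair <- npair + 1L
    if (d1 * d2 < 0) disc <- disc + 1L
  }
  list(points = pts,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_discordant = disc, n_pairs = npair)
}
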