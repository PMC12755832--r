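#' Default threshold grid
#'
#' 0 to 720 minutes (12 hours) in 5-minute steps — the window over which
#' LOS targets are clinically meaningful for low- and mid-acuity ED care.
#'
#' @return numeric vector of thresholds (minutes).
#' @export
default_grid <- function() seq(0, 720, by = 5)

#' Threshold attainment
#'
#' The proportion of a cohort whose KPI value is below threshold `t`:
#' `T_P(t) = (1/|P|) * sum 1{M_i < t}`. The inequality is strict by
#' default; with continuous KPIs and a 5-minute grid the difference from
#' `<=` is negligible, but the convention is exposed via `strict` because
#' it matters for degenerate (tied) fixtures.
#'
#' @param records patient log.
#' @param cohort a [cohort_spec()].
#' @param t threshold(s), minutes.
#' @param kpi KPI column name, default `"los"`.
#' @param strict logical; `TRUE` counts `M_i < t`, `FALSE` counts `M_i <= t`.
#' @return attainment proportion(s) in `[0, 1]`.
#' @examples
#' log <- make_fixture_log(fixture_spec(low = c(100, 200, 300)))
#' attainment(log, cohort_spec("Low", 4:5), 250)  # 2/3
#' @export
attainment <- function(records, cohort, t, kpi = "los", strict = TRUE) {
  x <- cohort_values(records, cohort, kpi)
  vapply(t, function(ti) if (strict) mean(x < ti) else mean(x <= ti), numeric(1))
}

#' Threshold-attainment curve
#'
#' Evaluates [attainment()] over a grid of thresholds. The curve is
#' non-decreasing by construction and reaches 1 once the grid passes the
#' largest KPI value in the cohort.
#'
#' @inheritParams attainment
#' @param grid strictly increasing threshold grid, default [default_grid()].
#' @param strategy optional label, defaults to the log's `strategy` attribute.
#' @return a tibble of class `attainment_curve` with columns `t`, `value`
#'   and attributes `strategy`, `cohort`, `kpi`, `strict`.
#' @export
attainment_curve <- function(records, cohort, grid = default_grid(),
                             kpi = "los", strict = TRUE,
                             strategy = attr(records, "strategy") %||% NA_character_) {
  if (any(diff(grid) <= 0)) abort("attainment_curve: `grid` must be strictly increasing")
  vals <- attainment(records, cohort, grid, kpi = kpi, strict = strict)
  new_attainment_curve(grid, vals, strategy = strategy, cohort = cohort$name,
                       kpi = kpi, strict = strict)
}

#' Construct an attainment curve from threshold/value pairs
#'
#' Low-level constructor for curves that do not come from a patient log,
#' e.g. re-assembled from a long-format CSV or built analytically in tests.
#' Validates monotonicity and range.
#'
#' @param t strictly increasing thresholds (minutes).
#' @param value attainment proportions, non-decreasing, in `[0, 1]`.
#' @param strategy,cohort,kpi,strict metadata attributes.
#' @return an `attainment_curve` tibble.
#' @export
new_attainment_curve <- function(t, value, strategy = NA_character_,
                                 cohort = NA_character_, kpi = "los",
                                 strict = TRUE) {
  if (any(diff(t) <= 0)) abort("attainment curve: `t` must be strictly increasing")
  if (any(value < -1e-12 | value > 1 + 1e-12))
    abort("attainment curve: values must lie in [0, 1]")
  if (any(diff(value) < -1e-12))
    abort("attainment curve: values must be non-decreasing in t")
  out <- tibble::tibble(t = as.numeric(t), value = pmin(pmax(value, 0), 1))
  attr(out, "strategy") <- strategy
  attr(out, "cohort") <- cohort
  attr(out, "kpi") <- kpi
  attr(out, "strict") <- strict
  class(out) <- c("attainment_curve", class(out))
  out
}

#' AUC specification
#'
#' Defines the integration window and weighting of the area under a
#' threshold-attainment curve. All variants are standardized so that a
#' curve identically equal to 1 scores 1:
#' * `uniform` — `w(t) = 1/t_max` over `[0, t_max]`;
#' * `half_range` — uniform weight over `[0, t_max/2]`;
#' * `linear_decreasing` — `w(t) = 2 (t_max - t) / t_max^2`, emphasizing
#'   early thresholds;
#' * `linear_increasing` — `w(t) = 2 t / t_max^2`, emphasizing late
#'   thresholds.
#'
#' @param t_max upper integration bound, minutes.
#' @param weight_kind one of the four variants above.
#' @return an `auc_spec`.
#' @export
auc_spec <- function(t_max = 720,
                     weight_kind = c("uniform", "half_range",
                                     "linear_decreasing", "linear_increasing")) {
  weight_kind <- match.arg(weight_kind)
  if (t_max <= 0) abort("auc_spec: `t_max` must be > 0")
  structure(list(t_max = t_max, weight_kind = weight_kind), class = "auc_spec")
}

#' Weighted area under an attainment curve
#'
#' Integrates `w(t) * T(t)` over the spec's window, treating the curve as
#' piecewise linear between grid points. Each segment is integrated
#' exactly (Simpson's rule, exact for the quadratic product of two linear
#' pieces), so the result is deterministic and oracle-checkable. Values lie
#' in `[0, 1]`; 1 means every patient attains every threshold in the
#' window.
#'
#' @param curve an [attainment_curve()] (or any data frame with `t`, `value`).
#' @param spec an [auc_spec()].
#' @return standardized AUC in `[0, 1]`.
#' @examples
#' lin <- new_attainment_curve(seq(0, 720, 5), seq(0, 720, 5) / 720)
#' auc(lin, auc_spec(720, "uniform"))            # 0.5
#' auc(lin, auc_spec(720, "linear_increasing"))  # 2/3
#' @export
auc <- function(curve, spec = auc_spec()) {
  stopifnot(inherits(spec, "auc_spec"))
  t_hi <- if (spec$weight_kind == "half_range") spec$t_max / 2 else spec$t_max
  tt <- curve$t; vv <- curve$value
  if (min(tt) > 0 || max(tt) < t_hi)
    abort(sprintf("auc: curve grid [%g, %g] does not cover [0, %g]; no extrapolation",
                  min(tt), max(tt), t_hi))
  w <- switch(spec$weight_kind,
    uniform           = function(t) rep(1 / t_hi, length(t)),
    half_range        = function(t) rep(1 / t_hi, length(t)),
    linear_decreasing = function(t) 2 * (spec$t_max - t) / spec$t_max^2,
    linear_increasing = function(t) 2 * t / spec$t_max^2)
  # knots: grid points inside the window, with interpolated endpoints
  inside <- tt > 0 & tt < t_hi
  knots <- sort(unique(c(0, tt[inside], t_hi)))
  Tk <- stats::approx(tt, vv, xout = knots, rule = 2)$y
  a <- knots[-length(knots)]; b <- knots[-1]
  Ta <- Tk[-length(Tk)]; Tb <- Tk[-1]
  m <- (a + b) / 2
  Tm <- (Ta + Tb) / 2
  seg <- (b - a) / 6 * (w(a) * Ta + 4 * w(m) * Tm + w(b) * Tb)
  sum(seg)
}

#' Speed to X% attainment
#'
#' The smallest grid threshold at which the curve reaches `X/100`
#' (`t_X = min{t : T_P(t) >= X/100}`). When the curve never reaches the
#' level on its grid, the target is not attained within the window and
#' `NA` is returned for that entry (an explicit signal, never a number).
#'
#' @param curve an [attainment_curve()].
#' @param X target percentage(s) in `(0, 100]`.
#' @return named numeric vector of thresholds (minutes), `NA` where the
#'   level is not attained on the grid.
#' @export
time_to_attainment <- function(curve, X) {
  if (any(X <= 0 | X > 100)) abort("time_to_attainment: `X` must be in (0, 100]")
  out <- vapply(X, function(x) {
    hit <- which(curve$value >= x / 100 - 1e-12)
    if (length(hit) == 0) NA_real_ else curve$t[hit[1]]
  }, numeric(1))
  names(out) <- paste0("t", X)
  out
}

#' Bootstrap confidence band for an attainment curve
#'
#' Patient-level resampling with replacement within the cohort; pointwise
#' percentile intervals at the requested level.
#'
#' @inheritParams attainment_curve
#' @param B bootstrap replicates (>= 100).
#' @param level band level, e.g. 0.95.
#' @param seed seed for the bootstrap substream.
#' @return tibble of class `bootstrap_band` with columns `t`, `value`
#'   (point estimate), `lower`, `upper`, and attributes `level`, `B`, `seed`.
#' @export
bootstrap_bands <- function(records, cohort, grid = default_grid(),
                            B = 1000, level = 0.95, seed = 1L,
                            kpi = "los", strict = TRUE) {
  if (B < 100) abort("bootstrap_bands: `B` must be at least 100")
  if (level <= 0 || level >= 1) abort("bootstrap_bands: `level` must be in (0, 1)")
  x <- cohort_values(records, cohort, kpi)
  if (length(x) < 2) abort("bootstrap_bands: cohort must have at least 2 patients")
  if (any(diff(grid) <= 0)) abort("bootstrap_bands: `grid` must be strictly increasing")
  point <- vapply(grid, function(ti) if (strict) mean(x < ti) else mean(x <= ti),
                  numeric(1))
  set.seed(substream_seed(seed, "bootstrap"))
  n <- length(x)
  xs <- sort(x)
  mat <- matrix(0, nrow = B, ncol = length(grid))
  for (b in seq_len(B)) {
    xb <- xs[sample.int(n, n, replace = TRUE)]
    mat[b, ] <- vapply(grid, function(ti) if (strict) mean(xb < ti) else mean(xb <= ti),
                       numeric(1))
  }
  alpha <- (1 - level) / 2
  lower <- apply(mat, 2, quantile, probs = alpha, type = 7, names = FALSE)
  upper <- apply(mat, 2, quantile, probs = 1 - alpha, type = 7, names = FALSE)
  out <- tibble::tibble(t = as.numeric(grid), value = point,
                        lower = pmin(lower, point), upper = pmax(upper, point))
  attr(out, "level") <- level
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "cohort") <- cohort$name
  class(out) <- c("bootstrap_band", class(out))
  out
}
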