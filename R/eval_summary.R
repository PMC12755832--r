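#' Patient cohort definition
#'
#' A cohort is a named subset of ESI levels 2..5. ESI-1 patients always
#' receive immediate treatment regardless of the dispatch rule and are
#' excluded from every cohort analysis by construction.
#'
#' @param name cohort label.
#' @param esi_levels non-empty subset of `2:5`.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(name, esi_levels) {
  esi_levels <- sort(unique(as.integer(esi_levels)))
  if (length(esi_levels) == 0) abort("cohort_spec: `esi_levels` must be non-empty")
  if (1L %in% esi_levels)
    abort("cohort_spec: ESI 1 is excluded from cohort analyses")
  if (!all(esi_levels %in% 2:5))
    abort("cohort_spec: `esi_levels` must be a subset of 2:5")
  structure(list(name = name, esi_levels = esi_levels), class = "cohort_spec")
}

#' Default acuity cohorts
#'
#' Low acuity = ESI 4-5 (the fast-track-eligible group), mid acuity =
#' ESI 2-3, and Overall their union.
#'
#' @return named list of three [cohort_spec()] objects.
#' @export
default_cohorts <- function() {
  list(
    Overall      = cohort_spec("Overall", 2:5),
    `Low Acuity` = cohort_spec("Low Acuity", 4:5),
    `Mid-Acuity` = cohort_spec("Mid-Acuity", 2:3)
  )
}

cohort_values <- function(records, cohort, kpi = "los") {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (!kpi %in% names(records))
    abort(sprintf("KPI column `%s` not found in the patient log", kpi))
  x <- records[[kpi]][records$esi %in% cohort$esi_levels]
  if (length(x) == 0)
    abort(sprintf("empty cohort: no patients with ESI in {%s}",
                  paste(cohort$esi_levels, collapse = ",")),
          class = "edflow_empty_cohort")
  x
}

#' Tail-aware KPI summary for one cohort
#'
#' Reports count, mean, median, the 75th/90th/95th/99th percentiles, sample
#' standard deviation, minimum and maximum of the chosen KPI. Percentiles
#' use linear interpolation between order statistics (`stats::quantile`
#' type 7); the convention matters for the 99th percentile of heavy-tailed
#' KPIs and is therefore fixed and documented rather than left to chance.
#' The standard deviation of a single observation is reported as 0.
#'
#' @param records patient log (from [ed_simulate()], [read_patient_log()]
#'   or [make_fixture_log()]).
#' @param cohort a [cohort_spec()].
#' @param kpi per-patient KPI column, default `"los"`.
#' @param strategy optional strategy label; defaults to the log's
#'   `strategy` attribute.
#' @return one-row tibble with columns `strategy`, `cohort`, `count`,
#'   `mean`, `median`, `p75`, `p90`, `p95`, `p99`, `std`, `min`, `max`.
#' @export
kpi_summary <- function(records, cohort, kpi = "los",
                        strategy = attr(records, "strategy") %||% NA_character_) {
  x <- cohort_values(records, cohort, kpi)
  q <- quantile(x, c(0.5, 0.75, 0.9, 0.95, 0.99), type = 7, names = FALSE)
  tibble::tibble(
    strategy = strategy, cohort = cohort$name,
    count = length(x), mean = mean(x), median = q[1],
    p75 = q[2], p90 = q[3], p95 = q[4], p99 = q[5],
    std = if (length(x) > 1) sd(x) else 0,
    min = min(x), max = max(x)
  )
}

#' Summary table across strategies and cohorts
#'
#' One row per (strategy, cohort) pair, replications pooled. This is the
#' tabular output of the first evaluation technique: central tendency plus
#' explicit upper-tail percentiles, stratified by acuity cohort so that
#' pooling cannot mask cohort-specific differences.
#'
#' @param logs named list of patient logs, one per strategy.
#' @param cohorts list of [cohort_spec()]s, default [default_cohorts()].
#' @param kpi KPI column name.
#' @return tibble with `length(logs) * length(cohorts)` rows.
#' @export
summary_table <- function(logs, cohorts = default_cohorts(), kpi = "los") {
  if (length(logs) == 0) abort("summary_table: `logs` is empty")
  rows <- list()
  for (s in names(logs)) {
    for (co in cohorts) {
      row <- tryCatch(
        kpi_summary(logs[[s]], co, kpi, strategy = s),
        edflow_empty_cohort = function(e)
          abort(sprintf("strategy \"%s\", cohort \"%s\": %s",
                        s, co$name, conditionMessage(e)),
                class = "edflow_empty_cohort")
      )
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-replication summary variant
#'
#' Same statistics as [kpi_summary()] computed separately for each
#' replication, the substrate for replication-level confidence intervals.
#'
#' @inheritParams kpi_summary
#' @return tibble with one row per replication.
#' @export
kpi_summary_by_replication <- function(records, cohort, kpi = "los",
                                       strategy = attr(records, "strategy") %||% NA_character_) {
  reps <- sort(unique(records$replication_id))
  dplyr::bind_rows(lapply(reps, function(r) {
    row <- kpi_summary(records[records$replication_id == r, , drop = FALSE],
                       cohort, kpi, strategy = strategy)
    row$replication_id <- r
    row
  }))
}
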