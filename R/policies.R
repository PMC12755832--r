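#' Prioritization policy specification
#'
#' A dispatch strategy is a base queue discipline plus an ordered set of
#' conditional add-on rules that are consulted before the base rule at every
#' dispatch epoch.
#'
#' Base rules:
#' * `FCFS` — earliest arrival first, acuity ignored.
#' * `ACUITY_FCFS` — highest acuity (lowest ESI number) first, FCFS within a level.
#' * `APQ` — accumulating priority queue: score = acuity weight x elapsed wait.
#' * `AAPQ` — additive APQ: score = acuity weight + epsilon x elapsed wait,
#'   i.e. acuity-first ordering with elapsed time as a tiebreaker whenever
#'   `aapq_epsilon` is small enough that the elapsed term cannot bridge the
#'   gap between adjacent weights.
#'
#' Add-ons (applied in the order given, before the base rule):
#' * `PFT` — partial fast track: one designated physician preferentially
#'   serves waiting ESI 4-5 patients FCFS whenever any are present.
#' * `LWP` — low-workload physician: when one physician's active-patient
#'   count falls `lwp_delta` or more below the mean of the others, the base
#'   rule's top-priority patient is routed to that physician.
#'
#' ESI-1 arrivals are always dispatched ahead of all others, regardless of
#' the policy (they never preempt a patient already in service).
#'
#' @param base base rule name.
#' @param addons character vector, ordered subset of `c("PFT", "LWP")`.
#' @param acuity_weights named positive weights for ESI levels 1 to 5,
#'   strictly decreasing in ESI level number.
#' @param aapq_epsilon per-minute elapsed-time scale for AAPQ (and the APQ
#'   score's units are weight x minutes). Must be small enough that
#'   `aapq_epsilon * horizon` stays below the smallest gap between adjacent
#'   weights, which is validated against the config at simulation time.
#' @param lwp_delta load-imbalance trigger, in patients.
#' @param pft_physician designated fast-track physician id (0-based), or
#'   `NULL` (default) for the last physician of whatever roster the policy
#'   runs against — keeping the fast-track role away from the rotation's
#'   first assignments.
#' @param name optional display label; defaults to `base` plus add-ons.
#' @return an `ed_policy` object.
#' @seealso [make_policy()] for the nine named strategies.
#' @export
policy_spec <- function(base = c("FCFS", "ACUITY_FCFS", "APQ", "AAPQ"),
                        addons = character(),
                        acuity_weights = c(`1` = 32, `2` = 16, `3` = 8, `4` = 2, `5` = 1),
                        aapq_epsilon = 1e-5,
                        lwp_delta = 3,
                        pft_physician = NULL,
                        name = NULL) {
  base <- match.arg(base)
  if (length(addons) && !all(addons %in% c("PFT", "LWP")))
    abort("policy_spec: `addons` must be an ordered subset of c(\"PFT\", \"LWP\")")
  if (anyDuplicated(addons)) abort("policy_spec: duplicated add-on")
  w <- as.numeric(acuity_weights[as.character(1:5)])
  if (anyNA(w) || any(w <= 0))
    abort("policy_spec: `acuity_weights` must give a positive weight to every ESI level 1..5")
  if (any(diff(w) >= 0))
    abort("policy_spec: `acuity_weights` must be strictly decreasing in ESI level number")
  if (aapq_epsilon <= 0) abort("policy_spec: `aapq_epsilon` must be > 0")
  if (lwp_delta <= 0) abort("policy_spec: `lwp_delta` must be > 0")
  if (!is.null(pft_physician) && pft_physician < 0)
    abort("policy_spec: `pft_physician` must be >= 0 (or NULL for the last physician)")
  structure(list(
    name = name %||% paste(c(base, addons), collapse = "+"),
    base = base, addons = addons,
    acuity_weights = setNames(w, 1:5),
    aapq_epsilon = aapq_epsilon,
    lwp_delta = lwp_delta,
    pft_physician = if (is.null(pft_physician)) NULL else as.integer(pft_physician)
  ), class = "ed_policy")
}

#' The nine named prioritization strategies
#'
#' Builds the policy specification for one of the nine strategies compared
#' in the workbench. Standalone `"LWP"` and `"PFT"` layer the add-on over
#' acuity-based FCFS as the base rule. Composite strategies consult PFT
#' first, then LWP, before falling back to the base rule.
#'
#' @param name one of `strategy_names()`.
#' @param ... overrides passed to [policy_spec()] (weights, `lwp_delta`, ...).
#' @return an `ed_policy`.
#' @examples
#' make_policy("AAPQ-LWP-PFT")$addons
#' @export
make_policy <- function(name, ...) {
  specs <- list(
    "FCFS"              = list(base = "FCFS"),
    "Acuity-Based FCFS" = list(base = "ACUITY_FCFS"),
    "APQ"               = list(base = "APQ"),
    "AAPQ"              = list(base = "AAPQ"),
    "LWP"               = list(base = "ACUITY_FCFS", addons = "LWP"),
    "PFT"               = list(base = "ACUITY_FCFS", addons = "PFT"),
    "AAPQ-LWP"          = list(base = "AAPQ", addons = "LWP"),
    "AAPQ-PFT"          = list(base = "AAPQ", addons = "PFT"),
    "AAPQ-LWP-PFT"      = list(base = "AAPQ", addons = c("PFT", "LWP"))
  )
  if (!name %in% names(specs))
    abort(sprintf("unknown strategy \"%s\"; valid names: %s",
                  name, paste(names(specs), collapse = ", ")))
  do.call(policy_spec, c(specs[[name]], list(name = name), list(...)))
}

#' @rdname make_policy
#' @export
strategy_names <- function() {
  c("FCFS", "Acuity-Based FCFS", "APQ", "AAPQ", "LWP", "PFT",
    "AAPQ-LWP", "AAPQ-PFT", "AAPQ-LWP-PFT")
}

# representation consumed by the C++ engine
policy_to_cpp <- function(policy) {
  base_code <- c(FCFS = 0L, ACUITY_FCFS = 1L, APQ = 2L, AAPQ = 3L)
  addon_code <- c(PFT = 0L, LWP = 1L)
  list(
    base_code = base_code[[policy$base]],
    addon_codes = unname(addon_code[policy$addons]),
    weights = unname(policy$acuity_weights),
    aapq_epsilon = policy$aapq_epsilon,
    lwp_delta = policy$lwp_delta,
    pft_physician = policy$pft_physician %||% -1L
  )
}

#' @export
print.ed_policy <- function(x, ...) {
  cat(sprintf("<ed_policy> %s (base %s%s)\n", x$name, x$base,
              if (length(x$addons)) paste0(", add-ons ", paste(x$addons, collapse = " then "))
              else ""))
  invisible(x)
}

#' Accumulating-priority scores
#'
#' `score_apq()` is the multiplicative accumulating-priority score
#' (weight x elapsed wait); `score_aapq()` is the additive variant
#' (weight + epsilon x elapsed wait), which orders patients by acuity first
#' and elapsed wait second whenever epsilon is small enough that the elapsed
#' term cannot bridge the gap between adjacent weights.
#'
#' @param weight positive acuity weight.
#' @param elapsed minutes since arrival (>= 0).
#' @param epsilon per-minute scale of the elapsed term.
#' @return numeric score (vectorised).
#' @examples
#' score_apq(4, 60)          # 240
#' score_aapq(2, 100, 1e-4)  # 2.01
#' @export
score_apq <- function(weight, elapsed) {
  stopifnot(all(weight > 0), all(elapsed >= 0))
  weight * elapsed
}

#' @rdname score_apq
#' @export
score_aapq <- function(weight, elapsed, epsilon) {
  stopifnot(all(weight > 0), all(elapsed >= 0), epsilon > 0)
  weight + epsilon * elapsed
}

#' Queue snapshot at a dispatch epoch
#'
#' The state a policy sees when a bed or physician becomes available.
#'
#' @param now current simulation clock, minutes.
#' @param waiting data frame with columns `patient_id`, `esi`,
#'   `arrival_time`; will be sorted by arrival time (ties by patient id).
#' @param physician_loads integer vector of in-service counts per physician.
#' @param capacity maximum concurrent patients per physician.
#' @param free_beds free treatment beds.
#' @return a `queue_snapshot` object.
#' @export
queue_snapshot <- function(now, waiting, physician_loads, capacity, free_beds) {
  stopifnot(is.data.frame(waiting),
            all(c("patient_id", "esi", "arrival_time") %in% names(waiting)))
  if (any(physician_loads > capacity))
    abort("queue_snapshot: a physician load exceeds `capacity`")
  if (any(physician_loads < 0) || free_beds < 0)
    abort("queue_snapshot: negative loads or free_beds")
  if (nrow(waiting) && any(waiting$arrival_time > now))
    abort("queue_snapshot: a waiting patient arrives after `now`")
  ord <- order(waiting$arrival_time, waiting$patient_id)
  structure(list(
    now = now,
    waiting = tibble::as_tibble(waiting[ord, , drop = FALSE]),
    physician_loads = as.integer(physician_loads),
    capacity = as.integer(capacity),
    free_beds = as.integer(free_beds)
  ), class = "queue_snapshot")
}

#' Dispatch decision at a snapshot
#'
#' Applies the full policy — ESI-1 override, add-ons in order, then the base
#' rule — and returns which waiting patient starts service with which
#' physician, or `NULL` when no dispatch is possible (empty queue, no free
#' bed, or all physicians at capacity). This calls the same compiled routine
#' the simulator uses at every epoch.
#'
#' @param policy an [policy_spec()] object.
#' @param snapshot a [queue_snapshot()].
#' @return `list(patient_id, physician_id)` or `NULL`.
#' @export
select_next <- function(policy, snapshot) {
  stopifnot(inherits(policy, "ed_policy"), inherits(snapshot, "queue_snapshot"))
  res <- cpp_select_next(policy_to_cpp(policy),
                         as.integer(snapshot$waiting$patient_id),
                         as.integer(snapshot$waiting$esi),
                         as.numeric(snapshot$waiting$arrival_time),
                         snapshot$now,
                         snapshot$physician_loads,
                         snapshot$capacity,
                         snapshot$free_beds)
  res
}

#' Add-on checks in isolation
#'
#' `pft_check()` runs only the partial-fast-track test: if the designated
#' physician has spare capacity, a bed is free and at least one ESI 4-5
#' patient waits, the earliest-arrived such patient is routed to the
#' designated physician. `lwp_check()` runs only the low-workload test: if
#' the least-loaded physician's count falls `lwp_delta` or more below the
#' mean load of the others, the base rule's top-priority patient is routed
#' to that physician. Both return `NULL` when the trigger does not fire.
#'
#' These are reference implementations in plain R used to test the
#' composite dispatch path; [select_next()] runs the compiled equivalent.
#'
#' @inheritParams select_next
#' @return `list(patient_id, physician_id)` or `NULL`.
#' @export
pft_check <- function(policy, snapshot) {
  stopifnot("PFT" %in% policy$addons)
  if (snapshot$free_beds < 1 || nrow(snapshot$waiting) == 0) return(NULL)
  d0 <- policy$pft_physician %||% (length(snapshot$physician_loads) - 1L)
  d <- d0 + 1L
  if (d > length(snapshot$physician_loads)) abort("pft_check: designated physician does not exist")
  if (snapshot$physician_loads[d] >= snapshot$capacity) return(NULL)
  low <- snapshot$waiting[snapshot$waiting$esi >= 4, , drop = FALSE]
  if (nrow(low) == 0) return(NULL)
  pick <- low[order(low$arrival_time, low$patient_id)[1], ]
  list(patient_id = pick$patient_id, physician_id = d0)
}

#' @rdname pft_check
#' @export
lwp_check <- function(policy, snapshot) {
  stopifnot("LWP" %in% policy$addons)
  loads <- snapshot$physician_loads
  if (length(loads) < 2) abort("lwp_check: needs at least 2 physicians")
  if (snapshot$free_beds < 1 || nrow(snapshot$waiting) == 0) return(NULL)
  pmin <- which.min(loads)
  mean_others <- (sum(loads) - loads[pmin]) / (length(loads) - 1)
  if (mean_others - loads[pmin] < policy$lwp_delta) return(NULL)
  if (loads[pmin] >= snapshot$capacity) return(NULL)
  base_only <- policy
  base_only$addons <- character()
  pick <- select_next(base_only, snapshot)
  if (is.null(pick)) return(NULL)
  list(patient_id = pick$patient_id, physician_id = pmin - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
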