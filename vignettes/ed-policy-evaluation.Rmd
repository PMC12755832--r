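---
title: "Evaluating ED prioritization policies: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ED prioritization policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

edflow compares patient-prioritization rules for a mixed-acuity emergency
department (ED) through three complementary lenses: tail-aware summary
statistics, threshold-attainment profiles, and stakeholder utility scores.
This vignette documents the simulation model behind the comparison, the
definitions of every metric, the parameters that matter and why their
defaults are what they are, and the places where the design was genuinely
open and a choice had to be made.

## 1. The patient-flow model

Patients arrive by a Poisson process (stationary by default, optionally a
24-hour rate profile realized by thinning) and are labelled with an
Emergency Severity Index (ESI) level drawn i.i.d. from a configurable mix.
The ED has `n_beds` treatment beds and `n_physicians` physicians, each able
to care for at most `physician_capacity` concurrent patients. A waiting
patient starts service only when a free bed *and* a physician with spare
capacity exist; both are re-checked at every arrival and departure epoch.
The patient then holds one bed and one slot of the assigned physician until
departure. There is no preemption: ESI-1 arrivals jump every queue at the
next availability epoch but never interrupt a patient already in service,
and they are excluded from all cohort analyses because no dispatch rule
changes their treatment.

Service durations are drawn per ESI level (lognormal by default, with
exponential and point-mass families available for validation work) and
floored at `service_floor = 32` minutes, representing the irreducible
overhead of rooming, assessment and discharge.

Two modelling choices deserve emphasis because they determine which
policies can matter at all:

**Workload-sensitive service progression.** A patient who starts service
with a physician already caring for `L` others takes
`1 + workload_sensitivity * L / (physician_capacity - 1)` times the drawn
duration. This encodes the fact that a physician's attention is divided
across their active caseload. Without it (set `workload_sensitivity = 0`),
physician identity is a pure label: any two assignment rules produce
distributionally identical patient outcomes, and workload-balancing
add-ons are provably inert. With it, routing decisions have real clinical
consequences, which is precisely what the LWP and PFT add-ons manipulate.

**Rotational default assignment.** When no add-on dictates a physician,
the dispatcher scans cyclically starting from `patient_id mod n_physicians`
for a physician with spare capacity — the deterministic analogue of a
charge nurse rotating assignments. Rotation is balanced in expectation, so
no base rule is handicapped, but heterogeneous service times make loads
drift apart; that drift is exactly the imbalance the low-workload-physician
add-on exists to correct. (A least-loaded default was rejected: it makes
LWP's routing identical to the default's, hence unobservable.)

The run design is warmup deletion plus horizon censoring: records arriving
during `warmup` are discarded, the clock stops at `horizon`, and patients
still waiting or in service are counted but excluded from KPI analysis
rather than imputed, avoiding truncation bias. Ties in event time are
broken deterministically (departures before arrivals, then patient id), so
a (config, policy, seed) triple replays to a byte-identical log.

## 2. The nine strategies

Four base rules: FCFS (arrival order), acuity-based FCFS (ESI level, then
arrival order), APQ (accumulating priority queue, score = acuity weight x
elapsed wait, so long-waiting low-acuity patients eventually overtake), and
AAPQ (additive APQ, score = acuity weight + epsilon x elapsed wait — acuity
first, waiting time as tiebreaker, provided `epsilon x horizon` stays below
the smallest weight gap, which is validated at simulation time).

Two conditional add-ons, consulted before the base rule (PFT first, then
LWP in the triple composite): **PFT** (partial fast track) designates one
physician — by default the last on the roster, i.e. the one the rotation
reaches least — to serve waiting ESI 4-5 patients FCFS whenever any are
present; otherwise every physician serves the base rule's queue. **LWP**
(low-workload physician) routes the base rule's top-priority patient to the
least-loaded physician whenever that physician's active count falls
`lwp_delta` or more below the mean of the others. Standalone `LWP` and
`PFT` strategies layer the add-on over acuity-based FCFS.

## 3. The three evaluation techniques

**Tail-aware summaries.** Per strategy and cohort: count, mean, median,
p75/p90/p95/p99, sample SD, min, max. Percentiles use linear interpolation
between order statistics (`quantile` type 7); the convention is fixed and
documented because the 99th percentile of a heavy-tailed LOS distribution
is sensitive to it. Cohorts are low acuity (ESI 4-5, the fast-track-eligible
group), mid acuity (ESI 2-3), and their union; pooling the cohorts is
demonstrably able to mask differences that stratification reveals, which is
why `summary_table()` always stratifies.

**Threshold attainment.** `T_P(t)` is the fraction of cohort `P` with KPI
strictly below `t` (a `strict` flag switches to non-strict; with continuous
KPIs on a 5-minute grid the difference is negligible, but it matters for
tied fixtures). Curves are computed on a 0-720 minute grid in 5-minute
steps — a 12-hour window within which LOS targets are clinically
meaningful. Summary functionals: the standardized AUC
`(1/t_max) * integral of T_P`, a half-range variant (first 6 hours), and
weighted variants with `w(t) = 2(t_max - t)/t_max^2` (early emphasis) or
`2t/t_max^2` (late emphasis) — the minimal normalized linear forms.
Integration treats the curve as piecewise linear and integrates each
segment exactly (Simpson's rule is exact for the quadratic product of two
linear pieces), so AUC values are deterministic and oracle-checkable rather
than quadrature-approximate. `t_X` is the smallest *grid* threshold whose
attainment reaches `X/100`; a level never reached returns `NA`, never a
number. Bootstrap bands resample patients within the cohort and report
pointwise percentile envelopes.

**Stakeholder utilities.** Both families map the pair of low/mid
attainments at a threshold into `[0, 1]`, equal 1 exactly when both goals
are met and 0 at zero attainment. The elliptical family U1 measures
relative goal deficits `e = max(0, (g - v')/g)` — where `v'` credits
overshoot at rate `delta` — and scores
`1 - sqrt((e_L^2 + lambda^2 e_M^2) / (1 + lambda^2))`; `lambda > 1`
penalizes mid-acuity shortfall more, and iso-utility loci are ellipse arcs.
The linear family U2 scores
`(alpha * min(v_L, g_L)/g_L + min(v_M, g_M)/g_M) / (alpha + 1)` with
`alpha < 1` down-weighting the low-acuity cohort. These closed forms are
this package's own concrete instantiation of "elliptical" and "linear"
goal-based utilities; each sits behind a single replaceable function so an
alternative algebra can be swapped in without touching the rest of the
module. Demonstration defaults: `lambda = 1.5`, `delta = 0.3`,
`alpha = 0.6`, goals of 100% (low) and 90% (mid). They are illustrative,
not elicited preferences. Scatter plots keep raw attainments on the axes —
utility enters only via contours and colouring — and the cross-utility
check regresses one family's scores on the other's across strategies and
counts discordant pairs.

## 4. Default calibration and why

| parameter | default | units | rationale |
|---|---|---|---|
| `n_beds` | 30 | beds | mixed-acuity ED of the size the comparison targets |
| `n_physicians` | 4 | — | typical single-shift staffing; >= 2 required by LWP/PFT |
| `physician_capacity` | 10 | patients | enough slack that beds, not slots, are the queueing gate, leaving real routing choices |
| `arrival_rate` | 7 | patients/h | ~12,000 low+mid discharges over 10 x 7.5 measured days |
| `esi_mix` | .03/.08/.13/.45/.31 | — | low-acuity-heavy mix typical of walk-in-dominated EDs |
| service means | 230/192/177/101/87 | min | per-ESI lognormal means; see below |
| `sdlog` | 0.55 | — | right-skewed service with CV ~0.6 |
| `service_floor` | 32 | min | fixed per-visit overhead |
| `workload_sensitivity` | 1.2 | — | caseload slowdown strong enough that balancing rules have clinical-scale effects |
| `acuity_weights` | 32/16/8/2/1 | — | geometric separation; doubling per level above the fast-track group |
| `aapq_epsilon` | 1e-5 | 1/min | tiebreaker property holds for horizons up to the weight gap / epsilon |
| `lwp_delta` | 3 | patients | fires on sustained, not transient, imbalance |
| `warmup`/`horizon` | 2880 / 13680 | min | 2-day warmup, 7.5 measured days per replication |
| `replications` | 10 | — | pooled reporting plus per-replication ordinal checks |

The service means and `workload_sensitivity` were calibrated jointly, once,
so that the simulated FCFS low-acuity mean LOS lands near 170 minutes in a
moderately congested 30-bed unit and the strategy family separates the way
the queueing structure implies: FCFS strongest for the low-acuity cohort it
never deprioritizes, the AAPQ-LWP-PFT composite strongest for the
mid-acuity cohort it both prioritizes and routes to lightly loaded
physicians. After calibration the parameters were frozen; all tests and the
acceptance script run against these values.

## 5. What the generator emulates — and what it does not

The simulator emulates: Poisson arrivals with an acuity mix, right-skewed
per-ESI service, joint bed/physician resource contention,
workload-dependent service progression, warmup and censoring, and
deterministic replay. It does **not** model: patients who leave without
being seen, inpatient boarding or hospital-wide flow, ambulance diversion,
staff shift changes, day-of-week seasonality, preemption, or
physician-to-patient heterogeneity beyond caseload. Consequently, passing
tests demonstrate that the evaluation machinery measures what it claims on
logs with the simulated structure — they do not certify that any strategy
ranking transfers to a real department, where the omitted mechanisms can
dominate. The evaluation functions deliberately accept externally recorded
patient logs so the same three techniques can be applied to real data.

## 6. Numerical and degenerate-input conventions

* Percentiles: type-7 linear interpolation; SD of a single observation is 0.
* Attainment: strict `<` by default, switchable; curves are clamped to
  `[0, 1]` and validated non-decreasing.
* AUC: exact per-segment integration of the piecewise-linear curve; a grid
  that does not cover the integration window is an error (no extrapolation).
* `t_X`: grid-resolution answers by construction; `NA` signals
  non-attainment.
* Bootstrap: percentile intervals, clamped to contain the point estimate;
  cohorts of fewer than 2 patients are an error.
* Empty cohorts raise a typed error (`edflow_empty_cohort`), never NaN rows.
* Event ties: departures before arrivals, then lower patient id; dispatch
  ties: earlier arrival, then lower patient id.
* All randomness flows from one root seed through named substreams
  (simulation replication, bootstrap, arrivals), so adding bootstrap
  replicates never perturbs simulated logs.

## 7. Open design points and how they were resolved

* **Standalone LWP/PFT base**: layered over acuity-based FCFS, the most
  conservative clinically realistic baseline.
* **LWP trigger**: least-loaded physician at least `lwp_delta` below the
  mean of the others; the routed patient is whatever the active base rule
  would pick, keeping LWP a pure routing override.
* **PFT designation**: the last physician on the roster, so the dedicated
  fast-track role is held by the physician the rotation would otherwise
  use least; the designated physician still serves the general queue when
  no ESI 4-5 patient waits.
* **Whether ESI-1 consumes a bed**: yes — they pass through the same
  resources, only the queue position is special.
* **Table-style pooling**: replications are pooled for the headline tables;
  `kpi_summary_by_replication()` supports replication-level intervals.

## 8. Known limitations

The per-replication ordinal races between near-tied strategies (e.g. FCFS
versus the LWP family on the low-acuity mean) are decided by margins of a
few minutes against replication standard errors of similar size, so
single-replication rankings are unstable even where the pooled ranking is
consistent; `scripts/acceptance.R` reports these rates explicitly rather
than hiding them. The workload-sensitivity mechanism is a deliberately
simple one-parameter stand-in for physician multitasking; its value changes
the *magnitude* of routing effects, and `workload_sensitivity = 0` recovers
the pure slot model in which only queue order matters. Utility parameters
are demonstration placeholders; any real deployment requires elicitation.

## 9. Problem sizes

The shipped configuration simulates 10 replications x 9 strategies of a
7.5-measured-day horizon (~12,000 pooled low+mid discharges per strategy,
~110,000 patients in total), which runs in seconds; the Erlang-C validation
uses an M/M/3 system at utilization 0.8 with 20 replications. Unit tests
use minutes-long toy horizons and deterministic fixture logs whose metrics
have closed forms.
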