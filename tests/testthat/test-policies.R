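test_that("accumulating priority scores behave as specified", {
  expect_equal(score_apq(4, 60), 240)
  expect_equal(score_apq(7, 0), 0)
  # APQ crossover: a long-waiting low-acuity patient overtakes a fresher
  # higher-acuity one
  expect_gt(score_apq(1, 40), score_apq(3, 10))
  expect_equal(score_aapq(2, 100, 1e-4), 2.01)
  # equal weights: longer wait scores higher
  expect_gt(score_aapq(2, 200, 1e-4), score_aapq(2, 50, 1e-4))
  # valid epsilon: higher acuity always dominates over any elapsed in horizon
  eps <- 1e-5; horizon <- 20000
  elapsed <- seq(0, horizon, length.out = 200)
  expect_true(all(outer(score_aapq(3, elapsed, eps), score_aapq(2, elapsed, eps), ">")))
})

test_that("make_policy builds all nine strategies with the documented structure", {
  expect_setequal(strategy_names(),
                  c("FCFS", "Acuity-Based FCFS", "APQ", "AAPQ", "LWP", "PFT",
                    "AAPQ-LWP", "AAPQ-PFT", "AAPQ-LWP-PFT"))
  p <- make_policy("AAPQ-LWP-PFT")
  expect_equal(p$base, "AAPQ")
  expect_equal(p$addons, c("PFT", "LWP")) # PFT consulted first, then LWP
  expect_equal(make_policy("FCFS")$addons, character(0))
  expect_equal(make_policy("AAPQ-PFT")$addons, "PFT")
  # standalone add-ons layer over acuity-based FCFS
  expect_equal(make_policy("LWP")$base, "ACUITY_FCFS")
  expect_equal(make_policy("PFT")$base, "ACUITY_FCFS")
  expect_error(make_policy("SJF"), "valid names")
})

test_that("policy_spec rejects invalid parameterizations", {
  expect_error(policy_spec("FCFS", acuity_weights = c(`1`=1,`2`=2,`3`=3,`4`=4,`5`=5)),
               "decreasing")
  expect_error(policy_spec("FCFS", addons = "FOO"), "addons")
  expect_error(policy_spec("AAPQ", aapq_epsilon = -1), "aapq_epsilon")
  # epsilon large enough to bridge a weight gap is caught at simulation time
  cfg <- small_config()
  bad <- policy_spec("AAPQ", aapq_epsilon = 0.1)
  expect_error(ed_simulate(cfg, bad), class = "edflow_config_error")
})

snap <- function(waiting, loads = c(0, 0, 0, 0), capacity = 10, beds = 5, now = 200) {
  queue_snapshot(now, waiting, loads, capacity, beds)
}

test_that("base rules select the specified patients", {
  w <- data.frame(patient_id = 1:2, esi = c(5L, 2L), arrival_time = c(0, 10))
  expect_equal(select_next(make_policy("Acuity-Based FCFS"), snap(w))$patient_id, 2)
  expect_equal(select_next(make_policy("FCFS"), snap(w))$patient_id, 1)
  # APQ: argmax of weight x wait; with weights (ESI2..5) = (4,3,2,1) and
  # waits (5,5,30,120) the long-waiting ESI5 patient wins with score 120
  w4 <- data.frame(patient_id = 1:4, esi = c(2L, 3L, 4L, 5L),
                   arrival_time = 200 - c(5, 5, 30, 120))
  apq <- make_policy("APQ", acuity_weights = c(`1`=5,`2`=4,`3`=3,`4`=2,`5`=1))
  scores <- c(4*5, 3*5, 2*30, 1*120)
  expect_equal(select_next(apq, snap(w4))$patient_id, which.max(scores))
})

test_that("dispatch returns nothing without a bed, an eligible physician, or a patient", {
  w <- data.frame(patient_id = 1L, esi = 3L, arrival_time = 0)
  p <- make_policy("FCFS")
  expect_null(select_next(p, snap(w, beds = 0)))
  expect_null(select_next(p, snap(w, loads = c(2, 2), capacity = 2)))
  empty <- data.frame(patient_id = integer(), esi = integer(), arrival_time = numeric())
  expect_null(select_next(p, snap(empty)))
})

test_that("ESI-1 patients are dispatched ahead of everyone under every policy", {
  w <- data.frame(patient_id = 1:3, esi = c(4L, 1L, 2L), arrival_time = c(0, 50, 10))
  for (nm in strategy_names()) {
    expect_equal(select_next(make_policy(nm), snap(w))$patient_id, 2,
                 info = nm)
  }
})

test_that("pft_check follows the fast-track contract", {
  p <- make_policy("PFT", pft_physician = 0L)
  w <- data.frame(patient_id = 1:3, esi = c(4L, 5L, 3L), arrival_time = c(5, 1, 0))
  # earliest low-acuity patient to the designated physician
  d <- pft_check(p, snap(w))
  expect_equal(d$patient_id, 2)
  expect_equal(d$physician_id, 0)
  # only mid-acuity waiting: no fast-track dispatch
  w2 <- data.frame(patient_id = 1:2, esi = c(2L, 3L), arrival_time = c(0, 1))
  expect_null(pft_check(p, snap(w2)))
  # designated physician at capacity: nothing even though low-acuity wait
  expect_null(pft_check(p, snap(w, loads = c(2, 0, 0, 0), capacity = 2)))
  # NULL designation resolves to the last physician
  d2 <- pft_check(make_policy("PFT"), snap(w))
  expect_equal(d2$physician_id, 3)
})

test_that("lwp_check fires only on sufficient load imbalance", {
  p <- make_policy("LWP", lwp_delta = 2)
  w <- data.frame(patient_id = 1:2, esi = c(3L, 4L), arrival_time = c(0, 5))
  d <- lwp_check(p, snap(w, loads = c(2, 5, 5, 5)))
  expect_equal(d$physician_id, 0)      # 5 - 2 >= 2 triggers
  expect_equal(d$patient_id, 1)        # base rule's top (higher acuity)
  expect_null(lwp_check(p, snap(w, loads = c(4, 5, 5, 5))))  # 5 - 4 < 2
  expect_null(lwp_check(p, snap(w, loads = c(3, 3, 3, 3))))  # balanced
})

test_that("AAPQ ordering equals lexicographic (acuity, elapsed) ordering", {
  p <- make_policy("AAPQ")
  for (i in 1:60) {
    s <- random_snapshot(n_wait = sample(1:12, 1), seed = 1000 + i)
    got <- select_next(p, s)$patient_id
    expect_equal(got, lex_pick(s$waiting, s$now), info = paste("case", i))
  }
})

test_that("composite policies reduce to add-on checks in priority order", {
  # on any snapshot the composite's decision equals: PFT if it fires,
  # else LWP if it fires, else the base rule
  comp <- make_policy("AAPQ-LWP-PFT")
  base <- make_policy("AAPQ")
  pft <- make_policy("PFT"); lwp <- make_policy("LWP", lwp_delta = comp$lwp_delta)
  for (i in 1:60) {
    s <- random_snapshot(n_wait = sample(1:10, 1), seed = 2000 + i)
    want <- pft_check(pft, s)
    if (is.null(want)) want <- lwp_check(lwp, s)
    if (is.null(want)) want <- select_next(base, s)
    got <- select_next(comp, s)
    expect_equal(got$patient_id, want$patient_id, info = paste("case", i))
    expect_equal(got$physician_id, want$physician_id, info = paste("case", i))
  }
})

test_that("every policy is total when a bed, physician and patient exist", {
  for (nm in strategy_names()) {
    p <- make_policy(nm)
    for (i in 1:20) {
      s <- random_snapshot(n_wait = sample(1:8, 1), seed = 3000 + 31 * i)
      if (s$free_beds >= 1 && any(s$physician_loads < s$capacity)) {
        expect_false(is.null(select_next(p, s)), info = paste(nm, i))
      }
    }
  }
})
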