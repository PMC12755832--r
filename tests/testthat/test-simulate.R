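test_that("simulation is reproducible and seeds separate replications", {
  cfg <- small_config(replications = 2)
  p <- make_policy("AAPQ-LWP-PFT")
  a <- ed_simulate(cfg, p, seed = 5)
  b <- ed_simulate(cfg, p, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- ed_simulate(cfg, p, seed = 6)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
  r1 <- a[a$replication_id == 1, ]$arrival_time
  r2 <- a[a$replication_id == 2, ]$arrival_time
  expect_false(identical(r1[seq_len(min(length(r1), length(r2)))],
                         r2[seq_len(min(length(r1), length(r2)))]))
})

test_that("every record respects time ordering and derived KPI definitions", {
  log <- ed_simulate(small_config(), make_policy("APQ"), seed = 3)
  expect_true(all(log$arrival_time <= log$service_start + 1e-9))
  expect_true(all(log$service_start <= log$departure_time + 1e-9))
  expect_equal(log$los, log$departure_time - log$arrival_time)
  expect_equal(log$wait, log$service_start - log$arrival_time)
  expect_true(all(log$esi %in% 1:5))
  expect_true(all(log$arrival_time >= small_config()$warmup))
})

test_that("arrivals are conserved across kept, warmup and censored records", {
  cfg <- small_config(replications = 3)
  log <- ed_simulate(cfg, make_policy("FCFS"), seed = 9)
  kept <- table(factor(log$replication_id, levels = 1:3))
  total <- as.integer(kept) + attr(log, "n_censored") + attr(log, "n_warmup")
  expect_equal(total, attr(log, "n_arrivals"))
})

test_that("no bed or physician is ever oversubscribed", {
  cfg <- small_config(n_beds = 6, n_physicians = 2, physician_capacity = 3,
                      warmup = 0)
  log <- ed_simulate(cfg, make_policy("AAPQ-LWP-PFT"), seed = 21)
  log <- log[log$replication_id == 1, ]
  ev <- rbind(
    data.frame(t = log$service_start, d = 1, phys = log$physician_id),
    data.frame(t = log$departure_time, d = -1, phys = log$physician_id)
  )
  ev <- ev[order(ev$t, ev$d), ] # departures (-1) first on ties
  expect_lte(max(cumsum(ev$d)), cfg$n_beds)
  for (ph in unique(ev$phys)) {
    sub <- ev[ev$phys == ph, ]
    expect_lte(max(cumsum(sub$d)), cfg$physician_capacity)
  }
})

test_that("FCFS with a single ESI class starts service in arrival order", {
  cfg <- small_config(esi_mix = c(0, 0, 1, 0, 0), replications = 1)
  log <- ed_simulate(cfg, make_policy("FCFS"), seed = 2)
  ord <- order(log$arrival_time)
  expect_equal(order(log$service_start[ord]), seq_along(ord))
})

test_that("an uncongested system gives zero waits and LOS equal to service", {
  cfg <- small_config(arrival_rate = 0.2, replications = 1, horizon = 30000,
                      warmup = 0, workload_sensitivity = 0)
  log <- ed_simulate(cfg, make_policy("Acuity-Based FCFS"), seed = 4)
  expect_gt(nrow(log), 20)
  expect_equal(log$wait, rep(0, nrow(log)))
  expect_true(all(log$los >= cfg$service_floor))
})

test_that("service draws respect the floor, the family and the configured mean", {
  cfg <- small_config()
  expect_true(all(sample_service_time(cfg, 5, n = 2000, seed = 1) >= 32))
  fixed <- small_config(service_params = rep(list(service_spec("fixed", value = 60)), 5))
  expect_equal(sample_service_time(fixed, 2, n = 10, seed = 1), rep(60, 10))
  expect_error(sample_service_time(cfg, 7), "esi")
  # moment check on an ESI level where the floor is almost never binding
  x <- sample_service_time(cfg, 2, n = 1e5, seed = 42)
  expect_lt(abs(mean(x) / cfg$service_params[[2]]$mean - 1), 0.01)
})

test_that("the arrival process matches its configured rate and mix", {
  cfg <- sim_config(arrival_rate = 6, horizon = 60000, warmup = 0)
  arr <- generate_arrivals(cfg, seed = 8)
  gaps <- diff(arr$time)
  # mean inter-arrival 10 min within a CLT bound (3 sigma)
  expect_lt(abs(mean(gaps) - 10), 3 * 10 / sqrt(length(gaps)))
  deg <- sim_config(esi_mix = c(0, 0, 0, 1, 0), horizon = 5000, warmup = 0)
  expect_true(all(generate_arrivals(deg, seed = 1)$esi == 4))
  expect_identical(generate_arrivals(cfg, seed = 3), generate_arrivals(cfg, seed = 3))
})

test_that("a 24-hour rate profile modulates arrivals by hour of day", {
  prof <- c(rep(2, 12), rep(12, 12)) # quiet nights, busy afternoons
  cfg <- sim_config(rate_profile = prof, horizon = 14 * 1440, warmup = 0)
  arr <- generate_arrivals(cfg, seed = 13)
  hour <- floor((arr$time / 60) %% 24)
  n_night <- sum(hour < 12); n_day <- sum(hour >= 12)
  expect_gt(n_day, 4 * n_night)
})

test_that("single-class exponential FCFS agrees with the Erlang-C closed form", {
  cfg <- sim_config(
    n_beds = 3, n_physicians = 2, physician_capacity = 10,
    arrival_rate = 14.4, esi_mix = c(0, 0, 1, 0, 0),
    service_params = rep(list(service_spec("exponential", mean = 10)), 5),
    service_floor = 0, workload_sensitivity = 0,
    warmup = 500, horizon = 3500, replications = 20
  )
  log <- ed_simulate(cfg, make_policy("FCFS"), seed = 11)
  wq_rep <- tapply(log$wait, log$replication_id, mean)
  ci <- stats::t.test(wq_rep)$conf.int
  wq <- erlang_c_wq(3, 14.4 / 60, 10)
  expect_gt(wq, ci[1])
  expect_lt(wq, ci[2])
})

test_that("invalid configurations fail with the offending key named", {
  expect_error(sim_config(esi_mix = c(0.5, 0.2, 0.1, 0.1, 0.2)), "esi_mix")
  expect_error(sim_config(n_physicians = 1), "n_physicians")
  expect_error(sim_config(warmup = 5000, horizon = 4000), "horizon")
  expect_error(sim_config(rate_profile = rep(5, 12)), "rate_profile")
  cfg <- small_config(n_physicians = 2)
  expect_error(ed_simulate(cfg, make_policy("PFT", pft_physician = 5L)),
               class = "edflow_config_error")
})
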