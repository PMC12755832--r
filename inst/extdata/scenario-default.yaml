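# Default comparison scenario: a moderately congested 30-bed mixed-acuity ED,
# all nine prioritization strategies, the standard cohorts, threshold grid,
# AUC variants and demonstration utility parameters. Every key shown here is
# optional; omitted keys take the package defaults (this file restates them).
sim:
  n_beds: 30
  n_physicians: 4
  physician_capacity: 10
  arrival_rate: 7.0          # patients/hour, stationary Poisson
  esi_mix: [0.03, 0.08, 0.13, 0.45, 0.31]
  service_params:            # one entry per ESI level 1..5
    - {family: lognormal, mean: 230, sdlog: 0.55}
    - {family: lognormal, mean: 192, sdlog: 0.55}
    - {family: lognormal, mean: 177, sdlog: 0.55}
    - {family: lognormal, mean: 101, sdlog: 0.55}
    - {family: lognormal, mean: 87,  sdlog: 0.55}
  service_floor: 32.0        # minutes; fixed rooming/discharge overhead
  workload_sensitivity: 1.2  # caseload slowdown of service progression
  warmup: 2880.0             # 2 days discarded
  horizon: 13680.0           # 7.5 measured days per replication
  replications: 10
  seed: 1
policies: [FCFS, Acuity-Based FCFS, APQ, AAPQ, LWP, PFT, AAPQ-LWP, AAPQ-PFT, AAPQ-LWP-PFT]
cohorts:
  Overall: [2, 3, 4, 5]
  Low Acuity: [4, 5]
  Mid-Acuity: [2, 3]
grid: {from: 0, to: 720, by: 5}
auc: {t_max: 720, kinds: [uniform, half_range, linear_decreasing, linear_increasing]}
utilities:
  U1: {family: elliptical, goal_low: 1.0, goal_mid: 0.9, lambda: 1.5, delta: 0.3}
  U2: {family: linear, goal_low: 1.0, goal_mid: 0.9, alpha: 0.6}
t_stars: [180, 300, 420]
seed: 1
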