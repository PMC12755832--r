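Package: edflow
Title: Simulation and Multi-Criteria Evaluation of Emergency-Department
    Prioritization Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-event simulator of patient flow through a mixed-acuity
    emergency department, nine queue-discipline dispatch policies (first-come
    first-served, acuity-based FCFS, accumulating priority queues, physician
    workload balancing, partial fast track, and their composites), and a
    three-part evaluation workbench: tail-aware summary statistics with
    explicit upper percentiles, threshold-attainment curves with weighted
    area-under-curve and speed-to-X% metrics plus bootstrap confidence bands,
    and stakeholder utility analysis over paired cohort attainments
    (elliptical and linear utility families, contour scatter data, and
    cross-utility robustness checks). Evaluation accepts either simulated or
    externally recorded patient event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
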