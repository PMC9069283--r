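# Evaluation metrics run against a small noiseless twin fixture.
eval_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- prep_cohort(config_noiseless(n = 220, seed = 9))
      p$twin <- suppressWarnings(fit_twin(p$train, p$scaling,
                                          grid = fast_grid(), seed = 2))
      cache <<- p
    }
    cache
  }
})

replay_decider <- function(data) {
  cbind(d1 = as.integer(data$d1), d2 = as.integer(data$d2),
        d3 = as.integer(data$d3))
}

test_that("similarity is 100 for a replaying decider and 0 for its complement", {
  p <- eval_fixture()
  sim <- similarity(replay_decider(p$test), p$test, p$scaling)
  expect_equal(sim$similarity, rep(100, 4))
  inv <- similarity(1L - replay_decider(p$test), p$test, p$scaling)
  expect_equal(inv$similarity, rep(0, 4))
})

test_that("overall similarity averages the per-decision similarities", {
  p <- eval_fixture()
  one <- p$test[1, ]
  # match D1 and D3 only
  dec <- cbind(d1 = one$d1, d2 = 1L - one$d2, d3 = one$d3)
  sim <- similarity(dec, one, p$scaling)
  expect_equal(sim$similarity[sim$decision == "overall"], 100 * 2 / 3,
               tolerance = 1e-10)
  expect_equal(mean(sim$similarity[sim$decision != "overall"]),
               sim$similarity[sim$decision == "overall"])
})

test_that("prescription deltas follow the rate arithmetic", {
  p <- eval_fixture()
  replay <- prescription_delta(replay_decider(p$test), p$test, p$scaling)
  expect_equal(replay$delta, rep(0, 3))
  always <- prescription_delta(c(1, 1, 1), p$test, p$scaling)
  expect_equal(always$delta, 100 - 100 * c(mean(p$test$d1), mean(p$test$d2),
                                           mean(p$test$d3)))
  expect_equal(always$n_prescribed, rep(nrow(p$test), 3))
  never <- prescription_delta(c(0, 0, 0), p$test, p$scaling)
  expect_equal(never$delta, -100 * c(mean(p$test$d1), mean(p$test$d2),
                                     mean(p$test$d3)))
})

test_that("guideline compliance flags exactly the uncovered advanced cases", {
  tab <- tibble::tibble(
    patient_id = paste0("p", 1:5),
    t_cat = c("T3", "T1", "T4", "Tx", "T2"),
    n_cat = c("N1", "N0", "N0", "N2", "N0"),
    d1 = c(0L, 0L, 1L, 0L, 0L), d2 = c(0L, 0L, 0L, 0L, 0L), d3 = 0L)
  comp <- nccn_compliance(tab)
  expect_equal(comp$violations$patient_id, c("p1", "p4"))
  expect_equal(comp$n_advanced, 3)
  expect_equal(comp$compliance_rate, 100 * (1 - 2 / 3))
  # Tx is reported on its own row and is non-advanced on the T axis
  tx_row <- comp$table[comp$table$axis == "T" & comp$table$category == "Tx", ]
  expect_equal(tx_row$n, 1)
  # prescribing concurrent chemotherapy to everyone is compliant by construction
  all_cc <- nccn_compliance(tab, cbind(d1 = rep(0L, 5), d2 = rep(1L, 5)))
  expect_equal(nrow(all_cc$violations), 0)
  expect_equal(all_cc$compliance_rate, 100)
})

test_that("policy evaluation reports ensemble spread and exact deltas", {
  p <- eval_fixture()
  mdp_traj <- assemble_trajectories(p$train, p$scaling)
  stack <- fit_backward(mdp_traj, network_spec(1, 8, max_epochs = 150, seed = 3))
  # a degenerate ensemble of identical members has zero-width CIs
  ens <- structure(list(members = list(stack, stack, stack), B = 3,
                        seed = 1, spec = stack$spec,
                        resample_indices = NULL),
                   class = "ot_policy_ensemble")
  rep1 <- evaluate_policy(ens, p$twin, p$test, p$scaling)
  expect_equal(rep1$rates$lower, rep1$rates$upper)
  expect_equal(rep1$rates$delta, rep1$rates$simulated - rep1$rates$baseline)
  expect_true(all(rep1$rates$simulated >= 0 & rep1$rates$simulated <= 100))
  expect_equal(glance(rep1)$B, 3)

  # replaying the physicians reproduces the start-to-finish simulated rates
  rep2 <- evaluate_policy(replay_decider(p$test), p$twin, p$test, p$scaling)
  sim_phys <- simulate_trajectory(p$twin, p$test, "physician", p$scaling)
  expect_equal(rep2$rates$simulated[rep2$rates$metric == "os_rate"],
               100 * mean(sim_phys$outcomes$os))
  expect_equal(rep2$rates$simulated[rep2$rates$metric == "dp_free_rate"],
               100 * mean(1 - sim_phys$outcomes$dp))
})

test_that("protocol violations abort evaluation", {
  p <- eval_fixture()
  traj <- assemble_trajectories(p$train, p$scaling)
  stack <- fit_backward(traj, network_spec(0, 1, max_epochs = 30, seed = 1))
  expect_error(evaluate_policy(stack, p$twin, p$train[1:8, ], p$scaling),
               "Protocol violation")
})

test_that("policy deciders only ever see the current state", {
  p <- eval_fixture()
  seen <- list()
  spy <- function(stage, states) {
    seen[[stage]] <<- colnames(states)
    rep(0L, nrow(states))
  }
  invisible(simulate_trajectory(p$twin, p$test, spy, p$scaling))
  # stage s sees groups up to s and earlier decisions, never outcomes
  expect_false(any(grepl("^os|^ft|^ar_after", unlist(seen))))
  expect_false(any(c("d1_0", "d1_1") %in% seen[[1]]))
  expect_true(all(c("d1_0", "d1_1") %in% seen[[2]]))
  expect_false(any(grepl("^cc_regimen", seen[[2]])))
  expect_true(any(grepl("^cc_regimen", seen[[3]])))
})

test_that("the depth sweep returns ordered CIs per requested depth", {
  p <- eval_fixture()
  traj <- assemble_trajectories(p$train, p$scaling)
  sw <- depth_sweep(traj, p$twin, p$test, p$scaling, depths = c(0, 1),
                    B = 2, spec = network_spec(width = 8, max_epochs = 80),
                    seed = 4)
  expect_equal(sort(unique(sw$depth)), c(0, 1))
  expect_equal(nrow(sw), 4)  # 2 depths x 2 metrics
  expect_true(all(sw$lower <= sw$simulated + 1e-9))
  expect_true(all(sw$simulated <= sw$upper + 1e-9))
})

test_that("the pipeline produces a complete, reproducible report", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- list(cohort = list(source = "synthetic", n = 150, seed = 2),
              depths = c(0, 1), bootstrap = 2, width = 8, max_epochs = 60,
              svc_cost = c(1, 10), svc_gamma = c(0.01, 0.1),
              accuracy_bootstrap = 10, seed = 5)
  rep1 <- suppressWarnings(suppressMessages(run_pipeline(cfg, out1)))
  expect_true(all(file.exists(file.path(
    out1, c("report.json", "accuracy.csv", "compliance.csv",
            "depth_sweep.csv", "delta.csv")))))
  expect_equal(sort(unique(rep1$depth_sweep$depth)), c(0, 1))
  expect_true(all(rep1$depth_sweep$simulated >= 0 &
                    rep1$depth_sweep$simulated <= 100))
  rep2 <- suppressWarnings(suppressMessages(run_pipeline(cfg, out2)))
  expect_identical(readLines(file.path(out1, "report.json")),
                   readLines(file.path(out2, "report.json")))
})

test_that("outcome modes differ only in the reward construction", {
  p <- eval_fixture()
  t_comp <- assemble_trajectories(p$train, p$scaling, outcome = "os_dp")
  t_os <- assemble_trajectories(p$train, p$scaling, outcome = "os")
  expect_identical(t_comp$s1, t_os$s1)
  expect_identical(t_comp$a3, t_os$a3)
  expect_equal(t_os$reward, as.numeric(p$train$os))
  expect_equal(t_comp$reward,
               compute_reward(p$train$os, p$train$ft, p$train$ar_after,
                              p$train$ar_before))
})
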