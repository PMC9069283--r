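# Twin fixtures: a noiseless regime (every transition a deterministic
# function of the decisions) fitted once and reused.
noiseless_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- prep_cohort(config_noiseless(n = 240, seed = 3))
      p$twin <- suppressWarnings(fit_twin(p$train, p$scaling,
                                          grid = fast_grid(), seed = 5))
      cache <<- p
    }
    cache
  }
})

test_that("inverse-frequency weights match their definition", {
  w <- inverse_frequency_weights(rep(c("0", "1"), c(90, 10)))
  expect_equal(unname(w["1"] / w["0"]), 9)
  expect_equal(mean(w), 1)
  wb <- inverse_frequency_weights(rep(c("a", "b"), 25))
  expect_equal(unname(wb), c(1, 1))
  w3 <- inverse_frequency_weights(rep(c("x", "y", "z"), c(50, 25, 25)))
  expect_equal(unname(w3 / w3[["x"]]), c(1, 2, 2))
  expect_error(inverse_frequency_weights(character(0)), "empty")
})

test_that("separable transitions are learned perfectly", {
  p <- noiseless_fixture()
  m1 <- p$twin$stage1
  # response to induction is a deterministic function of d1
  expect_equal(m1$features$cr_primary$type, "svm")
  expect_equal(m1$features$cr_primary$cv_f1, 1)
  pred <- simulate_step(m1, p$test, p$scaling)
  expect_equal(pred$cr_primary, p$test$cr_primary)
  expect_equal(pred$chemo, p$test$chemo)
})

test_that("single-class output features become constant predictors", {
  p <- noiseless_fixture()
  expect_equal(p$twin$stage1$features$chemo_mod$type, "constant")
  pred <- simulate_step(p$twin$stage1, p$test, p$scaling)
  expect_true(all(pred$chemo_mod == 0L))
})

test_that("an uninformative balanced label is predicted at chance level", {
  p <- prep_cohort(config_noiseless(n = 1000, seed = 13))
  train <- p$train
  heldout <- p$test
  with_seed <- oncotwin:::with_seed
  train$os <- with_seed(1, rbinom(nrow(train), 1, 0.5))
  heldout$os <- with_seed(2, rbinom(nrow(heldout), 1, 0.5))
  m3 <- suppressWarnings(fit_transition(train, 3, p$scaling,
                                        grid = fast_grid(), seed = 7))
  pred <- simulate_step(m3, heldout, p$scaling)
  acc <- mean(pred$os == heldout$os)
  se <- sqrt(0.25 / nrow(heldout))
  expect_lt(abs(acc - 0.5), 3 * se)
})

test_that("predicted feature maps are complete and action-sensitive", {
  p <- noiseless_fixture()
  sch <- default_schema()
  pred2 <- simulate_step(p$twin$stage2, p$test, p$scaling)
  expect_setequal(names(pred2), sch$name[sch$group == "3"])
  a_yes <- simulate_step(p$twin$stage2, p$test, p$scaling,
                         actions = rep(1L, nrow(p$test)))
  a_no <- simulate_step(p$twin$stage2, p$test, p$scaling,
                        actions = rep(0L, nrow(p$test)))
  expect_true(any(a_yes$cc_regimen != a_no$cc_regimen))
  # generator truth: concurrent chemotherapy enables the platinum regimen
  expect_true(all(a_yes$cc_regimen == "platinum"))
  expect_true(all(a_no$cc_regimen == "none"))
  broken <- p$test[, setdiff(names(p$test), "chemo")]
  broken <- oncotwin:::set_schema(broken, sch)
  expect_error(simulate_step(p$twin$stage2, broken, p$scaling), "chemo")
})

test_that("noiseless chains reproduce generator truth end to end", {
  p <- noiseless_fixture()
  acc <- one_step_accuracy(p$twin, p$test, p$scaling, B = 25, seed = 1)
  expect_true(all(acc$accuracy == 100))
  expect_true(all(acc$lower == 100 & acc$upper == 100))
  s2f <- start_to_finish_accuracy(p$twin, p$test, p$scaling, B = 25, seed = 1)
  expect_equal(s2f$accuracy, rep(100, 4))
  sim <- simulate_trajectory(p$twin, p$test, c(0, 0, 0), p$scaling)
  expect_true(all(sim$outcomes$os == 0))   # survival requires concurrent chemo here
  expect_true(all(sim$outcomes$ft == 0))
})

test_that("dysphagia accuracy follows the OR rule recomputation", {
  p <- noiseless_fixture()
  sim <- simulate_trajectory(p$twin, p$test, "physician", p$scaling)
  dp_direct <- as.integer(sim$outcomes$ft | sim$outcomes$ar_after)
  expect_equal(sim$outcomes$dp, dp_direct)
  truth_dp <- as.integer(p$test$ft | p$test$ar_after)
  s2f <- start_to_finish_accuracy(p$twin, p$test, p$scaling, B = 1)
  expect_equal(s2f$accuracy[s2f$feature == "dp"],
               100 * mean(dp_direct == truth_dp))
})

test_that("a constant predictor scores exactly the majority frequency", {
  p <- noiseless_fixture()
  # hand-built stage-3 model that always predicts survival
  const3 <- structure(list(
    stage = 3, features = list(os = list(type = "constant", value = "1",
                                         levels = "1")),
    input_dim = p$twin$stage3$input_dim, outputs = "os",
    train_ids = p$twin$train_ids), class = "ot_transition_model")
  twin2 <- p$twin
  twin2$stage3 <- const3
  acc <- one_step_accuracy(twin2, p$test, p$scaling, B = 1)
  expect_equal(acc$accuracy[acc$feature == "os"], 100 * mean(p$test$os == 1))
})

test_that("accuracy CIs degenerate correctly and ignore patient order", {
  p <- noiseless_fixture()
  a1 <- one_step_accuracy(p$twin, p$test, p$scaling, B = 1)
  expect_equal(a1$accuracy, a1$lower)
  shuffled <- p$test[rev(seq_len(nrow(p$test))), ]
  a2 <- one_step_accuracy(p$twin, shuffled, p$scaling, B = 1)
  expect_equal(a2$accuracy, a1$accuracy)
})

test_that("per-feature models are isolated from one another", {
  p <- noiseless_fixture()
  sch <- default_schema()
  reduced <- sch[sch$name != "pr_nodal", ]
  reduced <- as_schema(reduced)
  m_full <- p$twin$stage1
  m_red <- suppressWarnings(
    fit_transition(oncotwin:::set_schema(p$train, reduced), 1, p$scaling,
                   schema = reduced, grid = fast_grid(), seed = 5))
  expect_false("pr_nodal" %in% names(m_red$features))
  f_full <- m_full$features$cr_primary
  f_red <- m_red$features$cr_primary
  expect_equal(f_full$cost, f_red$cost)
  expect_equal(f_full$gamma, f_red$gamma)
  pred_full <- predict(f_full$fit, oncotwin:::twin_inputs(p$test, 1, p$scaling, sch))
  pred_red <- predict(f_red$fit, oncotwin:::twin_inputs(p$test, 1, p$scaling, reduced))
  expect_equal(as.character(pred_full), as.character(pred_red))
})

test_that("the twin refuses evaluation on its own training patients", {
  p <- noiseless_fixture()
  expect_error(one_step_accuracy(p$twin, p$train[1:5, ], p$scaling, B = 1),
               "Protocol violation")
})
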