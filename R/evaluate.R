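
# evaluation: off-policy evaluation of a policy ensemble against the patient
# twin, physician-similarity and prescription-delta metrics, the
# guideline-compliance audit, and the end-to-end pipeline.

as_members <- function(x) {
  if (inherits(x, "ot_policy_ensemble")) x$members else list(x)
}

#' Evaluate a policy ensemble against the patient twin
#'
#' Rolls every test patient through [simulate_trajectory()] with each
#' ensemble member as the decider, and summarizes the simulated overall
#' survival rate and dysphagia-free rate (dp-free = neither feeding tube nor
#' aspiration) as the ensemble mean with percentile (2.5, 97.5) intervals.
#' Baselines are the observed test-set outcome rates; deltas are simulated
#' minus baseline. The twin must have been trained on patients disjoint
#' from `test` (checked), and is never refit here.
#'
#' @param ensemble An `ot_policy_ensemble` (or a single stack).
#' @param twin An `ot_patient_twin`.
#' @param test Preprocessed test cohort tibble.
#' @param scaling Fitted scaling map.
#' @param schema Schema; defaults to the attached one.
#' @return A list of class `ot_eval_report` with `rates` (metric, simulated,
#'   CI, baseline, delta), `member_rates`, and sizes.
#' @export
evaluate_policy <- function(ensemble, twin, test, scaling, schema = NULL) {
  schema <- get_schema(test, schema)
  check_disjoint(twin, test)
  members <- as_members(ensemble)
  if (inherits(members[[1]], "ot_policy_stack")) {
    pol_overlap <- intersect(members[[1]]$train_ids, test$patient_id)
    if (length(pol_overlap)) {
      abort(sprintf("Protocol violation: %d test patient(s) entered policy training.",
                    length(pol_overlap)))
    }
  }
  member_rates <- purrr::imap_dfr(members, function(m, b) {
    sim <- simulate_trajectory(twin, test, m, scaling, schema)
    tibble::tibble(member = b,
                   os_rate = pct(sim$outcomes$os),
                   dp_free_rate = pct(1 - sim$outcomes$dp),
                   mean_reward = mean(sim$outcomes$reward))
  })
  baseline <- c(os_rate = pct(test$os),
                dp_free_rate = pct(1 - as.integer(test$ft | test$ar_after)))
  rates <- purrr::map_dfr(c("os_rate", "dp_free_rate"), function(metric) {
    v <- member_rates[[metric]]
    ci <- percentile_ci(v)
    base <- baseline[[metric]]
    tibble::tibble(metric = metric, simulated = mean(v),
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   baseline = base, delta = mean(v) - base)
  })
  structure(list(rates = rates, member_rates = member_rates,
                 B = length(members), n_test = nrow(test)),
            class = "ot_eval_report")
}

#' @export
tidy.ot_eval_report <- function(x, ...) x$rates

#' @export
glance.ot_eval_report <- function(x, ...) {
  tibble::tibble(B = x$B, n_test = x$n_test,
                 os_delta = x$rates$delta[x$rates$metric == "os_rate"],
                 dp_free_delta = x$rates$delta[x$rates$metric == "dp_free_rate"])
}

#' @export
print.ot_eval_report <- function(x, ...) {
  cat(sprintf("<ot_eval_report> %d members x %d test patients\n", x$B, x$n_test))
  print(x$rates)
  invisible(x)
}

#' Similarity of a policy to the recorded physician decisions
#'
#' Queries the decider at each junction on the patient's *recorded* history
#' (the treatment simulator is not involved) and reports the fraction of
#' patients where the prescribed action equals the recorded one, per
#' decision and overall (the mean of the three per-decision similarities).
#'
#' @param decider An `ot_policy_stack` (or any decider accepted by
#'   [simulate_trajectory()]).
#' @param test Preprocessed cohort with recorded decisions.
#' @param scaling Fitted scaling map.
#' @param schema Schema; defaults to the attached one.
#' @return A tibble with rows `d1`, `d2`, `d3`, `overall` and column
#'   `similarity` (%).
#' @export
similarity <- function(decider, test, scaling, schema = NULL) {
  schema <- get_schema(test, schema)
  per <- vapply(1:3, function(stage) {
    states <- build_states(test, stage - 1L, scaling, schema)
    a <- decider_actions(decider, stage, states, test)
    mean(a == as.integer(test[[paste0("d", stage)]]))
  }, numeric(1))
  tibble::tibble(decision = c("d1", "d2", "d3", "overall"),
                 similarity = 100 * c(per, mean(per)))
}

#' Prescription-rate change relative to physicians
#'
#' For each decision point, the model's yes-rate minus the physicians'
#' recorded yes-rate, in percentage points, along with the count of patients
#' the model prescribes the treatment to.
#'
#' @inheritParams similarity
#' @return A tibble of class `ot_prescription_delta` with one row per
#'   decision.
#' @export
prescription_delta <- function(decider, test, scaling, schema = NULL) {
  schema <- get_schema(test, schema)
  rows <- purrr::map_dfr(1:3, function(stage) {
    states <- build_states(test, stage - 1L, scaling, schema)
    a <- decider_actions(decider, stage, states, test)
    phys <- as.integer(test[[paste0("d", stage)]])
    tibble::tibble(decision = paste0("d", stage),
                   model_rate = pct(a), physician_rate = pct(phys),
                   delta = pct(a) - pct(phys), n_prescribed = sum(a))
  })
  class(rows) <- c("ot_prescription_delta", class(rows))
  rows
}

#' Guideline-compliance audit
#'
#' Advanced-stage patients (T3-4 or N1-3) must be prescribed chemotherapy at
#' D1 (induction) or D2 (concurrent); prescribing neither is a violation.
#' Unknown tumour codes (`Tx`) count as non-advanced on the T axis and get
#' their own row. The table partitions each T and N category by the
#' chemotherapy pattern prescribed: both, induction only, concurrent only,
#' or radiotherapy alone.
#'
#' @param test Cohort tibble with raw `t_cat`/`n_cat` codes.
#' @param decisions Data frame/matrix with columns `d1`, `d2` (defaults to
#'   the recorded decisions in `test`).
#' @return A list of class `ot_compliance` with `table`, `violations`,
#'   `n_advanced`, and `compliance_rate` (%).
#' @export
nccn_compliance <- function(test, decisions = NULL) {
  d1 <- as.integer(if (is.null(decisions)) test$d1 else decisions[, "d1"])
  d2 <- as.integer(if (is.null(decisions)) test$d2 else decisions[, "d2"])
  assert_binary(d1, "d1"); assert_binary(d2, "d2")
  adv <- is_advanced_stage(test$t_cat, test$n_cat)
  violation <- adv & d1 == 0 & d2 == 0
  pattern <- dplyr::case_when(
    d1 == 1 & d2 == 1 ~ "ic_cc", d1 == 1 ~ "ic_only",
    d2 == 1 ~ "cc_only", TRUE ~ "rt_alone")
  layout <- function(axis, values, cats) {
    purrr::map_dfr(cats, function(cc) {
      sel <- values == cc
      n <- sum(sel)
      p <- if (n) 100 * table(factor(pattern[sel],
                                     levels = c("ic_cc", "ic_only", "cc_only", "rt_alone"))) / n
      else setNames(rep(NA_real_, 4), c("ic_cc", "ic_only", "cc_only", "rt_alone"))
      tibble::tibble(axis = axis, category = cc, n = n,
                     ic_cc = p[["ic_cc"]], ic_only = p[["ic_only"]],
                     cc_only = p[["cc_only"]], rt_alone = p[["rt_alone"]])
    })
  }
  tab <- dplyr::bind_rows(
    layout("T", test$t_cat, c("T1", "T2", "T3", "T4", "Tx")),
    layout("N", test$n_cat, c("N0", "N1", "N2", "N3")))
  structure(list(
    table = tab,
    violations = tibble::tibble(patient_id = test$patient_id[violation],
                                t_cat = test$t_cat[violation],
                                n_cat = test$n_cat[violation]),
    n_advanced = sum(adv),
    compliance_rate = if (sum(adv)) 100 * (1 - sum(violation) / sum(adv)) else 100
  ), class = "ot_compliance")
}

#' @export
print.ot_compliance <- function(x, ...) {
  cat(sprintf("<ot_compliance> %d advanced-stage patients, compliance %.1f%% (%d violation(s))\n",
              x$n_advanced, x$compliance_rate, nrow(x$violations)))
  print(x$table)
  invisible(x)
}

#' Depth sweep of policy capacity
#'
#' Backward-trains a bootstrap ensemble at each hidden-layer depth and
#' evaluates it against the twin on the test cohort.
#'
#' @param trajectories Training `ot_trajectories`.
#' @param twin An `ot_patient_twin`.
#' @param test Preprocessed test cohort.
#' @param scaling Fitted scaling map.
#' @param depths Hidden-layer counts to sweep (0-8).
#' @param B Bootstrap members per depth.
#' @param spec Base [network_spec()]; its depth is overridden per sweep
#'   entry.
#' @param seed Integer seed.
#' @param schema Schema; defaults to the attached one.
#' @return A tibble of class `ot_depth_sweep`: one row per depth and metric
#'   with mean and CI, baselines attached.
#' @export
depth_sweep <- function(trajectories, twin, test, scaling, depths = 0:8,
                        B = 10, spec = network_spec(), seed = 1,
                        schema = NULL) {
  schema <- get_schema(test, schema)
  rows <- purrr::map_dfr(depths, function(d) {
    sp <- spec
    sp$n_hidden_layers <- as.integer(d)
    ens <- fit_bootstrap_ensemble(trajectories, sp, B = B,
                                  seed = derive_seed(seed, d + 1))
    rep <- evaluate_policy(ens, twin, test, scaling, schema)
    dplyr::mutate(rep$rates, depth = d, .before = 1)
  })
  attr(rows, "B") <- B
  class(rows) <- c("ot_depth_sweep", class(rows))
  rows
}

#' Run the full dyad pipeline
#'
#' Loads or generates a cohort, preprocesses it with training statistics
#' only, fits the patient twin and per-depth policy ensembles on the
#' training split, evaluates on the held-out split, and writes a report
#' directory: `report.json`, `accuracy.csv` (one-step layout),
#' `compliance.csv`, `depth_sweep.csv`, `delta.csv`, and a log.
#'
#' @param config A YAML file path or a list; see Details.
#' @param out_dir Output directory (created if needed).
#' @details Config fields (all optional): `cohort` (`source` `"synthetic"`
#'   or `"file"`, `n`, `seed`, `path`), `outcome` (`"os_dp"`/`"os"`),
#'   `radiomics` (logical), `train_fraction`, `split_seed`, `depths`,
#'   `width`, `bootstrap` (B), `cv_folds`, `svc_cost`/`svc_gamma` (SVC
#'   grid), `accuracy_bootstrap`, `max_epochs`, `seed`.
#' @return The report list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("oncotwin_report_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    cohort = list(source = "synthetic", n = 536, seed = 1, path = NULL),
    outcome = "os_dp", radiomics = FALSE, train_fraction = 0.75,
    split_seed = 1, depths = c(2), width = 64, bootstrap = 10,
    cv_folds = 5, svc_cost = c(0.1, 1, 10, 100),
    svc_gamma = c(1e-3, 1e-2, 1e-1, 1),
    accuracy_bootstrap = 200, max_epochs = 500, seed = 1)
  config <- utils::modifyList(defaults, config)
  cfg_hash <- rlang::hash(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
    message(msg)
  }
  run_stage <- function(name, expr) {
    logf("stage %s (config %s)", name, cfg_hash)
    tryCatch(expr, error = function(e) abort(sprintf(
      "Pipeline stage `%s` failed (config %s): %s", name, cfg_hash,
      conditionMessage(e))))
  }
  schema <- default_schema()
  cohort <- run_stage("load", {
    if (identical(config$cohort$source, "file")) {
      read_cohort(config$cohort$path, schema)
    } else {
      generate_cohort(generator_config(n = config$cohort$n,
                                       seed = config$cohort$seed,
                                       radiomics = isTRUE(config$radiomics)))
    }
  })
  radiomics_block <- attr(cohort, "radiomics")
  parts <- run_stage("split", split_cohort(cohort, config$train_fraction,
                                           config$split_seed))
  prep <- run_stage("preprocess", {
    train_raw <- parts$train; test_raw <- parts$test
    train <- impute_missing(train_raw, schema)
    stats <- attr(train, "imputation_stats")
    test <- impute_missing(test_raw, schema, stats = stats)
    if (isTRUE(config$radiomics) && !is.null(radiomics_block)) {
      tr_idx <- match(train$patient_id, cohort$patient_id)
      te_idx <- match(test$patient_id, cohort$patient_id)
      pcs_tr <- reduce_radiomics(radiomics_block[tr_idx, , drop = FALSE])
      proj <- attr(pcs_tr, "projection")
      pcs_te <- reduce_radiomics(radiomics_block[te_idx, , drop = FALSE],
                                 projection = proj)
      names(pcs_tr) <- names(pcs_te) <- paste0("rad_", names(pcs_tr))
      schema <- as_schema(dplyr::bind_rows(
        schema,
        tibble::tibble(name = names(pcs_tr), kind = "numeric", group = "1",
                       levels = vector("list", ncol(pcs_tr)),
                       na_levels = vector("list", ncol(pcs_tr)))))
      train <- set_schema(dplyr::bind_cols(train, pcs_tr), schema)
      test <- set_schema(dplyr::bind_cols(test, pcs_te), schema)
    }
    enc <- encode_features(train, schema)
    list(train = train, test = test, test_raw = test_raw,
         scaling = attr(enc, "scaling"), schema = schema)
  })
  schema <- prep$schema
  twin <- run_stage("fit_twin", fit_twin(
    prep$train, prep$scaling, schema, cv_folds = config$cv_folds,
    grid = expand.grid(cost = config$svc_cost, gamma = config$svc_gamma),
    seed = derive_seed(config$seed, 7)))
  traj <- run_stage("trajectories",
                    assemble_trajectories(prep$train, prep$scaling, schema,
                                          outcome = config$outcome))
  sweep <- run_stage("policy_sweep", {
    sp <- network_spec(width = config$width, max_epochs = config$max_epochs,
                       seed = derive_seed(config$seed, 11))
    depth_sweep(traj, twin, prep$test, prep$scaling, depths = config$depths,
                B = config$bootstrap, spec = sp,
                seed = derive_seed(config$seed, 13), schema = schema)
  })
  best_depth <- sweep$depth[which.max(sweep$simulated[sweep$metric == "os_rate"])]
  best_spec <- network_spec(n_hidden_layers = best_depth, width = config$width,
                            max_epochs = config$max_epochs,
                            seed = derive_seed(config$seed, 17))
  best_stack <- run_stage("best_policy", fit_backward(traj, best_spec))
  metrics <- run_stage("metrics", {
    list(
      accuracy = one_step_accuracy(twin, prep$test, prep$scaling, schema,
                                   B = config$accuracy_bootstrap,
                                   seed = derive_seed(config$seed, 19)),
      s2f = start_to_finish_accuracy(twin, prep$test, prep$scaling, schema,
                                     B = config$accuracy_bootstrap,
                                     seed = derive_seed(config$seed, 23)),
      similarity = similarity(best_stack, prep$test, prep$scaling, schema),
      delta = prescription_delta(best_stack, prep$test, prep$scaling, schema),
      compliance = {
        states_d1 <- build_states(prep$test, 0, prep$scaling, schema)
        a1 <- prescribe(best_stack, states_d1, 1)
        sim_test <- prep$test
        sim_test$d1 <- a1
        states_d2 <- build_states(sim_test, 1, prep$scaling, schema)
        a2 <- prescribe(best_stack, states_d2, 2)
        nccn_compliance(prep$test_raw, cbind(d1 = a1, d2 = a2))
      })
  })
  report <- list(
    config = config, config_hash = cfg_hash,
    n_train = nrow(prep$train), n_test = nrow(prep$test),
    best_depth = best_depth,
    depth_sweep = sweep,
    one_step_summary = attr(metrics$accuracy, "summary"),
    start_to_finish = metrics$s2f,
    similarity = metrics$similarity,
    prescription_delta = metrics$delta,
    compliance_rate = metrics$compliance$compliance_rate,
    n_violations = nrow(metrics$compliance$violations)
  )
  run_stage("write", {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    utils::write.csv(metrics$accuracy, file.path(out_dir, "accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics$compliance$table,
                     file.path(out_dir, "compliance.csv"), row.names = FALSE)
    utils::write.csv(sweep, file.path(out_dir, "depth_sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics$delta, file.path(out_dir, "delta.csv"),
                     row.names = FALSE)
  })
  logf("done: report in %s", out_dir)
  report$out_dir <- out_dir
  invisible(report)
}
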