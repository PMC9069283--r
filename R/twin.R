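
# patient_twin: per-stage, per-feature support-vector transition classifiers.
# Stage s consumes the encoded patient history through stage s-1 plus a
# one-hot of the stage-s decision, and predicts every next-group feature
# independently — the patient-side digital twin used for off-policy
# evaluation. Each classifier is tuned by 5-fold CV over macro-averaged F1
# with inverse-class-frequency example weights.

#' Inverse-class-frequency weights
#'
#' Weight of class c is proportional to 1/count(c), normalized so the
#' weights average 1 across classes; rare classes get proportionally more
#' emphasis (a 90/10 split gives a 1:9 weight ratio).
#'
#' @param labels Vector (or factor) of class labels.
#' @return Named numeric vector of per-class weights.
#' @export
inverse_frequency_weights <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (!length(labels)) abort("`labels` is empty.")
  counts <- table(as.character(labels))
  w <- 1 / as.numeric(counts)
  w <- w / mean(w)
  setNames(w, names(counts))
}

#' Default SVC hyperparameter grid
#'
#' @return A data frame of `cost` and `gamma` combinations for the RBF
#'   kernel.
#' @export
default_svc_grid <- function() {
  expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(1e-3, 1e-2, 1e-1, 1))
}

macro_f1 <- function(truth, pred, levels) {
  f1 <- vapply(levels, function(l) {
    tp <- sum(pred == l & truth == l)
    fp <- sum(pred == l & truth != l)
    fn <- sum(pred != l & truth == l)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  mean(f1)
}

# Transition inputs for a stage: encoded history state + one-hot decision.
twin_inputs <- function(data, stage, scaling, schema, actions = NULL) {
  a <- actions %||% data[[paste0("d", stage)]]
  if (is.null(a) || anyNA(a)) {
    abort(sprintf("Stage %d transition needs decision `d%d`.", stage, stage))
  }
  cbind(build_states(data, stage - 1L, scaling, schema),
        decision_onehot(as.numeric(a), paste0("d", stage)))
}

twin_outputs <- function(schema, stage) {
  if (stage == 3) c("os", "ft", "ar_after") else
    schema_features(schema, as.character(stage + 1))
}

#' Fit one stage of the treatment simulator
#'
#' One RBF support-vector classifier per output feature; `cost` and `gamma`
#' maximize the mean cross-validated macro-F1 over `grid`, with class
#' weights from [inverse_frequency_weights()]. An output feature with a
#' single observed class is fitted as a constant predictor (with a warning),
#' not an error.
#'
#' @param train Preprocessed training cohort tibble.
#' @param stage 1, 2 or 3 (predicting groups 2, 3 and the final outcomes).
#' @param scaling Fitted scaling map from [encode_features()].
#' @param schema Schema; defaults to the attached one.
#' @param cv_folds Number of CV folds.
#' @param grid Hyperparameter grid (see [default_svc_grid()]).
#' @param seed Integer seed (fold assignment).
#' @return An object of class `ot_transition_model`.
#' @export
fit_transition <- function(train, stage, scaling, schema = NULL, cv_folds = 5,
                           grid = default_svc_grid(), seed = 1) {
  if (!stage %in% 1:3) abort("`stage` must be 1, 2 or 3.")
  schema <- get_schema(train, schema)
  x <- twin_inputs(train, stage, scaling, schema)
  outputs <- twin_outputs(schema, stage)
  n <- nrow(x)
  fits <- purrr::imap(setNames(outputs, outputs), function(f, nm) {
    y <- as.character(train[[f]])
    if (anyNA(y)) abort(sprintf("Output feature `%s` has missing values.", f))
    lv <- sort(unique(y))
    if (length(lv) < 2) {
      warn(sprintf("Output feature `%s` has a single class (%s); fitted as a constant predictor.",
                   f, lv))
      return(list(type = "constant", value = lv, levels = lv))
    }
    yf <- factor(y, levels = lv)
    w <- inverse_frequency_weights(y)
    # fold seed depends on the feature name only, so each feature's model is
    # unchanged when other output features are added or removed
    folds <- with_seed(derive_seed(seed, sum(utf8ToInt(f))),
                       sample(rep_len(seq_len(cv_folds), n)))
    score <- vapply(seq_len(nrow(grid)), function(g) {
      fs <- vapply(seq_len(cv_folds), function(k) {
        tr <- folds != k
        if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
        fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr], type = "C-classification",
                          kernel = "radial", cost = grid$cost[g],
                          gamma = grid$gamma[g],
                          class.weights = w[levels(droplevels(yf[tr]))],
                          scale = FALSE)
        macro_f1(y[!tr], as.character(predict(fit, x[!tr, , drop = FALSE])), lv)
      }, numeric(1))
      mean(fs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(score)
    fit <- e1071::svm(x, yf, type = "C-classification", kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      class.weights = w, scale = FALSE)
    list(type = "svm", fit = fit, levels = lv,
         cost = grid$cost[best], gamma = grid$gamma[best],
         cv_f1 = score[best])
  })
  structure(list(stage = stage, features = fits, input_dim = ncol(x),
                 input_names = colnames(x), outputs = outputs,
                 train_ids = train$patient_id),
            class = "ot_transition_model")
}

#' Fit the full three-stage patient twin
#'
#' @inheritParams fit_transition
#' @return A list of class `ot_patient_twin` with elements `stage1..stage3`.
#' @export
fit_twin <- function(train, scaling, schema = NULL, cv_folds = 5,
                     grid = default_svc_grid(), seed = 1) {
  schema <- get_schema(train, schema)
  out <- list(
    stage1 = fit_transition(train, 1, scaling, schema, cv_folds, grid,
                            derive_seed(seed, 101)),
    stage2 = fit_transition(train, 2, scaling, schema, cv_folds, grid,
                            derive_seed(seed, 102)),
    stage3 = fit_transition(train, 3, scaling, schema, cv_folds, grid,
                            derive_seed(seed, 103)),
    train_ids = train$patient_id
  )
  class(out) <- "ot_patient_twin"
  out
}

# Cast predicted labels back to the schema's storage type.
cast_feature <- function(values, schema, feature) {
  kind <- schema_row(schema, feature)$kind
  if (kind == "binary") as.integer(values) else as.character(values)
}

#' Predict the next-stage features for a history and action
#'
#' Each output feature is predicted independently by its classifier
#' (hard labels); the result is a complete feature map for the next stage.
#'
#' @param model An `ot_transition_model`.
#' @param data Cohort tibble holding all input features for the stage.
#' @param scaling Fitted scaling map.
#' @param schema Schema; defaults to the attached one.
#' @param actions Optional 0/1 vector overriding the recorded decision.
#' @return A tibble of predicted next-stage features (one row per patient).
#' @export
simulate_step <- function(model, data, scaling, schema = NULL, actions = NULL) {
  schema <- get_schema(data, schema)
  x <- twin_inputs(data, model$stage, scaling, schema, actions = actions)
  if (ncol(x) != model$input_dim) {
    abort(sprintf("Stage %d twin expects %d input columns, got %d.",
                  model$stage, model$input_dim, ncol(x)))
  }
  preds <- purrr::imap(model$features, function(m, f) {
    v <- if (m$type == "constant") rep(m$value, nrow(x)) else
      as.character(predict(m$fit, x))
    cast_feature(v, schema, f)
  })
  tibble::as_tibble(preds)
}

decider_actions <- function(decider, stage, states, data) {
  if (inherits(decider, "ot_policy_stack")) {
    prescribe(decider, states, stage)
  } else if (is.function(decider)) {
    as.integer(decider(stage, states))
  } else if (identical(decider, "physician") || identical(decider, "recorded")) {
    d <- data[[paste0("d", stage)]]
    if (is.null(d) || anyNA(d)) abort(sprintf("Recorded decision d%d missing.", stage))
    as.integer(d)
  } else if (is.matrix(decider)) {
    as.integer(decider[, stage])
  } else if (is.numeric(decider) && length(decider) == 3) {
    rep(as.integer(decider[stage]), nrow(data))
  } else {
    abort("Unsupported decider.")
  }
}

#' Simulate full treatment trajectories through the twin
#'
#' Chains the three transition models from the pretreatment features: at
#' each junction the decider supplies the action given only the current
#' (simulated) history — a policy stack is queried with the current state
#' vector and never sees the simulator's future — then the twin predicts the
#' next-stage features. Returns the simulated final outcomes and composite
#' reward.
#'
#' @param twin An `ot_patient_twin`.
#' @param data Cohort tibble with at least the group-1 features (plus
#'   recorded decisions when `decider = "physician"`).
#' @param decider An `ot_policy_stack`, a length-3 fixed 0/1 sequence, an
#'   n-x-3 action matrix, `"physician"` (recorded decisions), or a
#'   `function(stage, states)`.
#' @param scaling Fitted scaling map.
#' @param schema Schema; defaults to the attached one.
#' @return A list with `data` (simulated history), `outcomes` (tibble with
#'   `os`, `ft`, `ar_after`, `dp`, `reward`), and `actions` (n x 3 matrix).
#' @export
simulate_trajectory <- function(twin, data, decider, scaling, schema = NULL) {
  schema <- get_schema(data, schema)
  g1 <- schema_features(schema, "1")
  sim <- data[, c("patient_id", g1)]
  sim <- set_schema(sim, schema)
  acts <- matrix(NA_integer_, nrow(data), 3,
                 dimnames = list(NULL, c("d1", "d2", "d3")))
  for (stage in 1:3) {
    states <- build_states(sim, stage - 1L, scaling, schema)
    a <- tryCatch(decider_actions(decider, stage, states, data),
                  error = function(e) abort(sprintf(
                    "Decider failed at stage %d: %s", stage, conditionMessage(e))))
    assert_binary(a, sprintf("action at stage %d", stage))
    acts[, stage] <- a
    model <- twin[[paste0("stage", stage)]]
    nxt <- tryCatch(simulate_step(model, sim, scaling, schema, actions = a),
                    error = function(e) abort(sprintf(
                      "Twin transition failed at stage %d: %s", stage,
                      conditionMessage(e))))
    sim[[paste0("d", stage)]] <- a
    for (f in names(nxt)) sim[[f]] <- nxt[[f]]
  }
  outcomes <- tibble::tibble(
    patient_id = sim$patient_id,
    os = sim$os, ft = sim$ft, ar_after = sim$ar_after,
    dp = as.integer(sim$ft | sim$ar_after),
    reward = compute_reward(sim$os, sim$ft, sim$ar_after,
                            as.integer(data$ar_before))
  )
  list(data = sim, outcomes = outcomes, actions = acts)
}

check_disjoint <- function(twin, test) {
  overlap <- intersect(twin$train_ids, test$patient_id)
  if (length(overlap)) {
    abort(sprintf("Protocol violation: %d test patient(s) were used to train the twin (e.g. %s).",
                  length(overlap), overlap[1]))
  }
  invisible(TRUE)
}

# Stratified bootstrap of a 0/1 correctness indicator; strata preserve the
# class counts of the true labels.
strat_boot_acc <- function(correct, strata, B, seed) {
  groups <- split(seq_along(correct), strata)
  accs <- with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- unlist(purrr::map(groups, ~ .x[sample.int(length(.x), length(.x),
                                                     replace = TRUE)]))
    mean(correct[idx])
  }, numeric(1)))
  100 * accs
}

#' One-step prediction accuracy of the twin
#'
#' Follows each recorded trajectory and, at each junction, predicts the
#' next-stage feature values under the physician's recorded action,
#' comparing with the recorded values. 95% CIs are percentile intervals
#' over `B` bootstrap resamples stratified by the evaluated feature's class.
#'
#' @param twin An `ot_patient_twin` (trained on data disjoint from `test`).
#' @param test Preprocessed test cohort tibble.
#' @param scaling Fitted scaling map.
#' @param schema Schema; defaults to the attached one.
#' @param B Bootstrap resamples.
#' @param seed Integer seed.
#' @return A tibble of class `ot_accuracy_report` (`stage`, `feature`,
#'   `accuracy`, `lower`, `upper`, in %), with mean/median accuracy in
#'   `attr(, "summary")`.
#' @export
one_step_accuracy <- function(twin, test, scaling, schema = NULL, B = 1000,
                              seed = 1) {
  schema <- get_schema(test, schema)
  check_disjoint(twin, test)
  rows <- purrr::map_dfr(1:3, function(stage) {
    model <- twin[[paste0("stage", stage)]]
    pred <- simulate_step(model, test, scaling, schema)
    purrr::map_dfr(model$outputs, function(f) {
      truth <- as.character(test[[f]])
      correct <- as.character(pred[[f]]) == truth
      ci <- if (B > 1) {
        percentile_ci(strat_boot_acc(correct, truth, B,
                                     derive_seed(seed, stage * 100 + match(f, model$outputs))))
      } else c(lower = 100 * mean(correct), upper = 100 * mean(correct))
      tibble::tibble(stage = stage, feature = f,
                     accuracy = 100 * mean(correct),
                     lower = ci[["lower"]], upper = ci[["upper"]])
    })
  })
  attr(rows, "summary") <- tibble::tibble(mean_accuracy = mean(rows$accuracy),
                                          median_accuracy = median(rows$accuracy))
  class(rows) <- c("ot_accuracy_report", class(rows))
  rows
}

#' Start-to-finish accuracy of the twin
#'
#' Simulates the full 3-step trajectory for each test patient under the
#' recorded physician decisions and compares the simulated final outcomes
#' (overall survival, feeding tube, aspiration, and dysphagia = feeding tube
#' OR aspiration) with the recorded ones.
#'
#' @inheritParams one_step_accuracy
#' @return An `ot_accuracy_report` tibble with one row per final outcome.
#' @export
start_to_finish_accuracy <- function(twin, test, scaling, schema = NULL,
                                     B = 1000, seed = 1) {
  schema <- get_schema(test, schema)
  check_disjoint(twin, test)
  sim <- simulate_trajectory(twin, test, "physician", scaling, schema)
  truth <- tibble::tibble(
    os = as.integer(test$os), ft = as.integer(test$ft),
    ar_after = as.integer(test$ar_after),
    dp = as.integer(test$ft | test$ar_after)
  )
  rows <- purrr::map_dfr(c("os", "ft", "ar_after", "dp"), function(f) {
    correct <- sim$outcomes[[f]] == truth[[f]]
    ci <- if (B > 1) {
      percentile_ci(strat_boot_acc(correct, as.character(truth[[f]]), B,
                                   derive_seed(seed, 400 + match(f, c("os", "ft", "ar_after", "dp")))))
    } else c(lower = 100 * mean(correct), upper = 100 * mean(correct))
    tibble::tibble(stage = NA_integer_, feature = f,
                   accuracy = 100 * mean(correct),
                   lower = ci[["lower"]], upper = ci[["upper"]])
  })
  attr(rows, "summary") <- tibble::tibble(mean_accuracy = mean(rows$accuracy),
                                          median_accuracy = median(rows$accuracy))
  class(rows) <- c("ot_accuracy_report", class(rows))
  rows
}
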