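
# dql_policy: three stage-wise Q-networks trained backward from the terminal
# reward (Q3 on the observed rewards, Q2 on max_a Q3, Q1 on max_a Q2), used
# forward at prescription time. No discounting: the reward is terminal-only.

#' Q-network specification
#'
#' @param n_hidden_layers Number of hidden layers, 0 (linear) to 8.
#' @param width Nodes per hidden layer.
#' @param activation Hidden activation; `"relu"` is implemented.
#' @param learning_rate Initial Adam learning rate.
#' @param max_epochs Epoch cap per stage fit.
#' @param convergence_tolerance Stop once the largest per-epoch parameter
#'   change falls below this (weights converged).
#' @param seed Integer seed; per-stage seeds are derived from it.
#' @return A list of class `ot_network_spec`.
#' @export
network_spec <- function(n_hidden_layers = 2, width = 64,
                         activation = "relu", learning_rate = 1e-2,
                         max_epochs = 2000, convergence_tolerance = 1e-4,
                         seed = 1) {
  if (!n_hidden_layers %in% 0:8) abort("`n_hidden_layers` must be in 0..8.")
  if (width < 1) abort("`width` must be >= 1.")
  if (!identical(activation, "relu")) abort("Only `relu` activation is implemented.")
  structure(list(n_hidden_layers = as.integer(n_hidden_layers),
                 width = as.integer(width), activation = activation,
                 learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 convergence_tolerance = convergence_tolerance,
                 seed = as.integer(seed)),
            class = "ot_network_spec")
}

stage_inputs <- function(traj, stage, actions = NULL) {
  s <- switch(stage, `1` = traj$s0, `2` = traj$s1, `3` = traj$s2)
  a <- actions %||% switch(stage, `1` = traj$a1, `2` = traj$a2, `3` = traj$a3)
  cbind(s, decision_onehot(as.numeric(a), paste0("a", stage)))
}

#' Fit one stage's Q-function
#'
#' Regresses the stage targets on (previous state, one-hot action). For
#' stage 3 the targets are the terminal rewards; for earlier stages they are
#' the max over actions of the already-fitted later Q (see
#' [fit_backward()]).
#'
#' @param trajectories An `ot_trajectories` list.
#' @param stage 1, 2 or 3.
#' @param targets Per-trajectory regression targets.
#' @param spec A [network_spec()].
#' @return An object of class `ot_stage_q`.
#' @export
fit_stage_q <- function(trajectories, stage, targets, spec = network_spec()) {
  if (!stage %in% 1:3) abort("`stage` must be 1, 2 or 3.")
  if (length(targets) != n_trajectories(trajectories)) {
    abort("`targets` must align with the trajectories.")
  }
  x <- stage_inputs(trajectories, stage)
  fit <- mlp_fit(x, targets,
                 hidden = rep(spec$width, spec$n_hidden_layers),
                 lr = spec$learning_rate, max_epochs = spec$max_epochs,
                 tol = spec$convergence_tolerance,
                 seed = derive_seed(spec$seed, stage))
  structure(list(stage = stage, model = fit, state_dim = ncol(x) - 2L,
                 fitted_at = Sys.time()),
            class = "ot_stage_q")
}

# Q(s, a) for both actions at a stage: n x 2 matrix.
q_values <- function(stage_q, states) {
  states <- if (is.null(dim(states))) matrix(states, nrow = 1) else as.matrix(states)
  n <- nrow(states)
  qa <- function(a) predict(stage_q$model,
                            cbind(states, decision_onehot(rep(a, n), "a")))
  cbind(qa(0), qa(1))
}

#' Backward-train the three-stage policy stack
#'
#' Q3 is fitted first, on the terminal rewards; Q2's targets are
#' `max_a3 Q3(s2, a3)` evaluated at each trajectory's observed `s2`; Q1's
#' targets are `max_a2 Q2(s1, a2)`. The fit order is recorded and auditable
#' via the timestamps in the training metadata.
#'
#' @param trajectories An `ot_trajectories` list (>= 2 episodes).
#' @param spec A [network_spec()].
#' @return An object of class `ot_policy_stack` with `q1`, `q2`, `q3` and
#'   `metadata`.
#' @export
fit_backward <- function(trajectories, spec = network_spec()) {
  if (n_trajectories(trajectories) < 2) abort("Need at least 2 trajectories.")
  q3 <- fit_stage_q(trajectories, 3, trajectories$reward, spec)
  t2 <- apply(q_values(q3, trajectories$s2), 1, max)
  q2 <- fit_stage_q(trajectories, 2, t2, spec)
  t1 <- apply(q_values(q2, trajectories$s1), 1, max)
  q1 <- fit_stage_q(trajectories, 1, t1, spec)
  meta <- tibble::tibble(
    stage = c(3L, 2L, 1L),
    epochs = c(q3$model$epochs, q2$model$epochs, q1$model$epochs),
    loss = c(q3$model$loss, q2$model$loss, q1$model$loss),
    n_params = c(n_params(q3$model), n_params(q2$model), n_params(q1$model)),
    fitted_at = c(q3$fitted_at, q2$fitted_at, q1$fitted_at)
  )
  structure(list(q1 = q1, q2 = q2, q3 = q3, spec = spec, metadata = meta,
                 n_train = n_trajectories(trajectories),
                 train_ids = unique(trajectories$patient_id)),
            class = "ot_policy_stack")
}

#' Prescribe the optimal action at a stage
#'
#' The argmax over the two actions of the stage's Q-function; an exact tie
#' goes to action 0 (no intervention).
#'
#' @param stack An `ot_policy_stack`.
#' @param states State matrix (or a single state vector) at stage - 1.
#' @param stage Decision point 1, 2 or 3.
#' @return Integer vector of 0/1 actions.
#' @export
prescribe <- function(stack, states, stage) {
  if (!stage %in% 1:3) abort("`stage` must be 1, 2 or 3.")
  q <- stack[[paste0("q", stage)]]
  states <- if (is.null(dim(states))) matrix(states, nrow = 1) else as.matrix(states)
  if (ncol(states) != q$state_dim) {
    abort(sprintf("Stage %d expects states of dimension %d, got %d.",
                  stage, q$state_dim, ncol(states)))
  }
  qv <- q_values(q, states)
  as.integer(qv[, 2] > qv[, 1])
}

#' Bootstrap ensemble of policy stacks
#'
#' Resamples the trajectories with replacement `B` times and backward-trains
#' one stack per resample; downstream summaries use percentile (2.5, 97.5)
#' intervals across members. Each member's stack is self-consistent: its own
#' Q3 feeds its own Q2 targets.
#'
#' @param trajectories An `ot_trajectories` list.
#' @param spec A [network_spec()].
#' @param B Number of bootstrap members (>= 2).
#' @param seed Integer seed; member seeds are derived from it.
#' @return An object of class `ot_policy_ensemble`.
#' @export
fit_bootstrap_ensemble <- function(trajectories, spec = network_spec(),
                                   B = 100, seed = 1) {
  if (B < 2) abort("`B` must be >= 2.")
  n <- n_trajectories(trajectories)
  members <- vector("list", B)
  indices <- vector("list", B)
  for (b in seq_len(B)) {
    sb <- derive_seed(seed, b)
    idx <- with_seed(sb, sample.int(n, n, replace = TRUE))
    spec_b <- spec
    spec_b$seed <- sb
    members[[b]] <- tryCatch(
      fit_backward(subset_trajectories(trajectories, idx), spec_b),
      error = function(e) abort(sprintf("Bootstrap member %d failed: %s",
                                        b, conditionMessage(e))))
    indices[[b]] <- idx
  }
  structure(list(members = members, B = B, seed = seed, spec = spec,
                 resample_indices = indices),
            class = "ot_policy_ensemble")
}

#' @export
tidy.ot_policy_stack <- function(x, ...) x$metadata

#' @export
glance.ot_policy_stack <- function(x, ...) {
  tibble::tibble(n_hidden_layers = x$spec$n_hidden_layers,
                 width = x$spec$width, n_train = x$n_train,
                 total_params = sum(x$metadata$n_params),
                 total_epochs = sum(x$metadata$epochs),
                 mean_loss = mean(x$metadata$loss))
}

#' @export
tidy.ot_policy_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$members, function(m, b)
    dplyr::mutate(glance(m), member = b, .before = 1))
}

#' @export
glance.ot_policy_ensemble <- function(x, ...) {
  tibble::tibble(B = x$B, n_hidden_layers = x$spec$n_hidden_layers,
                 width = x$spec$width, seed = x$seed)
}

#' @export
print.ot_policy_stack <- function(x, ...) {
  cat(sprintf("<ot_policy_stack> %d hidden layer(s) x %d nodes, trained on %d episodes\n",
              x$spec$n_hidden_layers, x$spec$width, x$n_train))
  print(x$metadata)
  invisible(x)
}

#' @export
print.ot_policy_ensemble <- function(x, ...) {
  cat(sprintf("<ot_policy_ensemble> B = %d members (%d hidden layers x %d nodes)\n",
              x$B, x$spec$n_hidden_layers, x$spec$width))
  invisible(x)
}
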