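
# mdp_core: the 3-stage decision process. Terminal-only composite reward,
# trajectory assembly from a preprocessed cohort, and exact planners on
# enumerable tabular processes used as oracles for the learned policy.

#' Composite survival/toxicity reward
#'
#' The terminal reward of an episode:
#' `os - (ft + ar_after - ar_before)`, i.e. survival credited, feeding-tube
#' dependence and new aspiration penalized, and pre-existing aspiration that
#' is still present not held against the treatment. Over binary inputs the
#' image is exactly \{-2, -1, 0, 1, 2\}. Rewards at the first two decisions
#' are identically zero, so no discounting is involved.
#'
#' @param os,ft,ar_after,ar_before Binary (0/1) vectors: 4-year survival,
#'   feeding tube at 6 months, aspiration after and before therapy.
#' @return Numeric vector of rewards.
#' @export
compute_reward <- function(os, ft, ar_after, ar_before) {
  assert_binary(os, "os")
  assert_binary(ft, "ft")
  assert_binary(ar_after, "ar_after")
  assert_binary(ar_before, "ar_before")
  os - (ft + ar_after - ar_before)
}

#' Enumerate binary action sequences
#'
#' @param n_decisions Number of binary decisions (default 3, giving the 8
#'   open-loop treatment sequences).
#' @return A tibble with columns `d1..dn`, rows in lexicographic order.
#' @export
enumerate_sequences <- function(n_decisions = 3) {
  if (n_decisions < 1) abort("`n_decisions` must be >= 1.")
  g <- expand.grid(rep(list(0:1), n_decisions))[, n_decisions:1, drop = FALSE]
  names(g) <- paste0("d", seq_len(n_decisions))
  tibble::as_tibble(g[do.call(order, g), , drop = FALSE])
}

#' Assemble learning trajectories from a cohort
#'
#' One episode per patient: states `s0`, `s1`, `s2` built with
#' [build_states()] (so training statistics are reused), the three recorded
#' decisions, and the terminal reward. In `outcome = "os"` mode the reward is
#' survival alone; in `"os_dp"` mode it is the composite
#' [compute_reward()].
#'
#' @param data Preprocessed cohort tibble (imputed, decisions and outcomes
#'   present).
#' @param scaling Fitted scaling map from [encode_features()].
#' @param schema Schema; defaults to the attached one.
#' @param outcome `"os_dp"` (composite) or `"os"` (survival only).
#' @return A list of class `ot_trajectories`: state matrices `s0`, `s1`,
#'   `s2`; integer actions `a1`, `a2`, `a3`; `reward`; `patient_id`.
#' @export
assemble_trajectories <- function(data, scaling, schema = NULL,
                                  outcome = c("os_dp", "os")) {
  outcome <- match.arg(outcome)
  schema <- get_schema(data, schema)
  for (col in c("os", "ft", "ar_after", "ar_before", "d1", "d2", "d3")) {
    if (anyNA(data[[col]]) || is.null(data[[col]])) {
      bad <- data$patient_id[which(is.na(data[[col]]))]
      abort(sprintf("Missing `%s` for patient(s): %s", col,
                    toString(head(bad, 5))))
    }
  }
  reward <- if (outcome == "os") {
    assert_binary(data$os, "os")
    as.numeric(data$os)
  } else {
    compute_reward(data$os, data$ft, data$ar_after, data$ar_before)
  }
  out <- list(
    s0 = build_states(data, 0, scaling, schema),
    s1 = build_states(data, 1, scaling, schema),
    s2 = build_states(data, 2, scaling, schema),
    a1 = as.integer(data$d1), a2 = as.integer(data$d2),
    a3 = as.integer(data$d3),
    reward = reward, patient_id = data$patient_id, outcome = outcome
  )
  class(out) <- "ot_trajectories"
  out
}

n_trajectories <- function(traj) length(traj$reward)

subset_trajectories <- function(traj, idx) {
  out <- list(s0 = traj$s0[idx, , drop = FALSE], s1 = traj$s1[idx, , drop = FALSE],
              s2 = traj$s2[idx, , drop = FALSE], a1 = traj$a1[idx],
              a2 = traj$a2[idx], a3 = traj$a3[idx], reward = traj$reward[idx],
              patient_id = traj$patient_id[idx], outcome = traj$outcome)
  class(out) <- "ot_trajectories"
  out
}

# ---- tabular MDPs -----------------------------------------------------------

validate_mdp <- function(mdp) {
  stopifnot(is.list(mdp), !is.null(mdp$p0), !is.null(mdp$P1),
            !is.null(mdp$P2), !is.null(mdp$R))
  if (abs(sum(mdp$p0) - 1) > 1e-8) abort("Initial distribution must sum to 1.")
  for (nm in c("P1", "P2")) {
    P <- mdp[[nm]]
    s <- apply(P, c(1, 2), sum)
    if (any(abs(s - 1) > 1e-8)) {
      abort(sprintf("Transition rows of `%s` must each sum to 1.", nm))
    }
  }
  invisible(mdp)
}

#' Random enumerable 3-stage MDP
#'
#' Dirichlet-random transitions, uniform-random terminal rewards in
#' `reward_range`, binary actions at each of the three stages. Used as a
#' ground-truth environment for validating the learned policy against exact
#' backward induction.
#'
#' @param n_states Integer vector of state-space sizes at stages 0, 1, 2.
#' @param seed Integer seed.
#' @param reward_range Range of the terminal reward `R(s2, a3)`.
#' @return A list with `p0` (initial distribution over stage-0 states),
#'   `P1[s0, a, s1]`, `P2[s1, a, s2]`, and terminal reward `R[s2, a]`.
#' @export
random_tabular_mdp <- function(n_states = c(3, 4, 4), seed = 1,
                               reward_range = c(-2, 2)) {
  stopifnot(length(n_states) == 3, all(n_states >= 1))
  with_seed(seed, {
    rdir <- function(k) { x <- stats::rexp(k); x / sum(x) }
    p0 <- rdir(n_states[1])
    P1 <- array(0, c(n_states[1], 2, n_states[2]))
    for (s in seq_len(n_states[1])) for (a in 1:2) P1[s, a, ] <- rdir(n_states[2])
    P2 <- array(0, c(n_states[2], 2, n_states[3]))
    for (s in seq_len(n_states[2])) for (a in 1:2) P2[s, a, ] <- rdir(n_states[3])
    R <- matrix(runif(n_states[3] * 2, reward_range[1], reward_range[2]),
                n_states[3], 2)
    list(p0 = p0, P1 = P1, P2 = P2, R = R)
  })
}

#' Exact backward-induction solution of a tabular MDP
#'
#' Dynamic programming over the three stages: `Q3 = R`,
#' `Q2(s1, a2) = E[V2(s2)]`, `Q1(s0, a1) = E[V1(s1)]`, with `V = max_a Q`.
#' The optimal action at a tie is 0 (no intervention).
#'
#' @param mdp A tabular MDP as from [random_tabular_mdp()].
#' @return A list with `Q1`, `Q2`, `Q3` (states x 2 matrices), `V0`, `V1`,
#'   `V2`, the optimal `policy` (`pi1`, `pi2`, `pi3`, 0/1 per state), and the
#'   start-state `value`.
#' @export
closed_loop_oracle <- function(mdp) {
  validate_mdp(mdp)
  Q3 <- mdp$R
  V2 <- pmax(Q3[, 1], Q3[, 2])
  Q2 <- cbind(mdp$P2[, 1, , drop = FALSE][, 1, ] %*% V2,
              mdp$P2[, 2, , drop = FALSE][, 1, ] %*% V2)
  Q2 <- matrix(Q2, ncol = 2)
  V1 <- pmax(Q2[, 1], Q2[, 2])
  Q1 <- cbind(mdp$P1[, 1, , drop = FALSE][, 1, ] %*% V1,
              mdp$P1[, 2, , drop = FALSE][, 1, ] %*% V1)
  Q1 <- matrix(Q1, ncol = 2)
  V0 <- pmax(Q1[, 1], Q1[, 2])
  argmax0 <- function(Q) as.integer(Q[, 2] > Q[, 1])
  list(Q1 = Q1, Q2 = Q2, Q3 = Q3, V0 = V0, V1 = V1, V2 = V2,
       policy = list(pi1 = argmax0(Q1), pi2 = argmax0(Q2), pi3 = argmax0(Q3)),
       value = sum(mdp$p0 * V0))
}

#' Exact open-loop sequence values of a tabular MDP
#'
#' Expected terminal reward of each fixed action sequence, by propagating the
#' state distribution through the transition matrices.
#'
#' @param mdp A tabular MDP.
#' @return A tibble with the 8 sequences (lexicographic) and their exact
#'   values.
#' @export
open_loop_values_exact <- function(mdp) {
  validate_mdp(mdp)
  seqs <- enumerate_sequences(3)
  seqs$value <- purrr::pmap_dbl(seqs, function(d1, d2, d3) {
    p1 <- drop(mdp$p0 %*% mdp$P1[, d1 + 1, ])
    p2 <- drop(p1 %*% mdp$P2[, d2 + 1, ])
    sum(p2 * mdp$R[, d3 + 1])
  })
  seqs
}

#' Exact value of a fixed stage-wise policy on a tabular MDP
#'
#' @param mdp A tabular MDP.
#' @param policy A list `pi1`, `pi2`, `pi3` of 0/1 actions per state.
#' @return The expected terminal reward from the initial distribution.
#' @export
evaluate_mdp_policy <- function(mdp, policy) {
  validate_mdp(mdp)
  n2 <- nrow(mdp$R)
  V2 <- mdp$R[cbind(seq_len(n2), policy$pi3 + 1)]
  n1 <- dim(mdp$P2)[1]
  V1 <- vapply(seq_len(n1), function(s) sum(mdp$P2[s, policy$pi2[s] + 1, ] * V2),
               numeric(1))
  n0 <- dim(mdp$P1)[1]
  V0 <- vapply(seq_len(n0), function(s) sum(mdp$P1[s, policy$pi1[s] + 1, ] * V1),
               numeric(1))
  sum(mdp$p0 * V0)
}

#' Sample trajectories from a tabular MDP
#'
#' States are emitted as one-hot vectors so the trajectories plug directly
#' into [fit_backward()]. Actions follow a uniform-random behaviour policy.
#'
#' @param mdp A tabular MDP.
#' @param n Number of trajectories.
#' @param seed Integer seed.
#' @return An `ot_trajectories` list.
#' @export
sample_mdp_trajectories <- function(mdp, n, seed = 1) {
  validate_mdp(mdp)
  with_seed(seed, {
    n0 <- length(mdp$p0); n1 <- dim(mdp$P2)[1]; n2 <- nrow(mdp$R)
    s0 <- sample.int(n0, n, replace = TRUE, prob = mdp$p0)
    a1 <- sample(0:1, n, replace = TRUE)
    s1 <- vapply(seq_len(n), function(i)
      sample.int(n1, 1, prob = mdp$P1[s0[i], a1[i] + 1, ]), integer(1))
    a2 <- sample(0:1, n, replace = TRUE)
    s2 <- vapply(seq_len(n), function(i)
      sample.int(n2, 1, prob = mdp$P2[s1[i], a2[i] + 1, ]), integer(1))
    a3 <- sample(0:1, n, replace = TRUE)
    reward <- mdp$R[cbind(s2, a3 + 1)]
    onehot <- function(s, k, prefix) {
      m <- matrix(0, length(s), k,
                  dimnames = list(NULL, paste0(prefix, seq_len(k))))
      m[cbind(seq_along(s), s)] <- 1
      m
    }
    out <- list(s0 = onehot(s0, n0, "s0_"), s1 = onehot(s1, n1, "s1_"),
                s2 = onehot(s2, n2, "s2_"), a1 = a1, a2 = a2, a3 = a3,
                reward = reward, patient_id = as.character(seq_len(n)),
                outcome = "reward",
                state_index = list(s0 = s0, s1 = s1, s2 = s2))
    class(out) <- "ot_trajectories"
    out
  })
}

# ---- environments and open-loop planning ------------------------------------

#' Simulation environments for open-loop planning
#'
#' An environment is a list with a single function `rollout(sequence)`
#' returning the (possibly stochastic) terminal reward of one episode under
#' a fixed decision sequence. `mdp_env()` wraps a tabular MDP;
#' `generator_env()` wraps the synthetic generator's outcome law.
#'
#' @param mdp A tabular MDP.
#' @param config A [generator_config()].
#' @return An environment list.
#' @export
mdp_env <- function(mdp) {
  validate_mdp(mdp)
  list(rollout = function(sequence) {
    s0 <- sample.int(length(mdp$p0), 1, prob = mdp$p0)
    s1 <- sample.int(dim(mdp$P2)[1], 1, prob = mdp$P1[s0, sequence[1] + 1, ])
    s2 <- sample.int(nrow(mdp$R), 1, prob = mdp$P2[s1, sequence[2] + 1, ])
    mdp$R[s2, sequence[3] + 1]
  })
}

#' @rdname mdp_env
#' @export
generator_env <- function(config = generator_config()) {
  validate_generator_config(config)
  m <- config$marginals
  mu <- decision_means(config)
  list(rollout = function(sequence) {
    D <- matrix(sequence, 1, dimnames = list(NULL, c("d1", "d2", "d3")))
    noisy_draw <- function(p0, eff) {
      x <- rbin(1, effect_prob(p0, eff, D, mu))
      flip(x, config$noise)
    }
    os <- noisy_draw(m$os, config$effects$os)
    ft <- noisy_draw(m$ft, config$effects$ft)
    ar <- noisy_draw(m$ar_after, config$effects$ar_after)
    arb <- rbin(1, m$ar_before)
    compute_reward(os, ft, ar, arb)
  })
}

#' Monte-Carlo open-loop planning
#'
#' Estimates the expected terminal reward of every fixed 3-decision sequence
#' by repeated environment rollouts, and reports the best sequence with a
#' deterministic tie-break (lexicographically smallest).
#'
#' @param env An environment (see [mdp_env()]).
#' @param n_samples Rollouts per sequence (>= 1).
#' @param seed Integer seed.
#' @return A tibble of class `ot_sequence_values`: 8 rows with `value`
#'   (Monte-Carlo mean), `se`, and `n`; the best row index in
#'   `attr(, "best")`.
#' @export
open_loop_plan <- function(env, n_samples = 1000, seed = 1) {
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  seqs <- enumerate_sequences(3)
  res <- with_seed(seed, purrr::pmap(seqs, function(d1, d2, d3) {
    r <- tryCatch(
      vapply(seq_len(n_samples), function(i) env$rollout(c(d1, d2, d3)),
             numeric(1)),
      error = function(e) abort(sprintf(
        "Environment rollout failed for sequence (%d,%d,%d): %s",
        d1, d2, d3, conditionMessage(e))))
    c(mean(r), if (n_samples > 1) sd(r) / sqrt(n_samples) else 0)
  }))
  seqs$value <- purrr::map_dbl(res, 1)
  seqs$se <- purrr::map_dbl(res, 2)
  seqs$n <- n_samples
  attr(seqs, "best") <- which.max(seqs$value)
  class(seqs) <- c("ot_sequence_values", class(seqs))
  seqs
}
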