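# Shared fixtures, built in code. Expensive objects are memoised per test
# file via local caches.

fast_grid <- function() expand.grid(cost = c(1, 10), gamma = c(0.01, 0.1))

# Generate, split and preprocess a cohort; returns everything downstream
# stages need.
prep_cohort <- function(config, split_seed = 1, train_fraction = 0.75) {
  cohort <- generate_cohort(config)
  parts <- split_cohort(cohort, train_fraction, seed = split_seed)
  train <- impute_missing(parts$train)
  test <- impute_missing(parts$test,
                         stats = attr(train, "imputation_stats"))
  enc <- encode_features(train)
  list(cohort = cohort, train = train, test = test,
       scaling = attr(enc, "scaling"), schema = default_schema())
}

# A tiny schema for arithmetic-level encoding checks.
toy_schema <- function() {
  as_schema(tibble::tibble(
    name = c("x", "flag", "ord", "cat"),
    kind = c("numeric", "binary", "ordinal", "categorical"),
    group = c("1", "1", "1", "1"),
    levels = list(NULL, NULL, c("low", "mid", "high"), c("a", "b")),
    na_levels = list(NULL, NULL, NULL, NULL)
  ))
}

toy_table <- function() {
  tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    x = c(2, 6, 4),
    flag = c(0L, 1L, 1L),
    ord = c("low", "high", "mid"),
    cat = c("a", "b", "a")
  )
}

# Hand-built linear policy stack: Q(s, a) = w_state . s + w0 * 1[a=0] +
# w1 * 1[a=1]. Used to test prescription logic without fitting.
manual_stack <- function(state_dim, w0 = 0, w1 = 0,
                         w_state = rep(0, state_dim)) {
  lin_mlp <- function() {
    structure(list(W = list(matrix(c(w_state, w0, w1), ncol = 1)),
                   b = list(0), hidden = integer(0), epochs = 0L,
                   loss = 0, lr_final = 0, input_dim = state_dim + 2L,
                   input_names = NULL),
              class = "ot_mlp")
  }
  q <- function(stage) structure(list(stage = stage, model = lin_mlp(),
                                      state_dim = state_dim,
                                      fitted_at = Sys.time()),
                                 class = "ot_stage_q")
  structure(list(q1 = q(1), q2 = q(2), q3 = q(3),
                 spec = network_spec(0, 1), metadata = tibble::tibble(),
                 n_train = 0L, train_ids = character(0)),
            class = "ot_policy_stack")
}

# Deterministic XOR-style MDP: a fair coin is revealed in the stage-1 state
# and the terminal reward is 1 when a3 matches it. Closed-loop value 1;
# every open-loop sequence gets 0.5.
xor_mdp <- function() {
  P1 <- array(0, c(1, 2, 2)); P1[1, 1, ] <- c(0.5, 0.5); P1[1, 2, ] <- c(0.5, 0.5)
  P2 <- array(0, c(2, 2, 2))
  for (a in 1:2) { P2[1, a, ] <- c(1, 0); P2[2, a, ] <- c(0, 1) }
  R <- rbind(c(1, 0), c(0, 1))
  list(p0 = 1, P1 = P1, P2 = P2, R = R)
}
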