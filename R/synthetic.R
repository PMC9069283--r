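
# synthetic_cohort: generative stand-in for the (private) clinical cohort.
#
# Per-feature Bernoulli/categorical structure with a stochastic physician
# policy and additive log-odds effects of the three decisions on downstream
# features and outcomes. Effects are centered at the physician decision
# rates, so the printed marginal frequencies stay calibrated even when
# effects are nonzero. Treatment-coupled blocks (prescribed chemotherapy,
# responses to induction, concurrent regimen, dose-limiting toxicity) are
# generated conditionally on the decision that enables them, mirroring the
# printed tables where e.g. the imaging and induction counts coincide.

safe_qlogis <- function(p) qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))

clamp01 <- function(p) ifelse(p < 1e-9, 0, ifelse(p > 1 - 1e-9, 1, p))

#' Generator configuration
#'
#' Defaults are transcribed from the published full-cohort marginal tables
#' (N = 536): pretreatment feature frequencies, physician decision rates
#' (D1 36.2%, D2 76.5%, D3 20.7%), treatment-conditional intermediate
#' frequencies, and outcome marginals (4-year survival 85.3%, feeding tube
#' 18.3%, aspiration after therapy 18.3%). `effects` carries additive
#' log-odds effects of (d1, d2, d3) on outcome and late-response features,
#' centered at the physician decision rates; `physician` carries per-decision
#' logistic policies (target rate plus optional weights on binary state
#' features). `noise` is a per-outcome label-flip probability and
#' `missingness` the per-feature missing-cell rate.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param marginals,physician,effects,conditionals,noise,missingness,radiomics
#'   Optional overrides of the corresponding default blocks (supply only the
#'   entries to change).
#' @return A list of class `ot_generator_config`.
#' @export
generator_config <- function(n = 536, seed = 1, marginals = list(),
                             physician = list(), effects = list(),
                             conditionals = list(), noise = 0,
                             missingness = NULL, radiomics = FALSE) {
  cfg <- list(
    n = n, seed = seed,
    marginals = utils::modifyList(default_marginals(), marginals),
    physician = utils::modifyList(default_physician(), physician),
    effects = utils::modifyList(default_effects(), effects),
    conditionals = utils::modifyList(default_conditionals(), conditionals),
    noise = noise,
    missingness = missingness %||% c(grade = 99 / 536, ajcc = 2 / 536,
                                     packs_year = 28 / 536),
    radiomics = radiomics
  )
  class(cfg) <- "ot_generator_config"
  validate_generator_config(cfg)
  cfg
}

default_marginals <- function() {
  list(
    age = c(mean = 58.9, sd = 9.5),
    grade = c(I = 6, II = 154, III = 274, IV = 3) / 437,
    sex_male = 471 / 536,
    hpv = c(negative = 43, unknown = 188, positive = 305) / 536,
    t_cat = c(T1 = 113, T2 = 219, T3 = 116, T4 = 86, Tx = 2) / 536,
    n_cat = c(N0 = 20, N1 = 249, N2 = 250, N3 = 17) / 536,
    ajcc = c(I = 186, II = 81, III = 64, IV = 203) / 534,
    smoking = c(current = 115, former = 203, never = 218) / 536,
    packs_year = c(mean = 17.7, sd = 23.7),
    ar_before = 16 / 536,
    nodes = c(mean = 2.0, sd = 1.3),
    laterality = c(bilateral = 21, left = 242, right = 273) / 536,
    subsite = c(base_of_tongue = 266, tonsil = 223, other = 47) / 536,
    race = c(black = 16, asian = 4, hispanic = 21, native_american = 1,
             white_other = 494) / 536,
    os = 457 / 536,
    ft = 98 / 536,
    ar_after = 98 / 536,
    cr_primary_2 = 450 / 536,
    cr_nodal_2 = 247 / 536,
    pr_primary_2 = 77 / 536,
    pr_nodal_2 = 257 / 536,
    sd_primary_2 = 2 / 536,
    sd_nodal_2 = 10 / 536
  )
}

default_physician <- function() {
  list(
    d1 = list(rate = 194 / 536, weights = NULL),
    d2 = list(rate = 410 / 536, weights = NULL),
    d3 = list(rate = 111 / 536, weights = NULL)
  )
}

# Centered additive log-odds effects of decisions; modest defaults keeping
# the decision sequence consequential without moving the calibrated
# marginals appreciably.
default_effects <- function() {
  list(
    os = c(d1 = 0.2, d2 = 0.5, d3 = 0.1),
    ft = c(d1 = 0.2, d2 = 0.4, d3 = 0.3),
    ar_after = c(d1 = 0.1, d2 = 0.3, d3 = 0.4),
    cr_primary_2 = c(d1 = 0.3, d2 = 0.8),
    cr_nodal_2 = c(d1 = 0.4, d2 = 0.5),
    pr_primary_2 = c(d1 = 0.0, d2 = 0.3),
    pr_nodal_2 = c(d1 = 0.2, d2 = 0.3),
    sd_primary_2 = c(d1 = 0, d2 = 0),
    sd_nodal_2 = c(d1 = 0, d2 = 0)
  )
}

# Frequencies of treatment-coupled features conditional on the enabling
# decision. Printed counts where available; the per-organ-system toxicity
# flags are not printed individually and carry plausible small rates.
default_conditionals <- function() {
  list(
    chemo_given_ic = c(single = 3, doublet = 41, triplet = 143, quadruplet = 7) / 194,
    chemo_mod_given_ic = 85 / 194,
    dlt_grade_given_ic = c("0" = 104, "1" = 7, "2" = 33, "3" = 41, "4" = 9) / 194,
    dlt_sys_given_ic = c(dlt_derm = 0.08, dlt_neuro = 0.10, dlt_gi = 0.12,
                         dlt_heme = 0.12, dlt_nephro = 0.013,
                         dlt_vascular = 0.02, dlt_infection = 0.013,
                         dlt_other = 0.06),
    response_given_ic = c(cr_primary = 84, cr_nodal = 16, pr_primary = 89,
                          pr_nodal = 156, sd_primary = 11, sd_nodal = 10) / 194,
    cc_regimen_given_cc = c(platinum = 257, cetuximab = 129, other = 24) / 410,
    cc_mod_given_cc = 99 / 410,
    dlt2_given_cc = 102 / 410,
    dlt2_sys_given_cc = c(dlt_derm_2 = 0.06, dlt_neuro_2 = 0.06,
                          dlt_gi_2 = 0.09, dlt_heme_2 = 0.10,
                          dlt_nephro_2 = 0.05, dlt_vascular_2 = 0.003,
                          dlt_other_2 = 0.06)
  )
}

validate_generator_config <- function(cfg) {
  if (cfg$n < 0) abort("Cohort size `n` must be non-negative.")
  if (cfg$noise < 0 || cfg$noise > 1) abort("`noise` must lie in [0, 1].")
  cats <- c("grade", "hpv", "t_cat", "n_cat", "ajcc", "smoking", "laterality",
            "subsite", "race")
  for (nm in cats) {
    p <- cfg$marginals[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      abort(sprintf("Inconsistent marginals for `%s`: must be non-negative and sum to 1.", nm))
    }
  }
  for (nm in c("sex_male", "ar_before", "os", "ft", "ar_after",
               "cr_primary_2", "cr_nodal_2", "pr_primary_2", "pr_nodal_2",
               "sd_primary_2", "sd_nodal_2")) {
    p <- cfg$marginals[[nm]]
    if (p < 0 || p > 1) abort(sprintf("Marginal `%s` must lie in [0, 1].", nm))
  }
  for (d in c("d1", "d2", "d3")) {
    r <- cfg$physician[[d]]$rate
    if (r < 0 || r > 1) abort(sprintf("Physician rate for `%s` must lie in [0, 1].", d))
  }
  invisible(cfg)
}

# Decision rates used for effect centering.
decision_means <- function(cfg) {
  c(d1 = cfg$physician$d1$rate, d2 = cfg$physician$d2$rate,
    d3 = cfg$physician$d3$rate)
}

# P(feature = 1) under decisions D (matrix with columns d1..d3), with
# effects centered at the physician rates.
effect_prob <- function(p0, eff, D, mu) {
  lo <- safe_qlogis(p0)
  if (!is.null(eff) && length(eff)) {
    for (d in names(eff)) lo <- lo + eff[[d]] * (D[, d] - mu[[d]])
  }
  clamp01(plogis(lo))
}

rcat <- function(n, probs) {
  names(probs)[1 + findInterval(runif(n), cumsum(probs), left.open = TRUE)]
}

rbin <- function(n, p) rbinom(n, 1L, clamp01(p))

flip <- function(x, noise) {
  if (noise <= 0) return(x)
  f <- rbin(length(x), noise)
  ifelse(f == 1, 1L - x, x)
}

draw_decision <- function(pol, data) {
  lo <- safe_qlogis(pol$rate)
  if (!is.null(pol$weights)) {
    for (f in names(pol$weights)) {
      x <- as.numeric(data[[f]])
      lo <- lo + pol$weights[[f]] * (x - mean(x))
    }
  }
  rbin(nrow(data), plogis(lo))
}

#' Generate a synthetic cohort
#'
#' Draws `n` patients: pretreatment features from the calibrated marginals,
#' three decisions from the physician policy, intermediate features from the
#' treatment-conditional model, and final outcomes from the centered
#' effect model, so outcomes depend on the full decision sequence.
#' Deterministic for a fixed config.
#'
#' @param config An [generator_config()].
#' @return A cohort tibble (schema attached); with `radiomics = TRUE` a
#'   numeric radiomics block is attached as `attr(, "radiomics")`.
#' @export
generate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  m <- config$marginals
  cd <- config$conditionals
  n <- config$n
  schema <- default_schema()
  if (n == 0) {
    empty <- tibble::as_tibble(setNames(
      purrr::map(schema$kind, ~ if (.x == "numeric") numeric(0) else
        if (.x == "binary") integer(0) else character(0)), schema$name))
    return(set_schema(tibble::add_column(empty, patient_id = character(0),
                                         .before = 1), schema))
  }
  with_seed(config$seed, {
    g1 <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = round(rnorm(n, m$age["mean"], m$age["sd"]), 1),
      grade = rcat(n, m$grade),
      sex_male = rbin(n, m$sex_male),
      hpv = rcat(n, m$hpv[c("negative", "unknown", "positive")]),
      t_cat = rcat(n, m$t_cat),
      n_cat = rcat(n, m$n_cat),
      ajcc = rcat(n, m$ajcc),
      smoking = rcat(n, m$smoking),
      packs_year = round(pmax(0, rnorm(n, m$packs_year["mean"], m$packs_year["sd"])), 1),
      ar_before = rbin(n, m$ar_before),
      nodes = pmax(0, round(rnorm(n, m$nodes["mean"], m$nodes["sd"]))),
      laterality = rcat(n, m$laterality),
      subsite = rcat(n, m$subsite),
      race = rcat(n, m$race)
    )
    d1 <- draw_decision(config$physician$d1, g1)
    ic <- d1 == 1
    chemo <- rep("none", n)
    if (any(ic)) chemo[ic] <- rcat(sum(ic), cd$chemo_given_ic)
    dlt_grade <- rep("0", n)
    if (any(ic)) dlt_grade[ic] <- rcat(sum(ic), cd$dlt_grade_given_ic)
    g2 <- tibble::tibble(
      chemo = chemo,
      chemo_mod = ifelse(ic, rbin(n, cd$chemo_mod_given_ic), 0L),
      dlt_grade = dlt_grade,
      dlt = as.integer(dlt_grade != "0"),
      imaging = as.integer(d1)
    )
    for (f in names(cd$dlt_sys_given_ic)) {
      g2[[f]] <- ifelse(ic, rbin(n, cd$dlt_sys_given_ic[[f]]), 0L)
    }
    for (f in names(cd$response_given_ic)) {
      g2[[f]] <- ifelse(ic, rbin(n, cd$response_given_ic[[f]]), 0L)
    }
    df1 <- dplyr::bind_cols(g1, d1 = as.integer(d1), g2)
    d2 <- draw_decision(config$physician$d2, df1)
    cc <- d2 == 1
    mu <- decision_means(config)
    D12 <- cbind(d1 = d1, d2 = d2, d3 = rep(0, n))
    cc_regimen <- rep("none", n)
    if (any(cc)) cc_regimen[cc] <- rcat(sum(cc), cd$cc_regimen_given_cc)
    g3 <- tibble::tibble(
      cc_regimen = cc_regimen,
      cc_mod = ifelse(cc, rbin(n, cd$cc_mod_given_cc), 0L),
      dlt_2 = ifelse(cc, rbin(n, cd$dlt2_given_cc), 0L)
    )
    for (f in names(cd$dlt2_sys_given_cc)) {
      g3[[f]] <- ifelse(cc, rbin(n, cd$dlt2_sys_given_cc[[f]]), 0L)
    }
    for (f in c("cr_primary_2", "cr_nodal_2", "pr_primary_2", "pr_nodal_2",
                "sd_primary_2", "sd_nodal_2")) {
      g3[[f]] <- rbin(n, effect_prob(m[[f]], config$effects[[f]], D12, mu))
    }
    df2 <- dplyr::bind_cols(df1, d2 = as.integer(d2), g3)
    d3 <- draw_decision(config$physician$d3, df2)
    D <- cbind(d1 = d1, d2 = d2, d3 = d3)
    g4 <- tibble::tibble(
      os = flip(rbin(n, effect_prob(m$os, config$effects$os, D, mu)), config$noise),
      ft = flip(rbin(n, effect_prob(m$ft, config$effects$ft, D, mu)), config$noise),
      ar_after = flip(rbin(n, effect_prob(m$ar_after, config$effects$ar_after, D, mu)),
                      config$noise)
    )
    out <- dplyr::bind_cols(df2, d3 = as.integer(d3), g4)
    for (f in names(config$missingness)) {
      r <- config$missingness[[f]]
      if (r > 0) out[[f]][rbin(n, r) == 1] <- NA
    }
    out <- out[, c("patient_id", default_schema()$name)]
    out <- set_schema(out, schema)
    if (isTRUE(config$radiomics) || is.list(config$radiomics)) {
      rcfg <- if (is.list(config$radiomics)) config$radiomics else list()
      attr(out, "radiomics") <- generate_radiomics(
        n, p = rcfg$p %||% 1000, n_factors = rcfg$n_factors %||% 6,
        noise_sd = rcfg$noise_sd %||% 0.3)
    }
    out
  })
}

# Correlated-Gaussian radiomics block: a low-rank factor structure so a
# handful of principal components carries ~all the variance. Drawn inside
# the generator's seeded RNG scope.
generate_radiomics <- function(n, p = 1000, n_factors = 6, noise_sd = 0.3) {
  z <- matrix(rnorm(n * n_factors), n, n_factors)
  l <- matrix(rnorm(n_factors * p), n_factors, p)
  x <- z %*% l + matrix(rnorm(n * p, sd = noise_sd), n, p)
  colnames(x) <- sprintf("radiomic_%04d", seq_len(p))
  x
}

#' Exact expected reward of each open-loop sequence
#'
#' Under the generative law, the outcome probabilities depend on the decision
#' sequence only (through the centered effect model), so the expected
#' composite reward of each of the 8 fixed sequences has a closed form:
#' `E[os] - E[ft] - E[ar_after] + E[ar_before]`, with label-flip noise folded
#' in analytically.
#'
#' @param config A [generator_config()].
#' @return A list of class `ot_ground_truth` with `values` (a tibble with one
#'   row per sequence, lexicographic order) and `optimal` (the row index of
#'   the best sequence; ties go to the lexicographically smallest).
#' @export
true_sequence_values <- function(config = generator_config()) {
  validate_generator_config(config)
  m <- config$marginals
  mu <- decision_means(config)
  seqs <- enumerate_sequences(3)
  D <- as.matrix(seqs)
  colnames(D) <- c("d1", "d2", "d3")
  noisy <- function(p) p * (1 - config$noise) + (1 - p) * config$noise
  p_os <- noisy(effect_prob(m$os, config$effects$os, D, mu))
  p_ft <- noisy(effect_prob(m$ft, config$effects$ft, D, mu))
  p_ar <- noisy(effect_prob(m$ar_after, config$effects$ar_after, D, mu))
  values <- tibble::tibble(
    d1 = D[, 1], d2 = D[, 2], d3 = D[, 3],
    p_os = p_os, p_ft = p_ft, p_ar_after = p_ar,
    value = p_os - p_ft - p_ar + m$ar_before
  )
  out <- list(values = values, optimal = which.max(values$value))
  class(out) <- "ot_ground_truth"
  out
}

#' Ensure a minimum number of advanced-stage records
#'
#' Rewrites the tumour category of the first non-advanced records to `T3`
#' until at least `k` records satisfy the advanced-stage predicate
#' (T3-4 or N1-3), for exercising the guideline-compliance audit.
#'
#' @param data Cohort tibble.
#' @param k Required number of advanced-stage records (`k <= nrow(data)`).
#' @return The adjusted tibble.
#' @export
inject_guideline_cases <- function(data, k) {
  if (k > nrow(data)) abort("`k` cannot exceed the cohort size.")
  adv <- is_advanced_stage(data$t_cat, data$n_cat)
  need <- k - sum(adv)
  if (need > 0) {
    idx <- head(which(!adv), need)
    data$t_cat[idx] <- "T3"
  }
  data
}

# Advanced-stage predicate (T3-4 or N1-3); unknown T codes count as
# non-advanced on the T axis.
is_advanced_stage <- function(t_cat, n_cat) {
  (t_cat %in% c("T3", "T4")) | (n_cat %in% c("N1", "N2", "N3"))
}

#' Stress-test generator presets
#'
#' `config_noiseless()` makes every transition and outcome a deterministic
#' function of the decisions (a perfect-simulator regime); `config_dominant()`
#' creates one decision sequence whose true expected reward exceeds all
#' others by a clear margin (induction and concurrent chemotherapy help
#' survival strongly, neck dissection is strongly toxic), for
#' policy-recovery checks.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return A `generator_config()`.
#' @export
config_noiseless <- function(n = 536, seed = 1) {
  big <- 80
  generator_config(
    n = n, seed = seed,
    marginals = list(ar_before = 0, os = 0.5, ft = 0.5, ar_after = 0,
                     cr_primary_2 = 0.5, cr_nodal_2 = 0, pr_primary_2 = 0,
                     pr_nodal_2 = 0, sd_primary_2 = 0, sd_nodal_2 = 0),
    physician = list(d1 = list(rate = 0.5, weights = NULL),
                     d2 = list(rate = 0.5, weights = NULL),
                     d3 = list(rate = 0.5, weights = NULL)),
    effects = list(os = c(d1 = 0, d2 = big, d3 = 0),
                   ft = c(d1 = 0, d2 = 0, d3 = big),
                   ar_after = c(d1 = 0, d2 = 0, d3 = 0),
                   cr_primary_2 = c(d1 = 0, d2 = big),
                   cr_nodal_2 = c(d1 = 0, d2 = 0),
                   pr_primary_2 = c(d1 = 0, d2 = 0),
                   pr_nodal_2 = c(d1 = 0, d2 = 0)),
    conditionals = list(
      chemo_given_ic = c(single = 0, doublet = 1, triplet = 0, quadruplet = 0),
      chemo_mod_given_ic = 0,
      dlt_grade_given_ic = c("0" = 0, "1" = 0, "2" = 1, "3" = 0, "4" = 0),
      dlt_sys_given_ic = c(dlt_derm = 0, dlt_neuro = 0, dlt_gi = 1,
                           dlt_heme = 0, dlt_nephro = 0, dlt_vascular = 0,
                           dlt_infection = 0, dlt_other = 0),
      response_given_ic = c(cr_primary = 1, cr_nodal = 0, pr_primary = 0,
                            pr_nodal = 0, sd_primary = 0, sd_nodal = 0),
      cc_regimen_given_cc = c(platinum = 1, cetuximab = 0, other = 0),
      cc_mod_given_cc = 0,
      dlt2_given_cc = 1,
      dlt2_sys_given_cc = c(dlt_derm_2 = 0, dlt_neuro_2 = 0, dlt_gi_2 = 0,
                            dlt_heme_2 = 0, dlt_nephro_2 = 0,
                            dlt_vascular_2 = 0, dlt_other_2 = 0)
    ),
    missingness = c(grade = 0, ajcc = 0, packs_year = 0)
  )
}

#' @rdname config_noiseless
#' @export
config_dominant <- function(n = 536, seed = 1) {
  generator_config(
    n = n, seed = seed,
    marginals = list(os = 0.5),
    effects = list(os = c(d1 = 2, d2 = 2, d3 = 0),
                   ft = c(d1 = 0, d2 = 0, d3 = 2.5),
                   ar_after = c(d1 = 0, d2 = 0, d3 = 2.5)),
    missingness = c(grade = 0, ajcc = 0, packs_year = 0)
  )
}
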