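
#' Published cohort summary counts
#'
#' Marginal counts for the single-institution oropharyngeal-cancer cohort
#' (N = 536; 402 training / 134 testing after the 75/25 split) that the
#' synthetic generator is calibrated against: physician decision rates,
#' final-outcome frequencies, and the main pretreatment marginals. These are
#' the only cohort quantities the package carries; the patient-level data are
#' not public.
#'
#' @return A tibble with columns `feature`, `level`, `n_all`, `n_train`,
#'   `n_test`. Binary features report the count of the level named;
#'   complements follow by subtraction from the totals (536/402/134).
#' @export
reported_marginals <- function() {
  tribble <- tibble::tribble
  tribble(
    ~feature, ~level, ~n_all, ~n_train, ~n_test,
    "n_patients", "total", 536L, 402L, 134L,
    # physician decisions
    "d1", "yes", 194L, 152L, 42L,
    "d2", "yes", 410L, 313L, 97L,
    "d3", "yes", 111L, 84L, 27L,
    # group 4 outcomes
    "os", "alive", 457L, 344L, 113L,
    "ft", "yes", 98L, 77L, 21L,
    "ar_after", "yes", 98L, 79L, 19L,
    "dysphagia", "yes", 154L, 122L, 32L,
    # selected pretreatment marginals
    "sex_male", "yes", 471L, 355L, 116L,
    "hpv", "negative", 43L, 33L, 10L,
    "hpv", "positive", 305L, 228L, 77L,
    "hpv", "unknown", 188L, 141L, 47L,
    "t_cat", "T1", 113L, 87L, 26L,
    "t_cat", "T2", 219L, 156L, 63L,
    "t_cat", "T3", 116L, 91L, 25L,
    "t_cat", "T4", 86L, 67L, 19L,
    "t_cat", "Tx", 2L, 1L, 1L,
    "n_cat", "N0", 20L, 14L, 6L,
    "n_cat", "N1", 249L, 181L, 68L,
    "n_cat", "N2", 250L, 194L, 56L,
    "n_cat", "N3", 17L, 13L, 4L,
    "ar_before", "no_recorded", 16L, 14L, 2L
  )
}

# Convenience: published full-cohort rate of a binary feature, as a fraction.
reported_rate <- function(feature, set = c("all", "train", "test")) {
  set <- match.arg(set)
  m <- reported_marginals()
  col <- paste0("n_", set)
  total <- m[[col]][m$feature == "n_patients"]
  n <- m[[col]][m$feature == feature][1]
  n / total
}
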