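
#' Cohort feature schema
#'
#' The schema names every column of a cohort table and assigns it a kind
#' (`numeric`, `binary`, `ordinal`, `categorical`) and a stage group:
#' group 1 holds pretreatment features, group 2 the features observed after
#' the induction-chemotherapy decision (D1), group 3 those observed after the
#' concurrent-chemotherapy decision (D2), and group 4 the final outcomes
#' (4-year overall survival, feeding-tube dependence at 6 months, and
#' aspiration after therapy). The three physician decisions are carried in
#' group `"decision"`. Ordinal and categorical kinds list their levels in
#' order; levels named in `na_levels` (e.g. an unrecorded tumour category
#' `Tx`) are treated as missing when features are encoded, but are preserved
#' in the raw table for audits.
#'
#' @param x For `as_schema`, a data frame with columns `name`, `kind`,
#'   `group`, and optionally list-columns `levels` and `na_levels`.
#' @return A tibble of class `ot_schema`.
#' @export
default_schema <- function() {
  lv <- function(...) list(c(...))
  rows <- list(
    # group 1: pretreatment
    list("age", "numeric", "1", NULL, NULL),
    list("grade", "ordinal", "1", c("I", "II", "III", "IV"), NULL),
    list("sex_male", "binary", "1", NULL, NULL),
    # 'unknown' sits between the poles so that it encodes to the
    # distinguished value 0 after [-1, 1] rescaling
    list("hpv", "ordinal", "1", c("negative", "unknown", "positive"), NULL),
    list("t_cat", "ordinal", "1", c("T1", "T2", "T3", "T4", "Tx"), "Tx"),
    list("n_cat", "ordinal", "1", c("N0", "N1", "N2", "N3"), NULL),
    list("ajcc", "ordinal", "1", c("I", "II", "III", "IV"), NULL),
    list("smoking", "categorical", "1", c("current", "former", "never"), NULL),
    list("packs_year", "numeric", "1", NULL, NULL),
    list("ar_before", "binary", "1", NULL, NULL),
    list("nodes", "numeric", "1", NULL, NULL),
    list("laterality", "categorical", "1", c("bilateral", "left", "right"), NULL),
    list("subsite", "categorical", "1", c("base_of_tongue", "tonsil", "other"), NULL),
    list("race", "categorical", "1",
         c("black", "asian", "hispanic", "native_american", "white_other"), NULL),
    # group 2: post-D1
    list("chemo", "ordinal", "2",
         c("none", "single", "doublet", "triplet", "quadruplet"), NULL),
    list("chemo_mod", "binary", "2", NULL, NULL),
    list("dlt", "binary", "2", NULL, NULL),
    list("dlt_grade", "ordinal", "2", c("0", "1", "2", "3", "4"), NULL),
    list("dlt_derm", "binary", "2", NULL, NULL),
    list("dlt_neuro", "binary", "2", NULL, NULL),
    list("dlt_gi", "binary", "2", NULL, NULL),
    list("dlt_heme", "binary", "2", NULL, NULL),
    list("dlt_nephro", "binary", "2", NULL, NULL),
    list("dlt_vascular", "binary", "2", NULL, NULL),
    list("dlt_infection", "binary", "2", NULL, NULL),
    list("dlt_other", "binary", "2", NULL, NULL),
    list("imaging", "binary", "2", NULL, NULL),
    list("cr_primary", "binary", "2", NULL, NULL),
    list("cr_nodal", "binary", "2", NULL, NULL),
    list("pr_primary", "binary", "2", NULL, NULL),
    list("pr_nodal", "binary", "2", NULL, NULL),
    list("sd_primary", "binary", "2", NULL, NULL),
    list("sd_nodal", "binary", "2", NULL, NULL),
    # group 3: post-D2
    list("cc_regimen", "categorical", "3",
         c("none", "platinum", "cetuximab", "other"), NULL),
    list("cc_mod", "binary", "3", NULL, NULL),
    list("cr_primary_2", "binary", "3", NULL, NULL),
    list("cr_nodal_2", "binary", "3", NULL, NULL),
    list("pr_primary_2", "binary", "3", NULL, NULL),
    list("pr_nodal_2", "binary", "3", NULL, NULL),
    list("sd_primary_2", "binary", "3", NULL, NULL),
    list("sd_nodal_2", "binary", "3", NULL, NULL),
    list("dlt_2", "binary", "3", NULL, NULL),
    list("dlt_derm_2", "binary", "3", NULL, NULL),
    list("dlt_neuro_2", "binary", "3", NULL, NULL),
    list("dlt_gi_2", "binary", "3", NULL, NULL),
    list("dlt_heme_2", "binary", "3", NULL, NULL),
    list("dlt_nephro_2", "binary", "3", NULL, NULL),
    list("dlt_vascular_2", "binary", "3", NULL, NULL),
    list("dlt_other_2", "binary", "3", NULL, NULL),
    # group 4: outcomes (never used in any state vector)
    list("os", "binary", "4", NULL, NULL),
    list("ft", "binary", "4", NULL, NULL),
    list("ar_after", "binary", "4", NULL, NULL),
    # physician decisions
    list("d1", "binary", "decision", NULL, NULL),
    list("d2", "binary", "decision", NULL, NULL),
    list("d3", "binary", "decision", NULL, NULL)
  )
  out <- tibble::tibble(
    name = purrr::map_chr(rows, 1),
    kind = purrr::map_chr(rows, 2),
    group = purrr::map_chr(rows, 3),
    levels = purrr::map(rows, 4),
    na_levels = purrr::map(rows, 5)
  )
  as_schema(out)
}

#' @rdname default_schema
#' @export
as_schema <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("name", "kind", "group")
  if (!all(needed %in% names(x))) {
    abort("A schema needs columns `name`, `kind`, `group`.")
  }
  if (anyDuplicated(x$name)) abort("Schema feature names must be unique.")
  bad <- setdiff(unique(x$kind), c("numeric", "binary", "ordinal", "categorical"))
  if (length(bad)) abort(sprintf("Unknown schema kind(s): %s", toString(bad)))
  if (!"levels" %in% names(x)) x$levels <- vector("list", nrow(x))
  if (!"na_levels" %in% names(x)) x$na_levels <- vector("list", nrow(x))
  class(x) <- c("ot_schema", class(x))
  x
}

#' Read or write a schema as YAML
#'
#' @param path File path.
#' @param schema An `ot_schema`.
#' @return `read_schema()` returns an `ot_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  as_schema(tibble::tibble(
    name = purrr::map_chr(y, "name"),
    kind = purrr::map_chr(y, "kind"),
    group = purrr::map_chr(y, ~ as.character(.x$group)),
    levels = purrr::map(y, ~ if (is.null(.x$levels)) NULL else as.character(.x$levels)),
    na_levels = purrr::map(y, ~ if (is.null(.x$na_levels)) NULL else as.character(.x$na_levels))
  ))
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  y <- purrr::pmap(schema, function(name, kind, group, levels, na_levels) {
    out <- list(name = name, kind = kind, group = group)
    if (!is.null(levels)) out$levels <- as.list(levels)
    if (!is.null(na_levels)) out$na_levels <- as.list(na_levels)
    out
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

# Feature names belonging to given group(s), in schema order.
schema_features <- function(schema, groups) {
  schema$name[schema$group %in% as.character(groups)]
}

schema_row <- function(schema, feature) {
  i <- match(feature, schema$name)
  if (is.na(i)) abort(sprintf("Feature `%s` is not in the schema.", feature))
  schema[i, ]
}

# Groups whose features enter the state at a given stage (0, 1, 2).
state_groups <- function(stage) as.character(seq_len(stage + 1))

# Decisions appended (one-hot) to the state at a given stage.
state_decisions <- function(stage) {
  if (stage == 0) character(0) else paste0("d", seq_len(stage))
}
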