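
# cohort_io: parsing, preprocessing and state construction for the flat
# patient table. Training statistics (imputation values, scaling ranges, PCA
# projection) are always fit on the table they are given and can be reused on
# held-out rows, so test-set transforms never touch test statistics.

get_schema <- function(data, schema = NULL) {
  schema %||% attr(data, "ot_schema") %||% default_schema()
}

set_schema <- function(data, schema) {
  attr(data, "ot_schema") <- schema
  data
}

#' Read a cohort CSV
#'
#' Reads a one-row-per-patient table, validates it against the schema, and
#' coerces each column to its declared kind. Cells that cannot be parsed
#' (or carry a missing-value sentinel) become `NA` and are handled later by
#' [impute_missing()]; rows are never dropped.
#'
#' @param path Path to a UTF-8 CSV with a header row and a `patient_id`
#'   column.
#' @param schema An [`ot_schema`][default_schema]; defaults to
#'   [default_schema()].
#' @param na Strings treated as missing.
#' @return A tibble (one row per patient) carrying the schema as an
#'   attribute.
#' @export
read_cohort <- function(path, schema = default_schema(), na = c("", "NA")) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("patient_id", schema$name), names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Cohort is missing mandatory column(s): %s",
                  toString(missing_cols)))
  }
  if (anyDuplicated(raw$patient_id)) {
    abort("Duplicate patient_id values in cohort input.")
  }
  out <- tibble::tibble(patient_id = raw$patient_id)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- raw[[nm]]
    v[v %in% na] <- NA_character_
    out[[nm]] <- switch(
      schema$kind[i],
      numeric = suppressWarnings(as.numeric(v)),
      binary = {
        x <- suppressWarnings(as.integer(v))
        x[!x %in% c(0L, 1L)] <- NA_integer_
        x
      },
      ordinal = ,
      categorical = {
        lv <- schema$levels[[i]]
        v[!v %in% lv] <- NA_character_
        v
      }
    )
  }
  set_schema(out, schema)
}

#' Write a cohort CSV
#'
#' @param data A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

# Most frequent value; ties broken by schema level order (categorical) or
# sorted value (numeric-coded binaries), so imputation is deterministic.
mode_value <- function(x, levels = NULL) {
  x <- x[!is.na(x)]
  tab <- table(factor(x, levels = levels %||% sort(unique(x))))
  names(tab)[which.max(tab)]
}

#' Impute missing values with training statistics
#'
#' Numeric features are imputed with the median and categorical/ordinal/
#' binary features with the mode, computed on the supplied table only (the
#' training set). HPV/P16 status is the one exception: an unknown status is
#' a real clinical category carrying the distinguished encoded value 0, so
#' missing HPV cells become `"unknown"` and are never mode-imputed. Ordinal
#' levels declared in the schema's `na_levels` (e.g. `Tx`) are treated as
#' missing here; the raw table should be kept when those codes matter for
#' audits.
#'
#' @param data Cohort tibble (possibly with `NA`s).
#' @param schema Schema; defaults to the one attached to `data`.
#' @param stats A fitted imputation map from a previous call, to transform a
#'   held-out table with training statistics. `NULL` fits on `data`.
#' @return The completed tibble, with the fitted map in
#'   `attr(, "imputation_stats")`.
#' @export
impute_missing <- function(data, schema = NULL, stats = NULL) {
  schema <- get_schema(data, schema)
  fit <- is.null(stats)
  if (fit) stats <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    x <- data[[nm]]
    na_lv <- schema$na_levels[[i]]
    if (!is.null(na_lv)) x[x %in% na_lv] <- NA
    if (nm == "hpv") {
      x[is.na(x)] <- "unknown"
      data[[nm]] <- x
      next
    }
    if (!anyNA(x)) {
      if (fit) {
        stats[[nm]] <- if (kind == "numeric") median(x) else
          mode_value(x, if (kind %in% c("ordinal", "categorical"))
            setdiff(schema$levels[[i]], na_lv))
      }
      data[[nm]] <- x
      next
    }
    if (fit) {
      if (all(is.na(x))) {
        abort(sprintf("Column `%s` is entirely missing; no statistic to compute.", nm))
      }
      stats[[nm]] <- if (kind == "numeric") median(x, na.rm = TRUE) else
        mode_value(x, if (kind %in% c("ordinal", "categorical"))
          setdiff(schema$levels[[i]], na_lv))
    }
    fill <- stats[[nm]]
    if (is.null(fill)) {
      abort(sprintf("No imputation statistic available for column `%s`.", nm))
    }
    if (kind == "numeric") {
      x[is.na(x)] <- as.numeric(fill)
    } else if (kind == "binary") {
      x[is.na(x)] <- as.integer(fill)
    } else {
      x[is.na(x)] <- as.character(fill)
    }
    data[[nm]] <- x
  }
  attr(data, "imputation_stats") <- stats
  data
}

# Expand features to raw numeric columns (before [-1, 1] rescaling):
# numeric/binary as-is, ordinal as consecutive integers over the non-missing
# levels, categorical as 0/1 one-hot columns named feature.level.
encode_raw <- function(data, schema, features) {
  cols <- list()
  for (nm in features) {
    row <- schema_row(schema, nm)
    kind <- row$kind
    x <- data[[nm]]
    if (kind == "numeric") {
      cols[[nm]] <- as.numeric(x)
    } else if (kind == "binary") {
      if (anyNA(x)) abort(sprintf("Binary feature `%s` has missing values; impute first.", nm))
      cols[[nm]] <- as.numeric(x)
    } else {
      lv <- setdiff(row$levels[[1]], row$na_levels[[1]])
      bad <- setdiff(unique(x), lv)
      if (length(bad)) {
        abort(sprintf("Feature `%s` has unencodable value(s): %s", nm, toString(bad)))
      }
      if (kind == "ordinal") {
        cols[[nm]] <- as.numeric(match(x, lv) - 1)
      } else {
        for (l in lv) cols[[paste0(nm, ".", l)]] <- as.numeric(x == l)
      }
    }
  }
  out <- tibble::as_tibble(cols)
  if (anyNA(out)) abort("Encoded features contain missing values; impute first.")
  out
}

#' Encode and rescale features to [-1, 1]
#'
#' Ordinals become consecutive integers (preserving their stated order),
#' unordered categoricals are one-hot expanded, and every resulting column is
#' affinely mapped to the \eqn{[-1, +1]} range using the min/max observed in
#' the fitting table. A constant column maps to 0. When a fitted `scaling`
#' map is supplied, its ranges and level maps are reused and out-of-range
#' held-out values are clipped to \eqn{[-1, +1]}, so the range contract holds
#' for any table.
#'
#' @param data A fully imputed cohort tibble.
#' @param schema Schema; defaults to the attached one.
#' @param features Features to encode; defaults to all state features
#'   (groups 1-3). Group-4 outcomes and decisions are never encoded here.
#' @param scaling A fitted scaling map from a previous call, or `NULL` to fit.
#' @return A tibble of encoded columns in \eqn{[-1, 1]}, with the scaling map
#'   in `attr(, "scaling")`.
#' @export
encode_features <- function(data, schema = NULL, features = NULL, scaling = NULL) {
  schema <- get_schema(data, schema)
  if (is.null(features)) {
    features <- if (is.null(scaling)) schema_features(schema, 1:3) else scaling$features
  }
  raw <- encode_raw(data, schema, features)
  fit <- is.null(scaling)
  if (fit) {
    ranges <- purrr::map(raw, ~ c(min(.x), max(.x)))
    layout <- split(names(raw), factor(
      sub("\\..*$", "", names(raw)), levels = unique(sub("\\..*$", "", names(raw)))))
    scaling <- list(features = features, ranges = ranges, layout = layout)
  } else {
    needed <- unlist(scaling$layout[features], use.names = FALSE)
    unknown <- setdiff(needed, names(scaling$ranges))
    if (length(unknown)) {
      abort(sprintf("Scaling map has no range for column(s): %s",
                    toString(unknown)))
    }
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols)) {
      abort(sprintf("Data lacks column(s) required by the scaling map: %s",
                    toString(missing_cols)))
    }
    raw <- raw[needed]
  }
  out <- purrr::imap(raw, function(x, nm) {
    r <- scaling$ranges[[nm]]
    if (r[1] == r[2]) return(rep(0, length(x)))
    pmin(1, pmax(-1, 2 * (x - r[1]) / (r[2] - r[1]) - 1))
  })
  out <- tibble::as_tibble(out)
  attr(out, "scaling") <- scaling
  attr(out, "refit") <- fit
  out
}

#' Reduce a radiomics block by principal components
#'
#' Fits a PCA (centering only) on the supplied rows and keeps the minimal
#' number of leading components whose cumulative explained-variance ratio
#' reaches `target_variance`. The returned projection transforms held-out
#' rows with the training centering and rotation.
#'
#' @param x Numeric matrix or data frame (patients x radiomics features).
#' @param target_variance Fraction of variance to retain, in (0, 1].
#' @param k Optional fixed number of components, overriding the variance rule.
#' @param projection A fitted projection from a previous call (transform mode).
#' @return A tibble of component scores (`PC1`, ...) with the projection in
#'   `attr(, "projection")`.
#' @export
reduce_radiomics <- function(x, target_variance = 0.90, k = NULL, projection = NULL) {
  x <- as.matrix(x)
  if (!is.null(projection)) {
    scores <- scale(x, center = projection$center, scale = FALSE) %*% projection$rotation
    out <- tibble::as_tibble(scores, .name_repair = "minimal")
    names(out) <- colnames(projection$rotation)
    attr(out, "projection") <- projection
    return(out)
  }
  if (target_variance <= 0 || target_variance > 1) {
    abort("`target_variance` must lie in (0, 1].")
  }
  if (nrow(x) < 2) abort("Radiomics PCA needs at least 2 rows.")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  ratio <- cumsum(ev) / sum(ev)
  kk <- k %||% which(ratio >= target_variance - 1e-12)[1]
  kk <- min(kk, ncol(p$rotation))
  rot <- p$rotation[, seq_len(kk), drop = FALSE]
  projection <- list(center = p$center, rotation = rot, k = kk,
                     explained_variance_ratio = ratio[seq_len(kk)])
  out <- tibble::as_tibble(p$x[, seq_len(kk), drop = FALSE], .name_repair = "minimal")
  names(out) <- colnames(rot)
  attr(out, "projection") <- projection
  out
}

#' Split a cohort into training and test sets
#'
#' Random disjoint partition with `round(train_fraction * n)` training rows
#' (half-up rounding: 536 patients at 0.75 give 402/134), deterministic for a
#' fixed seed.
#'
#' @param data Cohort tibble.
#' @param train_fraction Fraction of rows in the training set, in (0, 1).
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_cohort <- function(data, train_fraction = 0.75, seed = 1) {
  n <- nrow(data)
  if (n < 2) abort("Need at least 2 rows to split.")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1.")
  }
  n_train <- floor(train_fraction * n + 0.5)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Build state vectors for a decision stage
#'
#' Stage 0 states contain the encoded group-1 features only; stage 1 adds
#' group 2 and a one-hot of D1; stage 2 adds group 3 and a one-hot of D2.
#' Decision one-hots use two 0/1 slots per decision with the slot index equal
#' to the decision value. Group-4 outcomes can never appear: the layout is
#' built from the schema's stage groups by construction.
#'
#' @param data Preprocessed cohort tibble (imputed; decisions up to the stage
#'   present).
#' @param stage 0, 1 or 2.
#' @param scaling Fitted scaling map from [encode_features()] (required so
#'   training statistics are reused).
#' @param schema Schema; defaults to the attached one.
#' @return A numeric matrix (patients x state dimensions) with named columns.
#' @export
build_states <- function(data, stage, scaling, schema = NULL) {
  if (!stage %in% 0:2) abort("`stage` must be 0, 1 or 2.")
  schema <- get_schema(data, schema)
  feats <- intersect(schema_features(schema, state_groups(stage)),
                     scaling$features)
  enc <- encode_features(data, schema, features = feats, scaling = scaling)
  keep <- unlist(scaling$layout[feats], use.names = FALSE)
  m <- as.matrix(enc[, keep, drop = FALSE])
  for (d in state_decisions(stage)) {
    dv <- data[[d]]
    if (is.null(dv) || anyNA(dv)) {
      abort(sprintf("Stage %d state needs decision `%s`, which is missing.", stage, d))
    }
    m <- cbind(m, decision_onehot(as.numeric(dv), d))
  }
  rownames(m) <- data$patient_id
  m
}

#' @rdname build_states
#' @param record A single-row cohort tibble.
#' @export
build_state <- function(record, stage, scaling, schema = NULL) {
  drop(build_states(record, stage, scaling, schema))
}

#' Serialize preprocessing artifacts to JSON
#'
#' @param artifacts Named list, e.g. imputation stats, scaling map, PCA
#'   projection.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_preprocessing <- function(artifacts, path) {
  jsonlite::write_json(artifacts, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
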