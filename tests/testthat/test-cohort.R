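test_that("cohort CSV round-trips and flags unparseable cells as missing", {
  coh <- generate_cohort(generator_config(n = 12, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 12)
  expect_equal(back$os, coh$os)
  expect_equal(back$chemo, coh$chemo)
  expect_equal(back$age, coh$age)
  expect_equal(is.na(back$grade), is.na(coh$grade))

  # blank cell becomes NA, row is kept
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  raw$packs_year[2] <- ""
  raw$t_cat[3] <- "T9"   # unparseable level
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path2, row.names = FALSE)
  back2 <- read_cohort(path2)
  expect_true(is.na(back2$packs_year[2]))
  expect_true(is.na(back2$t_cat[3]))
  expect_equal(nrow(back2), 12)
})

test_that("missing mandatory columns and duplicate ids are rejected", {
  coh <- generate_cohort(generator_config(n = 4, seed = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh[, setdiff(names(coh), "os")], path)
  expect_error(read_cohort(path), "os")

  dup <- coh
  dup$patient_id <- rep("P0001", 4)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(dup, path2)
  expect_error(read_cohort(path2), "Duplicate")
})

test_that("schema YAML round-trips", {
  s <- default_schema()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_schema(s, path)
  s2 <- read_schema(path)
  expect_equal(s2$name, s$name)
  expect_equal(s2$kind, s$kind)
  expect_equal(s2$levels, s$levels)
})

test_that("imputation uses median/mode and training statistics only", {
  coh <- generate_cohort(generator_config(n = 30, seed = 7))
  coh$age[c(2, 5)] <- NA
  coh$smoking[3] <- NA
  done <- impute_missing(coh)
  stats <- attr(done, "imputation_stats")
  expect_false(anyNA(done$age))
  expect_equal(done$age[2], median(coh$age, na.rm = TRUE))
  tab <- table(coh$smoking)
  expect_equal(done$smoking[3], names(tab)[which.max(tab)])

  # held-out rows get the training statistic, not their own
  test <- coh[1:5, ]
  test$age <- NA
  test_done <- impute_missing(test, stats = stats)
  expect_true(all(test_done$age == stats$age))
})

test_that("unknown HPV is the distinguished category and is never imputed", {
  coh <- generate_cohort(generator_config(n = 40, seed = 2))
  coh$hpv[1:4] <- NA
  done <- impute_missing(coh)
  expect_true(all(done$hpv[1:4] == "unknown"))
  enc <- encode_features(done)
  expect_true(all(enc$hpv[done$hpv == "unknown"] == 0))
})

test_that("a fully missing column cannot be imputed", {
  coh <- generate_cohort(generator_config(n = 10, seed = 2))
  coh$packs_year <- NA_real_
  expect_error(impute_missing(coh), "packs_year")
})

test_that("encoding maps ranges to [-1, 1] with ordinal order preserved", {
  enc <- encode_features(toy_table(), toy_schema())
  expect_equal(enc$x, c(-1, 1, 0))            # {2, 6} endpoints
  expect_equal(sort(unique(enc$flag)), c(-1, 1))
  expect_equal(order(enc$ord), order(match(toy_table()$ord, c("low", "mid", "high"))))
  expect_named(enc, c("x", "flag", "ord", "cat.a", "cat.b"))
  expect_true(all(as.matrix(enc) >= -1 & as.matrix(enc) <= 1))
})

test_that("prescribed chemotherapy encodes as ordered integers before scaling", {
  coh <- generate_cohort(generator_config(n = 200, seed = 5))
  coh <- impute_missing(coh)
  enc <- encode_features(coh)
  codes <- tapply(enc$chemo, coh$chemo, unique)
  present <- intersect(c("none", "single", "doublet", "triplet", "quadruplet"),
                       names(codes))
  expect_true(all(diff(unlist(codes[present])) > 0))
})

test_that("constant columns encode to 0 and held-out values are clipped", {
  tab <- toy_table()
  tab$x <- 5
  enc <- encode_features(tab, toy_schema())
  expect_true(all(enc$x == 0))

  tab2 <- toy_table()
  enc2 <- encode_features(tab2, toy_schema())
  sc <- attr(enc2, "scaling")
  held <- toy_table()
  held$x <- c(-10, 100, 4)  # outside the fitted [2, 6] range
  enc3 <- encode_features(held, toy_schema(), scaling = sc)
  expect_equal(enc3$x, c(-1, 1, 0))
  expect_false(attr(enc3, "refit"))
  expect_identical(attr(enc3, "scaling"), sc)
})

test_that("transforming with a fitted map rejects unknown categories", {
  enc <- encode_features(toy_table(), toy_schema())
  held <- toy_table()
  held$cat[1] <- "zz"
  expect_error(encode_features(held, toy_schema(), scaling = attr(enc, "scaling")),
               "cat.*zz")
})

test_that("radiomics PCA keeps the minimal components reaching the target", {
  # axis-aligned variances (9, 0.5, 0.5): first axis carries 90%
  set.seed(4)
  x <- cbind(rnorm(200, sd = 3), rnorm(200, sd = sqrt(0.5)),
             rnorm(200, sd = sqrt(0.5)))
  ev <- sort(eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  k_expect <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  scores <- reduce_radiomics(x, 0.90)
  expect_equal(ncol(scores), k_expect)

  # rank-1 data of any width
  z <- rnorm(50)
  r1 <- outer(z, rnorm(8))
  expect_equal(ncol(reduce_radiomics(r1, 0.90)), 1)
})

test_that("radiomics component count matches an independent eigendecomposition", {
  set.seed(11)
  x <- matrix(rnorm(50 * 20), 50, 20) %*% diag(seq(2, 0.1, length.out = 20))
  for (tv in c(0.5, 0.75, 0.9, 0.99)) {
    ev <- sort(eigen(stats::cov(x), symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    k_oracle <- which(cumsum(ev) / sum(ev) >= tv)[1]
    expect_equal(ncol(reduce_radiomics(x, tv)), k_oracle)
  }
  # monotone non-decreasing in the variance target
  ks <- vapply(c(0.3, 0.6, 0.9, 0.999), function(tv) ncol(reduce_radiomics(x, tv)),
               numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(reduce_radiomics(x, 1.5), "target_variance")
})

test_that("radiomics projection transforms held-out rows with training axes", {
  set.seed(2)
  x <- matrix(rnorm(60 * 10), 60, 10)
  fit <- reduce_radiomics(x[1:40, ], 0.9)
  proj <- attr(fit, "projection")
  held <- reduce_radiomics(x[41:60, ], projection = proj)
  manual <- scale(x[41:60, ], center = proj$center, scale = FALSE) %*% proj$rotation
  expect_equal(as.matrix(held), manual, ignore_attr = TRUE)
})

test_that("cohort split is deterministic, disjoint, and half-up rounded", {
  tab <- tibble::tibble(patient_id = as.character(1:536), v = rnorm(536))
  s <- split_cohort(tab, 0.75, seed = 9)
  expect_equal(nrow(s$train), 402)
  expect_equal(nrow(s$test), 134)
  expect_length(intersect(s$train$patient_id, s$test$patient_id), 0)
  expect_setequal(c(s$train$patient_id, s$test$patient_id), tab$patient_id)

  s2 <- split_cohort(tab, 0.75, seed = 9)
  expect_identical(s$train$patient_id, s2$train$patient_id)

  tiny <- split_cohort(tab[1:4, ], 0.75, seed = 1)
  expect_equal(nrow(tiny$train), 3)
  expect_error(split_cohort(tab[1, ], 0.75, seed = 1), "at least 2")
})

test_that("state vectors respect stage layouts and never leak outcomes", {
  p <- prep_cohort(generator_config(n = 50, seed = 13))
  s0 <- build_states(p$train, 0, p$scaling)
  s1 <- build_states(p$train, 1, p$scaling)
  s2 <- build_states(p$train, 2, p$scaling)
  expect_false(any(grepl("^d\\d", colnames(s0))))
  expect_true(all(c("d1_0", "d1_1") %in% colnames(s1)))
  expect_true(all(c("d1_0", "d1_1", "d2_0", "d2_1") %in% colnames(s2)))
  expect_false(any(c("os", "ft", "ar_after") %in%
                     sub("\\..*", "", colnames(s2))))
  # exactly one hot slot per decision
  expect_true(all(s1[, "d1_0"] + s1[, "d1_1"] == 1))
  one <- build_state(p$train[3, ], 1, p$scaling)
  expect_equal(unname(one[c("d1_0", "d1_1")]),
               if (p$train$d1[3] == 1) c(0, 1) else c(1, 0))
  # same dimensionality for every patient at a stage
  expect_equal(ncol(build_states(p$test, 1, p$scaling)), ncol(s1))

  broken <- p$train
  broken$d2 <- NA
  expect_error(build_states(broken, 2, p$scaling), "d2")
})

test_that("preprocessing artifacts serialize to JSON", {
  p <- prep_cohort(generator_config(n = 20, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocessing(list(scaling = p$scaling["ranges"]), path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})
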