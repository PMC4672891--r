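test_that("read_dataset auto-flags 0/1 columns as binary", {
  path <- tmp_csv(data.frame(y = c(0, 1, 0, 1), d1 = c(0, 1, 1, 0),
                             d2 = c(1, 0, 0, 0), age = c(2, 5, 7, 1)))
  ds <- read_dataset(path, "y")
  expect_s3_class(ds, "como_data")
  expect_identical(ds$feature_kinds, c("binary", "binary", "numeric"))
  expect_identical(ds$feature_names, c("d1", "d2", "age"))
})

test_that("explicit binary declaration is validated with column and row", {
  path <- tmp_csv(data.frame(y = c(0, 1, 0, 1), d1 = c(0, 1, 2, 0),
                             age = c(2, 5, 7, 1)))
  err <- expect_error(read_dataset(path, "y", binary_columns = "d1"),
                      class = "comologit_validation_error")
  expect_match(conditionMessage(err), "d1")
  expect_match(conditionMessage(err), "row 3")
  # the same column is fine as an (auto-detected) numeric feature
  expect_identical(read_dataset(path, "y")$feature_kinds[1], "numeric")
})

test_that("binary_columns overrides auto-detection for count-like columns", {
  path <- tmp_csv(data.frame(y = c(0, 1, 0, 1), d1 = c(0, 1, 1, 0),
                             cnt = c(0, 1, 1, 0)))
  ds <- read_dataset(path, "y", binary_columns = "d1")
  expect_identical(ds$feature_kinds, c("binary", "numeric"))
})

test_that("missing outcome column and missing values are rejected", {
  path <- tmp_csv(data.frame(y = c(0, 1), d1 = c(0, 1)))
  expect_error(read_dataset(path, "outcome"),
               class = "comologit_config_error")
  path2 <- tmp_csv(data.frame(y = c(0, 1, 0), d1 = c(0, NA, 1)))
  err <- expect_error(read_dataset(path2, "y"),
                      class = "comologit_validation_error")
  expect_match(conditionMessage(err), "d1")
})

test_that("log-transformed companion columns are retained as distinct features", {
  los <- c(1.5, 3.2, 8.1, 2.0)
  path <- tmp_csv(data.frame(y = c(0, 1, 0, 1), los = los,
                             los_log = log(los)))
  ds <- read_dataset(path, "y")
  expect_identical(ds$feature_names, c("los", "los_log"))
  expect_identical(ds$feature_kinds, c("numeric", "numeric"))
})

test_that("CSV round-trip preserves the table", {
  ds <- make_binary_ds(n = 30, p = 3, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path, "y")
  expect_equal(ds2$X, ds$X)
  expect_equal(ds2$y, ds$y)
})

test_that("build_design implements the Boolean column algebra", {
  X <- cbind(d1 = c(1, 1, 0, 0), d2 = c(0, 1, 0, 1))
  ds <- como_data(X, c(0, 1, 0, 1))
  D <- build_design(ds, list(product_term("d1", "d2"),
                             left_only_term("d1", "d2"),
                             right_only_term("d1", "d2")))
  expect_equal(unname(D[1, ]), c(0, 1, 0))   # d1=1, d2=0
  expect_equal(unname(D[2, ]), c(1, 0, 0))   # both present
  expect_equal(unname(D[3, ]), c(0, 0, 0))   # neither
  expect_equal(unname(D[4, ]), c(0, 0, 1))   # d2 only
  # identity d1 = d1*d2 + d1*(1-d2), and the three columns partition <= 1
  expect_equal(D[, 1] + D[, 2], ds$X[, "d1"])
  expect_true(all(rowSums(D) <= 1))
})

test_that("build_design is row-local: permuting rows permutes output rows", {
  ds <- make_binary_ds(n = 40, p = 4, seed = 2)
  terms <- list(main_term("d01"), product_term("d01", "d02"),
                left_only_term("d03", "d04"))
  D <- build_design(ds, terms)
  perm <- sample(ds$n)
  expect_equal(build_design(subset_ds <- comologit:::subset_data(ds, perm),
                            terms),
               D[perm, ])
})

test_that("complement terms over numeric features are rejected", {
  X <- cbind(d1 = c(1, 0, 1), age = c(3, 5, 2))
  ds <- como_data(X, c(0, 1, 1))
  expect_error(build_design(ds, list(left_only_term("d1", "age"))),
               class = "comologit_validation_error")
  expect_error(build_design(ds, list(main_term("nope"))),
               class = "comologit_validation_error")
})
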