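test_that("auc matches brute-force pair counting and handles ties", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  set.seed(12)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), auc_bruteforce(s, y), tolerance = 1e-12)
  }
  expect_error(auc(1:3, c(1, 1, 1)), class = "comologit_validation_error")
})

test_that("the hold-out report honors its structural contract", {
  ds <- simulate_emr(small_emr_config(n = 1500, seed = 31))
  ev <- suppressMessages(repeated_holdout(ds, ndi = 1, repeats = 4,
                                          seed = 5))
  expect_identical(ev$methods, c("baseline", "opt", "1se"))
  expect_identical(dim(ev$auc_samples), c(4L, 3L))
  expect_true(all(ev$auc_samples >= 0 & ev$auc_samples <= 1))
  expect_true(all(ev$complexity_samples >= 0))
  expect_true(all(ev$complexity_samples == round(ev$complexity_samples)))
  expect_identical(rownames(ev$auc_summary), ev$methods)
  # percentile interval brackets the mean
  expect_true(all(ev$auc_summary[, "p2.5"] <= ev$auc_summary[, "mean"] &
                  ev$auc_summary[, "mean"] <= ev$auc_summary[, "p97.5"]))
})

test_that("evaluation is reproducible for a fixed seed", {
  ds <- simulate_emr(small_emr_config(n = 1200, prevalence = 0.3, seed = 37))
  e1 <- suppressMessages(repeated_holdout(ds, ndi = 1, repeats = 3, seed = 8))
  e2 <- suppressMessages(repeated_holdout(ds, ndi = 1, repeats = 3, seed = 8))
  expect_identical(e1$auc_samples, e2$auc_samples)
  expect_identical(e1$auc_summary, e2$auc_summary)
  expect_identical(e1$complexity_summary, e2$complexity_summary)
})

test_that("invalid evaluation configurations are rejected", {
  ds <- make_binary_ds(n = 100, p = 3, seed = 2)
  expect_error(repeated_holdout(ds, ndi = 1, repeats = 0))
  expect_error(repeated_holdout(ds, ndi = 1, repeats = 2,
                                split_fraction = 1.2))
})

test_that("frequency tables rank by OPT then 1SE selection percentage", {
  opt <- list(c(a = 1, b = -2, c = 0.5), c(a = 2, c = 1), c(a = 0.1, b = -1))
  se1 <- list(c(a = 1), c(a = 2, c = 0.2), c(b = -0.5))
  tab <- frequency_table(opt, "positive", models_1se = se1)
  expect_identical(tab$variable[1], "a")
  expect_equal(tab$opt[1], 100)
  expect_equal(tab$one_se[tab$variable == "a"], 200 / 3, tolerance = 1e-10)
  # a feature never selected with the requested sign does not appear
  expect_false("b" %in% tab$variable)
  neg <- frequency_table(opt, "negative", models_1se = se1)
  expect_identical(neg$variable[1], "b")
  expect_true(all(neg$opt >= 0 & neg$opt <= 100))
  # ranks are 1..k and percentages sorted descending by OPT
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$opt) <= 0))
})
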