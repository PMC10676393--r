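test_that("complete data give a degenerate MCAR test", {
  withr::with_seed(1, Y <- matrix(rnorm(200 * 3), ncol = 3))
  res <- little_mcar_test(Y)
  expect_equal(res$d2, 0, tolerance = 1e-6)
  expect_equal(res$df, 0L)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_patterns, 1L)
})

test_that("the MCAR test detects mean-dependent missingness", {
  withr::with_seed(2, {
    Y <- matrix(rnorm(2000 * 5), ncol = 5)
    Y[Y[, 1] > 0, 2] <- NA  # missingness driven by an observed variable
  })
  res <- little_mcar_test(Y)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$n_patterns, 2L)
  # df: complete pattern contributes 5, incomplete 4; total - p = 4
  expect_equal(res$df, 4L)
})

test_that("the MCAR test holds its size under MCAR at modest replication", {
  rej <- vapply(1:60, function(s) {
    withr::with_seed(1000 + s, {
      Y <- matrix(rnorm(500 * 4), ncol = 4)
      Y[matrix(runif(500 * 4) < 0.2, 500, 4)] <- NA
    })
    little_mcar_test(Y)$p_value < 0.05
  }, logical(1))
  # binomial 3-SE band around 0.05 at 60 replicates
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("the dropout model recovers severity-dependent attrition", {
  spec <- default_ground_truth(seed = 3, n_waves = 5)
  panel <- apply_attrition(simulate_panel(spec, 10000, seed = 3), spec)
  dm <- dropout_model(panel)
  tab <- dm$coefficients
  expect_gt(tab["baseline_sum", "Estimate"], 0)
  expect_lt(tab["baseline_sum", "Pr(>|z|)"], 0.05)
  expect_gt(tab["ethnicity", "Estimate"], 0)
  expect_false(dm$separation)

  complete <- simulate_panel(spec, 200, seed = 4)
  expect_error(dropout_model(complete), "no events")
})

test_that("imputation is the identity on complete data", {
  spec <- plain_spec(n_items = 3, n_waves = 2)
  panel <- simulate_panel(spec, 150, seed = 5)
  expect_identical(impute_chained(panel, seed = 1), panel)
})

test_that("imputed values are binary and observed cells untouched", {
  spec <- plain_spec(n_items = 4, n_waves = 3)
  panel <- simulate_panel(spec, 800, seed = 6)
  holed <- panel
  withr::with_seed(7,
    holed$items[cbind(sample(800, 300, TRUE), sample(3, 300, TRUE),
                      sample(4, 300, TRUE))] <- NA)
  imp <- impute_chained(holed, n_iterations = 5, seed = 8)
  expect_false(anyNA(imp$items))
  expect_true(all(imp$items %in% c(0, 1)))
  obs <- !is.na(holed$items)
  expect_identical(imp$items[obs], holed$items[obs])
  # reproducible from the seed
  imp2 <- impute_chained(holed, n_iterations = 5, seed = 8)
  expect_identical(imp$items, imp2$items)
  expect_false(identical(imp$items,
                         impute_chained(holed, n_iterations = 5, seed = 9)$items))
})

test_that("MCAR holes are refilled close to the complete-data endorsement", {
  spec <- default_ground_truth(seed = 9, n_waves = 2)
  panel <- simulate_panel(spec, 10000, seed = 9)
  truth <- mean(panel$items[, 2, "slp"])
  holed <- panel
  withr::with_seed(10, drop_idx <- which(runif(10000) < 0.2))
  holed$items[drop_idx, 2, "slp"] <- NA
  imp <- impute_chained(holed, n_iterations = 10, seed = 11)
  expect_lt(abs(mean(imp$items[, 2, "slp"]) - truth), 0.02)
})

test_that("an informative auxiliary reduces imputation bias under MAR", {
  # missingness in the target item depends on a complete auxiliary that is
  # strongly associated with the item; imputing with the auxiliary must
  # track the full-data endorsement more closely than imputing without it
  bias <- vapply(1:3, function(r) {
    spec <- plain_spec(n_items = 3, n_waves = 2)
    panel <- simulate_panel(spec, 6000, seed = 20 + r)
    y <- panel$items[, 2, 1]
    withr::with_seed(30 + r, {
      aux <- y + rnorm(6000, sd = 0.6)       # observed proxy of the item
      mis <- runif(6000) < plogis(-2.5 + 2.5 * aux)
    })
    truth <- mean(y)
    holed <- panel
    holed$items[mis, 2, 1] <- NA
    with_aux <- impute_chained(holed, auxiliaries = cbind(aux = aux),
                               n_iterations = 8, seed = 40 + r)
    without <- impute_chained(holed, n_iterations = 8, seed = 40 + r)
    c(with = abs(mean(with_aux$items[, 2, 1]) - truth),
      without = abs(mean(without$items[, 2, 1]) - truth))
  }, numeric(2))
  expect_lt(mean(bias["with", ]), mean(bias["without", ]))
})

test_that("variables with no observed values are refused", {
  spec <- plain_spec(n_items = 2, n_waves = 2)
  panel <- simulate_panel(spec, 50, seed = 12)
  panel$items[, 2, 1] <- NA
  expect_error(impute_chained(panel, seed = 1), "no observed values")
})
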