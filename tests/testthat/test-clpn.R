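test_that("at penalty zero the fit equals the unpenalized MLE", {
  withr::with_seed(21, {
    X <- cbind(x1 = rbinom(500, 1, 0.4), x2 = rbinom(500, 1, 0.3),
               x3 = rbinom(500, 1, 0.5))
    y <- rbinom(500, 1, plogis(-1 + 0.8 * X[, 1] - 0.5 * X[, 2]))
  })
  fit <- fit_penalized_logistic(X, y, penalty = 0)
  oracle <- glm(y ~ X, family = binomial())  # Newton-Raphson MLE oracle
  expect_equal(unname(fit$coefficients), unname(coef(oracle)[-1]),
               tolerance = 1e-4)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
})

test_that("a dominating penalty gives the null model", {
  withr::with_seed(22, {
    X <- matrix(rbinom(400 * 3, 1, 0.5), ncol = 3,
                dimnames = list(NULL, paste0("x", 1:3)))
    y <- rbinom(400, 1, 0.3)
  })
  fit <- fit_penalized_logistic(X, y, penalty = 5)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-6)
})

test_that("the penalty keeps separable data finite", {
  x <- c(rep(0, 30), rep(1, 30))
  y <- x  # perfectly separated
  X <- cbind(sep = x, noise = rep(c(0, 1), 30))
  fit <- fit_penalized_logistic(X, y, nfolds = 5, seed = 2)
  expect_true(all(is.finite(fit$coefficients)))
  expect_gt(fit$penalty, 0)
})

test_that("degenerate inputs are refused and constant columns zeroed", {
  X <- matrix(rbinom(100, 1, 0.5), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_error(fit_penalized_logistic(X, rep(1, 50)), "degenerate outcome")
  expect_error(fit_penalized_logistic(X, c(NA, rbinom(49, 1, .5))), "missing")
  withr::with_seed(3, {
    Xc <- cbind(const = rep(1, 300), x = rbinom(300, 1, 0.5))
    y <- rbinom(300, 1, plogis(-0.5 + Xc[, "x"]))
  })
  fit <- fit_penalized_logistic(Xc, y, nfolds = 5, seed = 1)
  expect_equal(unname(fit$coefficients["const"]), 0)
})

test_that("the number of selected edges is monotone along the penalty path", {
  spec <- recovery_spec()
  panel <- simulate_panel(spec, 2000, seed = 31)
  X <- cbind(wave_matrix_for_test(panel, 1), panel$covariates)
  y <- panel$items[, 2, 1]
  fit <- fit_penalized_logistic(X, y, nfolds = 5, seed = 4)
  # path is stored at decreasing penalties: support can only grow
  expect_true(all(diff(fit$path$n_nonzero) >= 0))
  expect_true(all(diff(fit$path$penalty) < 0))
})

test_that("the network fit assembles predictors-by-outcomes coefficients", {
  spec <- default_ground_truth(seed = 7, n_waves = 2)
  panel <- simulate_panel(spec, 1200, seed = 7)
  net <- clpn(panel, wave = 1, nfolds = 5, seed = 7)
  expect_s3_class(net, "clpn")
  expect_equal(dim(net$beta), c(10, 8))  # 8 items + 2 covariates
  expect_equal(rownames(net$beta), c(cesd8_items(), "gender", "ethnicity"))
  expect_equal(net$covariate_rows, c("gender", "ethnicity"))
  expect_equal(net$n, 1200)

  nocov <- clpn(panel, wave = 1, covariates = FALSE, nfolds = 5, seed = 7)
  expect_equal(dim(nocov$beta), c(8, 8))

  expect_error(clpn(panel, wave = 2), "must both exist")
  withNA <- panel; withNA$items[1, 2, 1] <- NA
  expect_error(clpn(withNA, wave = 1), "impute first")
  cc <- clpn(withNA, wave = 1, nfolds = 5, complete_cases = TRUE, seed = 7)
  expect_equal(cc$n, 1199)
})

test_that("a planted edge is recovered with its sign", {
  spec <- ground_truth_spec(
    n_waves = 2, endorsement = 0.25,
    edges = data.frame(from = "eft", to = "gng", weight = 1.0),
    autoregressive = 1.0, seed = 1)
  hits <- vapply(1:3, function(s) {
    panel <- simulate_panel(spec, 10000, seed = 100 + s)
    net <- clpn(panel, wave = 1, seed = s)
    coef(net)["eft", "gng"] > 0
  }, logical(1))
  expect_true(all(hits))
})

test_that("odds-ratio and log-odds views are exact duals", {
  b <- matrix(c(0, log(2), -log(2), 0.3), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  net <- fake_clpn(b)
  or <- to_odds_ratio(net)
  expect_equal(or$beta, exp(b))
  expect_equal(or$beta[1, 1], 1)        # 0 -> OR 1
  expect_equal(or$beta["a", "b"], exp(b["a", "b"]))  # -ln 2 -> 0.5
  expect_equal(or$beta["b", "a"], 2)                 # ln 2 -> 2 (column-major fill)
  expect_equal(coef(or, scale = "log_odds"), b)   # reversible
  expect_identical(to_odds_ratio(or)$scale, "OR")
  expect_equal(coef(net, scale = "OR"), exp(b))
})

test_that("expected influence sums cross-lagged edges only", {
  b <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  b["a", "b"] <- 0.5; b["a", "c"] <- 0.3; b["b", "a"] <- -0.2
  b["a", "a"] <- 1.0  # autoregressive: must be ignored
  net <- fake_clpn(b)
  ei <- expected_influence(net)
  expect_equal(ei$out_ei[ei$item == "a"], 0.8)
  expect_equal(ei$in_ei[ei$item == "a"], -0.2)
  expect_equal(ei$in_ei[ei$item == "b"], 0.5)

  # brute-force summation oracle on a random sparse network, with covariates
  withr::with_seed(17, {
    p <- 6
    bb <- matrix(rbinom(p * p, 1, 0.3) * rnorm(p * p), p, p,
                 dimnames = list(letters[1:p], letters[1:p]))
  })
  full <- rbind(bb, gender = rnorm(p))
  colnames(full) <- letters[1:p]
  netc <- fake_clpn(bb); netc$beta <- full; netc$covariate_rows <- "gender"
  eic <- expected_influence(netc)
  for (k in seq_len(p)) {
    expect_equal(eic$in_ei[k], sum(bb[-k, k]))
    expect_equal(eic$out_ei[k], sum(bb[k, -k]))
  }
  # total incoming equals total outgoing influence
  expect_equal(sum(eic$in_ei), sum(eic$out_ei))
  expect_equal(mean(eic$in_ei_z), 0, tolerance = 1e-12)
  expect_equal(sd(eic$in_ei_z), 1, tolerance = 1e-12)
})

test_that("prediction and residuals follow the logistic model", {
  spec <- plain_spec(n_items = 3, n_waves = 2)
  panel <- simulate_panel(spec, 500, seed = 12)
  net <- clpn(panel, wave = 1, nfolds = 5, seed = 12)
  pr <- predict(net)
  expect_equal(dim(pr), c(500, 3))
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(residuals(net), net$y - pr)
  eta <- predict(net, type = "link")
  expect_equal(plogis(eta), pr)
})
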