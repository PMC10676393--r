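test_that("intercepts solve the endorsement targets", {
  # no covariate effects: closed-form logit
  spec <- ground_truth_spec(items = letters[1:4], endorsement = 0.2,
                            covariate_prevalence = c(g = 0.5))
  expect_equal(unname(spec$transition_intercepts), rep(qlogis(0.2), 4),
               tolerance = 1e-10)

  # with covariate effects: marginal over covariate patterns hits targets
  targets <- c(0.1792, 0.2397, 0.4097, 0.8893)
  eff <- rbind(g1 = c(0.3, -0.2, 0.25, 0.1), g2 = c(0.5, 0.4, -0.3, 0.2))
  spec <- ground_truth_spec(items = letters[1:4], endorsement = targets,
                            covariate_effects = eff,
                            covariate_prevalence = c(g1 = 0.54, g2 = 0.03))
  pat <- as.matrix(expand.grid(0:1, 0:1))
  w <- apply(pat, 1, function(z) prod(ifelse(z == 1, c(0.54, 0.03),
                                             1 - c(0.54, 0.03))))
  marg <- vapply(1:4, function(k)
    sum(w * plogis(spec$wave1_intercepts[k] + pat %*% eff[, k])), numeric(1))
  expect_equal(marg, targets, tolerance = 1e-8)
})

test_that("edge lists populate the transition matrix directly", {
  spec <- ground_truth_spec(
    edges = data.frame(from = "eft", to = "gng", weight = 0.8))
  expect_equal(spec$B["eft", "gng"], 0.8)
  expect_equal(sum(spec$B != 0), 1L)
})

test_that("invalid generative configurations are rejected", {
  expect_error(ground_truth_spec(endorsement = 1.2), "inside \\(0, 1\\)")
  expect_error(ground_truth_spec(endorsement = 0), "inside \\(0, 1\\)")
  expect_error(ground_truth_spec(B = matrix(0, 3, 2)), "square")
  expect_error(ground_truth_spec(items = letters[1:3], B = matrix(0, 2, 2)),
               "match the items")
  expect_error(ground_truth_spec(B = matrix(Inf, 8, 8)), "finite")
})

test_that("simulation is deterministic in the seed", {
  spec <- plain_spec()
  a <- simulate_panel(spec, 200, seed = 9)
  b <- simulate_panel(spec, 200, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a$items,
                         simulate_panel(spec, 200, seed = 10)$items))

  spec$attrition <- list(intercept = -1, covariate_coefs = NULL, sum_coef = 0)
  pa <- apply_attrition(simulate_panel(spec, 200, seed = 9), spec, seed = 3)
  pb <- apply_attrition(simulate_panel(spec, 200, seed = 9), spec, seed = 3)
  expect_identical(pa$items, pb$items)
})

test_that("with a zero transition matrix endorsement matches the targets", {
  spec <- ground_truth_spec(n_waves = 3, endorsement = 0.2,
                            covariate_prevalence = c(gender = 0.54, ethnicity = 0.03))
  panel <- simulate_panel(spec, 20000, seed = 4)
  se3 <- 3 * sqrt(0.2 * 0.8 / 20000)
  tab <- endorsement_table(panel)
  expect_true(all(abs(tab$endorsement - 0.2) < se3))
})

test_that("a strong autoregressive path reproduces its lag-1 log-odds ratio", {
  spec <- ground_truth_spec(items = c("a", "b"), n_waves = 2,
                            endorsement = 0.2, autoregressive = 3.0,
                            covariate_prevalence = c(g = 0.5))
  panel <- simulate_panel(spec, 50000, seed = 8)
  x <- panel$items[, 1, "a"]; y <- panel$items[, 2, "a"]
  tab <- table(x, y) + 0  # 2x2 table oracle
  lor <- log(tab[2, 2] * tab[1, 1] / (tab[1, 2] * tab[2, 1]))
  expect_equal(lor, 3.0, tolerance = 0.12)
  # agreement far above independence
  expect_gt(mean(x == y), mean(x) * mean(y) + (1 - mean(x)) * (1 - mean(y)) + 0.05)
})

test_that("attrition is monotone, seeded, and follows the hazard model", {
  spec <- plain_spec(n_items = 8, n_waves = 9)

  # near-zero hazard leaves the panel unchanged
  spec$attrition <- list(intercept = -50, covariate_coefs = NULL, sum_coef = 0)
  panel <- simulate_panel(spec, 500, seed = 2)
  expect_identical(apply_attrition(panel, spec, seed = 1)$items, panel$items)

  # constant hazard 0.10: retention at wave 9 near 0.9^8 (geometric survival)
  spec$attrition <- list(intercept = qlogis(0.10), covariate_coefs = NULL,
                         sum_coef = 0)
  big <- simulate_panel(spec, 20000, seed = 3)
  dropped <- apply_attrition(big, spec, seed = 5)
  ret <- retained_per_wave(dropped)
  p9 <- 0.9^8
  expect_lt(abs(ret[9] / 20000 - p9), 3 * sqrt(p9 * (1 - p9) / 20000))

  # retained counts never increase; monotone pattern per subject
  expect_true(all(diff(ret) <= 0))
  obs <- !is.na(dropped$items[, , 1])
  expect_true(all(apply(obs, 1, function(r) all(diff(as.integer(r)) <= 0))))
})

test_that("severity-dependent attrition selects out severer cases", {
  spec <- ground_truth_spec(n_waves = 2, endorsement = 0.25,
                            attrition = list(hazard = 0.3, sum_coef = 0.5))
  panel <- simulate_panel(spec, 8000, seed = 6)
  dropped <- apply_attrition(panel, spec, seed = 7)
  score1 <- sum_scores(panel)[, 1]
  gone <- is.na(dropped$items[, 2, 1])
  expect_gt(mean(score1[gone]), mean(score1[!gone]))
})

test_that("ground-truth specs round-trip through the config file", {
  spec <- default_ground_truth(seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ground_truth(spec, path)
  back <- read_ground_truth(path)
  expect_equal(back$B, spec$B)
  expect_equal(back$wave1_intercepts, spec$wave1_intercepts)
  expect_equal(back$transition_intercepts, spec$transition_intercepts)
  expect_equal(back$attrition, spec$attrition)
  expect_identical(simulate_panel(back, 50, seed = 1)$items,
                   simulate_panel(spec, 50, seed = 1)$items)
})
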