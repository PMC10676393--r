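test_that("bootstrap distributions are reproducible from the seed", {
  spec <- recovery_spec()
  panel <- simulate_panel(spec, 600, seed = 1)
  a <- bootstrap_edges(panel, wave = 1, B = 20, refit_penalty = "fixed",
                       nfolds = 5, seed = 42)
  b <- bootstrap_edges(panel, wave = 1, B = 20, refit_penalty = "fixed",
                       nfolds = 5, seed = 42)
  expect_identical(a$edges, b$edges)
  expect_identical(a$ci, b$ci)
  expect_false(identical(
    a$edges, bootstrap_edges(panel, wave = 1, B = 20,
                             refit_penalty = "fixed", nfolds = 5,
                             seed = 43)$edges))
  expect_error(bootstrap_edges(panel, B = 1), "B must be >= 2")
})

test_that("edge confidence intervals tighten with the sample size", {
  spec <- recovery_spec()
  small <- simulate_panel(spec, 600, seed = 2)
  large <- simulate_panel(spec, 2400, seed = 3)
  bs <- bootstrap_edges(small, wave = 1, B = 50, refit_penalty = "fixed",
                        nfolds = 5, seed = 7)
  bl <- bootstrap_edges(large, wave = 1, B = 50, refit_penalty = "fixed",
                        nfolds = 5, seed = 7)
  expect_lt(mean(bl$ci$ci_upper - bl$ci$ci_lower),
            mean(bs$ci$ci_upper - bs$ci$ci_lower))
  # OR view is the exponential of the log-odds CI
  expect_equal(bl$ci$or_ci_lower, exp(bl$ci$ci_lower))
})

test_that("percentile intervals cover a strong edge most of the time", {
  # under CV-min selection; the one-SE rule shrinks strong edges enough
  # that its intervals sit below the generating value (see vignette)
  spec <- ground_truth_spec(
    n_waves = 2, endorsement = 0.25,
    edges = data.frame(from = "eft", to = "gng", weight = 1.0),
    autoregressive = 1.0, seed = 1)
  covered <- vapply(1:8, function(s) {
    panel <- simulate_panel(spec, 2500, seed = 600 + s)
    bt <- bootstrap_edges(panel, wave = 1, B = 50, rule = "min",
                          refit_penalty = "fixed", seed = s)
    ci <- bt$ci[bt$ci$from == "eft" & bt$ci$to == "gng", ]
    ci$ci_lower <= 1.0 && ci$ci_upper >= 1.0
  }, logical(1))
  expect_gte(mean(covered), 0.5)
})

test_that("difference tests are symmetric with a silent diagonal", {
  spec <- ground_truth_spec(
    n_waves = 2, endorsement = 0.25,
    edges = data.frame(from = "eft", to = "gng", weight = 1.2),
    autoregressive = 0.8, seed = 1)
  panel <- simulate_panel(spec, 2000, seed = 4)
  bt <- bootstrap_edges(panel, wave = 1, B = 100, refit_penalty = "fixed",
                        seed = 5)

  et <- edge_difference_test(bt)
  expect_false(any(diag(et$significant)))       # an edge never differs from itself
  expect_identical(et$significant, t(et$significant))
  # a strong true edge is distinguished from a null edge
  expect_true(et$significant["eft->gng", "dep->slp"])

  ct <- centrality_difference_test(bt, index = "out")
  expect_false(any(diag(ct$significant)))
  expect_identical(ct$significant, t(ct$significant))
  # eft has out-EI 1.2, slp has 0
  expect_true(ct$significant["eft", "slp"])
})

test_that("exchangeable items are rarely flagged as different", {
  spec <- ground_truth_spec(n_waves = 2, endorsement = 0.3,
                            autoregressive = 1.0, seed = 2)
  panel <- simulate_panel(spec, 2000, seed = 6)
  bt <- bootstrap_edges(panel, wave = 1, B = 100, refit_penalty = "fixed",
                        seed = 7)
  ct <- centrality_difference_test(bt, index = "in")
  off <- ct$significant[upper.tri(ct$significant)]
  expect_lte(mean(off), 0.25)  # near the nominal rate, with slack
})

test_that("case-drop stability: exact at zero drop, strong spec is stable", {
  panel <- simulate_panel(default_ground_truth(seed = 2), 4000, seed = 44)
  st0 <- casedrop_stability(panel, wave = 1, proportions = 0, B = 3,
                            refit_penalty = "fixed", seed = 1)
  expect_true(all(abs(st0$curve$in_ei - 1) < 1e-8))
  expect_true(all(abs(st0$curve$out_ei - 1) < 1e-8))

  st <- casedrop_stability(panel, wave = 1, proportions = c(0.1, 0.3, 0.5),
                           B = 25, refit_penalty = "fixed", seed = 9)
  expect_gte(st$cs["in_ei"], 0.3)
  expect_gte(st$cs["out_ei"], 0.3)
  agg <- aggregate(in_ei ~ proportion, st$curve, mean)
  # mean correlation drifts down as more cases are dropped (trend, with slack)
  expect_gt(agg$in_ei[1] + 0.05, agg$in_ei[nrow(agg)])
  expect_identical(
    st$curve,
    casedrop_stability(panel, wave = 1, proportions = c(0.1, 0.3, 0.5),
                       B = 25, refit_penalty = "fixed", seed = 9)$curve)
})

test_that("a noise-only small sample is unstable", {
  spec <- ground_truth_spec(n_waves = 2, endorsement = 0.3, seed = 3)
  panel <- simulate_panel(spec, 300, seed = 33)
  st <- casedrop_stability(panel, wave = 1, proportions = seq(0.1, 0.7, 0.2),
                           B = 25, refit_penalty = "fixed", seed = 10)
  expect_lte(st$cs["in_ei"], 0.25)
})
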