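# Shared fixtures and independent oracles for the test suite.

# small spec without covariate effects or attrition
plain_spec <- function(n_items = 4, n_waves = 3, endorsement = 0.2, ...) {
  ground_truth_spec(items = paste0("it", seq_len(n_items)),
                    n_waves = n_waves, endorsement = endorsement,
                    covariate_prevalence = c(gender = 0.5, ethnicity = 0.1),
                    ...)
}

# recovery configuration: eight cross-lagged edges, |b| in [0.6, 1.2],
# autoregressive diagonal 1.0, endorsement targets 0.2
recovery_spec <- function(seed = 1) {
  edges <- data.frame(
    from   = c("eft", "gng", "lnl", "lnl", "eft", "slp", "hyp", "enj"),
    to     = c("gng", "eft", "dep", "sad", "dep", "eft", "enj", "hyp"),
    weight = c(0.8, 0.7, 0.9, 0.6, 0.65, 0.6, -0.7, 1.2))
  ground_truth_spec(n_waves = 2, endorsement = 0.2, edges = edges,
                    autoregressive = 1.0, seed = seed)
}

# bare network object for tests of summaries/export that do not need a fit
fake_clpn <- function(beta_items, covariate_rows = character(), wave = 1) {
  items <- colnames(beta_items) %||% paste0("it", seq_len(ncol(beta_items)))
  dimnames(beta_items) <- list(items, items)
  structure(list(beta = beta_items,
                 intercepts = stats::setNames(numeric(length(items)), items),
                 penalties = stats::setNames(numeric(length(items)), items),
                 n = 0L, items = items, covariate_rows = covariate_rows,
                 wave = wave, scale = "log_odds", nfolds = 10, rule = "1se",
                 seed = 1L),
            class = "clpn", label = sprintf("t%d_t%d", wave, wave + 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gibbs sampler for a {0,1} Ising model: independent oracle for the
# pseudo-likelihood estimator. P(x_k = 1 | rest) = plogis(tau_k + W[,k].x).
gibbs_ising <- function(n, W, thresholds, burnin = 1000, thin = 5, seed = 1) {
  p <- ncol(W)
  withr::with_seed(seed, {
    x <- rbinom(p, 1, 0.5)
    out <- matrix(0L, n, p)
    total <- burnin + n * thin
    r <- 0L
    for (sweep in seq_len(total)) {
      for (k in seq_len(p)) {
        eta <- thresholds[k] + sum(W[, k] * x) - W[k, k] * x[k]
        x[k] <- rbinom(1, 1, stats::plogis(eta))
      }
      if (sweep > burnin && (sweep - burnin) %% thin == 0) {
        r <- r + 1L
        out[r, ] <- x
      }
    }
    colnames(out) <- colnames(W)
    out
  })
}

# items-at-wave matrix without reaching into package internals
wave_matrix_for_test <- function(panel, w) {
  m <- panel$items[, w, ]
  colnames(m) <- panel$item_labels
  m
}

# closed-form Bernoulli moments at observed prevalence
bernoulli_skew <- function(p) (1 - 2 * p) / sqrt(p * (1 - p))
bernoulli_kurt <- function(p) (1 - 6 * p * (1 - p)) / (p * (1 - p))
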