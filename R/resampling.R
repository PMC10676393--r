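# Bootstrap accuracy, case-drop stability and difference tests for
# cross-lagged networks.

# Internal: node-wise penalized fits on raw matrices (used by the
# resampling loops, where rebuilding a panel object per replicate would be
# wasteful). `penalties` fixes the per-outcome penalty; NULL re-selects by CV.
fit_beta_matrix <- function(X, Y, nfolds, rule, seed, penalties = NULL) {
  p <- ncol(Y)
  beta <- matrix(0, ncol(X), p, dimnames = list(colnames(X), colnames(Y)))
  for (k in seq_len(p)) {
    y <- Y[, k]
    if (length(unique(y)) < 2) stopf("degenerate outcome '%s'", colnames(Y)[k])
    if (is.null(penalties)) {
      fit <- fit_penalized_logistic(X, y, nfolds = nfolds, rule = rule,
                                    seed = substream_seed(seed, colnames(Y)[k]))
      beta[, k] <- fit$coefficients
    } else {
      lam <- penalties[k]
      path <- glmnet::glmnet(X, y, family = "binomial",
                             lambda = lam * c(8, 4, 2, 1))
      beta[, k] <- as.numeric(coef(path, s = lam))[-1]
    }
  }
  beta
}

ei_from_beta <- function(beta, items) {
  b <- beta[items, items, drop = FALSE]
  diag(b) <- 0
  cbind(in_ei = colSums(b), out_ei = rowSums(b))
}

#' Nonparametric bootstrap for edge-weight accuracy
#'
#' Subjects are resampled with replacement and the cross-lagged network for
#' the given transition refit per replicate; percentile 95% confidence
#' intervals are formed per edge on the log-odds scale (an OR view is
#' derived by exponentiation). By default the penalty is re-selected by
#' cross-validation in every replicate so the intervals reflect the full
#' uncertainty of the procedure; `refit_penalty = "fixed"` reuses the
#' full-sample penalties. Replicates with a degenerate (single-class)
#' outcome are skipped and logged.
#'
#' @param panel a complete [symptom_panel()].
#' @param wave transition index t (waves t and t+1 are used).
#' @param B number of bootstrap replicates (>= 2).
#' @param refit_penalty `"reselect"` or `"fixed"`.
#' @param covariates,nfolds,rule passed to the network fit.
#' @param seed integer seed; the whole distribution is reproducible from
#'   `(seed, B)`.
#' @param alpha 1 - confidence level for the CI table.
#' @return An object of class `clpn_boot`: the full-sample `clpn` fit, the
#'   per-replicate edge arrays and centrality tables, a CI table, and the
#'   count of skipped replicates.
#' @export
bootstrap_edges <- function(panel, wave = 1, B = 1000,
                            refit_penalty = c("reselect", "fixed"),
                            covariates = TRUE, nfolds = 10,
                            rule = c("1se", "min"), seed = 1L, alpha = 0.05) {
  refit_penalty <- match.arg(refit_penalty)
  rule <- match.arg(rule)
  if (B < 2) stopf("B must be >= 2")
  full <- clpn(panel, wave = wave, covariates = covariates, nfolds = nfolds,
               rule = rule, seed = seed)
  X <- full$X
  Y <- full$y
  items <- full$items
  n <- nrow(X)
  p <- length(items)
  fixed <- if (refit_penalty == "fixed") full$penalties else NULL

  edge_reps <- array(NA_real_, c(B, p, p), dimnames = list(NULL, items, items))
  ei_reps <- array(NA_real_, c(B, p, 2),
                   dimnames = list(NULL, items, c("in_ei", "out_ei")))
  failures <- character()
  for (b in seq_len(B)) {
    idx <- with_substream(seed, paste0("boot", b),
                          sample.int(n, n, replace = TRUE))
    beta <- tryCatch(
      fit_beta_matrix(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                      nfolds = nfolds, rule = rule,
                      seed = substream_seed(seed, paste0("bootfit", b)),
                      penalties = fixed),
      error = function(e) conditionMessage(e))
    if (is.character(beta)) { failures <- c(failures, beta); next }
    edge_reps[b, , ] <- beta[items, items]
    ei_reps[b, , ] <- ei_from_beta(beta, items)
  }
  ok <- !is.na(edge_reps[, 1, 1])
  est <- item_beta(full)
  ci <- do.call(rbind, lapply(seq_len(p), function(j)
    do.call(rbind, lapply(seq_len(p), function(k) {
      d <- edge_reps[ok, j, k]
      q <- quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      data.frame(from = items[j], to = items[k],
                 estimate = est[j, k], boot_mean = mean(d),
                 ci_lower = q[1], ci_upper = q[2],
                 or_estimate = exp(est[j, k]),
                 or_ci_lower = exp(q[1]), or_ci_upper = exp(q[2]))
    }))))
  structure(list(kind = "nonparametric", B = B, n_ok = sum(ok),
                 failures = failures, edges = edge_reps[ok, , , drop = FALSE],
                 centrality = ei_reps[ok, , , drop = FALSE],
                 full = full, ci = ci, alpha = alpha, seed = seed,
                 refit_penalty = refit_penalty),
            class = "clpn_boot")
}

#' @export
print.clpn_boot <- function(x, ...) {
  cat(sprintf("Bootstrap distribution (%s): B = %d (%d usable), penalty %s\n",
              x$kind, x$B, x$n_ok, x$refit_penalty))
  if (length(x$failures))
    cat(sprintf("  skipped replicates: %d (e.g. %s)\n", length(x$failures),
                x$failures[1]))
  invisible(x)
}

#' Bootstrap edge-weight difference test
#'
#' For every pair of cross-lagged edges, the bootstrap distribution of the
#' difference of their weights is formed and the pair is flagged
#' significant when the percentile `(alpha/2, 1-alpha/2)` interval excludes
#' zero. No multiplicity correction is applied, following the convention of
#' the bootstrap-difference framework this implements; interpret the matrix
#' accordingly.
#'
#' @param dist a `clpn_boot` from [bootstrap_edges()].
#' @param alpha significance level.
#' @param include_autoregressive include the diagonal (autoregressive)
#'   edges among those compared?
#' @return Object of class `difference_test`: logical significance matrix
#'   (symmetric, diagonal `FALSE`), plus the CI arrays of the differences.
#' @export
edge_difference_test <- function(dist, alpha = 0.05,
                                 include_autoregressive = FALSE) {
  stopifnot(inherits(dist, "clpn_boot"))
  items <- dist$full$items
  p <- length(items)
  pos <- which(include_autoregressive | (row(diag(p)) != col(diag(p))),
               arr.ind = TRUE)
  labs <- paste0(items[pos[, 1]], "->", items[pos[, 2]])
  flat <- t(apply(dist$edges, 1, function(m) m[pos]))
  difference_test(flat, labs, alpha, kind = "edge")
}

#' Bootstrap centrality difference test
#'
#' As [edge_difference_test()], over the items' expected-influence values.
#'
#' @param dist a `clpn_boot`.
#' @param index `"in"` or `"out"` expected influence.
#' @param alpha significance level.
#' @return A `difference_test` over items.
#' @export
centrality_difference_test <- function(dist, index = c("in", "out"),
                                       alpha = 0.05) {
  stopifnot(inherits(dist, "clpn_boot"))
  index <- match.arg(index)
  flat <- dist$centrality[, , paste0(index, "_ei")]
  difference_test(flat, dist$full$items, alpha, kind = paste0(index, "-EI"))
}

difference_test <- function(flat, labs, alpha, kind) {
  q <- ncol(flat)
  sig <- matrix(FALSE, q, q, dimnames = list(labs, labs))
  lo <- hi <- matrix(0, q, q, dimnames = list(labs, labs))
  for (i in seq_len(q - 1)) for (j in (i + 1):q) {
    d <- flat[, i] - flat[, j]
    ci <- quantile(d, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    lo[i, j] <- ci[1]; hi[i, j] <- ci[2]
    lo[j, i] <- -ci[2]; hi[j, i] <- -ci[1]
    sig[i, j] <- sig[j, i] <- (ci[1] > 0 || ci[2] < 0)
  }
  structure(list(significant = sig, ci_lower = lo, ci_upper = hi,
                 alpha = alpha, kind = kind),
            class = "difference_test")
}

#' @export
print.difference_test <- function(x, ...) {
  cat(sprintf("Bootstrap %s difference test (alpha = %.2f): %d of %d pairs significant\n",
              x$kind, x$alpha, sum(x$significant[upper.tri(x$significant)]),
              sum(upper.tri(x$significant))))
  invisible(x)
}

#' Case-drop bootstrap stability of centrality indices
#'
#' For each drop proportion, `B` subsamples without replacement retain
#' `1 - proportion` of the subjects; the network is refit and each
#' centrality index is correlated (Spearman rank by default) with its
#' full-sample values. The CS-coefficient per index is the largest
#' proportion at which at least 95% of the replicate correlations stay at
#' or above 0.7 (0 if none does).
#'
#' @param panel a complete [symptom_panel()].
#' @param wave transition index.
#' @param proportions drop proportions in (0, 1).
#' @param B subsamples per proportion.
#' @param covariates,nfolds,rule,seed as in [bootstrap_edges()].
#' @param refit_penalty `"reselect"` or `"fixed"`.
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @param cor_threshold,confidence CS-coefficient definition parameters.
#' @return Object of class `clpn_stability`: the correlation curve (long
#'   data frame) and the CS-coefficient per index.
#' @export
casedrop_stability <- function(panel, wave = 1,
                               proportions = seq(0.1, 0.7, by = 0.1),
                               B = 1000, covariates = TRUE, nfolds = 10,
                               rule = c("1se", "min"), seed = 1L,
                               refit_penalty = c("reselect", "fixed"),
                               cor_method = c("spearman", "pearson"),
                               cor_threshold = 0.7, confidence = 0.95) {
  rule <- match.arg(rule)
  refit_penalty <- match.arg(refit_penalty)
  cor_method <- match.arg(cor_method)
  if (any(proportions < 0 | proportions >= 1))
    stopf("drop proportions must lie in [0, 1)")
  full <- clpn(panel, wave = wave, covariates = covariates, nfolds = nfolds,
               rule = rule, seed = seed)
  X <- full$X; Y <- full$y; items <- full$items
  full_ei <- ei_from_beta(item_beta(full), items)
  fixed <- if (refit_penalty == "fixed") full$penalties else NULL
  n <- nrow(X)

  rows <- list()
  for (pr in proportions) {
    keep_n <- max(2L, floor((1 - pr) * n))
    for (b in seq_len(B)) {
      idx <- with_substream(seed, sprintf("drop%.3f_%d", pr, b),
                            sample.int(n, keep_n, replace = FALSE))
      beta <- tryCatch(
        fit_beta_matrix(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                        nfolds = nfolds, rule = rule,
                        seed = substream_seed(seed, sprintf("dropfit%.3f_%d", pr, b)),
                        penalties = fixed),
        error = function(e) NULL)
      if (is.null(beta)) next
      ei <- ei_from_beta(beta, items)
      rows[[length(rows) + 1]] <- data.frame(
        proportion = pr, replicate = b,
        in_ei = suppressWarnings(cor(full_ei[, "in_ei"], ei[, "in_ei"],
                                     method = cor_method)),
        out_ei = suppressWarnings(cor(full_ei[, "out_ei"], ei[, "out_ei"],
                                      method = cor_method)))
    }
  }
  curve <- do.call(rbind, rows)
  cs <- vapply(c(in_ei = "in_ei", out_ei = "out_ei"), function(ix) {
    ok <- vapply(proportions, function(pr) {
      v <- curve[curve$proportion == pr, ix]
      length(v) > 0 && mean(v >= cor_threshold, na.rm = TRUE) >= confidence
    }, logical(1))
    if (any(ok)) max(proportions[ok]) else 0
  }, numeric(1))
  structure(list(curve = curve, cs = cs, proportions = proportions, B = B,
                 cor_method = cor_method, cor_threshold = cor_threshold,
                 confidence = confidence, full = full, seed = seed),
            class = "clpn_stability")
}

#' @export
print.clpn_stability <- function(x, ...) {
  cat(sprintf("Case-drop stability (%s correlation, B = %d per proportion)\n",
              x$cor_method, x$B))
  cat(sprintf("  CS-coefficient: in-EI %.1f, out-EI %.1f (threshold %.2f at %.0f%%)\n",
              x$cs["in_ei"], x$cs["out_ei"], x$cor_threshold,
              100 * x$confidence))
  invisible(x)
}

#' @export
plot.clpn_stability <- function(x, ...) {
  agg <- aggregate(cbind(in_ei, out_ei) ~ proportion, data = x$curve, mean)
  graphics::matplot(agg$proportion, agg[, c("in_ei", "out_ei")], type = "b",
                    pch = 1:2, lty = 1:2, col = 1:2, ylim = c(-1, 1),
                    xlab = "drop proportion", ylab = "correlation with full sample")
  graphics::abline(h = x$cor_threshold, lty = 3)
  graphics::legend("bottomleft", c("in-EI", "out-EI"), pch = 1:2, col = 1:2,
                   lty = 1:2, bty = "n")
  invisible(x)
}
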