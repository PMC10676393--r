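#' L1-penalized logistic regression with cross-validated penalty selection
#'
#' Thin, seeded wrapper around a lasso-penalized logistic fit: folds are a
#' seeded permutation stratified by the outcome class (so no fold is left
#' without events at low endorsement), the penalty is chosen on the mean
#' cross-validated binomial deviance by the `"min"` or `"1se"` rule, and
#' coefficients are reported on the original 0/1 predictor scale with small
#' coefficients exactly zero. Predictors are standardized internally for
#' the penalized fit and back-transformed. A fixed `penalty` (including 0,
#' giving the unpenalized maximum-likelihood fit) bypasses cross-validation.
#'
#' @param x predictor matrix (no missing values).
#' @param y binary 0/1 outcome with both classes present.
#' @param nfolds number of cross-validation folds.
#' @param rule `"1se"` (default) or `"min"`; see Details in the package
#'   vignette for why the one-standard-error rule is the default.
#' @param penalty optional fixed penalty value; overrides cross-validation.
#' @param seed integer seed for the fold assignment.
#' @return List with `coefficients` (named), `intercept`, `penalty`, and
#'   `path` (data frame of penalty vs number of nonzero coefficients).
#' @export
fit_penalized_logistic <- function(x, y, nfolds = 10,
                                   rule = c("1se", "min"),
                                   penalty = NULL, seed = 1L) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) stopf("missing values are not allowed here; impute upstream")
  if (length(unique(y)) < 2) stopf("degenerate outcome: y has a single class")

  if (!is.null(penalty)) {
    base <- glmnet::glmnet(x, y, family = "binomial", nlambda = 60,
                           thresh = 1e-10)
    lam <- sort(unique(c(base$lambda, penalty)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lam,
                          thresh = 1e-10)
    cf <- as.numeric(coef(fit, s = penalty, exact = TRUE, x = x, y = y))
    path <- data.frame(penalty = fit$lambda, n_nonzero = fit$df)
    return(list(coefficients = setNames(cf[-1], colnames(x)),
                intercept = cf[1], penalty = penalty, path = path))
  }

  foldid <- with_substream(seed, "cv_folds", stratified_folds(y, nfolds))
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                          nlambda = 60, type.measure = "deviance")
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(coef(cv, s = lam))
  path <- data.frame(penalty = cv$glmnet.fit$lambda,
                     n_nonzero = cv$glmnet.fit$df)
  list(coefficients = setNames(cf[-1], colnames(x)),
       intercept = cf[1], penalty = lam, path = path)
}

# Seeded fold assignment, stratified by outcome class.
stratified_folds <- function(y, nfolds) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Fit a cross-lagged panel network for one consecutive wave pair
#'
#' One lasso-penalized logistic regression per outcome item at wave
#' `wave + 1`, with predictors all items at wave `wave` plus (optionally)
#' the binary covariates. Edge weights are the log-odds coefficients; the
#' entry `[j, k]` of the coefficient matrix is the directed edge from item
#' j at wave t to item k at wave t+1. The item-diagonal holds the
#' autoregressive paths; covariate rows are flagged and excluded from
#' symptom-network summaries such as [expected_influence()].
#'
#' @param panel a complete (post-imputation) [symptom_panel()], or one with
#'   missing values when `complete_cases = TRUE`.
#' @param wave index t of the transition t -> t+1.
#' @param covariates include the panel's covariates as predictors?
#' @param nfolds,rule,seed passed to [fit_penalized_logistic()].
#' @param complete_cases drop subjects with any missing value in the two
#'   waves instead of erroring on missingness.
#' @return An object of class `clpn` with components `beta` (predictors x
#'   outcomes, log-odds), `intercepts`, `penalties`, `n`, `items`,
#'   `covariate_rows`, `scale`.
#' @export
#' @examples
#' spec <- ground_truth_spec(items = letters[1:3], n_waves = 2,
#'                           autoregressive = 2, seed = 7)
#' panel <- simulate_panel(spec, 400)
#' net <- clpn(panel, wave = 1, nfolds = 5)
#' round(coef(net), 2)
clpn <- function(panel, wave = 1, covariates = TRUE, nfolds = 10,
                 rule = c("1se", "min"), seed = 1L, complete_cases = FALSE) {
  rule <- match.arg(rule)
  stopifnot(inherits(panel, "symptom_panel"))
  if (wave < 1 || wave + 1 > panel$n_waves)
    stopf("waves %d and %d must both exist", wave, wave + 1)
  x_items <- wave_matrix(panel, wave)
  y_items <- wave_matrix(panel, wave + 1)
  use_covs <- isTRUE(covariates) && ncol(panel$covariates) > 0
  X <- if (use_covs) cbind(x_items, panel$covariates) else x_items
  keep <- complete.cases(cbind(X, y_items))
  if (!all(keep)) {
    if (!complete_cases)
      stopf("panel has missing values in waves %d-%d; impute first or set complete_cases = TRUE",
            wave, wave + 1)
    X <- X[keep, , drop = FALSE]
    y_items <- y_items[keep, , drop = FALSE]
  }
  p <- panel$n_items
  beta <- matrix(0, ncol(X), p, dimnames = list(colnames(X), panel$item_labels))
  intercepts <- setNames(numeric(p), panel$item_labels)
  penalties <- setNames(numeric(p), panel$item_labels)
  for (k in seq_len(p)) {
    fit <- tryCatch(
      fit_penalized_logistic(X, y_items[, k], nfolds = nfolds, rule = rule,
                             seed = substream_seed(seed, panel$item_labels[k])),
      error = function(e) stopf("outcome '%s': %s",
                                panel$item_labels[k], conditionMessage(e)))
    beta[, k] <- fit$coefficients
    intercepts[k] <- fit$intercept
    penalties[k] <- fit$penalty
  }
  structure(list(beta = beta, intercepts = intercepts, penalties = penalties,
                 n = nrow(X), items = panel$item_labels,
                 covariate_rows = if (use_covs) colnames(panel$covariates)
                                  else character(),
                 wave = wave, scale = "log_odds",
                 nfolds = nfolds, rule = rule, seed = seed,
                 X = X, y = y_items),
            class = "clpn",
            label = sprintf("t%d_t%d", wave, wave + 1))
}

#' Switch a cross-lagged network between log-odds and odds-ratio scales
#'
#' Elementwise `exp` of the edge-weight matrix: an OR of 1 corresponds to a
#' log-odds coefficient of 0 (no relationship), ORs above/below 1 to
#' positive/negative relationships. The log-odds view is retained so the
#' transformation is reversible.
#'
#' @param network a `clpn` object.
#' @return The network with `beta` on the OR scale and `scale = "OR"`.
#' @export
to_odds_ratio <- function(network) {
  stopifnot(inherits(network, "clpn"))
  if (identical(network$scale, "OR")) return(network)
  network$log_odds <- network$beta
  network$beta <- exp(network$beta)
  network$scale <- "OR"
  network
}

#' @export
coef.clpn <- function(object, scale = c("log_odds", "OR"), ...) {
  scale <- match.arg(scale)
  b <- if (identical(object$scale, "OR")) object$log_odds else object$beta
  if (scale == "OR") exp(b) else b
}

# items-only (cross-lagged + autoregressive) view of the weight matrix
item_beta <- function(network) {
  b <- coef(network, scale = "log_odds")
  b[network$items, network$items, drop = FALSE]
}

#' Cross-lagged expected-influence centrality
#'
#' In-expected-influence of item k is the sum of incoming cross-lagged
#' log-odds edge weights (column k, excluding the autoregressive diagonal
#' and covariate rows); out-expected-influence of item j is the sum of its
#' outgoing cross-lagged weights (row j, same exclusions). z-standardized
#' versions across the items are appended. Summation is on the log-odds
#' scale, where "no effect" contributes 0.
#'
#' @param network a `clpn` object.
#' @return Data frame of class `centrality_table` with columns `item`,
#'   `in_ei`, `out_ei`, `in_ei_z`, `out_ei_z`.
#' @export
expected_influence <- function(network) {
  stopifnot(inherits(network, "clpn"))
  b <- item_beta(network)
  diag(b) <- 0
  out <- data.frame(item = network$items,
                    in_ei = colSums(b),
                    out_ei = rowSums(b))
  out$in_ei_z <- zstd(out$in_ei)
  out$out_ei_z <- zstd(out$out_ei)
  rownames(out) <- NULL
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' @export
print.clpn <- function(x, digits = 3, ...) {
  b <- item_beta(x)
  cross <- b[row(b) != col(b)]
  cat(sprintf("Cross-lagged panel network (waves %d -> %d), %s scale\n",
              x$wave, x$wave + 1,
              if (identical(x$scale, "OR")) "odds-ratio" else "log-odds"))
  cat(sprintf("  n = %d; penalty rule: %s (%d-fold CV)\n", x$n, x$rule, x$nfolds))
  cat(sprintf("  nonzero cross-lagged edges: %d / %d; autoregressive range [%s, %s]\n",
              sum(cross != 0), length(cross),
              format(min(diag(b)), digits = digits),
              format(max(diag(b)), digits = digits)))
  if (length(x$covariate_rows))
    cat(sprintf("  covariates: %s\n", paste(x$covariate_rows, collapse = ", ")))
  invisible(x)
}

#' @export
summary.clpn <- function(object, ...) {
  b <- item_beta(object)
  ei <- expected_influence(object)
  cross <- b; diag(cross) <- NA
  structure(list(
    label = attr(object, "label"),
    n = object$n,
    rule = object$rule,
    penalties = object$penalties,
    autoregressive = diag(b),
    n_nonzero_cross = sum(cross != 0, na.rm = TRUE),
    strongest = {
      idx <- which(!is.na(cross) & abs(cross) == max(abs(cross), na.rm = TRUE),
                   arr.ind = TRUE)[1, , drop = FALSE]
      data.frame(from = rownames(b)[idx[, 1]], to = colnames(b)[idx[, 2]],
                 log_odds = cross[idx], OR = exp(cross[idx]))
    },
    centrality = ei), class = "summary.clpn")
}

#' @export
print.summary.clpn <- function(x, digits = 3, ...) {
  cat(sprintf("CLPN %s: n = %d, %d nonzero cross-lagged edges\n",
              x$label, x$n, x$n_nonzero_cross))
  cat("Autoregressive paths (log-odds):\n")
  print(round(x$autoregressive, digits))
  cat("Strongest cross-lagged edge:\n")
  print(x$strongest, digits = digits, row.names = FALSE)
  cat("Expected influence:\n")
  print(x$centrality, digits = digits)
  invisible(x)
}

#' @export
predict.clpn <- function(object, newdata = NULL,
                         type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  b <- if (identical(object$scale, "OR")) object$log_odds else object$beta
  if (!all(rownames(b) %in% colnames(X)))
    stopf("newdata must contain columns: %s", paste(rownames(b), collapse = ", "))
  eta <- sweep(X[, rownames(b), drop = FALSE] %*% b, 2, object$intercepts, "+")
  if (type == "response") plogis(eta) else eta
}

#' @export
residuals.clpn <- function(object, ...) {
  object$y - predict(object, type = "response")
}

#' @export
#' @importFrom graphics axis barplot image par text
plot.clpn <- function(x, which = c("network", "centrality"), ...) {
  which <- match.arg(which)
  if (which == "centrality") {
    ei <- expected_influence(x)
    op <- par(mfrow = c(1, 2)); on.exit(par(op))
    barplot(ei$in_ei_z, names.arg = ei$item, las = 2,
            main = "in-expected-influence (z)")
    barplot(ei$out_ei_z, names.arg = ei$item, las = 2,
            main = "out-expected-influence (z)")
  } else {
    b <- item_beta(x)
    p <- ncol(b)
    image(seq_len(p), seq_len(p), t(b[p:1, , drop = FALSE]), axes = FALSE,
          xlab = sprintf("item at wave %d+1", x$wave),
          ylab = sprintf("item at wave %d", x$wave),
          main = attr(x, "label"), ...)
    axis(1, seq_len(p), colnames(b), las = 2)
    axis(2, seq_len(p), rev(rownames(b)), las = 2)
  }
  invisible(x)
}
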