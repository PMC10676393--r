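#' Cross-sectional Ising network via node-wise penalized logistic regression
#'
#' Each item is regressed on all others with an L1 penalty; the penalty is
#' chosen per item by the extended BIC, `EBIC = deviance + df log(n) +
#' 2 gamma df log(p - 1)`, over the glmnet path. The two directed estimates
#' for a pair are combined into one symmetric coupling: under the `"AND"`
#' rule the edge is zero unless both directed coefficients are nonzero (then
#' their mean); under `"OR"` it is the mean of the available nonzero
#' estimates. Item thresholds come from the node-wise intercepts. This is
#' the pseudo-likelihood (eLasso) estimator; no partition-function
#' likelihood is computed.
#'
#' @param x a [symptom_panel()] (with `wave` giving the wave to use) or a
#'   complete binary subjects x items matrix.
#' @param wave wave index when `x` is a panel.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule `"AND"` (default) or `"OR"` edge combination rule.
#' @param ... unused.
#' @return An object of class `ising_net` with `weights` (symmetric, zero
#'   diagonal), `thresholds`, `gamma`, `rule`, `items`, `n`, and `dropped`
#'   (items excluded for having a single observed class).
#' @export
ising <- function(x, ...) UseMethod("ising")

#' @rdname ising
#' @export
ising.symptom_panel <- function(x, wave = 1, gamma = 0.25,
                                rule = c("AND", "OR"), ...) {
  m <- wave_matrix(x, wave)
  m <- m[complete.cases(m), , drop = FALSE]
  out <- ising(m, gamma = gamma, rule = rule)
  attr(out, "label") <- sprintf("ising_w%s", x$wave_labels[wave])
  out
}

#' @rdname ising
#' @export
ising.default <- function(x, gamma = 0.25, rule = c("AND", "OR"), ...) {
  rule <- match.arg(rule)
  m <- as.matrix(x)
  if (anyNA(m)) stopf("item matrix must be complete")
  if (!all(m %in% c(0, 1))) stopf("item matrix must be binary")
  if (gamma < 0) stopf("gamma must be nonnegative")

  single <- which(apply(m, 2, function(v) length(unique(v)) < 2))
  dropped <- colnames(m)[single]
  if (length(single)) {
    warning(sprintf("dropping single-class item(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    m <- m[, -single, drop = FALSE]
  }
  p <- ncol(m)
  if (p < 2) stopf("need at least 2 items with both classes")
  items <- colnames(m) %||% paste0("item_", seq_len(p))
  colnames(m) <- items
  n <- nrow(m)

  directed <- matrix(0, p, p, dimnames = list(items, items))
  thresholds <- setNames(numeric(p), items)
  for (k in seq_len(p)) {
    x <- m[, -k, drop = FALSE]
    # glmnet needs >= 2 columns; pad with a constant (gets zero coefficient)
    if (ncol(x) < 2) x <- cbind(x, `.pad` = 0)
    fit <- glmnet::glmnet(x, m[, k], family = "binomial",
                          nlambda = 60)
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    ebic <- dev + fit$df * log(n) + 2 * gamma * fit$df * log(p - 1)
    best <- which.min(ebic)
    cf <- as.numeric(coef(fit, s = fit$lambda[best]))
    directed[-k, k] <- cf[2:p]
    thresholds[k] <- cf[1]
  }

  weights <- matrix(0, p, p, dimnames = list(items, items))
  for (j in seq_len(p - 1)) for (k in (j + 1):p) {
    a <- directed[j, k]; b <- directed[k, j]
    w <- if (rule == "AND") {
      if (a != 0 && b != 0) (a + b) / 2 else 0
    } else {
      nz <- c(a, b)[c(a, b) != 0]
      if (length(nz)) mean(nz) else 0
    }
    weights[j, k] <- weights[k, j] <- w
  }

  structure(list(weights = weights, thresholds = thresholds, gamma = gamma,
                 rule = rule, items = items, n = n, dropped = dropped,
                 directed = directed),
            class = "ising_net")
}

#' @export
print.ising_net <- function(x, ...) {
  cat(sprintf("Ising network: %d items, n = %d, gamma = %.2f, %s rule\n",
              length(x$items), x$n, x$gamma, x$rule))
  cat(sprintf("  nonzero couplings: %d / %d\n",
              sum(x$weights[upper.tri(x$weights)] != 0),
              sum(upper.tri(x$weights))))
  if (length(x$dropped))
    cat(sprintf("  dropped single-class items: %s\n",
                paste(x$dropped, collapse = ", ")))
  invisible(x)
}

#' Correlation between an Ising network and a cross-lagged network
#'
#' Reporting convenience for contrasting cross-sectional with temporal
#' association patterns: the Pearson correlation between the Ising
#' couplings and the symmetrized (averaged with its transpose) cross-lagged
#' weight matrix over the off-diagonal item pairs.
#'
#' @param ising_net an `ising_net`.
#' @param clpn_net a `clpn` over the same items.
#' @return A single correlation.
#' @export
ising_clpn_correlation <- function(ising_net, clpn_net) {
  stopifnot(inherits(ising_net, "ising_net"), inherits(clpn_net, "clpn"))
  if (!setequal(ising_net$items, clpn_net$items))
    stopf("item sets differ")
  b <- item_beta(clpn_net)[ising_net$items, ising_net$items]
  sym <- (b + t(b)) / 2
  ut <- upper.tri(sym)
  cor(ising_net$weights[ut], sym[ut])
}
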