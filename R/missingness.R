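# Missing-data stage: MCAR testing, dropout modelling and single-dataset
# chained-equations imputation with logistic models.

#' Little's MCAR test
#'
#' Tests whether data are missing completely at random by comparing the
#' observed-variable means of each missingness pattern with the grand
#' maximum-likelihood estimates. The mean vector and covariance matrix are
#' estimated by EM under multivariate normality; the statistic
#' `d2 = sum_j n_j (ybar_j - mu_j)' Sigma_j^{-1} (ybar_j - mu_j)` over
#' missingness patterns is referred to a chi-square distribution with
#' `sum_j p_j - p` degrees of freedom (`p_j` = number of variables observed
#' in pattern j). The reference method assumes normality; applying it to
#' binary items follows common applied practice and should be read as
#' approximate.
#'
#' @param data numeric matrix or data frame, subjects x variables, `NA`
#'   for missing; rows with no observed value are dropped.
#' @param max_iter,tol EM stopping parameters.
#' @return Object of class `mcar_test`: `d2`, `df`, `p_value`,
#'   `n_patterns`, and the EM estimates.
#' @export
little_mcar_test <- function(data, max_iter = 200, tol = 1e-8) {
  Y <- as.matrix(data)
  storage.mode(Y) <- "double"
  p <- ncol(Y)
  if (p < 2) stopf("need at least 2 variables")
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  n <- nrow(Y)
  M <- is.na(Y)
  pat_id <- apply(M, 1, function(r) paste(as.integer(r), collapse = ""))
  pats <- split(seq_len(n), pat_id)

  est <- em_mvnorm(Y, M, pats, max_iter = max_iter, tol = tol)
  mu <- est$mu; Sigma <- est$Sigma

  d2 <- 0; df <- 0L
  for (rows in pats) {
    obs <- which(!M[rows[1], ])
    if (!length(obs)) next
    nj <- length(rows)
    ybar <- colMeans(Y[rows, obs, drop = FALSE])
    S <- Sigma[obs, obs, drop = FALSE]
    diff <- ybar - mu[obs]
    quad <- tryCatch(sum(diff * solve(S, diff)), error = function(e) {
      warning("singular pattern submatrix; ridge-stabilized inverse used",
              call. = FALSE)
      sum(diff * solve(S + diag(1e-8 * mean(diag(S)), length(obs)), diff))
    })
    d2 <- d2 + nj * quad
    df <- df + length(obs)
  }
  df <- df - p
  p_value <- if (df > 0) pchisq(d2, df, lower.tail = FALSE) else 1
  structure(list(d2 = d2, df = df, p_value = p_value,
                 n_patterns = length(pats), mu = mu, Sigma = Sigma,
                 n = n, iterations = est$iterations),
            class = "mcar_test")
}

#' @export
print.mcar_test <- function(x, ...) {
  cat(sprintf("Little's MCAR test: d2 = %.3f, df = %d, p %s (%d missingness patterns, n = %d)\n",
              x$d2, x$df,
              if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value),
              x$n_patterns, x$n))
  invisible(x)
}

# EM for multivariate normal mean/covariance with missing data, rows
# grouped by missingness pattern (ML covariance, divisor n).
em_mvnorm <- function(Y, M, pats, max_iter, tol) {
  n <- nrow(Y); p <- ncol(Y)
  Yf <- Y
  for (k in seq_len(p)) Yf[M[, k], k] <- mean(Y[, k], na.rm = TRUE)
  mu <- colMeans(Yf)
  Sigma <- crossprod(sweep(Yf, 2, mu)) / n
  it <- 0L
  repeat {
    it <- it + 1L
    Cadd <- matrix(0, p, p)
    for (rows in pats) {
      mis <- which(M[rows[1], ])
      if (!length(mis)) next
      obs <- which(!M[rows[1], ])
      if (!length(obs)) { Yf[rows, ] <- rep(mu, each = length(rows)); next }
      Soo <- Sigma[obs, obs, drop = FALSE]
      Smo <- Sigma[mis, obs, drop = FALSE]
      A <- tryCatch(t(solve(Soo, t(Smo))), error = function(e)
        t(solve(Soo + diag(1e-8 * mean(diag(Soo)), length(obs)), t(Smo))))
      resid <- sweep(Y[rows, obs, drop = FALSE], 2, mu[obs])
      Yf[rows, mis] <- rep(mu[mis], each = length(rows)) + resid %*% t(A)
      Cmm <- Sigma[mis, mis, drop = FALSE] - A %*% t(Smo)
      Cadd[mis, mis] <- Cadd[mis, mis] + length(rows) * Cmm
    }
    mu_new <- colMeans(Yf)
    Sigma_new <- (crossprod(sweep(Yf, 2, mu_new)) + Cadd) / n
    delta <- max(abs(mu_new - mu), abs(Sigma_new - Sigma))
    mu <- mu_new; Sigma <- Sigma_new
    if (delta < tol || it >= max_iter) break
  }
  list(mu = mu, Sigma = Sigma, iterations = it)
}

#' Logistic model for study dropout
#'
#' Regresses an ever-dropped-out indicator (subject not observed at the
#' final wave) on the panel covariates and the baseline (wave 1) sum
#' score, optionally with extra subject-level predictors. Complete
#' separation is flagged and the coefficients refit with a small ridge
#' penalty in that case.
#'
#' @param panel a [symptom_panel()] with missingness.
#' @param extra optional subjects x variables matrix of additional
#'   predictors (e.g. age, education).
#' @param reverse_items passed to [sum_scores()] for the baseline score.
#' @return Object of class `dropout_model`: coefficient table (estimate,
#'   SE, z, p), the fitted `glm` (when well-behaved) and a `separation`
#'   flag.
#' @export
dropout_model <- function(panel, extra = NULL,
                          reverse_items = intersect(c("hyp", "enj"),
                                                    panel$item_labels)) {
  stopifnot(inherits(panel, "symptom_panel"))
  observed_last <- rowSums(!is.na(panel$items[, panel$n_waves, , drop = FALSE])) > 0
  dropped <- as.integer(!observed_last)
  if (sum(dropped) == 0) stopf("no events: no subject ever dropped out")
  base_score <- sum_scores(panel, reverse_items)[, 1]
  X <- cbind(panel$covariates, baseline_sum = base_score)
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  dat <- data.frame(dropped = dropped, X, check.names = TRUE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fit <- glm(dropped ~ ., data = dat, family = binomial())
  sep <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  tab <- summary(fit)$coefficients
  if (sep) {
    Xm <- as.matrix(dat[, -1, drop = FALSE])
    rf <- glmnet::glmnet(Xm, dat$dropped, family = "binomial", alpha = 0,
                         lambda = 0.01)
    cf <- as.numeric(coef(rf))
    tab <- cbind(Estimate = cf, `Std. Error` = NA, `z value` = NA,
                 `Pr(>|z|)` = NA)
    rownames(tab) <- c("(Intercept)", colnames(Xm))
    warning("complete separation suspected; penalized (ridge) coefficients reported",
            call. = FALSE)
  }
  structure(list(coefficients = tab, separation = sep,
                 n = nrow(dat), n_events = sum(dat$dropped),
                 glm = if (!sep) fit),
            class = "dropout_model")
}

#' @export
print.dropout_model <- function(x, digits = 3, ...) {
  cat(sprintf("Dropout model: %d events / %d subjects%s\n", x$n_events, x$n,
              if (x$separation) " [separation: penalized coefficients]" else ""))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Chained-equations imputation with logistic models
#'
#' Produces complete data from a panel with missing binary measurements.
#' Missing cells are initialized by random draws from each variable's
#' observed marginal; then, for `n_iterations` sweeps in fixed column
#' order, each incomplete variable is regressed (logistic) on all other
#' variables — the items at every wave, the panel covariates, and any
#' extra auxiliary variables — and its missing entries are redrawn by
#' perturbing the fitted coefficients with a draw from their asymptotic
#' normal distribution and sampling from the implied Bernoulli. Observed
#' values are never altered. One imputed dataset is returned by default
#' (network estimation is not pooled over multiple imputations); set
#' `m > 1` for sensitivity analyses.
#'
#' @param panel a [symptom_panel()] with missing values.
#' @param auxiliaries optional subjects x variables numeric matrix of
#'   complete auxiliary predictors included in every imputation model.
#' @param n_iterations chained-equation sweeps (default 20).
#' @param m number of imputed datasets.
#' @param seed integer seed.
#' @return A complete `symptom_panel` (or a list of `m` of them), with the
#'   per-variable imputed-prevalence trace attached as attribute
#'   `"convergence"`.
#' @export
impute_chained <- function(panel, auxiliaries = NULL, n_iterations = 20,
                           m = 1, seed = 1L) {
  stopifnot(inherits(panel, "symptom_panel"))
  if (!anyNA(panel$items)) return(panel)
  n <- panel$n_subjects
  wide <- do.call(cbind, lapply(seq_len(panel$n_waves), function(w) {
    mm <- wave_matrix(panel, w)
    colnames(mm) <- paste0(panel$item_labels, "_w", w)
    mm
  }))
  fixed <- cbind(panel$covariates,
                 if (!is.null(auxiliaries)) as.matrix(auxiliaries))
  if (is.null(fixed)) fixed <- matrix(0, n, 0)
  if (anyNA(fixed)) stopf("covariates/auxiliaries must be complete")
  miss <- is.na(wide)
  no_obs <- colSums(!miss) == 0
  if (any(no_obs))
    stopf("variable(s) with no observed values: %s",
          paste(colnames(wide)[no_obs], collapse = ", "))
  incomplete <- which(colSums(miss) > 0)

  run_one <- function(chain) {
    filled <- wide
    trace <- matrix(NA_real_, n_iterations, length(incomplete),
                    dimnames = list(NULL, colnames(wide)[incomplete]))
    with_substream(seed, paste0("impute_chain", chain), {
      for (j in incomplete) {
        pobs <- mean(wide[!miss[, j], j])
        filled[miss[, j], j] <- rbinom(sum(miss[, j]), 1, pobs)
      }
      for (it in seq_len(n_iterations)) {
        for (idx in seq_along(incomplete)) {
          j <- incomplete[idx]
          mj <- miss[, j]
          preds <- cbind(1, filled[, -j, drop = FALSE], fixed)
          yobs <- wide[!mj, j]
          if (length(unique(yobs)) < 2) {
            filled[mj, j] <- yobs[1]
          } else {
            draw <- impute_draw(preds[!mj, , drop = FALSE], yobs,
                                preds[mj, , drop = FALSE])
            filled[mj, j] <- draw
          }
          trace[it, idx] <- mean(filled[mj, j])
        }
      }
    })
    # wide columns are item-within-wave: reshape back to the panel array
    items <- array(NA_real_, c(n, panel$n_waves, panel$n_items),
                   dimnames = list(NULL, NULL, panel$item_labels))
    for (w in seq_len(panel$n_waves))
      items[, w, ] <- filled[, (w - 1) * panel$n_items + seq_len(panel$n_items)]
    out <- symptom_panel(items, covariates = panel$covariates,
                         subject_ids = panel$subject_ids,
                         item_labels = panel$item_labels,
                         wave_labels = panel$wave_labels)
    attr(out, "convergence") <- trace
    out
  }
  if (m == 1) run_one(1) else lapply(seq_len(m), run_one)
}

# One posterior-predictive-style logistic draw: fit by IRLS (glm.fit),
# perturb coefficients with their asymptotic normal distribution, draw
# Bernoulli responses for the missing rows. Falls back to a marginal draw
# if the fit degenerates.
impute_draw <- function(Xobs, yobs, Xmis) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(Xobs, yobs, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(coef(fit))) {
    # degenerate model: draw from the observed marginal
    return(rbinom(nrow(Xmis), 1, mean(yobs)))
  }
  beta <- coef(fit)
  w <- fit$weights
  XtWX <- crossprod(Xobs * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e)
    solve(XtWX + diag(1e-6 * mean(diag(XtWX)), ncol(XtWX))))
  L <- tryCatch(chol(V), error = function(e) NULL)
  bstar <- if (is.null(L)) beta else
    beta + as.numeric(t(L) %*% rnorm(length(beta)))
  eta <- pmin(pmax(Xmis %*% bstar, -30), 30)
  rbinom(nrow(Xmis), 1, plogis(eta))
}
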