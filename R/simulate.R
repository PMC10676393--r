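#' Simulate a fully observed symptom panel from a ground truth
#'
#' Covariates are drawn from their prevalences; wave-1 items are drawn
#' independently per item from the intercept-implied probabilities
#' conditional on covariates; each later wave is drawn from the lag-1
#' logistic transition model
#' \deqn{logit P(y_{k,t+1} = 1) = c_k + \sum_j B_{jk} y_{j,t} + \gamma_k' z.}
#' Three named random sub-streams (covariates, wave 1, transitions) are
#' derived from the master seed so the stages are independently
#' reproducible; the same spec and seed always yield a bit-identical panel.
#'
#' @param spec a [ground_truth_spec()].
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; defaults to the seed stored in the spec.
#' @return A fully observed [symptom_panel()].
#' @export
simulate_panel <- function(spec, n_subjects, seed = spec$seed) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  n <- as.integer(n_subjects)
  p <- spec$n_items; W <- spec$n_waves

  covs <- with_substream(seed, "covariates", {
    m <- vapply(spec$covariate_prevalence, function(pr) rbinom(n, 1, pr),
                numeric(n))
    if (n == 1) m <- matrix(m, nrow = 1)
    m <- as.matrix(m)
    colnames(m) <- spec$covariates
    m
  })

  cov_shift <- if (length(spec$covariates))
    covs %*% spec$covariate_effects else matrix(0, n, p)

  items <- array(NA_real_, c(n, W, p),
                 dimnames = list(NULL, NULL, spec$items))
  items[, 1, ] <- with_substream(seed, "wave1", {
    eta <- sweep(cov_shift, 2, spec$wave1_intercepts, "+")
    matrix(rbinom(n * p, 1, plogis(eta)), n, p)
  })
  if (W > 1) with_substream(seed, "transitions", {
    for (w in seq_len(W - 1)) {
      eta <- items[, w, ] %*% spec$B + cov_shift
      eta <- sweep(eta, 2, spec$transition_intercepts, "+")
      items[, w + 1, ] <- matrix(rbinom(n * p, 1, plogis(eta)), n, p)
    }
  })

  symptom_panel(items, covariates = covs,
                item_labels = spec$items, wave_labels = seq_len(W))
}

#' @export
#' @param object a `ground_truth_spec`.
#' @param nsim number of subjects to simulate.
#' @param attrition apply the spec's attrition model after simulation?
#' @param ... unused.
#' @rdname simulate_panel
simulate.ground_truth_spec <- function(object, nsim = 1000, seed = object$seed,
                                       attrition = !is.null(object$attrition),
                                       ...) {
  panel <- simulate_panel(object, n_subjects = nsim, seed = seed)
  if (isTRUE(attrition)) panel <- apply_attrition(panel, object, seed = seed)
  panel
}

#' Impose monotone missing-at-random attrition on a fully observed panel
#'
#' From wave 2 onward each still-observed subject drops out with hazard
#' `plogis(a0 + a'z + b * sum score at the previous wave)`, where the sum
#' score reverses the spec's positively worded items. Once dropped, a
#' subject is missing at all later waves (monotone pattern). The retained
#' count per wave is attached as attribute `"retained"`.
#'
#' @param panel a fully observed [symptom_panel()].
#' @param spec a [ground_truth_spec()] whose `attrition` component is set.
#' @param seed integer seed (sub-stream "attrition" is derived from it).
#' @return A `symptom_panel` with monotone missingness.
#' @export
apply_attrition <- function(panel, spec, seed = spec$seed) {
  stopifnot(inherits(panel, "symptom_panel"), inherits(spec, "ground_truth_spec"))
  if (is.null(spec$attrition)) stopf("spec has no attrition model")
  if (anyNA(panel$items)) stopf("panel must be fully observed")
  am <- spec$attrition
  n <- panel$n_subjects; W <- panel$n_waves
  rev_idx <- match(spec$reverse_items, panel$item_labels)
  cov_term <- if (length(am$covariate_coefs))
    as.numeric(panel$covariates[, names(am$covariate_coefs), drop = FALSE] %*%
                 am$covariate_coefs) else rep(0, n)
  items <- panel$items
  with_substream(seed, "attrition", {
    present <- rep(TRUE, n)
    for (w in 2:W) {
      prev <- items[, w - 1, ]
      if (length(rev_idx)) prev[, rev_idx] <- 1 - prev[, rev_idx]
      score <- rowSums(prev)
      hz <- plogis(am$intercept + cov_term + am$sum_coef * score)
      drop_now <- present & (runif(n) < hz)
      present <- present & !drop_now
      items[!present, w, ] <- NA_real_
    }
  })
  out <- symptom_panel(items, covariates = panel$covariates,
                       subject_ids = panel$subject_ids,
                       item_labels = panel$item_labels,
                       wave_labels = panel$wave_labels)
  attr(out, "retained") <- retained_per_wave(out)
  out
}
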