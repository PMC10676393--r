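#' Sample skewness and excess kurtosis of a (binary) item
#'
#' Population-style central moments with divisor n, computed on observed
#' values: skewness `m3 / m2^1.5` and excess kurtosis `m4 / m2^2 - 3`. For
#' a Bernoulli(p) item these converge to `(1 - 2p) / sqrt(p(1-p))` and
#' `(1 - 6p(1-p)) / (p(1-p))`; no small-sample bias correction is applied,
#' which is numerically irrelevant at panel-study sample sizes.
#'
#' @param values numeric vector, missing values allowed.
#' @return Named numeric vector `c(skewness, kurtosis)` (excess kurtosis).
#' @export
#' @examples
#' x <- rep(c(1, 0), c(179, 821))
#' moment_stats(x)
moment_stats <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) stopf("need at least 3 observed values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stopf("undefined statistic: zero variance")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

#' Per-item, per-wave endorsement proportions
#'
#' @param panel a [symptom_panel()].
#' @return Data frame with columns `wave`, `item`, `endorsement` (proportion
#'   of 1s among observed values), `n_observed`.
#' @export
endorsement_table <- function(panel) {
  stopifnot(inherits(panel, "symptom_panel"))
  out <- expand.grid(item = panel$item_labels, wave = panel$wave_labels,
                     stringsAsFactors = FALSE)[, 2:1]
  out$endorsement <- NA_real_
  out$n_observed <- NA_integer_
  r <- 1L
  for (w in seq_len(panel$n_waves)) {
    m <- wave_matrix(panel, w)
    for (k in seq_len(panel$n_items)) {
      x <- m[, k]
      out$endorsement[r] <- mean(x, na.rm = TRUE)
      out$n_observed[r] <- sum(!is.na(x))
      r <- r + 1L
    }
  }
  out
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(sum score))`, computed
#' on complete cases.
#'
#' @param x subjects x items matrix (>= 2 items); rows with any missing
#'   value are dropped.
#' @return Alpha as a single number.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stopf("need at least 2 items")
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3) stopf("need at least 3 complete cases")
  total_var <- var(rowSums(x))
  if (total_var == 0) stopf("undefined alpha: zero total-score variance")
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / total_var)
}

#' Per-subject, per-wave sum scores
#'
#' Listed items are reverse-coded (`1 - x`) before summation, so the score
#' counts symptoms: 0 (none) to `n_items` (all). Sums are complete-case per
#' wave: a subject with any missing item at a wave gets a missing sum.
#'
#' @param panel a [symptom_panel()].
#' @param reverse_items labels of the positively worded items to reverse;
#'   defaults to `hyp`/`enj` when present.
#' @return subjects x waves numeric matrix.
#' @export
sum_scores <- function(panel,
                       reverse_items = intersect(c("hyp", "enj"),
                                                 panel$item_labels)) {
  stopifnot(inherits(panel, "symptom_panel"))
  rev_idx <- match(reverse_items, panel$item_labels)
  out <- matrix(NA_real_, panel$n_subjects, panel$n_waves)
  for (w in seq_len(panel$n_waves)) {
    m <- wave_matrix(panel, w)
    if (length(rev_idx)) m[, rev_idx] <- 1 - m[, rev_idx]
    out[, w] <- rowSums(m)  # NA whenever any item is missing
  }
  out
}

#' Item- and scale-level descriptives for every wave
#'
#' Endorsement, skewness and excess kurtosis per item and wave, plus
#' per-wave Cronbach's alpha for the full scale and for the depressed-affect
#' and somatic-complaints subscales (computed on symptom-coded items, i.e.
#' after reversing the positively worded items), and a sum-score summary.
#'
#' @param panel a [symptom_panel()].
#' @param reverse_items positively worded items, reversed for alphas and
#'   sum scores.
#' @param subscales named list of item-label vectors; the defaults apply
#'   when the panel carries the standard eight item labels.
#' @return List with data frames `items` (per wave x item) and `waves`
#'   (per wave).
#' @export
describe_panel <- function(panel,
                           reverse_items = intersect(c("hyp", "enj"),
                                                     panel$item_labels),
                           subscales = default_subscales(panel)) {
  stopifnot(inherits(panel, "symptom_panel"))
  items_df <- endorsement_table(panel)
  items_df$skewness <- NA_real_
  items_df$kurtosis <- NA_real_
  r <- 1L
  for (w in seq_len(panel$n_waves)) {
    m <- wave_matrix(panel, w)
    for (k in seq_len(panel$n_items)) {
      x <- m[, k]
      ms <- tryCatch(moment_stats(x), error = function(e) c(NA_real_, NA_real_))
      items_df$skewness[r] <- ms[1]
      items_df$kurtosis[r] <- ms[2]
      r <- r + 1L
    }
  }

  rev_idx <- match(reverse_items, panel$item_labels)
  scores <- sum_scores(panel, reverse_items)
  waves_df <- do.call(rbind, lapply(seq_len(panel$n_waves), function(w) {
    m <- wave_matrix(panel, w)
    if (length(rev_idx)) m[, rev_idx] <- 1 - m[, rev_idx]
    a_full <- tryCatch(cronbach_alpha(m), error = function(e) NA_real_)
    subs <- vapply(subscales, function(it) {
      tryCatch(cronbach_alpha(m[, it, drop = FALSE]),
               error = function(e) NA_real_)
    }, numeric(1))
    s <- scores[, w]
    data.frame(wave = panel$wave_labels[w], n_complete = sum(!is.na(s)),
               alpha_full = a_full,
               t(setNames(subs, paste0("alpha_", names(subscales)))),
               sum_mean = mean(s, na.rm = TRUE),
               sum_sd = sd(s, na.rm = TRUE),
               sum_min = suppressWarnings(min(s, na.rm = TRUE)),
               sum_max = suppressWarnings(max(s, na.rm = TRUE)))
  }))
  list(items = items_df, waves = waves_df)
}

default_subscales <- function(panel) {
  std <- list(affect = c("dep", "hyp", "lnl", "enj", "sad"),
              somatic = c("eft", "slp", "gng"))
  if (all(unlist(std) %in% panel$item_labels)) std else
    list(full = panel$item_labels)
}
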