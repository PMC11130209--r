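#' Cohen's kappa for two classifiers
#'
#' Chance-corrected agreement \eqn{(p_o - p_e) / (1 - p_e)} with expected
#' agreement from the marginal products.
#'
#' @param table Square contingency table (matrix) of group labels from two
#'   classifiers, same category order on both axes.
#' @return Kappa in \[-1, 1\]; NA (with a warning) when expected agreement
#'   is 1.
#' @export
cohens_kappa <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != ncol(table) || nrow(table) < 2)
    stop("need a square table with at least 2 categories")
  if (any(table < 0) || sum(table) == 0)
    stop("table cells must be nonnegative with a positive total")
  n <- sum(table)
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (pe == 1) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Stouffer's weighted p-value combination
#'
#' Converts one-sided p-values to normal quantiles
#' \eqn{Z_i = \Phi^{-1}(1 - p_i)} and combines them as
#' \eqn{Z = \sum w_i Z_i / \sqrt{\sum w_i^2}}; the combined p is the upper
#' tail of Z. Callers must orient the inputs one-sided in a common
#' direction. By convention weights are the square root of each study's
#' sample size.
#'
#' @param p_values One-sided p-values in (0, 1); boundary values are
#'   clipped to a machine-safe range with a warning.
#' @param weights Positive weights (default equal).
#' @return Combined p-value.
#' @export
stouffer_weighted <- function(p_values, weights = rep(1, length(p_values))) {
  if (length(p_values) != length(weights) || any(weights <= 0))
    stop("weights must be positive and match p_values in length")
  if (any(p_values <= 0 | p_values >= 1)) {
    warning("p-values at 0 or 1 clipped to a machine-safe range")
    p_values <- pmin(pmax(p_values, 1e-300), 1 - 1e-16)
  }
  z <- stats::qnorm(p_values, lower.tail = FALSE)
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  stats::pnorm(Z, lower.tail = FALSE)
}

#' Concordance index for survival risk scores
#'
#' Fraction of comparable sample pairs in which the higher risk score has
#' the earlier event. A pair is comparable when the earlier sample has an
#' event and the later sample's follow-up extends beyond it (censoring
#' respected); score ties count 1/2. Higher scores are taken to mean higher
#' risk.
#'
#' @param scores Numeric risk scores.
#' @param time,event Survival outcome.
#' @return C-index in \[0, 1\]; NA when no pair is comparable.
#' @export
concordance_index <- function(scores, time, event) {
  ok <- !is.na(scores) & !is.na(time) & !is.na(event)
  scores <- scores[ok]; time <- time[ok]; event <- event[ok]
  n <- length(scores)
  num <- 0; den <- 0
  for (i in which(event == 1)) {
    comparable <- (time > time[i]) | (time == time[i] & event == 0)
    comparable[i] <- FALSE
    den <- den + sum(comparable)
    num <- num + sum(scores[i] > scores[comparable]) +
      0.5 * sum(scores[i] == scores[comparable])
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Kaplan-Meier survival at a time point plus log-rank test
#'
#' Product-limit survival estimate per group evaluated at `eval_time`
#' (the step-function value at the largest event time at or before it) and
#' the two-sided log-rank test across groups.
#'
#' @param groups Factor of group labels (every level non-empty).
#' @param time,event Survival outcome.
#' @param eval_time Evaluation time in years.
#' @return List with `survival` (named per-group proportions), `logrank_p`,
#'   and `chisq`.
#' @export
km_logrank <- function(groups, time, event, eval_time) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("every group must contain samples")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  df <- data.frame(time = time, event = event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, times = eval_time, extend = TRUE)
  surv <- stats::setNames(sm$surv, sub("^group=", "", as.character(sm$strata)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd$chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  list(survival = surv, logrank_p = p, chisq = unname(sd$chisq))
}
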