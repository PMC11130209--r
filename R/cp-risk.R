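#' Univariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation (Efron tie handling) of a single
#' covariate; the Wald p-value is computed from beta/se. Monotone-likelihood
#' separation (diverging coefficient) is flagged and the coefficient capped
#' at |beta| = 10.
#'
#' @param x Numeric covariate, one value per sample (not constant).
#' @param time,event Survival outcome (>= 2 events required).
#' @param term Coefficient label.
#' @return A `cox_fit`: `terms` data frame (term, beta, se, hr, ci_low,
#'   ci_high, wald_p), `n`, `n_events`, `separation` flag.
#' @export
fit_univariable_cox <- function(x, time, event, term = "x") {
  ok <- !is.na(x) & !is.na(time) & !is.na(event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  if (sum(event) < 2) stop("need at least 2 events")
  if (stats::var(x) == 0) stop("covariate is constant")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "efron"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  separation <- !is.finite(beta) || abs(beta) > 10
  if (separation) beta <- sign(beta) * 10
  wald_p <- 2 * stats::pnorm(-abs(beta / se))
  terms <- data.frame(term = term, beta = beta, se = se, hr = exp(beta),
                      ci_low = exp(beta - 1.96 * se),
                      ci_high = exp(beta + 1.96 * se),
                      wald_p = wald_p, stringsAsFactors = FALSE)
  structure(list(terms = terms, n = length(x), n_events = sum(event),
                 separation = separation),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("cox_fit: n = %d, events = %d%s\n", x$n, x$n_events,
              if (isTRUE(x$separation)) " [separation: beta capped]" else ""))
  print(format(x$terms, digits = digits), row.names = FALSE)
  for (extra in c("trend_p", "schoenfeld_p", "logrank_p"))
    if (!is.null(x[[extra]]))
      cat(sprintf("  %s = %.3g\n", extra, x[[extra]]))
  invisible(x)
}

#' Fit a per-CP survival risk model on the discovery cohort
#'
#' Each gene of the CP is tested in a univariable Cox model on its z-scored
#' expression; genes with Wald p below the selection threshold are retained
#' with their discovery coefficients. Per-patient discovery risk scores (the
#' coefficient-weighted sum of z-scores) then yield the discovery cut-offs
#' (median and 33rd/66th percentiles) used for risk grouping everywhere
#' downstream. A CP in which no gene passes selection is flagged
#' non-informative.
#'
#' @param cp A CP entry (`list(cp_id, genes, ...)`) or a character vector of
#'   genes.
#' @param discovery A standardized, survival-truncated [expression_cohort].
#' @param p_select Wald selection threshold (default 0.05).
#' @return A `cp_model`: `cp_id`, selected `genes`, named `betas`,
#'   `cutoffs` (median/q33/q66 of discovery scores), `selection` table of
#'   all per-gene fits, `informative` flag, `endpoint`, `horizon`.
#' @export
build_cp_model <- function(cp, discovery, p_select = 0.05) {
  if (is.character(cp)) cp <- list(cp_id = "CP", genes = cp)
  stopifnot(inherits(discovery, "expression_cohort"))
  if (!discovery$standardized)
    stop("discovery cohort must be standardized (see zscore_genes)")
  horizon <- attr(discovery, "truncated_at")
  if (is.null(horizon))
    warning("discovery survival has not been truncated (see truncate_survival)")
  tumour <- !discovery$is_normal
  clin <- discovery$clinical[tumour, ]
  genes <- intersect(cp$genes, discovery$genes)
  rows <- lapply(genes, function(g) {
    fit <- tryCatch(
      fit_univariable_cox(discovery$values[g, tumour], clin$time,
                          clin$event, term = g),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cbind(fit$terms, separation = fit$separation)
  })
  selection <- do.call(rbind, rows)
  model <- list(cp_id = cp$cp_id, genes = character(0),
                betas = stats::setNames(numeric(0), character(0)),
                cutoffs = NULL, selection = selection,
                informative = FALSE,
                endpoint = unique(stats::na.omit(clin$endpoint))[1],
                horizon = horizon %||% NA_real_)
  class(model) <- "cp_model"
  if (is.null(selection) || !any(selection$wald_p < p_select)) {
    warning(sprintf("CP '%s' is non-informative: no gene passed selection (p < %g)",
                    cp$cp_id, p_select))
    return(model)
  }
  sel <- selection[selection$wald_p < p_select, ]
  model$genes <- sel$term
  model$betas <- stats::setNames(sel$beta, sel$term)
  model$informative <- TRUE
  scores <- score_patients(model, discovery)
  model$cutoffs <- c(median = stats::median(scores$score),
                     q33 = unname(stats::quantile(scores$score, 1 / 3)),
                     q66 = unname(stats::quantile(scores$score, 2 / 3)))
  model
}

#' @export
print.cp_model <- function(x, ...) {
  if (!x$informative) {
    cat(sprintf("cp_model '%s': non-informative (no selected genes)\n",
                x$cp_id))
    return(invisible(x))
  }
  cat(sprintf("cp_model '%s': %d selected gene(s), cutoffs median = %.3f, q33 = %.3f, q66 = %.3f\n",
              x$cp_id, length(x$genes), x$cutoffs["median"],
              x$cutoffs["q33"], x$cutoffs["q66"]))
  invisible(x)
}

#' @export
coef.cp_model <- function(object, ...) object$betas

#' @export
predict.cp_model <- function(object, cohort, ...) {
  score_patients(object, cohort)
}

#' Per-patient CP risk scores
#'
#' The score of sample s is \eqn{\sum_g \beta_g z_{g,s}} over the model's
#' selected genes. Selected genes absent from the cohort contribute 0 (mean
#' imputation on the z scale) with a coverage warning; a cohort missing all
#' selected genes is an error.
#'
#' @param model A fitted, informative `cp_model`.
#' @param cohort A standardized [expression_cohort] (tumour samples are
#'   scored).
#' @return A `risk_scores`: data frame `sample`, `score`; attributes
#'   `cutoffs`, `model_id`.
#' @export
score_patients <- function(model, cohort) {
  stopifnot(inherits(model, "cp_model"), inherits(cohort, "expression_cohort"))
  if (!model$informative) stop("model is non-informative; cannot score")
  if (!cohort$standardized) stop("cohort must be standardized before scoring")
  tumour <- which(!cohort$is_normal)
  present <- intersect(model$genes, cohort$genes)
  if (!length(present) && length(tumour))
    stop(sprintf("cohort '%s' has none of the %d genes of %s",
                 cohort$cohort_id, length(model$genes), model$cp_id))
  if (length(present) < length(model$genes))
    warning(sprintf("cohort '%s' covers %d/%d genes of %s; missing genes score 0",
                    cohort$cohort_id, length(present), length(model$genes),
                    model$cp_id))
  if (!length(tumour)) {
    scores <- numeric(0)
  } else {
    z <- cohort$values[present, tumour, drop = FALSE]
    scores <- as.numeric(crossprod(z, model$betas[present]))
  }
  res <- data.frame(sample = cohort$samples[tumour], score = scores,
                    stringsAsFactors = FALSE)
  structure(res, cutoffs = model$cutoffs, model_id = model$cp_id,
            class = c("risk_scores", "data.frame"))
}

#' Assign risk groups from discovery cut-offs
#'
#' Two-group mode: score above the median is high, otherwise low (the
#' cut-off value itself is low, keeping the discovery median split
#' balanced). Three-group mode: at or below q33 is low, above q66 is high,
#' otherwise intermediate.
#'
#' @param scores A `risk_scores` or numeric vector.
#' @param cutoffs Named vector with `median`, `q33`, `q66` (from a
#'   discovery-fitted model); defaults to the `cutoffs` attribute of
#'   `scores`.
#' @param n_groups 2 or 3.
#' @return Factor of group labels (`low < high` or
#'   `low < intermediate < high`); for `risk_scores` input, the input with a
#'   `group` column added.
#' @export
assign_risk_groups <- function(scores, cutoffs = attr(scores, "cutoffs"),
                               n_groups = 2) {
  if (is.null(cutoffs)) stop("no cutoffs supplied")
  vals <- if (is.data.frame(scores)) scores$score else scores
  if (n_groups == 2) {
    grp <- factor(ifelse(vals > cutoffs["median"], "high", "low"),
                  levels = c("low", "high"))
  } else if (n_groups == 3) {
    if (cutoffs["q33"] > cutoffs["q66"]) stop("q33 exceeds q66")
    grp <- factor(ifelse(vals <= cutoffs["q33"], "low",
                         ifelse(vals > cutoffs["q66"], "high",
                                "intermediate")),
                  levels = c("low", "intermediate", "high"))
  } else stop("n_groups must be 2 or 3")
  if (is.data.frame(scores)) {
    scores$group <- grp
    return(scores)
  }
  grp
}

# adjustment covariates per the standard clinical model: dichotomous age
# (> 55), T-stage factors, dichotomous nodal status, continuous purity
clinical_covariates <- function(clinical) {
  data.frame(age_old = factor(ifelse(clinical$age > 55, "old", "young"),
                              levels = c("young", "old")),
             t_stage = factor(clinical$t_stage,
                              levels = c("T1", "T2", "T3")),
             nodal = clinical$nodal,
             purity = clinical$purity)
}

#' Prognostic evaluation of risk groups
#'
#' Cox proportional-hazards fit of the risk-group indicator(s) (reference =
#' low), optionally adjusted for clinical covariates (dichotomous age > 55,
#' T-stage factors, dichotomous nodal status, continuous tumour purity). In
#' three-group mode a trend p-value from the ordinal group coding is added.
#' A Schoenfeld zero-slope test p-value (global) is attached. When a group
#' has zero events the Wald HR is suppressed and a log-rank p-value is
#' reported instead.
#'
#' @param groups Factor of risk-group labels (first level = reference).
#' @param outcomes Data frame with `time` and `event` (e.g. a cohort's
#'   `clinical` table).
#' @param covariates Optional data frame of clinical covariates (columns
#'   `age`, `t_stage`, `nodal`, `purity`), transformed internally.
#' @return A `cox_fit` with group terms (and covariate terms when
#'   adjusted), plus `trend_p`, `schoenfeld_p`, and `logrank_p` when the
#'   Wald fit is suppressed.
#' @export
evaluate_prognosis <- function(groups, outcomes, covariates = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 risk groups represented")
  df <- data.frame(time = outcomes$time, event = outcomes$event,
                   group = groups)
  df <- df[stats::complete.cases(df[c("time", "event")]), ]
  if (!is.null(covariates)) df <- cbind(df, clinical_covariates(covariates))
  ev_by_group <- tapply(df$event, df$group, sum)
  zero_event_group <- any(ev_by_group == 0)

  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  logrank_p <- stats::pchisq(sd$chisq, df = nlevels(groups) - 1,
                             lower.tail = FALSE)
  if (zero_event_group) {
    out <- structure(list(terms = NULL, n = nrow(df),
                          n_events = sum(df$event),
                          logrank_p = logrank_p,
                          note = "zero-event group: HR suppressed, log-rank reported"),
                     class = "cox_fit")
    return(out)
  }
  rhs <- paste(c("group", if (!is.null(covariates))
    c("age_old", "t_stage", "nodal", "purity")), collapse = " + ")
  fit <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", rhs)), data = df, ties = "efron")
  sm <- summary(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, "coef"],
                      se = sm$coefficients[, "se(coef)"],
                      hr = sm$coefficients[, "exp(coef)"],
                      ci_low = sm$conf.int[, "lower .95"],
                      ci_high = sm$conf.int[, "upper .95"],
                      wald_p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  out <- list(terms = terms, n = sm$n, n_events = sm$nevent)
  if (nlevels(groups) > 2) {
    df$group_ord <- as.numeric(df$group)
    rhs_tr <- sub("^group", "group_ord", rhs)
    tr <- survival::coxph(stats::as.formula(
      paste("survival::Surv(time, event) ~", rhs_tr)), data = df,
      ties = "efron")
    out$trend_p <- summary(tr)$coefficients["group_ord", "Pr(>|z|)"]
  }
  out$schoenfeld_p <- tryCatch(
    survival::cox.zph(fit)$table["GLOBAL", "p"],
    error = function(e) NA_real_)
  out$logrank_p <- logrank_p
  structure(out, class = "cox_fit")
}

#' Risk-group by treatment interaction test
#'
#' Cox model with risk group, chemotherapy, their interaction and optional
#' clinical covariates. Reports the interaction coefficient and p-value plus
#' stratified within-group treatment fits; a group-by-treatment cell with no
#' samples (or a stratum with < 2 events) has its stratified HR suppressed
#' and flagged.
#'
#' @param groups Factor of risk-group labels.
#' @param chemo 0/1 chemotherapy flags.
#' @param outcomes Data frame with `time` and `event`.
#' @param covariates Optional clinical covariate data frame (see
#'   [evaluate_prognosis()]).
#' @return List with `interaction` (a `cox_fit` restricted to the
#'   interaction term(s)), `model` (full term table), and `within` (named
#'   list of per-group treatment `cox_fit`s or NULL where suppressed).
#' @export
evaluate_interaction <- function(groups, chemo, outcomes,
                                 covariates = NULL) {
  groups <- droplevels(as.factor(groups))
  df <- data.frame(time = outcomes$time, event = outcomes$event,
                   group = groups, chemo = chemo)
  if (!is.null(covariates)) df <- cbind(df, clinical_covariates(covariates))
  df <- df[stats::complete.cases(df[c("time", "event", "chemo")]), ]
  if (!all(table(df$group) > 0)) stop("empty risk group")
  if (length(unique(df$chemo)) < 2)
    stop("both treatment arms must be present")
  rhs <- paste(c("group * chemo", if (!is.null(covariates))
    c("age_old", "t_stage", "nodal", "purity")), collapse = " + ")
  fit <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", rhs)), data = df, ties = "efron")
  sm <- summary(fit)
  terms <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, "coef"],
                      se = sm$coefficients[, "se(coef)"],
                      hr = sm$coefficients[, "exp(coef)"],
                      wald_p = sm$coefficients[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  inter <- terms[grepl(":chemo", terms$term), ]
  within <- lapply(levels(df$group), function(g) {
    sub <- df[df$group == g, ]
    cells <- table(factor(sub$chemo, levels = c(0, 1)))
    if (any(cells == 0) || sum(sub$event) < 2) return(NULL)
    tryCatch(fit_univariable_cox(sub$chemo, sub$time, sub$event,
                                 term = "chemo"),
             error = function(e) NULL)
  })
  names(within) <- levels(df$group)
  list(interaction = structure(list(terms = inter, n = sm$n,
                                    n_events = sm$nevent),
                               class = "cox_fit"),
       model = terms, within = within)
}
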