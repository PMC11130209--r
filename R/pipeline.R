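#' Prepare a cohort for survival modelling
#'
#' Convenience composition of the standard preprocessing: keep tumour
#' samples, truncate survival at the horizon, z-score genes within the
#' cohort (cohort-internal standardization; validation cohorts are
#' processed independently of discovery).
#'
#' @param cohort An [expression_cohort] (may contain normals; they are
#'   dropped).
#' @param horizon Survival truncation horizon in years (default 10).
#' @return A standardized, truncated tumour-only [expression_cohort].
#' @export
prepare_cohort <- function(cohort, horizon = 10) {
  tumour <- split_tumour_normal(cohort)$tumour
  if (is.null(tumour)) stop("cohort has no tumour samples")
  zscore_genes(truncate_survival(tumour, horizon))
}

#' Combined-validation prognostic evaluation of CP models
#'
#' Applies each informative CP model to every validation cohort, assigns
#' risk groups with the model's discovery-derived cut-offs, pools the risk
#' groups across validation cohorts, and tests the pooled groups for
#' association with outcome in a Cox model (Wald test; log-rank fallback
#' when a pooled group has no events).
#'
#' @param models List of `cp_model` objects.
#' @param cohorts List of prepared (standardized, truncated) validation
#'   [expression_cohort] objects.
#' @param n_groups 2 or 3 risk groups.
#' @return Data frame with one row per informative CP: `cp_id`, `n`,
#'   `n_events`, `beta`, `hr`, `wald_p`, `logrank_p` (`beta`/`hr`/`wald_p`
#'   are NA when the Wald fit is suppressed).
#' @export
evaluate_cp_validation <- function(models, cohorts, n_groups = 2) {
  usable <- Filter(function(m) isTRUE(m$informative), models)
  if (!length(usable)) stop("no informative CP models to evaluate")
  rows <- lapply(usable, function(m) {
    groups <- character(0); time <- numeric(0); event <- integer(0)
    for (co in cohorts) {
      sc <- assign_risk_groups(score_patients(m, co), n_groups = n_groups)
      clin <- co$clinical[match(sc$sample, co$samples), ]
      groups <- c(groups, as.character(sc$group))
      time <- c(time, clin$time); event <- c(event, clin$event)
    }
    lv <- if (n_groups == 2) c("low", "high")
          else c("low", "intermediate", "high")
    groups <- factor(groups, levels = lv)
    fit <- tryCatch(
      evaluate_prognosis(droplevels(groups),
                         data.frame(time = time, event = event)),
      error = function(e) NULL)
    hi <- if (!is.null(fit$terms))
      fit$terms[fit$terms$term == "grouphigh", ] else NULL
    data.frame(cp_id = m$cp_id,
               n = fit$n %||% NA_integer_,
               n_events = fit$n_events %||% NA_integer_,
               beta = if (!is.null(hi) && nrow(hi)) hi$beta else NA_real_,
               hr = if (!is.null(hi) && nrow(hi)) hi$hr else NA_real_,
               wald_p = if (!is.null(hi) && nrow(hi)) hi$wald_p else NA_real_,
               logrank_p = fit$logrank_p %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Permutation importance of CP features in a PSILC model
#'
#' Concordance-based permutation importance: the drop in concordance index
#' of the forest's predicted risk score when one feature column is permuted,
#' averaged over `n_perm` permutations.
#'
#' @param model A fitted `psilc` model.
#' @param features Samples x CP matrix matching the model's feature order.
#' @param outcomes Data frame with `time` and `event`.
#' @param n_perm Permutations per feature (default 3).
#' @param seed Integer seed.
#' @return Named numeric vector of importance (concordance drop) per CP.
#' @export
psilc_importance <- function(model, features, outcomes, n_perm = 3,
                             seed = 1L) {
  base_score <- rsf_mortality(model$forest, features)
  base_c <- concordance_index(base_score, outcomes$time, outcomes$event)
  with_seed(seed, {
    imp <- vapply(seq_len(ncol(features)), function(j) {
      drops <- vapply(seq_len(n_perm), function(r) {
        perm <- features
        perm[, j] <- perm[sample(nrow(perm)), j]
        base_c - concordance_index(rsf_mortality(model$forest, perm),
                                   outcomes$time, outcomes$event)
      }, 0)
      mean(drops)
    }, 0)
    stats::setNames(imp, colnames(features))
  })
}
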