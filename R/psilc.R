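#' Sample-by-CP feature matrix
#'
#' One column per informative CP model, each the per-patient risk score of
#' that CP ([score_patients()]); columns are CP-id sorted and the order is
#' recorded so training and prediction stay aligned. Non-informative CP
#' models are excluded consistently.
#'
#' @param cp_models List of `cp_model` objects.
#' @param cohort A standardized [expression_cohort].
#' @return Numeric samples x CP matrix with attribute `feature_order`.
#' @export
build_feature_matrix <- function(cp_models, cohort) {
  usable <- Filter(function(m) isTRUE(m$informative), cp_models)
  if (!length(usable)) stop("no usable (informative) CP models")
  ids <- vapply(usable, `[[`, "", "cp_id")
  usable <- usable[order(ids)]
  ids <- sort(ids)
  tumour_samples <- cohort$samples[!cohort$is_normal]
  cols <- lapply(usable, function(m) {
    if (!length(intersect(m$genes, cohort$genes))) {
      warning(sprintf("cohort '%s' has none of the genes of %s; its column is 0",
                      cohort$cohort_id, m$cp_id))
      return(rep(0, length(tumour_samples)))
    }
    score_patients(m, cohort)$score
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- ids
  rownames(mat) <- tumour_samples
  structure(mat, feature_order = ids)
}

#' Default hyperparameter sweep grid for the survival forest
#'
#' @param ntrees Tree counts (default 501 to 1001, step 100).
#' @param nodesize Minimal node sizes (default 10 to 15).
#' @param mtry Features tried per split (default 5 to 10).
#' @return Data frame of all combinations (216 rows for the defaults).
#' @export
psilc_grid <- function(ntrees = seq(501, 1001, by = 100),
                       nodesize = 10:15, mtry = 5:10) {
  expand.grid(ntrees = ntrees, nodesize = nodesize, mtry = mtry,
              KEEP.OUT.ATTRS = FALSE)
}

rsf_fit <- function(features, time, event, ntrees, nodesize, mtry, seed) {
  df <- data.frame(time = time, event = event, features,
                   check.names = FALSE)
  ranger::ranger(survival::Surv(time, event) ~ ., data = df,
                 num.trees = ntrees, min.node.size = nodesize,
                 mtry = min(mtry, ncol(features)), seed = seed,
                 num.threads = 1, splitrule = "logrank")
}

# ensemble mortality: cumulative hazard summed over the event-time grid
rsf_mortality <- function(forest, features) {
  p <- stats::predict(forest, data = data.frame(features,
                                                check.names = FALSE),
                      num.threads = 1)
  stats::setNames(rowSums(p$chf), rownames(features))
}

#' Train the multivariable pathway signature (survival forest over CP scores)
#'
#' The discovery cohort's CP-score feature matrix is split into 66% training
#' and 33% internal validation (stratified by event indicator). For every
#' hyperparameter combination a random survival forest (log-rank splitting,
#' ensemble mortality as risk score) is fitted on the training split; its
#' out-of-bag error (1 - OOB concordance) and the Cox coefficient of its
#' predicted score on the held-out third are recorded. The winner is the
#' candidate with the highest internal coefficient among the lowest decile
#' of OOB error. Discovery cut-offs (median/tertiles) are computed from the
#' selected forest's predicted scores on the full discovery cohort.
#'
#' @param features Samples x CP matrix from [build_feature_matrix()].
#' @param outcomes Data frame with `time` and `event` aligned to the rows of
#'   `features`.
#' @param split_fraction Training share (default 0.66).
#' @param grid Hyperparameter sweep, see [psilc_grid()].
#' @param seed Integer seed controlling the split and every forest.
#' @return A `psilc` model: `forest`, `hyperparameters`, `candidates`
#'   (sweep table with `oob_error` and `internal_beta`), `feature_order`,
#'   `cutoffs`, `discovery_scores`, `split` bookkeeping.
#' @export
train_psilc <- function(features, outcomes, split_fraction = 0.66,
                        grid = psilc_grid(), seed = 1L) {
  stopifnot(is.matrix(features))
  if (!nrow(grid)) stop("empty hyperparameter grid")
  n <- nrow(features)
  if (n < 30) stop("need at least 30 samples to train")
  time <- outcomes$time; event <- outcomes$event
  ok <- !is.na(time) & !is.na(event)
  features <- features[ok, , drop = FALSE]
  time <- time[ok]; event <- event[ok]; n <- nrow(features)
  if (sum(event) < 5) stop("need at least 5 events to train")

  idx_train <- with_seed(seed, {
    tr <- integer(0)
    for (e in unique(event)) {
      grp <- which(event == e)
      tr <- c(tr, sample(grp, round(split_fraction * length(grp))))
    }
    sort(tr)
  })
  idx_val <- setdiff(seq_len(n), idx_train)

  cand <- grid
  cand$oob_error <- NA_real_
  cand$internal_beta <- NA_real_
  for (i in seq_len(nrow(cand))) {
    rf <- rsf_fit(features[idx_train, , drop = FALSE], time[idx_train],
                  event[idx_train], cand$ntrees[i], cand$nodesize[i],
                  cand$mtry[i], seed = seed)
    cand$oob_error[i] <- rf$prediction.error
    val_score <- rsf_mortality(rf, features[idx_val, , drop = FALSE])
    cand$internal_beta[i] <- tryCatch(
      unname(stats::coef(survival::coxph(
        survival::Surv(time[idx_val], event[idx_val]) ~ scale(val_score),
        ties = "efron"))),
      error = function(e) NA_real_)
  }
  top <- order(cand$oob_error)[seq_len(max(1L, ceiling(nrow(cand) / 10)))]
  best <- top[which.max(replace(cand$internal_beta[top],
                                is.na(cand$internal_beta[top]), -Inf))]

  forest <- rsf_fit(features[idx_train, , drop = FALSE], time[idx_train],
                    event[idx_train], cand$ntrees[best], cand$nodesize[best],
                    cand$mtry[best], seed = seed)
  disc_scores <- rsf_mortality(forest, features)
  cutoffs <- c(median = stats::median(disc_scores),
               q33 = unname(stats::quantile(disc_scores, 1 / 3)),
               q66 = unname(stats::quantile(disc_scores, 2 / 3)))
  structure(list(forest = forest,
                 hyperparameters = cand[best, c("ntrees", "nodesize", "mtry")],
                 candidates = cand,
                 feature_order = colnames(features),
                 cutoffs = cutoffs,
                 discovery_scores = disc_scores,
                 split = list(seed = seed, train = idx_train,
                              validation = idx_val)),
            class = "psilc")
}

#' @export
print.psilc <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf("psilc survival-forest model: ntrees = %d, nodesize = %d, mtry = %d\n",
              hp$ntrees, hp$nodesize, hp$mtry))
  cat(sprintf("  selected from %d candidates; OOB error %.3f, internal beta %.3f\n",
              nrow(x$candidates),
              x$candidates$oob_error[rownames(x$candidates) == rownames(hp)],
              x$candidates$internal_beta[rownames(x$candidates) == rownames(hp)]))
  cat(sprintf("  %d CP features; cutoffs median = %.3f, q33 = %.3f, q66 = %.3f\n",
              length(x$feature_order), x$cutoffs["median"], x$cutoffs["q33"],
              x$cutoffs["q66"]))
  invisible(x)
}

#' @export
summary.psilc <- function(object, ...) {
  print(object)
  cand <- object$candidates[order(object$candidates$oob_error), ]
  cat("\nTop 5 sweep candidates by OOB error:\n")
  print(utils::head(cand, 5), row.names = FALSE)
  invisible(object$candidates)
}

#' Predict risk scores and groups from a fitted PSILC model
#'
#' @param object A `psilc` model.
#' @param features Samples x CP matrix whose columns match the model's
#'   stored feature order exactly.
#' @param n_groups 2 or 3 risk groups (discovery-derived cut-offs).
#' @param ... Unused.
#' @return A `risk_scores` data frame with `sample`, `score`, `group`.
#' @export
predict.psilc <- function(object, features, n_groups = 2, ...) {
  stopifnot(is.matrix(features))
  if (!identical(colnames(features), object$feature_order)) {
    extra <- setdiff(colnames(features), object$feature_order)
    miss <- setdiff(object$feature_order, colnames(features))
    stop(sprintf(
      "feature columns do not match the model's feature order%s%s%s",
      if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", "))
      else "",
      if (length(extra)) paste0("; unexpected: ",
                                paste(extra, collapse = ", ")) else "",
      if (!length(miss) && !length(extra)) " (column order differs)" else ""))
  }
  score <- rsf_mortality(object$forest, features)
  res <- data.frame(sample = rownames(features) %||%
                      as.character(seq_len(nrow(features))),
                    score = unname(score), stringsAsFactors = FALSE)
  res <- structure(res, cutoffs = object$cutoffs, model_id = "PSILC",
                   class = c("risk_scores", "data.frame"))
  assign_risk_groups(res, n_groups = n_groups)
}
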