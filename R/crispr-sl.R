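#' Classify cell lines by PSILC score
#'
#' Scores each cell line with the fitted PSILC model (CP feature matrix
#' built from the line panel's standardized expression) and splits at the
#' discovery-derived cut-off: score strictly above the cut-off is high,
#' otherwise low — the same boundary rule as two-group risk assignment in
#' patients.
#'
#' @param model A fitted `psilc` model.
#' @param cp_models The CP models used to build its feature matrix.
#' @param line_expression A standardized [expression_cohort] of cell lines.
#' @param cutoff Score threshold (default: the model's discovery median).
#' @return Data frame with `line`, `score`, `group` (`high`/`low`).
#' @export
classify_lines <- function(model, cp_models, line_expression,
                           cutoff = model$cutoffs[["median"]]) {
  stopifnot(inherits(model, "psilc"))
  if (length(line_expression$samples) < 6)
    warning("fewer than 6 cell lines: downstream group tests may be underpowered")
  features <- build_feature_matrix(cp_models, line_expression)
  scores <- predict(model, features, n_groups = 2)
  data.frame(line = scores$sample, score = scores$score,
             group = ifelse(scores$score > cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Contextual synthetic-lethality screen on CRISPR gene-effect scores
#'
#' Per gene, compares gene-effect (GE) scores between high- and low-score
#' cell-line groups. A gene passes the selectivity filter iff its mean GE in
#' the high group is below `high_mean_max`, its mean in the low group is
#' above `low_mean_min`, and the high mean is below the low mean (strict
#' inequalities). A one-sided Welch t-test (alternative: high mean < low
#' mean) is computed when both groups have at least `min_group` lines;
#' otherwise p is left undefined (never 1). Commonly essential genes
#' (full-panel median GE < -1) are annotated post-hoc and excluded from the
#' significant list by default. With `exclude_erbb2_altered`, lines whose
#' ERBB2 status is amplified or mutant are dropped before grouping.
#'
#' @param screen A `ge_screen`.
#' @param exclude_erbb2_altered Drop ERBB2-altered (amplified or mutant)
#'   lines first.
#' @param high_mean_max,low_mean_min GE-score selectivity thresholds
#'   (defaults -0.5 and -0.75).
#' @param min_group Minimum lines per group for the Welch test (default 3).
#' @param p_max Significance threshold (default 0.05).
#' @param exclude_essential Exclude essential-flagged genes from the
#'   significant set (default TRUE).
#' @return Data frame (class `sl_result`) with `gene`, `mean_high`,
#'   `mean_low`, `delta`, `p`, `passes_filter`, `essential`, `significant`,
#'   `n_high`, `n_low`; attribute `significant` lists significant genes.
#' @export
sl_screen <- function(screen, exclude_erbb2_altered = FALSE,
                      high_mean_max = -0.5, low_mean_min = -0.75,
                      min_group = 3, p_max = 0.05,
                      exclude_essential = TRUE) {
  stopifnot(inherits(screen, "ge_screen"))
  keep <- rep(TRUE, ncol(screen$values))
  if (exclude_erbb2_altered)
    keep <- screen$lines$erbb2_status == "wildtype"
  vals <- screen$values[, keep, drop = FALSE]
  grp <- screen$lines$psilc_group[keep]
  hi <- vals[, grp == "high", drop = FALSE]
  lo <- vals[, grp == "low", drop = FALSE]
  n1 <- ncol(hi); n2 <- ncol(lo)
  mh <- rowMeans(hi); ml <- rowMeans(lo)
  passes <- mh < high_mean_max & ml > low_mean_min & mh < ml

  if (n1 >= min_group && n2 >= min_group) {
    v1 <- row_vars(hi); v2 <- row_vars(lo)
    se2 <- v1 / n1 + v2 / n2
    t_stat <- (mh - ml) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- stats::pt(t_stat, df = df)
    # zero-variance degenerate case: the direction decides
    degen <- se2 == 0
    p[degen] <- ifelse(mh[degen] < ml[degen], 0, 1)
  } else {
    p <- rep(NA_real_, nrow(vals))
  }
  sig <- passes & !is.na(p) & p < p_max
  if (exclude_essential) sig <- sig & !screen$essential
  res <- data.frame(gene = rownames(vals), mean_high = mh, mean_low = ml,
                    delta = mh - ml, p = p, passes_filter = passes,
                    essential = unname(screen$essential),
                    significant = sig, n_high = n1, n_low = n2,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("sl_result", "data.frame")
  attr(res, "significant") <- res$gene[sig]
  res
}

#' Overlap of two synthetic-lethality analyses
#'
#' Fisher exact (hypergeometric upper-tail) p-value for the overlap of the
#' two significant-gene lists given the shared tested universe, plus the
#' Spearman correlation of the two mean-difference (delta) vectors over the
#' overlap genes (undefined when fewer than 3 overlap).
#'
#' @param res_all,res_wt `sl_result` objects from the two analyses (e.g.
#'   full panel vs ERBB2-wildtype panel).
#' @param universe Genes tested in both analyses.
#' @return An `overlap_result`: `n_list_all`, `n_list_wt`, `n_overlap`,
#'   `n_universe`, `fisher_p`, `spearman_rho`, `overlap_genes`.
#' @export
overlap_analysis <- function(res_all, res_wt, universe) {
  N <- length(unique(universe))
  if (N < max(length(attr(res_all, "significant")),
              length(attr(res_wt, "significant"))))
    stop("universe smaller than a significant list")
  a <- intersect(attr(res_all, "significant"), universe)
  b <- intersect(attr(res_wt, "significant"), universe)
  ov <- intersect(a, b)
  fisher_p <- stats::phyper(length(ov) - 1, length(a), N - length(a),
                            length(b), lower.tail = FALSE)
  rho <- NA_real_
  if (length(ov) >= 3) {
    d1 <- res_all$delta[match(ov, res_all$gene)]
    d2 <- res_wt$delta[match(ov, res_wt$gene)]
    rho <- stats::cor(d1, d2, method = "spearman")
  }
  structure(list(n_list_all = length(a), n_list_wt = length(b),
                 n_overlap = length(ov), n_universe = N,
                 fisher_p = fisher_p, spearman_rho = rho,
                 overlap_genes = sort(ov)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: %d / %d vs %d genes overlap (universe %d), Fisher p = %.3g, Spearman rho = %s\n",
              x$n_overlap, x$n_list_all, x$n_list_wt, x$n_universe,
              x$fisher_p,
              if (is.na(x$spearman_rho)) "NA (overlap < 3)"
              else sprintf("%.3f", x$spearman_rho)))
  invisible(x)
}
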