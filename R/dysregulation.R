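#' Differentially expressed genes between tumour and normal
#'
#' Per-gene two-group test on log2 values with empirical-Bayes variance
#' moderation: gene-wise pooled variances are shrunk towards a common prior
#' estimated by moment matching on the log scale (a scaled inverse
#' chi-square prior whose degrees of freedom and scale are obtained from the
#' mean and excess variance of log sample variances), and the moderated t
#' statistic gains the prior degrees of freedom. A plain Welch t-test is
#' available as a fallback. P-values are Benjamini-Hochberg adjusted across
#' all tested genes; the significant set requires both a fold-change and an
#' FDR threshold.
#'
#' @param tumour,normal Unstandardized [expression_cohort] objects with the
#'   same genes and >= 2 samples each.
#' @param abs_log2fc_min Minimum absolute log2 fold change (default 1).
#' @param q_max FDR threshold (default 0.001).
#' @param method `"moderated"` (default) or `"welch"`.
#' @return Data frame (class `de_result`) with columns `gene`,
#'   `mean_tumour`, `mean_normal`, `log2fc`, `t_statistic`, `p`, `q`,
#'   `significant`; attribute `significant` holds the significant gene set
#'   and `prior` the estimated (df0, s02).
#' @export
differential_expression <- function(tumour, normal, abs_log2fc_min = 1,
                                    q_max = 0.001,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(tumour, "expression_cohort"),
            inherits(normal, "expression_cohort"))
  if (tumour$standardized || normal$standardized)
    stop("differential expression requires unstandardized cohorts")
  if (!identical(tumour$genes, normal$genes))
    stop("cohorts must have identical gene lists")
  x <- tumour$values; y <- normal$values
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")

  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- row_vars(x); v2 <- row_vars(y)
  lfc <- m1 - m2
  prior <- c(df0 = Inf, s02 = NA_real_)

  if (method == "moderated") {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    fit <- squeeze_var(s2, d)
    prior <- c(df0 = fit$df0, s02 = fit$s02)
    tt <- lfc / sqrt(fit$var_post * (1 / n1 + 1 / n2))
    df <- d + fit$df0
    p <- 2 * stats::pt(-abs(tt), df = df)
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- lfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df = df)
  }
  q <- stats::p.adjust(p, method = "BH")
  sig <- abs(lfc) > abs_log2fc_min & q < q_max
  res <- data.frame(gene = tumour$genes, mean_tumour = m1, mean_normal = m2,
                    log2fc = lfc, t_statistic = tt, p = p, q = q,
                    significant = sig, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  attr(res, "significant") <- res$gene[sig]
  attr(res, "prior") <- prior
  res
}

# EB shrinkage of gene-wise variances: scaled inverse chi-square prior
# fitted by matching moments of log(s^2) (digamma/trigamma identities).
squeeze_var <- function(s2, df) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(df0 / 2) - log(df0 / 2))
    var_post <- (df0 * s02 + df * s2) / (df0 + df)
  } else {
    df0 <- Inf
    s02 <- exp(emean)
    var_post <- rep(s02, length(s2))
  }
  list(df0 = df0, s02 = s02, var_post = var_post)
}

# Newton solve of trigamma(x) = y
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Differentially variable genes between tumour and normal
#'
#' Per-gene two-sided F-test on the ratio of sample variances
#' (tumour / normal), BH-adjusted. The significant set additionally requires
#' the tumour SD to exceed both the normal SD and an absolute floor, so
#' selection is directional even though the test is two-sided. Genes with
#' zero variance in either group are skipped (flagged, not tested).
#'
#' @param tumour,normal Unstandardized [expression_cohort] objects with the
#'   same genes.
#' @param sigma_min Minimum tumour SD, log2 units (default 0.5).
#' @param q_max FDR threshold (default 1e-15).
#' @return Data frame (class `dv_result`) with columns `gene`, `sigma_ilc`,
#'   `sigma_normal`, `f_statistic`, `p`, `q`, `skipped`, `significant`;
#'   attribute `significant` holds the significant gene set.
#' @export
differential_variance <- function(tumour, normal, sigma_min = 0.5,
                                  q_max = 1e-15) {
  stopifnot(inherits(tumour, "expression_cohort"),
            inherits(normal, "expression_cohort"))
  if (tumour$standardized || normal$standardized)
    stop("differential variance requires unstandardized cohorts")
  if (!identical(tumour$genes, normal$genes))
    stop("cohorts must have identical gene lists")
  n1 <- ncol(tumour$values); n2 <- ncol(normal$values)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  v1 <- row_vars(tumour$values); v2 <- row_vars(normal$values)
  skipped <- v1 == 0 | v2 == 0
  f <- ifelse(skipped, NA_real_, v1 / v2)
  lower <- stats::pf(f, n1 - 1, n2 - 1)
  p <- pmin(1, 2 * pmin(lower, 1 - lower))
  p[skipped] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[!skipped] <- stats::p.adjust(p[!skipped], method = "BH")
  s1 <- sqrt(v1); s2 <- sqrt(v2)
  sig <- !skipped & s1 > s2 & s1 > sigma_min & q < q_max
  res <- data.frame(gene = tumour$genes, sigma_ilc = s1, sigma_normal = s2,
                    f_statistic = f, p = p, q = q, skipped = skipped,
                    significant = sig, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(res) <- c("dv_result", "data.frame")
  attr(res, "significant") <- res$gene[sig]
  res
}

#' Union of differentially expressed and differentially variable genes
#'
#' @param de_set,dv_set Character vectors of significant genes.
#' @return Lexicographically sorted union with attribute `sizes`
#'   (`n_de`, `n_dv`, `overlap`, `union`).
#' @export
dysregulated_union <- function(de_set, dv_set) {
  u <- sort(union(de_set, dv_set))
  structure(u, sizes = c(n_de = length(unique(de_set)),
                         n_dv = length(unique(dv_set)),
                         overlap = length(intersect(de_set, dv_set)),
                         union = length(u)))
}
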