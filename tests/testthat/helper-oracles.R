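# Independent oracles used by the tests: each computes its quantity from
# the definition, without calling the code path it checks.

# Efron partial log-likelihood for a single covariate
efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + beta * sum(x[D])
    sumR <- sum(exp(beta * x[R]))
    sumD <- sum(exp(beta * x[D]))
    for (l in 0:(d - 1)) ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

grid_search_cox_beta <- function(x, time, event, lo = -5, hi = 5,
                                 step = 5e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, efron_loglik, 0, x = x, time = time, event = event)
  grid[which.max(ll)]
}

# average silhouette width from the definition (singletons contribute 0)
silhouette_by_definition <- function(labels, d) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(lab)
      mean(d[i, labels == lab]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Kaplan-Meier product-limit estimate at a time point
km_by_definition <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# two-group log-rank chi-square from hypergeometric increments
logrank_by_definition <- function(time, event, group) {
  g1 <- unique(group)[1]
  O1 <- E1 <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- sum(time >= t)
    at1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * at1 / at_risk
    if (at_risk > 1)
      V <- V + d * (at1 / at_risk) * (1 - at1 / at_risk) *
        (at_risk - d) / (at_risk - 1)
  }
  (O1 - E1)^2 / V
}

# hypergeometric upper tail by exhaustive enumeration of query draws
ora_p_by_enumeration <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inside <- colSums(draws <= K)   # pathway = first K universe elements
  mean(inside >= k)
}

# build a tumour/normal cohort pair directly from Gaussian matrices
make_pair <- function(n_genes, n_t, n_n, mu_t = 7, mu_n = 7, sd_t = 0.5,
                      sd_n = 0.5, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  tum <- matrix(rnorm(n_genes * n_t, mu_t, sd_t), n_genes,
                dimnames = list(genes, sprintf("T%03d", seq_len(n_t))))
  nor <- matrix(rnorm(n_genes * n_n, mu_n, sd_n), n_genes,
                dimnames = list(genes, sprintf("N%03d", seq_len(n_n))))
  list(tumour = expression_cohort(tum, cohort_id = "t"),
       normal = expression_cohort(nor, cohort_id = "n"))
}

# standardized cohort with survival outcomes from given z matrix
make_surv_cohort <- function(z, time, event, id = "c") {
  clin <- data.frame(sample = colnames(z), time = time, event = event,
                     stringsAsFactors = FALSE)
  expression_cohort(z, clinical = clin, cohort_id = id,
                    standardized = TRUE)
}

# a tiny fitted CP-model object built by hand (for composition tests)
manual_cp_model <- function(cp_id, betas, cutoffs = c(median = 0, q33 = -0.5,
                                                      q66 = 0.5)) {
  structure(list(cp_id = cp_id, genes = names(betas), betas = betas,
                 cutoffs = cutoffs, selection = NULL, informative = TRUE,
                 endpoint = "OS", horizon = 10),
            class = "cp_model")
}
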