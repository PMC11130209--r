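test_that("univariable Cox matches a dense grid-search partial-likelihood oracle", {
  # non-separable toys: mixed covariate/event patterns
  toys <- list(
    list(time = 1:8, event = rep(1, 8), x = c(1, 0, 1, 0, 0, 1, 0, 1)),
    list(time = c(2, 4, 4, 6, 7, 9, 11, 12),
         event = c(1, 1, 0, 1, 1, 0, 1, 0),
         x = c(0.5, 1.2, -0.3, 0.1, -1, 0.7, -0.2, 0.4)),
    list(time = c(1, 2, 3, 4, 5, 6), event = c(1, 0, 1, 1, 0, 1),
         x = c(1, 1, 0, 1, 0, 0)))
  for (toy in toys) {
    fit <- fit_univariable_cox(toy$x, toy$time, toy$event)
    oracle <- grid_search_cox_beta(toy$x, toy$time, toy$event)
    expect_lt(abs(fit$terms$beta - oracle), 1e-3)
  }

  # covariate positively ordered with hazard: positive coefficient
  set.seed(1)
  x <- rnorm(80)
  tm <- rexp(80, 0.2 * exp(x))
  fit <- fit_univariable_cox(x, tm, rep(1, 80))
  expect_gt(fit$terms$beta, 0)
  expect_true(fit$terms$ci_low <= fit$terms$hr &
                fit$terms$hr <= fit$terms$ci_high)

  expect_error(fit_univariable_cox(rep(1, 6), 1:6, rep(1, 6)), "constant")
  expect_error(fit_univariable_cox(rnorm(6), 1:6, rep(0, 6)), "2 events")

  # monotone likelihood (all early events share one covariate level):
  # separation is flagged and the coefficient capped
  fit <- fit_univariable_cox(c(1, 1, 1, 0, 0, 0), 1:6, rep(1, 6))
  expect_true(fit$separation)
  expect_equal(abs(fit$terms$beta), 10)
})

test_that("CP gene selection is calibrated on noise and powered on planted signal", {
  n <- 150; n_genes <- 20
  frac <- numeric(50)
  for (seed in 1:50) {
    set.seed(seed)
    z <- matrix(rnorm(n_genes * n), n_genes,
                dimnames = list(sprintf("g%02d", 1:n_genes),
                                sprintf("s%03d", 1:n)))
    tm <- pmin(rexp(n, 0.15), 10)
    ev <- as.integer(tm < 10)
    co <- make_surv_cohort(z, tm, ev)
    attr(co, "truncated_at") <- 10
    m <- suppressWarnings(build_cp_model(list(cp_id = "CP", genes = rownames(z)), co))
    frac[seed] <- length(m$genes) / n_genes
  }
  expect_gt(mean(frac), 0.02)
  expect_lt(mean(frac), 0.08)

  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    z <- matrix(rnorm(10 * n), 10,
                dimnames = list(sprintf("g%02d", 1:10),
                                sprintf("s%03d", 1:n)))
    tm <- pmin(rexp(n, 0.1 * exp(z[1, ])), 10)
    ev <- as.integer(tm < 10)
    co <- make_surv_cohort(z, tm, ev)
    attr(co, "truncated_at") <- 10
    m <- suppressWarnings(build_cp_model(list(cp_id = "CP", genes = rownames(z)), co))
    hits <- hits + ("g01" %in% m$genes)
  }
  expect_gte(hits, 45)

  # no selected genes: non-informative flag with a warning
  set.seed(3)
  z <- matrix(rnorm(3 * 60), 3, dimnames = list(c("a", "b", "c"),
                                                sprintf("s%02d", 1:60)))
  co <- make_surv_cohort(z, sample(60), rep(c(1, 0), 30))
  attr(co, "truncated_at") <- 10
  expect_warning(
    m <- build_cp_model(list(cp_id = "CPX", genes = c("a", "b", "c")), co,
                        p_select = 1e-12),
    "non-informative")
  expect_false(m$informative)
  expect_error(score_patients(m, co), "non-informative")
})

test_that("risk scoring is the coefficient-weighted sum of z-scores", {
  m <- manual_cp_model("CP01", c(gA = 0.5, gB = -1.0))
  z <- matrix(c(1.0, 0.5, 2, 1, -1, 0.25), 2, 3,
              dimnames = list(c("gA", "gB"), c("p1", "p2", "p3")))
  co <- expression_cohort(z, standardized = TRUE)
  sc <- score_patients(m, co)
  expect_equal(sc$score, c(0.5 * 1 - 1 * 0.5, 0.5 * 2 - 1 * 1,
                           0.5 * -1 - 1 * 0.25))
  expect_equal(sc$score[1], 0)

  # invariant to gene ordering
  m_rev <- manual_cp_model("CP01", c(gB = -1.0, gA = 0.5))
  expect_equal(score_patients(m_rev, co)$score, sc$score)

  # linearity in the expression profile
  z2 <- z * 2
  co2 <- expression_cohort(z2, standardized = TRUE)
  expect_equal(score_patients(m, co2)$score, 2 * sc$score)

  # missing gene contributes zero, with a coverage warning
  co_miss <- expression_cohort(z["gA", , drop = FALSE], standardized = TRUE)
  expect_warning(sc_miss <- score_patients(m, co_miss), "covers 1/2")
  expect_equal(sc_miss$score, 0.5 * z["gA", ], ignore_attr = TRUE)
  co_none <- expression_cohort(
    matrix(0, 1, 2, dimnames = list("other", c("p1", "p2"))),
    standardized = TRUE)
  expect_error(score_patients(m, co_none), "none of the")

  # empty patient set gives an empty result
  co_empty <- expression_cohort(z, standardized = TRUE,
                                is_normal = rep(TRUE, 3))
  expect_equal(nrow(score_patients(m, co_empty)), 0)
})

test_that("risk-group assignment follows the discovery cut-off boundary rules", {
  cuts <- c(median = 0.5, q33 = 0.3, q66 = 0.7)
  expect_equal(as.character(assign_risk_groups(c(0.1, 0.5, 0.9), cuts, 2)),
               c("low", "low", "high"))
  expect_equal(as.character(assign_risk_groups(c(0.1, 0.2), cuts, 3)),
               c("low", "low"))
  expect_equal(as.character(assign_risk_groups(0.7, cuts, 3)),
               "intermediate")
  expect_equal(as.character(assign_risk_groups(c(0.3, 0.31, 0.71), cuts, 3)),
               c("low", "intermediate", "high"))
  expect_error(assign_risk_groups(1, c(median = 0, q33 = 2, q66 = 1), 3),
               "q33 exceeds q66")

  # a cohort split at its own median yields balanced groups
  for (seed in 1:5) {
    set.seed(seed)
    s <- rnorm(101)
    g <- assign_risk_groups(s, c(median = median(s), q33 = NA, q66 = NA), 2)
    expect_lte(abs(diff(table(g))), 1)
  }
})

test_that("prognostic evaluation orients hazards and falls back to log-rank", {
  # separable toy: high-risk samples fail early, low-risk mostly censored
  time <- c(1, 2, 3, 4, 5, 6, 7, 10, 10, 10)
  event <- c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0)
  groups <- factor(rep(c("high", "low"), each = 5),
                   levels = c("low", "high"))
  fit <- suppressWarnings(   # near-complete separation is the point here
    evaluate_prognosis(groups, data.frame(time = time, event = event)))
  expect_gt(fit$terms$beta[1], 0)
  expect_lt(fit$logrank_p, 0.01)

  # zero events in the low-risk group: HR suppressed, log-rank reported
  ev0 <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  fit0 <- evaluate_prognosis(groups, data.frame(time = time, event = ev0))
  expect_null(fit0$terms)
  expect_false(is.null(fit0$logrank_p))

  # null calibration: Wald p approximately uniform across random groupings
  p <- numeric(100)
  for (seed in 1:100) {
    set.seed(seed)
    n <- 60
    tm <- rexp(n, 0.2); ev <- rbinom(n, 1, 0.8)
    g <- factor(sample(c("low", "high"), n, replace = TRUE),
                levels = c("low", "high"))
    f <- evaluate_prognosis(g, data.frame(time = tm, event = ev))
    p[seed] <- if (is.null(f$terms)) NA else f$terms$wald_p[1]
  }
  ks <- suppressWarnings(ks.test(na.omit(p), "punif"))
  expect_lt(unname(ks$statistic), 0.15)

  # trend p is reported for three ordered groups
  set.seed(2)
  n <- 150
  g3 <- factor(sample(c("low", "intermediate", "high"), n, replace = TRUE),
               levels = c("low", "intermediate", "high"))
  lp <- c(low = 0, intermediate = 0.5, high = 1)[as.character(g3)]
  tm <- pmin(rexp(n, 0.1 * exp(lp)), 10)
  f3 <- evaluate_prognosis(g3, data.frame(time = tm,
                                          event = as.integer(tm < 10)))
  expect_false(is.null(f3$trend_p))
  expect_lt(f3$trend_p, 0.05)
  expect_false(is.null(f3$schoenfeld_p))
  expect_error(evaluate_prognosis(factor(rep("high", 5)),
                                  data.frame(time = 1:5,
                                             event = rep(1, 5))),
               "at least 2")
})

test_that("interaction model recovers planted group-specific treatment benefit", {
  simulate_arm <- function(n, benefit_high, benefit_low, seed) {
    set.seed(seed)
    g <- factor(sample(c("low", "high"), n, replace = TRUE),
                levels = c("low", "high"))
    chemo <- rbinom(n, 1, 0.5)
    lp <- 0.7 * (g == "high") + benefit_high * chemo * (g == "high") +
      benefit_low * chemo * (g == "low")
    tm <- pmin(rexp(n, 0.1 * exp(lp)), 10)
    list(g = g, chemo = chemo,
         out = data.frame(time = tm, event = as.integer(tm < 10)))
  }

  # benefit confined to the high-risk group: negative interaction
  neg <- 0
  for (seed in 1:10) {
    a <- simulate_arm(600, log(0.5), 0, seed)
    res <- evaluate_interaction(a$g, a$chemo, a$out)
    neg <- neg + (res$interaction$terms$beta < 0)
  }
  expect_gte(neg, 8)

  # equal benefit in both groups: interaction near zero at large n
  a <- simulate_arm(2000, log(0.6), log(0.6), seed = 99)
  res <- evaluate_interaction(a$g, a$chemo, a$out)
  expect_lt(abs(res$interaction$terms$beta), 0.15)
  expect_named(res$within, c("low", "high"))
  expect_false(is.null(res$within$high))

  # an empty treatment cell suppresses the stratified fit for that group
  a <- simulate_arm(120, 0, 0, seed = 5)
  a$chemo[a$g == "low"] <- 0
  res <- evaluate_interaction(a$g, a$chemo, a$out)
  expect_null(res$within$low)
})
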