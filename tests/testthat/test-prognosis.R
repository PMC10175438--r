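test_that("prognostic classification uses half-open boundary intervals", {
  expect_identical(as.character(classify_prognosis(141)), "excellent")
  expect_identical(as.character(classify_prognosis(0)), "excellent")
  expect_identical(as.character(classify_prognosis(150)), "excellent")
  expect_identical(as.character(classify_prognosis(150.1)), "good")
  expect_identical(as.character(classify_prognosis(550)), "good")
  expect_identical(as.character(classify_prognosis(550.1)), "moderate")
  expect_identical(as.character(classify_prognosis(1000)), "moderate")
  expect_identical(as.character(classify_prognosis(1200)), "poor")
  expect_error(classify_prognosis(-1), "non-negative")
  expect_error(classify_prognosis(100, boundaries = c(500, 400, 300)),
               "increasing")
})

test_that("the high-risk flag is >= 550 and documents the boundary overlap", {
  expect_true(high_risk_flag(550))
  expect_false(high_risk_flag(549.9))
  expect_true(high_risk_flag(954.5))
  expect_error(high_risk_flag(-5), "non-negative")
  # documented asymmetry: 550 is good by group but high-risk by flag
  expect_identical(as.character(classify_prognosis(550)), "good")
  expect_true(high_risk_flag(550))
  # away from 550 the two are consistent
  for (a in c(10, 300, 551, 800, 2000)) {
    expect_identical(high_risk_flag(a),
                     as.character(classify_prognosis(a)) %in%
                       c("moderate", "poor"))
  }
})

test_that("Youden's J is sensitivity + specificity - 1", {
  expect_equal(round(youden_j(0.915, 0.414), 2), 0.33)
  expect_identical(youden_j(1, 1), 1)
  expect_identical(youden_j(0.5, 0.5), 0)
  expect_error(youden_j(1.2, 0.5), "\\[0, 1\\]")
  expect_error(youden_j(0.5, -0.1), "\\[0, 1\\]")
})

test_that("the reference cut-off table is internally consistent", {
  tab <- gap_cutoff_table()
  j <- youden_j(tab$sensitivity / 100, tab$specificity / 100)
  expect_true(all(abs(j - tab$youden_j) <= 0.005 + 1e-9))
  # sensitivity falls and specificity rises with the cut-off
  expect_true(all(diff(tab$sensitivity) < 0))
  expect_true(all(diff(tab$specificity) > 0))
})

test_that("ROC is empirical, oriented for high score = event, AUC by trapezoid", {
  # perfectly separated scores
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(roc$auc, 1)
  expect_error(roc_curve(1:5, c(1, 1, 1, 1, 1)), "both outcome classes")

  # Mann-Whitney equivalence, brute force over all pairs (ties count 1/2)
  set.seed(42)
  scores <- round(c(rnorm(60, 1), rnorm(40, 0)), 1)
  labels <- rep(c(TRUE, FALSE), c(60, 40))
  pos <- scores[labels]; neg <- scores[!labels]
  mw <- 0
  for (p in pos) for (q in neg)
    mw <- mw + (p > q) + 0.5 * (p == q)
  expect_equal(roc_curve(scores, labels)$auc, mw / (60 * 40),
               tolerance = 1e-12)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(9)
  scores <- c(rlnorm(80, log(400), 1), rlnorm(20, log(900), 0.8))
  labels <- rep(c(0, 1), c(80, 20))
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("chance-level AUC sits near 0.5 on independent labels", {
  set.seed(123)
  n <- 10000
  auc <- roc_curve(runif(n), rbinom(n, 1, 0.3))$auc
  expect_lt(abs(auc - 0.5), 0.02)
})

test_that("cut-off selection maximizes J with ties to the smaller value", {
  expect_identical(as.numeric(select_cutoff(gap_cutoff_table())), 550)
  one <- data.frame(cutoff = 300, sensitivity = 80, specificity = 60)
  expect_identical(as.numeric(select_cutoff(one)), 300)
  tie <- data.frame(cutoff = c(400, 200), sensitivity = c(70, 80),
                    specificity = c(60, 50))
  expect_identical(as.numeric(select_cutoff(tie)), 200)
  expect_error(select_cutoff(data.frame()), "empty")
  # raw-score route: scores 1..4, events on the top two; J is maximal (= 1)
  # at threshold 3
  expect_identical(as.numeric(select_cutoff(c(1, 2, 3, 4),
                                            c(0, 0, 1, 1))), 3)
})

test_that("Kaplan-Meier estimates match hand calculations", {
  # four events, no censoring: S is the empirical survival
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km_surv(km, 2.5), 0.5)
  expect_equal(km_surv(km, c(0.5, 1, 4)), c(1, 0.75, 0))

  # all censored: S stays at 1
  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_surv(km2, c(1, 3)), c(1, 1))

  # censoring at t = 2: S(3) = 3/4 * 1/2 = 0.375
  km3 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km_surv(km3, 3), 0.375)

  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("without censoring the KM curve equals 1 - ECDF", {
  set.seed(5)
  t <- round(rexp(40, 0.3), 2) + 0.01
  km <- km_estimate(t, rep(1, 40))
  for (tt in c(0.5, 1, 2, 5)) {
    expect_equal(km_surv(km, tt), 1 - mean(t <= tt), tolerance = 1e-12)
  }
})

test_that("log-rank statistic is zero on duplicated groups and matches a
           hand tabulation", {
  t <- c(1, 3, 4, 6, 8, 9)
  e <- c(1, 1, 0, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 6))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_identical(lr0$df, 1L)

  # independent observed-minus-expected tabulation for two groups
  t1 <- c(2, 4, 5, 7); e1 <- c(1, 1, 1, 0)
  t2 <- c(3, 6, 8, 9); e2 <- c(1, 0, 1, 1)
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  o_minus_e <- 0; v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d2 <- sum(t2 == tt & e2 == 1)
    d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  oracle <- o_minus_e^2 / v
  lr <- logrank_test(c(t1, t2), c(e1, e2), rep(c("a", "b"), each = 4))
  expect_equal(lr$statistic, oracle, tolerance = 1e-10)
  expect_error(logrank_test(t1, e1, rep("a", 4)), "2 non-empty groups")
})

test_that("Cox fit recovers a known hazard ratio and flags degenerate input", {
  set.seed(2024)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, 0.1 * exp(log(2) * x))
  t_cens <- runif(n, 1, 15)
  d <- data.frame(followup_years = pmin(t_event, t_cens),
                  tka = as.integer(t_event <= t_cens), x = x)
  expect_gt(sum(d$tka), 300)
  fit <- cox_fit(d, "x")
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["x"]] - log(2)), 0.2)
  hr <- fit$coefficients
  expect_equal(hr$hr, exp(hr$coef), tolerance = 1e-12)
  expect_true(hr$hr_lower < hr$hr && hr$hr < hr$hr_upper)

  d$z <- 1
  expect_error(cox_fit(d, "z"), "no variation")
  expect_error(cox_fit(d[d$tka == 0, ], "x"), "at least one event")
})

test_that("Cox null coverage: |coef| < 2 SE in at least 90% of replicates", {
  set.seed(77)
  cover <- replicate(100, {
    n <- 300
    x <- rnorm(n)
    t_event <- rexp(n, 0.15)
    t_cens <- runif(n, 1, 12)
    d <- data.frame(followup_years = pmin(t_event, t_cens),
                    tka = as.integer(t_event <= t_cens), x = x)
    f <- cox_fit(d, "x")
    abs(f$coefficients$coef) < 2 * f$coefficients$se
  })
  expect_gte(mean(cover), 0.9)
})

test_that("Cox coefficient sign follows the group with earlier events", {
  # group x = 1 has clearly earlier events: positive log-hazard
  d <- data.frame(followup_years = c(1, 2, 3, 4, 10, 11, 12, 13),
                  tka = c(1, 1, 1, 1, 1, 1, 1, 1),
                  x = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- cox_fit(d, "x")
  expect_gt(coef(fit)[["x"]], 0)
})

test_that("reduction adequacy is the inclusive 2 mm rule", {
  expect_true(reduction_adequacy(2, 2))
  expect_false(reduction_adequacy(2.1, 0))
  expect_false(reduction_adequacy(0, 2.1))
  expect_true(reduction_adequacy(0, 0))
  expect_error(reduction_adequacy(-1, 0), "non-negative")
})
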