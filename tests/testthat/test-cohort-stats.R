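test_that("Shapiro-Wilk routing behaves under null and skewed sampling", {
  set.seed(101)
  p_norm <- replicate(50, normality_test(rnorm(500))$p)
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_skew <- replicate(50, normality_test(rlnorm(500))$p)
  expect_true(all(p_skew < 0.05))
  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(rnorm(2)), "3 <= n")
})

test_that("group comparison matches the exact Mann-Whitney enumeration", {
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  r <- compare_groups(x, y, test = "mann-whitney")
  expect_equal(r$test, "mann-whitney")
  # brute-force permutation oracle: all C(6,3) labelings of the pooled data
  pool <- c(x, y)
  uobs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  us <- apply(combn(6, 3), 2, function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  p_exact <- mean(abs(us - 4.5) >= abs(uobs - 4.5))
  expect_equal(r$p, p_exact)   # = 0.1
  expect_equal(p_exact, 0.1)

  # identical samples: U = n^2/2, p ~ 1
  ri <- suppressWarnings(compare_groups(c(1, 2, 3), c(1, 2, 3),
                                        test = "mann-whitney"))
  expect_equal(unname(ri$statistic), 4.5)
  expect_gt(ri$p, 0.99)

  # symmetry under swapping the groups
  set.seed(3)
  a <- rlnorm(20); b <- rlnorm(25) * 1.5
  expect_equal(compare_groups(a, b)$p, compare_groups(b, a)$p)

  # normal samples route to the t-test
  set.seed(4)
  expect_equal(compare_groups(rnorm(50), rnorm(50) + 1)$test, "t")
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("Fisher's exact test agrees with hypergeometric enumeration", {
  # probability-mass rule oracle
  fisher_oracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
    probs <- dhyper(lo:hi, c1, n - c1, r1)
    pobs <- dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= pobs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact(c(23, 14, 15, 25)),
               fisher_oracle(23, 14, 15, 25), tolerance = 1e-12)
  expect_equal(fisher_exact(c(10, 10, 10, 10)), 1)
  expect_equal(fisher_exact(c(1, 0, 0, 1)), 1)   # two equi-probable tables
  # random spot checks against the oracle
  set.seed(9)
  for (i in 1:25) {
    t4 <- rmultinom(1, sample(8:30, 1), rep(0.25, 4))[, 1]
    if (sum(t4[1] + t4[2]) == 0 || sum(t4[3] + t4[4]) == 0) next
    expect_equal(fisher_exact(t4), fisher_oracle(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact(c(0, 0, 0, 0)), "empty")
})

test_that("Wald odds ratios reproduce the closed form with zero-cell care", {
  r <- odds_ratio_wald(c(23, 14, 15, 25))
  expect_equal(r$or, 23 * 25 / (14 * 15), tolerance = 1e-12)
  lo <- exp(log(r$or) - qnorm(0.975) * sqrt(1 / 23 + 1 / 14 + 1 / 15 + 1 / 25))
  expect_equal(r$ci_low, lo, tolerance = 1e-12)
  expect_false(r$corrected)

  sym <- odds_ratio_wald(c(5, 5, 5, 5))
  expect_equal(sym$or, 1)
  expect_equal(log(sym$ci_low), -log(sym$ci_high), tolerance = 1e-12)

  z <- odds_ratio_wald(c(5, 0, 3, 4))
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
})

test_that("Spearman correlation is rank-invariant and matches the formula", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8, 6)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  set.seed(12)
  a <- rnorm(6); b <- rnorm(6)
  d <- rank(a) - rank(b)
  expect_equal(spearman_cor(a, b)$rho, 1 - 6 * sum(d^2) / (6 * 35),
               tolerance = 1e-12)
  expect_error(spearman_cor(a[1:3], b[1:3]), "n >= 4")
  expect_error(spearman_cor(rep(1, 6), b), "constant")
})

test_that("logistic regression on a 2x2 equals the closed-form log odds ratio", {
  a <- 23; b <- 14; cc <- 15; d <- 25
  x <- rep(c(1, 1, 0, 0), c(a, b, cc, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, cc, d))
  fit <- logistic_fit(data.frame(dirWSSG = x), y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[2]), log(a * d / (b * cc)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se[2]), sqrt(1 / a + 1 / b + 1 / cc + 1 / d),
               tolerance = 1e-6)
  expect_equal(unname(fit$or[2]), 2.738, tolerance = 1e-3)
})

test_that("logistic regression is calibrated under the null", {
  ok <- replicate(20, {
    set.seed(sample.int(1e6, 1))
    x <- rnorm(2000)
    y <- rbinom(2000, 1, 0.4)
    f <- logistic_fit(data.frame(x = x), y)
    abs(f$coefficients[2]) < 0.1 && f$p[2] > 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("logistic regression recovers cohort-scale generating coefficients", {
  set.seed(2024)
  n <- 5000
  wss <- rlnorm(n, log(72), 0.35)
  wssg <- rnorm(n, 0, 40)
  beta <- c(1.133, -0.014, 0.009)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * wss + beta[3] * wssg))
  fit <- logistic_fit(data.frame(WSS = wss, WSSG = wssg), y)
  expect_true(fit$converged)
  for (k in 1:3)
    expect_lt(abs(fit$coefficients[k] - beta[k]), 3 * fit$se[k])
})

test_that("separation and degenerate outcomes are flagged or rejected", {
  x <- c(rep(0, 20), rep(1, 20))
  expect_warning(f <- logistic_fit(data.frame(x = x), x), "separation")
  expect_true(f$separation)
  expect_error(logistic_fit(data.frame(x = x), rep(1, 40)), "both classes")
})

test_that("variable selection reproduces the printed univariate screen", {
  p_uni <- c(WSS = 0.077, WSSG = 0.028, dirWSSG = 0.030,
             absWSSG = 0.207, OSI = 0.918)
  cors <- data.frame(
    var1 = c("WSSG", "absWSSG", "absWSSG"),
    var2 = c("dirWSSG", "WSS", "OSI"),
    rho = c(0.865, 0.488, -0.309),
    p = c(1e-5, 1e-5, 0.006))
  expect_setequal(select_variables(p_uni, cors), c("WSS", "WSSG"))

  expect_equal(length(select_variables(c(a = 0.5, b = 0.2), NULL)), 0)
  expect_setequal(select_variables(c(a = 0.05, b = 0.06), NULL), c("a", "b"))
  expect_setequal(select_variables(c(a = 0.05, b = 0.06),
                                   data.frame(var1 = "a", var2 = "b",
                                              rho = 0.9, p = 0.001)), "a")
})

test_that("the logistic risk score evaluates the fitted formula", {
  beta <- c(1.133, -0.014, 0.009)
  expect_equal(logistic_score(0, 0, beta), 1 / (1 + exp(-1.133)),
               tolerance = 1e-12)
  expect_equal(logistic_score(0, 0, beta), 0.756, tolerance = 1e-3)
  expect_equal(logistic_score(50, -10, c(0, 0, 0)), 0.5)
  # monotone: decreasing in WSS, increasing in WSSG
  expect_lt(logistic_score(80, 0, beta), logistic_score(60, 0, beta))
  expect_gt(logistic_score(70, 20, beta), logistic_score(70, -20, beta))
})

test_that("ROC analysis matches the U-statistic identity and Youden rule", {
  # perfect separation
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$cutoff_sensitivity, 1)
  expect_equal(r$cutoff_specificity, 1)

  # AUC == U / (n1 n2) on seeded random data, with ties
  set.seed(31)
  for (i in 1:20) {
    n1 <- sample(10:40, 1); n0 <- sample(10:40, 1)
    sc <- c(round(rnorm(n1, 0.3), 1), round(rnorm(n0), 1))
    lab <- rep(c(1, 0), c(n1, n0))
    r <- roc_curve(sc, lab)
    u <- sum(outer(sc[lab == 1], sc[lab == 0], ">")) +
      0.5 * sum(outer(sc[lab == 1], sc[lab == 0], "=="))
    expect_equal(r$auc, u / (n1 * n0), tolerance = 1e-12)
  }

  # null AUC near 0.5
  set.seed(77)
  rn <- roc_curve(rnorm(1000), rbinom(1000, 1, 0.5))
  expect_lt(abs(rn$auc - 0.5), 0.05)

  expect_error(roc_curve(rnorm(5), rep(1, 5)), "both classes")
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  sc <- rnorm(200)
  lab <- rbinom(200, 1, plogis(sc))
  r <- roc_curve(sc, lab)
  pr <- pROC::roc(lab, sc, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
})

test_that("the end-to-end case-control fit is stable across seeds", {
  # the gradient signal (continuous WSSG or its categorical direction)
  # should enter the model and carry a positive coefficient: cases have
  # higher / more often positive gradients by construction
  res <- sapply(1:50, function(seed) {
    tab <- make_cohort(cohort_params(seed = seed))
    cc <- suppressWarnings(casecontrol_analysis(tab))
    if (is.null(cc$multivariate)) return(c(done = FALSE, pos = NA))
    grad <- intersect(c("WSSG", "dirWSSG"), cc$selected)
    if (length(grad) == 0) return(c(done = TRUE, pos = NA))
    c(done = cc$multivariate$converged,
      pos = unname(cc$multivariate$coefficients[grad[1]] > 0))
  })
  expect_true(all(res["done", ], na.rm = TRUE))
  pos <- res["pos", ][!is.na(res["pos", ])]
  expect_gt(length(pos), 40)       # the gradient variable almost always enters
  expect_gte(mean(pos), 0.8)       # and points in the case direction
})

test_that("the case-control object prints, predicts and summarises", {
  tab <- make_cohort(cohort_params(seed = 8))
  cc <- suppressWarnings(casecontrol_analysis(tab))
  expect_s3_class(cc, "casecontrol")
  expect_output(print(cc), "casecontrol")
  s <- summary(cc)
  expect_s3_class(s, "summary.casecontrol")
  expect_equal(nrow(s$comparison), 4)
  expect_output(print(s), "Fisher exact p")
  expect_equal(sum(s$contingency), 77)
  if (!is.null(cc$multivariate)) {
    pr <- predict(cc)
    expect_true(all(pr > 0 & pr < 1))
    expect_equal(length(coef(cc)), length(cc$selected) + 1)
  }
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(cc); grDevices::dev.off()
  expect_true(file.exists(f))
})
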