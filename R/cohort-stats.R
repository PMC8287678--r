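#' Shapiro-Wilk normality check
#'
#' Used only to route group comparisons to the parametric or
#' nonparametric test.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk needs 3 <= n <= 5000")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Two-group comparison routed by normality
#'
#' Student's t-test when both groups pass Shapiro-Wilk at `alpha`,
#' otherwise the Mann-Whitney U test (exact for small untied samples,
#' normal approximation with tie correction otherwise). Medians and
#' quartiles are reported alongside, matching the median (25th-75th)
#' summary convention.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param alpha normality routing level (default 0.05).
#' @param test `"auto"` (Shapiro-Wilk routing) or force
#'   `"mann-whitney"` / `"t"`.
#' @return list with `test`, `statistic`, `p`, `medians`, `iqrs`, `n`.
#' @export
compare_groups <- function(x, y, alpha = 0.05,
                           test = c("auto", "mann-whitney", "t")) {
  test <- match.arg(test)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("both groups need n >= 2")
  normal <- if (test == "auto") {
    length(x) >= 3L && length(y) >= 3L &&
      stats::sd(x) > 0 && stats::sd(y) > 0 &&
      normality_test(x)$p > alpha && normality_test(y)$p > alpha
  } else test == "t"
  if (normal) {
    tt <- stats::t.test(x, y)
    test <- "t"; statistic <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    test <- "mann-whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
  }
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  qx <- qs(x); qy <- qs(y)
  list(test = test, statistic = statistic, p = p,
       medians = c(x = qx[2], y = qy[2]),
       iqrs = rbind(x = qx[c(1, 3)], y = qy[c(1, 3)]),
       n = c(x = length(x), y = length(y)))
}

# coerce (a, b, c, d) or a 2x2 matrix into the canonical contingency
# layout: rows dir+/dir-, columns case/control
as_table2x2 <- function(t) {
  if (is.matrix(t)) {
    if (!all(dim(t) == c(2L, 2L))) stop("need a 2x2 table")
    m <- t
  } else if (length(t) == 4L) {
    m <- matrix(as.numeric(t), 2L, 2L, byrow = TRUE)
  } else stop("need a 2x2 table or 4 counts (a, b, c, d)")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (sum(m) == 0) stop("empty table")
  m
}

#' Fisher's exact test (two-sided) on a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities, at fixed margins, of all tables no more probable than
#' the observed one.
#'
#' @param t 2x2 matrix, or 4 counts `(a, b, c, d)` = (case/dir+,
#'   control/dir+, case/dir-, control/dir-).
#' @return two-sided p-value.
#' @export
fisher_exact <- function(t) {
  m <- as_table2x2(t)
  stats::fisher.test(m)$p.value
}

#' Odds ratio with Wald 95% confidence interval
#'
#' `OR = (a d) / (b c)` with
#' `CI = exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Zero cells
#' trigger the Haldane-Anscombe 0.5 correction, flagged in the result.
#'
#' @param t as in [fisher_exact()].
#' @param conf confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `se_log`, `corrected`.
#' @export
odds_ratio_wald <- function(t, conf = 0.95) {
  m <- as_table2x2(t)
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       se_log = se, corrected = corrected)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-aware (midranks); the p-value uses the
#' `t = rho sqrt((n-2)/(1-rho^2))` approximation.
#'
#' @param x,y numeric vectors, n >= 4.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Logistic regression with Wald inference
#'
#' Maximum-likelihood fit by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 100 iterations), reporting
#' per-coefficient odds ratios, Wald 95% CIs and Wald p-values.
#' Non-convergence and (quasi-)separation are flagged; separated fits
#' carry no usable estimates.
#'
#' @param predictors data frame (or matrix) of predictor columns.
#' @param outcome 0/1 vector (or logical), both classes present.
#' @return object of class `logistic_model`: list with `coefficients`,
#'   `se`, `or`, `ci` (2-column matrix), `p`, `converged`, `separation`,
#'   and the underlying `glm` fit.
#' @export
logistic_fit <- function(predictors, outcome) {
  X <- as.data.frame(predictors)
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be 0/1")
  if (length(unique(y)) < 2L) stop("outcome must contain both classes")
  if (nrow(X) != length(y)) stop("predictor/outcome length mismatch")
  if (nrow(X) <= ncol(X) + 1L) stop("too few observations for the model")
  dat <- cbind(X, .y = y)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  mu <- stats::fitted(fit)
  separation <- any(abs(co[-1]) > 15) || all(mu < 1e-8 | mu > 1 - 1e-8)
  if (separation)
    warning("perfect or quasi-perfect separation detected; estimates unreliable")
  z <- co / se
  ci <- cbind(low = exp(co - stats::qnorm(0.975) * se),
              high = exp(co + stats::qnorm(0.975) * se))
  structure(list(coefficients = co, se = se, or = exp(co), ci = ci,
                 p = 2 * stats::pnorm(-abs(z)),
                 converged = fit$converged, separation = separation,
                 fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model (", if (x$converged) "converged" else "NOT converged",
      if (x$separation) ", separation flagged" else "", ")\n", sep = "")
  tab <- data.frame(coef = x$coefficients, se = x$se, OR = x$or,
                    ci_low = x$ci[, 1], ci_high = x$ci[, 2], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Univariate screen with correlation de-duplication
#'
#' Keeps candidates with univariate p below `p_enter` (default 0.1); then,
#' for every pair of surviving variables that is significantly correlated
#' (correlation p below `cor_alpha`, default 0.05), drops the member with
#' the larger univariate p. This reproduces the selection that determines
#' the multivariate model.
#'
#' @param univariate_p named numeric vector of univariate p-values.
#' @param correlations data frame with columns `var1`, `var2`, `rho`, `p`
#'   (one row per tested pair), or `NULL` for none.
#' @param p_enter univariate entry threshold.
#' @param cor_alpha correlation significance threshold.
#' @return character vector of selected variable names.
#' @export
select_variables <- function(univariate_p, correlations = NULL,
                             p_enter = 0.1, cor_alpha = 0.05) {
  if (is.null(names(univariate_p)) || any(!nzchar(names(univariate_p))))
    stop("univariate_p must be named")
  keep <- names(univariate_p)[univariate_p < p_enter]
  if (length(keep) == 0L || is.null(correlations)) return(keep)
  cp <- as.data.frame(correlations)
  cp <- cp[cp$p < cor_alpha, , drop = FALSE]
  if (nrow(cp)) {
    # deterministic: resolve pairs in order of the worse member's p
    repeat {
      both <- cp$var1 %in% keep & cp$var2 %in% keep
      if (!any(both)) break
      pair <- cp[which(both)[1], ]
      drop <- if (univariate_p[pair$var1] > univariate_p[pair$var2])
        pair$var1 else pair$var2
      keep <- setdiff(keep, drop)
    }
  }
  keep
}

#' Aneurysm-risk logistic score
#'
#' Evaluates `1 / (1 + exp(-(b0 + b1 WSS + b2 WSSG)))` — the fitted
#' two-predictor risk score — either from a fitted [logistic_fit()] model
#' with predictors (WSS, WSSG) or from an explicit coefficient vector
#' `c(b0, b1, b2)`.
#'
#' @param wss WSS values (Pa).
#' @param wssg WSSG values (Pa/mm).
#' @param model a `logistic_model` or numeric `c(b0, b1, b2)`.
#' @return probabilities in (0, 1).
#' @export
logistic_score <- function(wss, wssg, model) {
  beta <- if (inherits(model, "logistic_model")) {
    unname(model$coefficients[1:3])
  } else {
    if (length(model) != 3L) stop("need coefficients c(b0, b1, b2)")
    as.numeric(model)
  }
  stats::plogis(beta[1] + beta[2] * wss + beta[3] * wssg)
}

#' Empirical ROC curve, AUC and Youden-optimal cutoff
#'
#' Sweeps all unique score thresholds (prediction positive when
#' `score >= threshold`), computes sensitivity/specificity, the AUC by
#' trapezoid, and the cutoff maximizing Youden's J (ties broken toward
#' higher sensitivity).
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels 0/1 or logical (1/TRUE = case).
#' @return object of class `roc_result`: `thresholds`, `sensitivities`,
#'   `specificities`, `auc`, `cutoff`, `cutoff_sensitivity`,
#'   `cutoff_specificity`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  ok <- is.finite(scores)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1L) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & y == 0L) / n0, numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(sens[best])]
  structure(list(thresholds = thr, sensitivities = sens,
                 specificities = spec, auc = auc,
                 cutoff = thr[best],
                 cutoff_sensitivity = sens[best],
                 cutoff_specificity = spec[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f; optimal cutoff %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$cutoff, x$cutoff_sensitivity, x$cutoff_specificity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = 1, ...) {
  fpr <- 1 - x$specificities
  ord <- order(fpr, x$sensitivities)
  if (!add) {
    graphics::plot(fpr[ord], x$sensitivities[ord], type = "l", col = col,
                   xlab = "1 - specificity", ylab = "sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(fpr[ord], x$sensitivities[ord], col = col, ...)
  }
  invisible(x)
}
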