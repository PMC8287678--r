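#' Case-control analysis of haemodynamic wall parameters
#'
#' The central fitting routine: given a per-subject metric table it runs
#' the full case-control statistical procedure —
#' \enumerate{
#'   \item per-metric group comparison (Shapiro-Wilk routing to Student's
#'     t or Mann-Whitney U), summarised as median (25th-75th);
#'   \item the 2x2 gradient-direction contingency table with Fisher's
#'     exact test and the Wald odds ratio;
#'   \item univariate logistic regressions for every metric;
#'   \item the Spearman correlation screen among metrics;
#'   \item variable selection (univariate p < 0.1, correlated pairs
#'     de-duplicated) and the multivariate logistic fit;
#'   \item ROC analysis for the signed gradient alone and for the
#'     multivariate risk score, with Youden-optimal cutoffs.
#' }
#'
#' @param table a `cohort_table` (or data frame with the same columns, see
#'   [cohort_table()]).
#' @param metrics metric columns entered as candidates.
#' @param p_enter univariate entry threshold for the multivariate model.
#' @param cor_alpha correlation significance threshold used by the
#'   de-duplication rule.
#' @return object of class `casecontrol`; see
#'   [summary.casecontrol()], [coef.casecontrol()],
#'   [predict.casecontrol()], [plot.casecontrol()].
#' @export
casecontrol_analysis <- function(table,
                                 metrics = c("WSS", "WSSG", "absWSSG",
                                             "OSI", "dirWSSG"),
                                 p_enter = 0.1, cor_alpha = 0.05) {
  tab <- cohort_table(as.data.frame(table))
  y <- as.integer(tab$group == "case")
  continuous <- setdiff(metrics, "dirWSSG")

  group_tests <- lapply(continuous, function(m)
    compare_groups(tab[[m]][y == 1L], tab[[m]][y == 0L]))
  names(group_tests) <- continuous

  # contingency: rows dir+/dir-, columns case/control
  ct <- matrix(c(sum(y == 1L & tab$dirWSSG == 1L),
                 sum(y == 0L & tab$dirWSSG == 1L),
                 sum(y == 1L & tab$dirWSSG == 0L),
                 sum(y == 0L & tab$dirWSSG == 0L)),
               2L, 2L, byrow = TRUE,
               dimnames = list(c("dirWSSG+", "dirWSSG-"),
                               c("case", "control")))
  fisher_p <- fisher_exact(ct)
  or <- odds_ratio_wald(ct)

  uni <- lapply(metrics, function(m)
    logistic_fit(stats::setNames(tab[m], m), y))
  names(uni) <- metrics
  uni_p <- vapply(uni, function(f) unname(f$p[2]), numeric(1))

  pairs <- utils::combn(metrics, 2)
  cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    sc <- spearman_cor(tab[[pairs[1, k]]], tab[[pairs[2, k]]])
    data.frame(var1 = pairs[1, k], var2 = pairs[2, k],
               rho = sc$rho, p = sc$p, stringsAsFactors = FALSE)
  }))

  selected <- select_variables(uni_p, cors, p_enter = p_enter,
                               cor_alpha = cor_alpha)
  multi <- if (length(selected) >= 1L)
    logistic_fit(tab[selected], y) else NULL

  roc_wssg <- roc_curve(tab$WSSG, y)
  roc_score <- if (!is.null(multi))
    roc_curve(stats::predict(multi$fit, type = "response"), y) else NULL

  structure(list(table = tab, metrics = metrics,
                 group_tests = group_tests,
                 contingency = ct, fisher_p = fisher_p, odds_ratio = or,
                 univariate = uni, univariate_p = uni_p,
                 correlations = cors, selected = selected,
                 multivariate = multi,
                 roc_wssg = roc_wssg, roc_score = roc_score),
            class = "casecontrol")
}

#' @export
print.casecontrol <- function(x, ...) {
  n <- table(x$table$group)
  cat(sprintf("casecontrol: %d cases vs %d controls\n",
              n[["case"]], n[["control"]]))
  cat(sprintf("  dirWSSG contingency: Fisher p = %.3f, OR = %.3f (%.3f-%.3f)\n",
              x$fisher_p, x$odds_ratio$or, x$odds_ratio$ci_low,
              x$odds_ratio$ci_high))
  cat("  multivariate model: ",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(no variable selected)", "\n", sep = "")
  if (!is.null(x$roc_score))
    cat(sprintf("  AUC: WSSG %.3f, combined score %.3f\n",
                x$roc_wssg$auc, x$roc_score$auc))
  invisible(x)
}

#' Summarise a case-control analysis
#'
#' @param object a [casecontrol_analysis()] result.
#' @param ... unused.
#' @return list of data frames: `comparison` (median/IQR/test/p per
#'   metric), `contingency`, `regression` (univariate and multivariate
#'   OR/CI/p), printed compactly.
#' @export
summary.casecontrol <- function(object, ...) {
  comp <- do.call(rbind, lapply(names(object$group_tests), function(m) {
    g <- object$group_tests[[m]]
    data.frame(metric = m,
               case_median = g$medians[["x"]],
               case_q25 = g$iqrs["x", 1], case_q75 = g$iqrs["x", 2],
               control_median = g$medians[["y"]],
               control_q25 = g$iqrs["y", 1], control_q75 = g$iqrs["y", 2],
               test = g$test, p = g$p, stringsAsFactors = FALSE)
  }))
  reg <- do.call(rbind, lapply(names(object$univariate), function(m) {
    u <- object$univariate[[m]]
    row <- data.frame(metric = m, or_uni = unname(u$or[2]),
                      ci_low_uni = unname(u$ci[2, 1]),
                      ci_high_uni = unname(u$ci[2, 2]),
                      p_uni = unname(u$p[2]),
                      or_multi = NA_real_, ci_low_multi = NA_real_,
                      ci_high_multi = NA_real_, p_multi = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(object$multivariate) && m %in% object$selected) {
      mu <- object$multivariate
      i <- match(m, names(mu$coefficients))
      row$or_multi <- unname(mu$or[i])
      row$ci_low_multi <- unname(mu$ci[i, 1])
      row$ci_high_multi <- unname(mu$ci[i, 2])
      row$p_multi <- unname(mu$p[i])
    }
    row
  }))
  out <- list(comparison = comp, contingency = object$contingency,
              fisher_p = object$fisher_p, odds_ratio = object$odds_ratio,
              regression = reg, selected = object$selected,
              auc_wssg = object$roc_wssg$auc,
              auc_score = if (!is.null(object$roc_score))
                object$roc_score$auc else NA_real_)
  class(out) <- "summary.casecontrol"
  out
}

#' @export
print.summary.casecontrol <- function(x, ...) {
  cat("Group comparison (median [q25-q75]):\n")
  print(transform(x$comparison, p = signif(p, 3)), row.names = FALSE)
  cat("\nGradient-direction contingency:\n")
  print(x$contingency)
  cat(sprintf("Fisher exact p = %.3f; OR = %.3f (95%% CI %.3f-%.3f)\n",
              x$fisher_p, x$odds_ratio$or, x$odds_ratio$ci_low,
              x$odds_ratio$ci_high))
  cat("\nLogistic regression (univariate / multivariate):\n")
  print(transform(x$regression, p_uni = signif(p_uni, 3),
                  p_multi = signif(p_multi, 3)), row.names = FALSE)
  cat("\nSelected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("AUC: WSSG %.3f, combined score %s\n", x$auc_wssg,
              ifelse(is.na(x$auc_score), "-", sprintf("%.3f", x$auc_score))))
  invisible(x)
}

#' @export
coef.casecontrol <- function(object, ...) {
  if (is.null(object$multivariate)) return(NULL)
  object$multivariate$coefficients
}

#' Predict case probability for new subjects
#'
#' @param object a [casecontrol_analysis()] result with a multivariate
#'   model.
#' @param newdata data frame containing the selected metric columns;
#'   defaults to the training table.
#' @param ... unused.
#' @return predicted probabilities of being a case.
#' @export
predict.casecontrol <- function(object, newdata = NULL, ...) {
  if (is.null(object$multivariate)) stop("no multivariate model was selected")
  if (is.null(newdata)) newdata <- object$table
  stats::predict(object$multivariate$fit, newdata = newdata,
                 type = "response")
}

#' Plot the ROC curves of a case-control analysis
#'
#' @param x a [casecontrol_analysis()] result.
#' @param ... passed to [plot.roc_result()].
#' @export
plot.casecontrol <- function(x, ...) {
  plot(x$roc_wssg, col = "steelblue", ...)
  if (!is.null(x$roc_score)) plot(x$roc_score, add = TRUE, col = "firebrick")
  graphics::legend("bottomright", bty = "n",
                   col = c("steelblue", "firebrick"), lty = 1,
                   legend = c(sprintf("WSSG (AUC %.3f)", x$roc_wssg$auc),
                              if (!is.null(x$roc_score))
                                sprintf("combined score (AUC %.3f)",
                                        x$roc_score$auc)))
  invisible(x)
}
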