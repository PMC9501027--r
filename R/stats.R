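#' Shapiro-Wilk normality gate for a two-group comparison
#'
#' Decides whether a parametric (t-test) comparison is justified: returns
#' TRUE only if the Shapiro-Wilk test fails to reject normality (p >= alpha)
#' in \emph{both} groups. Degenerate zero-variance groups cannot be declared
#' normal and return FALSE with a warning.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param alpha gate level (default 0.05).
#' @return Logical: use the parametric test?
#' @export
normality_gate <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3)
    stop("Shapiro-Wilk requires at least 3 values per group")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a group; normality undecidable, using nonparametric test")
    return(FALSE)
  }
  stats::shapiro.test(a)$p.value >= alpha &&
    stats::shapiro.test(b)$p.value >= alpha
}

#' Normality-gated unpaired two-group comparison
#'
#' Reproduces the study's testing pipeline for one variable: an unpaired
#' t-test when the Shapiro-Wilk gate passes in both groups, otherwise the
#' two-sided Wilcoxon rank-sum (Mann-Whitney) test --- exact when the
#' combined sample is small (n_a + n_b <= 12) and tie-free, with the
#' tie-corrected normal approximation otherwise. Summaries follow the
#' reporting convention: mean +/- sd when parametric, median with IQR when
#' nonparametric.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alpha significance level for the result flag and the normality
#'   gate.
#' @param var_equal passed to [t.test()] when the parametric branch is
#'   taken.
#' @param test \code{"auto"} (the normality gate decides), or force
#'   \code{"t"} / \code{"wilcoxon"}.
#' @return An object of class \code{"group_comparison"}: list with
#'   \code{test} ("t" or "wilcoxon"), \code{p_value}, \code{significant},
#'   \code{summary_a}, \code{summary_b}.
#' @export
compare_groups <- function(a, b, alpha = 0.05, var_equal = FALSE,
                           test = c("auto", "t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  if (test == "auto")
    test <- if (length(a) >= 3 && length(b) >= 3 &&
                normality_gate(a, b, alpha)) "t" else "wilcoxon"
  if (test == "t") {
    p <- stats::t.test(a, b, var.equal = var_equal)$p.value
    sa <- c(mean = mean(a), sd = stats::sd(a))
    sb <- c(mean = mean(b), sd = stats::sd(b))
  } else {
    p <- rank_sum_test(a, b)
    sa <- c(median = stats::median(a), IQR = stats::IQR(a))
    sb <- c(median = stats::median(b), IQR = stats::IQR(b))
  }
  structure(list(test = test, p_value = p, significant = p < alpha,
                 summary_a = sa, summary_b = sb,
                 n = c(length(a), length(b))),
            class = "group_comparison")
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' The nonparametric branch of [compare_groups()]: exact when the combined
#' sample is small (\code{n_a + n_b <= 12}) and tie-free, otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric vectors.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  exact <- length(a) + length(b) <= 12 && !any(duplicated(c(a, b)))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(s) paste(sprintf("%s %.3g", names(s), s), collapse = ", ")
  cat(sprintf("%s test: p = %.4g%s\n  group A (n=%d): %s\n  group B (n=%d): %s\n",
              x$test, x$p_value, if (x$significant) " *" else "",
              x$n[1], fmt(x$summary_a), x$n[2], fmt(x$summary_b)))
  invisible(x)
}

#' ROC analysis with the Youden operating point
#'
#' Builds the full ROC curve of a score for detecting the positive class.
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores, extended by -Inf and +Inf; at a threshold c, sensitivity is the
#' fraction of positives with score >= c and specificity the fraction of
#' negatives with score < c. The operating cutoff maximises Youden's index
#' J = sensitivity + specificity - 1, ties broken toward the smaller
#' threshold (favouring sensitivity). AUC is the trapezoidal area under the
#' full curve.
#'
#' @param scores numeric scores, larger = more suspicious of the positive
#'   class.
#' @param labels logical or 0/1: TRUE/1 for the positive class; both classes
#'   must be present.
#' @return An object of class \code{"roc_result"}: list with
#'   \code{thresholds}, \code{sensitivities}, \code{specificities},
#'   \code{youden_cutoff}, \code{sensitivity_at_cutoff},
#'   \code{specificity_at_cutoff}, \code{auc}.
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(thr, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(thr, function(c) mean(neg < c), numeric(1))
  j <- sens + spec - 1
  # smallest threshold achieving the maximum; the 1e-12 slack makes the
  # tie-break immune to floating-point differences between equal J values
  # reached via different sensitivity/specificity fractions
  best <- which(j > max(j) - 1e-12)[1]
  # trapezoid over the (FPR, TPR) curve
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thr, sensitivities = sens,
                 specificities = spec, youden_cutoff = thr[best],
                 sensitivity_at_cutoff = sens[best],
                 specificity_at_cutoff = spec[best], auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f; Youden cutoff = %.4g (sensitivity %.1f%%, specificity %.1f%%)\n",
              x$auc, x$youden_cutoff, 100 * x$sensitivity_at_cutoff,
              100 * x$specificity_at_cutoff))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$specificities, x$sensitivities, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  i <- which(x$thresholds == x$youden_cutoff)[1]
  graphics::points(1 - x$specificities[i], x$sensitivities[i], pch = 19)
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties averaged); the two-sided p-value
#' uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return Named vector \code{c(rho, p)}.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance; correlation undefined")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  c(rho = rho, p = p)
}

#' Cohort summary of quantitative lesion parameters
#'
#' Mirrors the study's comparison table: for each of SUV_max, LBR(SUV_max),
#' Ki_max, LBR(Ki_max), Vd_max and LBR(Vd_max), group medians and IQRs for
#' cancer vs inflammatory/infectious lesions with the normality-gated
#' comparison p-value; plus the pooled paired contrast of LBR(Ki) against
#' LBR(SUV) across all lesions (Wilcoxon signed-rank), and the Spearman
#' correlation between the two LBRs. No multiplicity correction is applied
#' (raw p-values, as in the source analysis convention).
#'
#' @param records lesion-record data frame as from [measure_cohort()] or
#'   [measure_lesions()], with a \code{group} column.
#' @param alpha significance level.
#' @return An object of class \code{"cohort_summary"}: list with
#'   \code{table} (one row per variable: group medians, IQRs, p, test,
#'   significance), \code{paired_lbr} (p-value and pooled medians of the
#'   LBR(Ki) vs LBR(SUV) contrast), \code{spearman} (rho, p), and group
#'   sizes.
#' @export
summarize_cohort <- function(records, alpha = 0.05) {
  vars <- c("SUV_max", "LBR_suv", "Ki_max", "LBR_ki", "Vd_max", "LBR_vd")
  stopifnot(all(vars %in% names(records)), "group" %in% names(records))
  ca <- records[records$group == "cancer", ]
  infl <- records[records$group == "inflammatory", ]
  if (nrow(ca) == 0 || nrow(infl) == 0) stop("empty group")
  rows <- lapply(vars, function(v) {
    cmp <- compare_groups(ca[[v]], infl[[v]], alpha = alpha)
    data.frame(variable = v,
               cancer_median = stats::median(ca[[v]]),
               cancer_iqr = stats::IQR(ca[[v]]),
               inflammatory_median = stats::median(infl[[v]]),
               inflammatory_iqr = stats::IQR(infl[[v]]),
               test = cmp$test, p_value = cmp$p_value,
               significant = cmp$significant,
               stringsAsFactors = FALSE)
  })
  paired_p <- suppressWarnings(
    stats::wilcox.test(records$LBR_ki, records$LBR_suv,
                       paired = TRUE)$p.value)
  sp <- spearman_rho(records$LBR_ki, records$LBR_suv)
  structure(list(table = do.call(rbind, rows),
                 paired_lbr = list(
                   p_value = paired_p,
                   pooled_median_lbr_ki = stats::median(records$LBR_ki),
                   pooled_median_lbr_suv = stats::median(records$LBR_suv)),
                 spearman = sp,
                 n = c(cancer = nrow(ca), inflammatory = nrow(infl)),
                 alpha = alpha),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Lesion cohort summary: %d cancer vs %d inflammatory/infectious\n\n",
              x$n[["cancer"]], x$n[["inflammatory"]]))
  tab <- x$table
  scale <- ifelse(tab$variable == "Ki_max", 100, 1)  # print Ki as x10^-2
  lab <- ifelse(tab$variable == "Ki_max", "Ki_max [x10^-2]", tab$variable)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-16s %.1f (IQR %.1f) vs %.1f (IQR %.1f)  p = %.3g%s [%s]\n",
                lab[i], scale[i] * tab$cancer_median[i],
                scale[i] * tab$cancer_iqr[i],
                scale[i] * tab$inflammatory_median[i],
                scale[i] * tab$inflammatory_iqr[i],
                tab$p_value[i], ifelse(tab$significant[i], " *", ""),
                tab$test[i]))
  cat(sprintf("\n  pooled LBR(Ki) %.1f vs LBR(SUV) %.1f, signed-rank p = %.3g\n",
              x$paired_lbr$pooled_median_lbr_ki,
              x$paired_lbr$pooled_median_lbr_suv, x$paired_lbr$p_value))
  cat(sprintf("  Spearman rho[LBR(Ki), LBR(SUV)] = %.2f (p = %.3g)\n",
              x$spearman[["rho"]], x$spearman[["p"]]))
  invisible(x)
}
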