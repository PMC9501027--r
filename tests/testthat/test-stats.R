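test_that("normality gate passes Gaussian data at the expected rate", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    normality_gate(rnorm(60), rnorm(60))
  }, logical(1))
  # independent gates: pass probability (1 - alpha)^2 ~ 0.9025
  expect_equal(mean(hits), 0.9025, tolerance = 0.07)
})

test_that("normality gate rejects heavy skew and degenerate input", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    normality_gate(rlnorm(60, sdlog = 1), rlnorm(60, sdlog = 1))
  }, logical(1))
  expect_lt(mean(hits), 0.05)
  expect_error(normality_gate(c(1, 2), c(1, 2, 3)), "at least 3")
  expect_warning(res <- normality_gate(rep(1, 10), rnorm(10)),
                 "zero variance")
  expect_false(res)
})

test_that("rank-sum p-values match full enumeration for small samples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(99)
  for (na in 2:5) for (nb in 2:5) {
    if (na + nb > 10) next
    x <- sample(100, na + nb)  # tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(rank_sum_test(a, b), oracle_ranksum_p(a, b),
                 info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("comparison routes through the gate and reports group summaries", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "wilcoxon")
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$test, "wilcoxon")
  expect_named(cmp$summary_a, c("median", "IQR"))
  set.seed(2)
  a <- rnorm(40); b <- rnorm(40, 1)
  cmp_t <- compare_groups(a, b)
  expect_equal(cmp_t$test, "t")
  expect_equal(cmp_t$p_value, stats::t.test(a, b)$p.value)
  skew <- rlnorm(40, sdlog = 1.5)
  cmp_w <- compare_groups(skew, rlnorm(40, 0.5, 1.5))
  expect_equal(cmp_w$test, "wilcoxon")
  expect_error(compare_groups(numeric(0), 1:3), "empty group")
})

test_that("cohort-shaped Ki contrast is detected with high power", {
  sig <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(seed = s, noise_scale = 0))
    r <- co$records
    compare_groups(r$true_Ki[r$group == "cancer"],
                   r$true_Ki[r$group == "inflammatory"])$significant
  }, logical(1))
  expect_gte(mean(sig), 0.8)
})

test_that("Youden cutoff and curve match the exhaustive oracle", {
  r <- roc_youden(c(3, 4, 5, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$youden_cutoff, 2.5)  # tie with 3.5 broken downward
  expect_equal(r$sensitivity_at_cutoff, 1.0)
  expect_equal(r$specificity_at_cutoff, 2 / 3)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    got <- roc_youden(scores, labels)
    ora <- oracle_roc_youden(scores, labels)
    expect_equal(got$youden_cutoff, ora$cutoff)
    expect_equal(got$sensitivity_at_cutoff + got$specificity_at_cutoff - 1,
                 ora$j)
  }
})

test_that("perfect separation and null scores bound the ROC", {
  perf <- roc_youden(c(10, 11, 12, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(perf$auc, 1)
  expect_equal(perf$sensitivity_at_cutoff + perf$specificity_at_cutoff - 1, 1)
  expect_error(roc_youden(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the Mann-Whitney normalisation on tie-free data", {
  set.seed(8)
  pos <- rnorm(25, 1); neg <- rnorm(30)
  r <- roc_youden(c(pos, neg), rep(c(TRUE, FALSE), c(25, 30)))
  u <- sum(outer(pos, neg, ">"))
  expect_equal(r$auc, u / (25 * 30), tolerance = 1e-12)
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- suppressMessages(pROC::auc(rep(c(1, 0), c(25, 30)),
                                      c(pos, neg)))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("Spearman correlation handles monotone, reversed and tied data", {
  expect_equal(spearman_rho(1:10, exp(1:10))[["rho"]], 1)
  expect_equal(spearman_rho(1:10, -(1:10))[["rho"]], -1)
  hand <- spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5))
  expect_equal(hand[["rho"]], 0.9)  # 1 - 6*2/(5*24)
  ref <- stats::cor.test(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5),
                         method = "spearman", exact = FALSE)
  expect_equal(hand[["rho"]], unname(ref$estimate))
  expect_error(spearman_rho(rep(1, 5), 1:5), "zero rank variance")
  set.seed(12)
  x <- rnorm(40); y <- x + rnorm(40)
  mine <- spearman_rho(x, y)
  ref2 <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(mine[["rho"]], unname(ref2$estimate), tolerance = 1e-12)
  expect_equal(mine[["p"]], ref2$p.value, tolerance = 1e-6)
})

test_that("cohort summary mirrors the six-variable comparison table", {
  co <- generate_cohort(cohort_spec(
    ki_iqr = c(cancer = 0, inflammatory = 0),
    vd_iqr = c(cancer = 0, inflammatory = 0),
    vb_iqr = c(cancer = 0, inflammatory = 0),
    noise_scale = 0, seed = 3))
  rec <- measure_cohort(co)
  # zero-spread groups legitimately trip the zero-variance warning of the
  # normality gate and fall through to the nonparametric branch
  summ <- suppressWarnings(summarize_cohort(rec))
  expect_equal(nrow(summ$table), 6)
  tab <- summ$table
  expect_equal(tab$cancer_median[tab$variable == "Ki_max"], 0.030,
               tolerance = 1e-6)
  expect_equal(tab$inflammatory_median[tab$variable == "Ki_max"], 0.020,
               tolerance = 1e-6)
  expect_equal(tab$cancer_median[tab$variable == "Vd_max"], 0.9,
               tolerance = 1e-6)
  expect_error(summarize_cohort(rec[rec$group == "cancer", ]), "empty group")
})

test_that("deterministic LBR link yields rho 1 and a paired difference", {
  co <- generate_cohort(cohort_spec(seed = 6, noise_scale = 0.02))
  rec <- measure_cohort(co)
  rec$LBR_ki <- 1.5 * rec$LBR_suv
  summ <- summarize_cohort(rec)
  expect_lt(summ$paired_lbr$p_value, 0.05)
  expect_equal(summ$spearman[["rho"]], 1)
})
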