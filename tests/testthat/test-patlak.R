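test_that("Patlak design evaluates the graphical regressors", {
  g <- seq(0, 45, by = 0.01)
  flat <- plasma_input(g, rep(1, length(g)))
  sched <- make_study_schedule()
  d <- patlak_design(flat, sched, 20)
  expect_equal(d$icp, d$t, tolerance = 1e-9)
  expect_equal(d$cp, rep(1, nrow(d)))
  expect_equal(sum(d$w), 1)
  expect_error(patlak_design(flat, sched, 60), "beyond")

  A1 <- 12; l1 <- 0.4; A2 <- 3; l2 <- 0.02
  cp <- plasma_input(g, A1 * exp(-l1 * g) + A2 * exp(-l2 * g))
  d2 <- patlak_design(cp, sched, 20)
  closed <- A1 / l1 * (1 - exp(-l1 * d2$t)) + A2 / l2 * (1 - exp(-l2 * d2$t))
  expect_equal(d2$icp, closed, tolerance = 1e-6)
})

test_that("macro-model curves are recovered to machine precision", {
  cp <- plasma_input_from_params(input_function_params(), t_max = 45)
  sched <- make_study_schedule()
  d <- patlak_design(cp, sched, 20)
  ct <- macro_patlak_curve(tissue_kinetics("macro", Ki = 0.03, Vd = 0.9),
                           cp, d$t)
  fit <- fit_patlak(ct, d)
  expect_equal(unname(coef(fit)), c(0.03, 0.9), tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  # blood-pool voxel: CT == Cp -> (0, 1)
  fit_blood <- fit_patlak(d$cp, d)
  expect_equal(unname(coef(fit_blood)), c(0, 1), tolerance = 1e-10)
})

test_that("patlak object supports the standard modelling verbs", {
  cp <- plasma_input_from_params(input_function_params(), t_max = 45)
  sched <- make_study_schedule()
  d <- patlak_design(cp, sched, 20)
  ct <- macro_patlak_curve(tissue_kinetics("macro", Ki = 0.02, Vd = 0.8),
                           cp, d$t)
  fit <- fit_patlak(ct + 0.01 * sin(seq_len(nrow(d))), d)
  expect_s3_class(fit, "patlak")
  expect_named(coef(fit), c("Ki", "Vd"))
  expect_equal(fitted(fit) + residuals(fit), ct + 0.01 * sin(seq_len(nrow(d))))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, newdata = data.frame(icp = 0, cp = 1)),
               coef(fit)[["Vd"]])
  s <- summary(fit)
  expect_true(all(s$coefficients[, "Std. Error"] >= 0))
  expect_output(print(fit), "Ki")
})

test_that("2TC curves yield the asymptotic macro-parameters at t* = 20", {
  cp_fun <- default_cp_fun()
  g <- seq(0, 45, by = 0.005)
  cp <- plasma_input(g, cp_fun(g))
  sched <- make_study_schedule()
  ct_fun <- stats::approxfun(g, solve_2tc_irreversible(
    tissue_kinetics("micro", K1 = 0.1, k2 = 0.15, k3 = 0.05, vb = 0.05),
    cp, g))
  frames <- sample_frames(ct_fun, sched)
  d <- patlak_design(cp, sched, 20)
  fit <- fit_patlak(frames[d$frame], d)
  expect_equal(coef(fit)[["Ki"]], 0.025, tolerance = 0.05)
  vd_asym <- 0.05 + 0.1 * 0.15 / (0.15 + 0.05)^2
  expect_equal(coef(fit)[["Vd"]], vd_asym, tolerance = 0.15)
})

test_that("fit matches the brute-force grid-search oracle", {
  set.seed(77)
  cp <- plasma_input_from_params(input_function_params(), t_max = 45)
  sched <- make_study_schedule()
  d <- patlak_design(cp, sched, 20)
  for (i in 1:20) {
    ki <- runif(1, 0, 0.06); vd <- runif(1, 0, 1.5)
    ct <- macro_patlak_curve(tissue_kinetics("macro", Ki = ki, Vd = vd),
                             cp, d$t)
    if (i > 10) ct <- pmax(ct + rnorm(length(ct), 0, 0.3), 0)  # noisy half
    ls <- coef(fit_patlak(ct, d))
    grid <- oracle_patlak_grid(ct, d)
    expect_equal(unname(ls), unname(grid), tolerance = 1e-4)
  }
})

test_that("degenerate designs are refused, scale leaves estimates invariant", {
  g <- seq(0, 45, by = 0.01)
  sched <- make_study_schedule()
  # Cp == 0 on the fit window makes both regressors collinear/degenerate
  dead <- plasma_input(g, c(seq(1, 0, length.out = 100),
                            rep(0, length(g) - 100)))
  dead_design <- patlak_design(dead, sched, 20)
  expect_error(fit_patlak(rep(1, nrow(dead_design)), dead_design),
               "degenerate")
  cp <- plasma_input_from_params(input_function_params(), t_max = 45)
  d <- patlak_design(cp, sched, 20)
  ct <- macro_patlak_curve(tissue_kinetics("macro", Ki = 0.02, Vd = 0.5),
                           cp, d$t) + 0.1
  f1 <- coef(fit_patlak(ct, d))
  d2 <- d; d2$icp <- 7 * d$icp; d2$cp <- 7 * d$cp
  f2 <- coef(fit_patlak(7 * ct, d2))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("Ki error shrinks as t* grows on noiseless 2TC data", {
  cp_fun <- default_cp_fun()
  g <- seq(0, 45, by = 0.005)
  cp <- plasma_input(g, cp_fun(g))
  sched <- make_study_schedule()
  ct_fun <- stats::approxfun(g, solve_2tc_irreversible(
    tissue_kinetics("micro", K1 = 0.1, k2 = 0.15, k3 = 0.05, vb = 0),
    cp, g))
  frames <- sample_frames(ct_fun, sched)
  errs <- vapply(c(12, 16, 20, 25, 30), function(ts) {
    d <- patlak_design(cp, sched, ts)
    abs(coef(fit_patlak(frames[d$frame], d))[["Ki"]] - 0.025)
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-12))
})

test_that("parametric maps recover labelwise truth and flag failures", {
  ph <- small_phantom(shape = c(16, 16, 16))
  cp <- phantom_true_input(ph)
  maps <- fit_patlak_map(ph, cp, 20)
  for (id in c(3L, 4L)) {
    tru <- ph$truth[[as.character(id)]]
    expect_equal(unique(round(maps$Ki_map[ph$labels == id], 10)), tru$Ki,
                 tolerance = 1e-8)
    expect_equal(unique(round(maps$Vd_map[ph$labels == id], 10)), tru$Vd,
                 tolerance = 1e-8)
  }
  ph0 <- ph
  ph0$activity[] <- 0
  maps0 <- fit_patlak_map(ph0, cp, 20)
  expect_true(all(maps0$Ki_map == 0))
  expect_true(all(maps0$Vd_map == 0))
  expect_true(all(maps0$qc_map == 0))
})

test_that("noisy maps keep labelwise medians near truth", {
  ph <- small_phantom(shape = c(16, 16, 16), noise_scale = 0.05, seed = 8)
  cp <- plasma_input_from_params(ph$params, t_max = 45)
  maps <- fit_patlak_map(ph, cp, 20)
  expect_equal(stats::median(maps$Ki_map[ph$labels == 3L]), 0.03,
               tolerance = 0.1)
})

test_that("SUV image is the dose-per-weight normalised static average", {
  ph <- small_phantom(shape = c(12, 12, 12))
  ph$activity[] <- 5.0
  suv <- static_suv_image(ph, c(20, 30), dose = 200, weight = 80)
  expect_equal(unique(as.vector(suv$volume)), 2.0)
  suv2 <- static_suv_image(ph, c(20, 30), dose = 400, weight = 80)
  expect_equal(suv2$volume, suv$volume / 2)
  ph$activity[] <- 0
  expect_equal(unique(as.vector(
    static_suv_image(ph, c(20, 30), 200, 80)$volume)), 0)
  expect_error(static_suv_image(ph, c(100, 110), 200, 80), "outside")
})
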