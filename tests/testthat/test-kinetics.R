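test_that("2TC solution matches the independent convolution oracle", {
  cp_fun <- default_cp_fun()
  t <- seq(0, 45, by = 0.25)
  sets <- list(c(0.1, 0.15, 0.05, 0),
               c(0.3, 0.5, 0.02, 0.05),
               c(0.8, 0.76, 0.0097, 0.05),
               c(0.05, 0.05, 0.1, 0.1))
  for (s in sets) {
    kin <- tissue_kinetics("micro", K1 = s[1], k2 = s[2], k3 = s[3],
                           vb = s[4])
    ct <- solve_2tc_irreversible(kin, cp_fun, t)
    ref <- oracle_2tc(s[1], s[2], s[3], s[4], cp_fun, t)
    expect_lt(max(abs(ct - ref)) / max(ref), 1e-4)
  }
})

test_that("2TC limiting cases behave analytically", {
  cp_fun <- default_cp_fun()
  t <- seq(0, 30, by = 0.5)
  zero <- solve_2tc_irreversible(
    tissue_kinetics("micro", K1 = 0, k2 = 0.2, k3 = 0.1), cp_fun, t)
  expect_equal(zero, rep(0, length(t)))
  # k2 = 0, constant input: pure accumulation K1 * t
  acc <- solve_2tc_irreversible(
    tissue_kinetics("micro", K1 = 0.1, k2 = 0, k3 = 0.3),
    function(t) rep(1, length(t)), t)
  expect_equal(acc, 0.1 * t, tolerance = 1e-7)
})

test_that("late Patlak slope of 2TC data converges to K1*k3/(k2+k3)", {
  cp_fun <- default_cp_fun()
  t <- seq(0, 60, by = 0.05)
  kin <- tissue_kinetics("micro", K1 = 0.1, k2 = 0.15, k3 = 0.05, vb = 0)
  ct <- oracle_2tc(0.1, 0.15, 0.05, 0, cp_fun, t)
  g <- seq(0, 60, by = 0.005)
  cp <- plasma_input(g, cp_fun(g))
  icp <- eval_plasma(cp, t, "cumint")
  late <- t > 40
  # no-intercept regression on the two graphical regressors
  slope <- stats::coef(stats::lm(ct[late] ~ 0 + icp[late] +
                                   eval_plasma(cp, t[late])))[1]
  expect_equal(unname(slope), 0.025, tolerance = 0.01)
  expect_equal(implied_ki(kin), 0.025)
})

test_that("macro Patlak curve is the exact graphical identity", {
  p <- input_function_params()
  cp <- plasma_input_from_params(p, t_max = 45)
  t <- seq(0, 44, by = 0.5)
  blood <- macro_patlak_curve(tissue_kinetics("macro", Ki = 0, Vd = 1), cp, t)
  expect_equal(blood, eval_plasma(cp, t))
  ramp <- macro_patlak_curve(tissue_kinetics("macro", Ki = 0.03, Vd = 0),
                             function(t) rep(1, length(t)), t)
  expect_equal(ramp, 0.03 * t, tolerance = 1e-8)
})

test_that("frame sampling averages the curve over each frame", {
  sched <- frame_schedule(c(0, 10), c(10, 5))
  expect_equal(sample_frames(function(t) rep(3.2, length(t)), sched),
               c(3.2, 3.2))
  ramp <- sample_frames(function(t) t, frame_schedule(0, 10))
  expect_equal(ramp, 5.0)
  dec <- sample_frames(function(t) exp(-t), frame_schedule(0, 1),
                       n_sub = 512)
  expect_equal(dec, 1 - exp(-1), tolerance = 1e-6)
})

test_that("frame noise is seeded, duration-scaled and clipped", {
  sched <- make_study_schedule(2, 5, 5, 35)
  frames <- sample_frames(default_cp_fun(), sched)
  expect_identical(add_noise(frames, sched, 0, seed = 3), frames)
  n1 <- add_noise(frames, sched, 0.05, seed = 42)
  n2 <- add_noise(frames, sched, 0.05, seed = 42)
  expect_identical(n1, n2)
  expect_false(identical(n1, add_noise(frames, sched, 0.05, seed = 43)))
  expect_true(all(n1 >= 0))
  expect_error(add_noise(frames, sched, -1, seed = 1), ">= 0")
  # Monte-Carlo: sd of unit-value, unit-duration frames ~ noise_scale
  one <- frame_schedule(0, 1)
  reps <- add_noise(matrix(1, 1e4, 1), one, 0.05, seed = 9)
  expect_equal(stats::sd(reps), 0.05, tolerance = 0.05)
})
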