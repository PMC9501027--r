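with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# sdlog of a log-normal with given median and interquartile range:
# IQR = m (e^{z s} - e^{-z s}) with z = qnorm(0.75), so s = asinh(IQR/2m)/z
lnorm_sdlog <- function(median, iqr) asinh(iqr / (2 * median)) / stats::qnorm(0.75)

#' Specification of a synthetic lesion cohort
#'
#' Describes the two-group lesion cohort the simulator draws: group sizes and
#' per-group log-normal distributions of the true net influx rate Ki and
#' apparent distribution volume Vd, parameterised by median and interquartile
#' range (IQR). Defaults reproduce the shape of the clinical cohort the
#' package emulates: 60 cancer and 17 inflammatory/infectious lesions with
#' cancer Ki median 3.0e-2 (IQR 2.2e-2) vs inflammatory 2.0e-2 (IQR 1.1e-2)
#' mL/min/mL, Vd 0.9 (IQR 0.5) vs 0.7 (IQR 0.4) mL/mL, a fractional blood
#' volume around 0.05, and normal-liver kinetics Ki 1.0e-2, Vd 1.1.
#'
#' @param n_cancer,n_inflammatory group sizes (>= 0).
#' @param ki_median,ki_iqr named length-2 vectors (\code{cancer},
#'   \code{inflammatory}) of true-Ki medians and IQRs, mL/min/mL.
#' @param vd_median,vd_iqr likewise for Vd, mL/mL.
#' @param vb_median,vb_iqr likewise for the fractional blood volume.
#' @param liver [tissue_kinetics()] of the liver reference tissue.
#' @param noise_scale frame-noise magnitude (see [add_noise()]).
#' @param seed integer RNG seed.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_cancer = 60, n_inflammatory = 17,
                        ki_median = c(cancer = 0.030, inflammatory = 0.020),
                        ki_iqr = c(cancer = 0.022, inflammatory = 0.011),
                        vd_median = c(cancer = 0.9, inflammatory = 0.7),
                        vd_iqr = c(cancer = 0.5, inflammatory = 0.4),
                        vb_median = c(cancer = 0.05, inflammatory = 0.05),
                        vb_iqr = c(cancer = 0.02, inflammatory = 0.02),
                        liver = tissue_kinetics("macro", Ki = 0.010, Vd = 1.1),
                        noise_scale = 0.05, seed = 1) {
  stopifnot(n_cancer >= 0, n_inflammatory >= 0,
            all(ki_median > 0), all(vd_median > 0),
            all(ki_iqr >= 0), all(vd_iqr >= 0), noise_scale >= 0)
  structure(list(n_cancer = n_cancer, n_inflammatory = n_inflammatory,
                 ki_median = ki_median, ki_iqr = ki_iqr,
                 vd_median = vd_median, vd_iqr = vd_iqr,
                 vb_median = vb_median, vb_iqr = vb_iqr,
                 liver = liver, noise_scale = noise_scale, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic lesion cohort
#'
#' Draws per-lesion true (Ki, Vd) log-normally around the group medians of a
#' [cohort_spec()] (zero IQR collapses a group onto its median), synthesises
#' each lesion's frame-sampled Patlak-linear time-activity curve and a liver
#' reference curve under a shared plasma input, and adds duration-scaled
#' noise. The measured apparent distribution volume includes the blood
#' contribution, so the drawn Vd is used directly as the Patlak intercept;
#' the drawn fractional blood volume is retained as truth metadata. Bitwise
#' reproducible for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param params [input_function_params()] of the shared plasma input.
#' @param schedule [frame_schedule()] of the simulated dynamic acquisition.
#' @param static_window length-2 minutes: the clinical static acquisition
#'   window simulated for SUV measurement (default 60-70 min
#'   post-injection).
#' @return An object of class \code{"lesion_cohort"}: list with
#'   \code{records} (data frame: lesion_id, group, true_Ki, true_Vd,
#'   true_vb), \code{tacs} (lesions x frames matrix, kBq/mL),
#'   \code{liver_tac}, \code{static} and \code{liver_static} (simulated
#'   static-window activities, kBq/mL), \code{static_window},
#'   \code{schedule}, \code{params}, \code{spec}.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            params = input_function_params(),
                            schedule = make_study_schedule(),
                            static_window = c(60, 70)) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cancer + spec$n_inflammatory
  group <- rep(c("cancer", "inflammatory"),
               c(spec$n_cancer, spec$n_inflammatory))
  draw <- function(med, iqr, grp) {
    s <- ifelse(iqr[grp] > 0, lnorm_sdlog(med[grp], iqr[grp]), 0)
    stats::rlnorm(length(grp), meanlog = log(med[grp]), sdlog = s)
  }
  t_end <- max(schedule$start + schedule$duration)
  cp <- plasma_input_from_params(params,
                                 t_max = max(t_end, static_window[2]) + 1,
                                 grid_step = 0.005)
  avg_cp <- sample_frames(cp, schedule)
  avg_icp <- sample_frames(function(t) eval_plasma(cp, t, "cumint"), schedule)
  static_sched <- frame_schedule(static_window[1], diff(static_window),
                                 "static")
  st_cp <- sample_frames(cp, static_sched)
  st_icp <- sample_frames(function(t) eval_plasma(cp, t, "cumint"),
                          static_sched)
  res <- with_seed(spec$seed, {
    ki <- draw(spec$ki_median, spec$ki_iqr, group)
    vd <- draw(spec$vd_median, spec$vd_iqr, group)
    vb <- draw(spec$vb_median, spec$vb_iqr, group)
    tacs <- outer(ki, avg_icp) + outer(vd, avg_cp)
    tacs <- add_noise(tacs, schedule, spec$noise_scale,
                      seed = spec$seed + 1L)
    static <- matrix(ki * st_icp + vd * st_cp, ncol = 1)
    static <- add_noise(static, static_sched, spec$noise_scale,
                        seed = spec$seed + 3L)
    liver <- spec$liver$Ki * avg_icp + spec$liver$Vd * avg_cp
    liver <- add_noise(liver, schedule, spec$noise_scale,
                       seed = spec$seed + 2L)
    liver_static <- add_noise(spec$liver$Ki * st_icp + spec$liver$Vd * st_cp,
                              static_sched, spec$noise_scale,
                              seed = spec$seed + 4L)
    list(ki = ki, vd = vd, vb = vb, tacs = tacs, liver = liver,
         static = as.vector(static), liver_static = liver_static)
  })
  records <- data.frame(
    lesion_id = if (n > 0) sprintf("L%03d", seq_len(n)) else character(0),
    group = group,
    true_Ki = res$ki, true_Vd = res$vd, true_vb = res$vb,
    stringsAsFactors = FALSE
  )
  structure(list(records = records, tacs = res$tacs, liver_tac = res$liver,
                 static = res$static, liver_static = res$liver_static,
                 static_window = static_window,
                 schedule = schedule, params = params, spec = spec),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  tab <- table(x$records$group)
  cat(sprintf("Synthetic lesion cohort: %d lesions (%s), %d frames, noise %.3g, seed %d\n",
              nrow(x$records),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$schedule), x$spec$noise_scale, x$spec$seed))
  invisible(x)
}
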