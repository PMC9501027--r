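#' Build the Patlak regressor table
#'
#' The Patlak graphical model for irreversible tracers is
#' \deqn{C_T(t) = K_i \int_0^t C_p(s)\,ds + V_d\, C_p(t), \qquad t \ge t^*,}
#' linear in the two regressors once the transient has decayed (t past
#' \eqn{t^*}). For every frame mid-time at or past \code{t_star} this returns
#' the regressor pair evaluated from the cached running integral, together
#' with fit weights proportional to frame duration (normalised to sum to 1)
#' --- the variance of a reconstructed frame mean scales inversely with its
#' duration.
#'
#' @param Cp a [plasma_input()].
#' @param schedule a [frame_schedule()].
#' @param t_star start of the Patlak-linear window, minutes (default 20).
#' @param average how to evaluate the regressors per retained frame:
#'   \code{"midpoint"} (point values at the frame mid-time, matching
#'   instantaneous tissue samples) or \code{"frame"} (time-averages over the
#'   frame, matching frame-mode acquisition where the measured value is the
#'   frame average). Voxelwise and cohort fits use \code{"frame"}.
#' @return Data frame with columns \code{t} (mid-times), \code{icp}
#'   (\eqn{\int_0^t C_p}), \code{cp}, \code{w} and \code{frame} (row index
#'   into the schedule).
#' @export
patlak_design <- function(Cp, schedule, t_star = 20,
                          average = c("midpoint", "frame")) {
  stopifnot(inherits(Cp, "plasma_input"), inherits(schedule, "frame_schedule"))
  average <- match.arg(average)
  if (t_star > max(schedule$mid)) stop("t_star lies beyond the last frame")
  keep <- which(schedule$mid >= t_star)
  if (length(keep) < 2) stop("need at least 2 frames at t >= t_star")
  t <- schedule$mid[keep]
  w <- schedule$duration[keep]
  if (average == "midpoint") {
    icp <- eval_plasma(Cp, t, "cumint")
    cp <- eval_plasma(Cp, t, "Cp")
  } else {
    sub <- frame_schedule(schedule$start[keep], schedule$duration[keep],
                          schedule$bed[keep])
    icp <- sample_frames(function(u) eval_plasma(Cp, u, "cumint"), sub)
    cp <- sample_frames(Cp, sub)
  }
  data.frame(t = t, icp = icp, cp = cp, w = w / sum(w), frame = keep)
}

patlak_normal_equations <- function(design) {
  w <- design$w; x1 <- design$icp; x2 <- design$cp
  A <- matrix(c(sum(w * x1 * x1), sum(w * x1 * x2),
                sum(w * x1 * x2), sum(w * x2 * x2)), 2, 2)
  scale <- sqrt(diag(A))
  if (any(scale == 0) ||
      abs(det(A / tcrossprod(scale))) < 1e-12)
    stop("degenerate design: Patlak regressors are collinear")
  A
}

#' Fit the Patlak model to a tissue time-activity curve
#'
#' Weighted multilinear regression of the frame activities on the Patlak
#' regressors: \eqn{(K_i, V_d)} minimise
#' \eqn{\sum_k w_k (C_T(t_k) - K_i \int_0^{t_k} C_p - V_d C_p(t_k))^2},
#' solved in closed form from the 2x2 weighted normal equations. The
#' regression is run in undivided form (response \eqn{C_T}, regressors
#' \eqn{\int C_p} and \eqn{C_p}) rather than on the divided Patlak-plot
#' coordinates: the model is identical but dividing by \eqn{C_p} would
#' amplify noise. Estimates are not constrained to be non-negative; negative
#' values are reported as estimated.
#'
#' @param tissue frame activities aligned with the design rows (one value per
#'   row of \code{design}), kBq/mL.
#' @param design a [patlak_design()] table.
#' @return An object of class \code{"patlak"} with components
#'   \code{coefficients} (named \code{Ki}, \code{Vd}), \code{fitted.values},
#'   \code{residuals}, \code{r.squared} (on weighted residuals),
#'   \code{weighted_residual_norm}, \code{design}, \code{t_star},
#'   \code{n_points_used}.
#' @examples
#' cp <- plasma_input_from_params(input_function_params(), t_max = 45)
#' sched <- make_study_schedule()
#' ct <- macro_patlak_curve(tissue_kinetics("macro", Ki = 0.03, Vd = 0.9),
#'                          cp, sched$mid)
#' fit <- fit_patlak(ct[sched$mid >= 20], patlak_design(cp, sched, 20))
#' coef(fit)
#' @export
fit_patlak <- function(tissue, design) {
  stopifnot(length(tissue) == nrow(design))
  A <- patlak_normal_equations(design)
  w <- design$w
  b <- c(sum(w * design$icp * tissue), sum(w * design$cp * tissue))
  beta <- solve(A, b)
  fitted <- beta[1] * design$icp + beta[2] * design$cp
  res <- tissue - fitted
  ss_res <- sum(w * res^2)
  ybar <- sum(w * tissue) / sum(w)
  ss_tot <- sum(w * (tissue - ybar)^2)
  structure(list(coefficients = c(Ki = beta[1], Vd = beta[2]),
                 fitted.values = fitted, residuals = res,
                 r.squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 weighted_residual_norm = sqrt(ss_res),
                 design = design, t_star = min(design$t),
                 n_points_used = nrow(design)),
            class = "patlak")
}

#' @export
print.patlak <- function(x, ...) {
  cat("Patlak graphical fit\n")
  cat(sprintf("  Ki = %.4g mL/min/mL (%.3g x 10^-2)\n",
              x$coefficients[["Ki"]], 100 * x$coefficients[["Ki"]]))
  cat(sprintf("  Vd = %.4g mL/mL\n", x$coefficients[["Vd"]]))
  cat(sprintf("  %d frames from t = %.1f min, weighted R^2 = %.4f\n",
              x$n_points_used, x$t_star, x$r.squared))
  invisible(x)
}

#' @export
coef.patlak <- function(object, ...) object$coefficients

#' @export
fitted.patlak <- function(object, ...) object$fitted.values

#' @export
residuals.patlak <- function(object, ...) object$residuals

#' Predict tissue activity from a Patlak fit
#'
#' @param object a [fit_patlak()] result.
#' @param newdata optional data frame with columns \code{icp} and \code{cp};
#'   defaults to the fitted design.
#' @param ... unused.
#' @return Predicted tissue activity, kBq/mL.
#' @export
predict.patlak <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  stopifnot(all(c("icp", "cp") %in% names(newdata)))
  object$coefficients[["Ki"]] * newdata$icp +
    object$coefficients[["Vd"]] * newdata$cp
}

#' @export
summary.patlak <- function(object, ...) {
  d <- object$design
  n <- nrow(d)
  # weighted residual variance with 2 fitted parameters
  s2 <- sum(d$w * object$residuals^2) * n / max(n - 2, 1)
  A <- patlak_normal_equations(d)
  se <- sqrt(pmax(diag(solve(A)) * s2 / n, 0))
  out <- list(coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = se),
              r.squared = object$r.squared,
              n_points_used = object$n_points_used,
              t_star = object$t_star)
  class(out) <- "summary.patlak"
  out
}

#' @export
print.summary.patlak <- function(x, ...) {
  cat("Patlak graphical fit (weighted multilinear regression)\n\n")
  stats::printCoefmat(x$coefficients)
  cat(sprintf("\n%d frames from t* = %.1f min, weighted R^2 = %.4f\n",
              x$n_points_used, x$t_star, x$r.squared))
  invisible(x)
}

#' Patlak plot of a fitted curve
#'
#' Displays the fit in the classical divided Patlak coordinates: normalised
#' time \eqn{\int_0^t C_p / C_p} against normalised activity \eqn{C_T/C_p},
#' where the model is a straight line with slope Ki and intercept Vd.
#'
#' @param x a [fit_patlak()] result.
#' @param ... passed to [plot()].
#' @export
plot.patlak <- function(x, ...) {
  d <- x$design
  ct <- x$fitted.values + x$residuals
  px <- d$icp / d$cp
  py <- ct / d$cp
  graphics::plot(px, py, xlab = "normalised time  ∫Cp / Cp  (min)",
                 ylab = "CT / Cp", main = "Patlak plot", ...)
  graphics::abline(a = x$coefficients[["Vd"]], b = x$coefficients[["Ki"]])
  invisible(x)
}

#' Voxelwise Patlak parametric maps
#'
#' Runs the closed-form weighted Patlak regression at every voxel of a
#' dynamic volume, vectorised over voxels (the normal-equation matrix is
#' shared; only the right-hand sides differ, so results are independent of
#' evaluation order). Voxels whose fit fails or is undefined (non-finite
#' estimates, undefined R^2) are set to 0 with quality-control value 0.
#'
#' @param phantom a [build_phantom()] result (supplies the 4D data and
#'   schedule).
#' @param Cp a [plasma_input()] on the same time base.
#' @param t_star start of the Patlak window, minutes.
#' @return An object of class \code{"parametric_maps"}: list with 3D arrays
#'   \code{Ki_map} (mL/min/mL), \code{Vd_map} (mL/mL), \code{qc_map}
#'   (weighted R^2, 0 for failed voxels), plus \code{t_star} and
#'   \code{voxel_size}.
#' @export
fit_patlak_map <- function(phantom, Cp, t_star = 20) {
  stopifnot(inherits(phantom, "dynamic_phantom"))
  design <- patlak_design(Cp, phantom$schedule, t_star, average = "frame")
  d <- dim(phantom$activity)
  Y <- matrix(phantom$activity, ncol = d[4])[, design$frame, drop = FALSE]
  A <- patlak_normal_equations(design)
  X <- cbind(design$icp, design$cp)
  B <- crossprod(X * design$w, t(Y))          # 2 x n_vox
  beta <- solve(A, B)
  fitted <- X %*% beta                         # n_frames x n_vox
  res <- t(Y) - fitted
  ss_res <- colSums(design$w * res^2)
  ybar <- colSums(design$w * t(Y)) / sum(design$w)
  ss_tot <- colSums(design$w * (t(Y) - rep(ybar, each = nrow(X)))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  ki <- beta[1, ]; vd <- beta[2, ]
  bad <- !is.finite(ki) | !is.finite(vd)
  ki[bad] <- 0; vd[bad] <- 0
  r2[bad | !is.finite(r2)] <- 0
  structure(list(Ki_map = array(ki, d[1:3]), Vd_map = array(vd, d[1:3]),
                 qc_map = array(r2, d[1:3]), t_star = t_star,
                 voxel_size = phantom$voxel_size),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("Patlak parametric maps (%s voxels, t* = %.1f min)\n",
              paste(dim(x$Ki_map), collapse = " x "), x$t_star))
  cat(sprintf("  Ki range: [%.4g, %.4g] mL/min/mL; Vd range: [%.4g, %.4g] mL/mL\n",
              min(x$Ki_map), max(x$Ki_map), min(x$Vd_map), max(x$Vd_map)))
  invisible(x)
}

#' Static SUV image from a dynamic volume
#'
#' Time-averages the activity over a static window and normalises by
#' injected activity per body weight:
#' \eqn{SUV = C\,[kBq/mL] / (dose\,[kBq] / weight\,[g])}, unit g/mL. Frames
#' are weighted by their overlap with the window.
#'
#' @param phantom a [build_phantom()] result.
#' @param window length-2 minutes (start, end); must overlap the schedule.
#' @param dose injected activity, MBq.
#' @param weight body weight, kg.
#' @return An object of class \code{"suv_image"}: list with \code{volume}
#'   (3D, g/mL) and \code{window}.
#' @export
static_suv_image <- function(phantom, window, dose, weight) {
  stopifnot(inherits(phantom, "dynamic_phantom"),
            length(window) == 2, window[2] > window[1])
  if (dose <= 0 || weight <= 0) stop("dose and weight must be positive")
  sched <- phantom$schedule
  overlap <- pmax(0, pmin(sched$start + sched$duration, window[2]) -
                     pmax(sched$start, window[1]))
  if (sum(overlap) == 0) stop("window outside the acquired time span")
  d <- dim(phantom$activity)
  m <- matrix(phantom$activity, ncol = d[4])
  conc <- as.vector(m %*% overlap) / sum(overlap)
  suv <- conc * weight / dose  # (kBq/mL) / (dose*1000 kBq / weight*1000 g)
  structure(list(volume = array(suv, d[1:3]), window = window),
            class = "suv_image")
}
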