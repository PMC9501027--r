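#' Tissue kinetic parameters
#'
#' Kinetics of one tissue class, in one of two modes. \emph{micro}: the rate
#' constants of the irreversible two-tissue compartment (2TC) model --- K1
#' (plasma to tissue, mL/min/mL), k2 (tissue to plasma, 1/min), k3
#' (phosphorylation, 1/min, irreversible) and the fractional blood volume vb.
#' \emph{macro}: the Patlak macro-parameters Ki (net influx rate, mL/min/mL)
#' and Vd (apparent distribution volume, mL/mL), for which the tissue curve is
#' exactly Patlak-linear. Mode \emph{blood} marks a blood-pool region whose
#' voxels follow the whole-blood curve.
#'
#' In micro mode the implied macro slope is \eqn{K_i = K_1 k_3/(k_2+k_3)}.
#'
#' @param mode \code{"micro"}, \code{"macro"} or \code{"blood"}.
#' @param K1,k2,k3 2TC rate constants (micro mode), all >= 0.
#' @param vb fractional blood volume in [0, 1].
#' @param Ki,Vd Patlak macro-parameters (macro mode), >= 0.
#' @return An object of class \code{"tissue_kinetics"}.
#' @export
tissue_kinetics <- function(mode = c("macro", "micro", "blood"),
                            K1 = NULL, k2 = NULL, k3 = NULL, vb = 0,
                            Ki = NULL, Vd = NULL) {
  mode <- match.arg(mode)
  if (mode == "micro") {
    stopifnot(!is.null(K1), !is.null(k2), !is.null(k3))
    if (K1 < 0 || k2 < 0 || k3 < 0) stop("rate constants must be >= 0")
    if (vb < 0 || vb > 1) stop("vb must be in [0, 1]")
    obj <- list(mode = mode, K1 = K1, k2 = k2, k3 = k3, vb = vb)
  } else if (mode == "macro") {
    stopifnot(!is.null(Ki), !is.null(Vd))
    if (Ki < 0 || Vd < 0) stop("Ki and Vd must be >= 0")
    obj <- list(mode = mode, Ki = Ki, Vd = Vd)
  } else {
    obj <- list(mode = mode)
  }
  structure(obj, class = "tissue_kinetics")
}

#' Net influx rate implied by micro-parameters
#'
#' @param kin a micro-mode [tissue_kinetics()] object.
#' @return \eqn{K_1 k_3/(k_2+k_3)} (0 when \eqn{k_2+k_3=0} and \eqn{k_3=0}).
#' @export
implied_ki <- function(kin) {
  stopifnot(inherits(kin, "tissue_kinetics"), kin$mode == "micro")
  if (kin$k2 + kin$k3 == 0) return(if (kin$k3 > 0) kin$K1 else 0)
  kin$K1 * kin$k3 / (kin$k2 + kin$k3)
}

as_time_function <- function(curve) {
  if (is.function(curve)) return(curve)
  if (inherits(curve, "plasma_input")) {
    t_hi <- max(curve$grid)
    # clamp: ODE solvers may probe marginally outside the tabulated span
    return(function(t) eval_plasma(curve, pmin(pmax(t, 0), t_hi)))
  }
  if (is.list(curve) && all(c("t", "y") %in% names(curve)))
    return(stats::approxfun(curve$t, curve$y, rule = 2))
  stop("curve must be a function, a plasma_input, or a list(t, y)")
}

#' Solve the irreversible 2TC model
#'
#' Integrates the standard irreversible two-tissue compartment ODEs
#' \deqn{dC_1/dt = K_1 C_p - (k_2+k_3) C_1, \qquad dC_2/dt = k_3 C_1,}
#' with the measured tissue activity
#' \eqn{C_T = C_1 + C_2 + v_b C_p} (the plasma curve serves as the
#' whole-blood proxy for the vascular term). Integration uses lsoda with
#' tight tolerances.
#'
#' @param kin a micro-mode [tissue_kinetics()] object.
#' @param Cp plasma input: a [plasma_input()], a function of minutes, or a
#'   \code{list(t, y)}.
#' @param t output time grid, minutes, increasing, starting at >= 0.
#' @return Tissue activity \eqn{C_T(t)} in kBq/mL on \code{t}.
#' @export
solve_2tc_irreversible <- function(kin, Cp, t) {
  stopifnot(inherits(kin, "tissue_kinetics"), kin$mode == "micro")
  cp_fun <- as_time_function(Cp)
  tt <- if (t[1] > 0) c(0, t) else t
  deriv <- function(time, state, parms) {
    cp <- cp_fun(time)
    list(c(parms[["K1"]] * cp - (parms[["k2"]] + parms[["k3"]]) * state[1],
           parms[["k3"]] * state[1]))
  }
  sol <- deSolve::lsoda(c(C1 = 0, C2 = 0), tt, deriv,
                        c(K1 = kin$K1, k2 = kin$k2, k3 = kin$k3),
                        rtol = 1e-10, atol = 1e-10)
  ct <- sol[, "C1"] + sol[, "C2"] + kin$vb * cp_fun(tt)
  pmax(if (t[1] > 0) ct[-1] else ct, 0)
}

#' Patlak-linear tissue curve from macro-parameters
#'
#' The exact Patlak identity
#' \eqn{C_T(t) = K_i \int_0^t C_p(s)\,ds + V_d\, C_p(t)}; feeding the result
#' back through [fit_patlak()] recovers (Ki, Vd) to machine precision.
#'
#' @param kin a macro-mode [tissue_kinetics()] object.
#' @param Cp plasma input (as in [solve_2tc_irreversible()]).
#' @param t output time grid, minutes.
#' @return Tissue activity on \code{t}, kBq/mL.
#' @export
macro_patlak_curve <- function(kin, Cp, t) {
  stopifnot(inherits(kin, "tissue_kinetics"), kin$mode == "macro")
  if (inherits(Cp, "plasma_input")) {
    kin$Ki * eval_plasma(Cp, t, "cumint") + kin$Vd * eval_plasma(Cp, t, "Cp")
  } else {
    cp_fun <- as_time_function(Cp)
    icp <- vapply(t, function(u)
      stats::integrate(cp_fun, 0, u, rel.tol = 1e-10,
                       subdivisions = 1000L)$value, numeric(1))
    kin$Ki * icp + kin$Vd * cp_fun(t)
  }
}

#' Average a continuous curve over acquisition frames
#'
#' Each frame value is the time-average of the curve over
#' \code{[start, start + duration]}, computed by the trapezoidal rule on at
#' least 32 sub-samples per frame --- the discrete analogue of frame-mode
#' acquisition of a decay-corrected signal.
#'
#' @param curve a function of minutes, a [plasma_input()], or \code{list(t, y)}.
#' @param schedule a [frame_schedule()].
#' @param n_sub sub-samples per frame (minimum 32).
#' @return Numeric vector of frame activities.
#' @export
sample_frames <- function(curve, schedule, n_sub = 32L) {
  stopifnot(inherits(schedule, "frame_schedule"))
  n_sub <- max(32L, as.integer(n_sub))
  f <- as_time_function(curve)
  vapply(seq_len(nrow(schedule)), function(k) {
    tt <- seq(schedule$start[k], schedule$start[k] + schedule$duration[k],
              length.out = n_sub + 1L)
    y <- f(tt)
    sum((y[-1] + y[-length(y)]) / 2) / n_sub
  }, numeric(1))
}

#' Add duration-scaled Gaussian noise to frame activities
#'
#' A count-statistics proxy for reconstructed-image noise: additive zero-mean
#' Gaussian with standard deviation
#' \eqn{\sigma_k = s\sqrt{\max(y_k, floor)/\Delta t_k}}, so the variance is
#' inversely proportional to frame duration. Output is clipped at zero.
#' Deterministic under a fixed seed; the seed is a mandatory argument, never
#' global state.
#'
#' @param frames non-negative frame activities (vector or matrix with one row
#'   per curve and one column per frame).
#' @param schedule the [frame_schedule()] the frames were sampled on.
#' @param noise_scale noise magnitude s >= 0 (0 returns the input unchanged).
#' @param seed integer RNG seed.
#' @param floor lower bound used inside the square root (stabilises the
#'   variance of near-zero frames).
#' @return Noisy frames, same shape as \code{frames}.
#' @export
add_noise <- function(frames, schedule, noise_scale, seed, floor = 0.1) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (any(frames < 0)) stop("frames must be non-negative")
  if (noise_scale == 0) return(frames)
  dur <- schedule$duration
  if (is.matrix(frames)) {
    stopifnot(ncol(frames) == nrow(schedule))
    dur <- matrix(dur, nrow(frames), ncol(frames), byrow = TRUE)
  } else {
    stopifnot(length(frames) == nrow(schedule))
  }
  sd <- noise_scale * sqrt(pmax(frames, floor) / dur)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noisy <- frames + stats::rnorm(length(frames)) * sd
  pmax(noisy, 0)
}
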