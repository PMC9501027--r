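#' Plasma input-function shape parameters
#'
#' The simulated arterial plasma curve is a triangular bolus rising linearly
#' from zero to \code{peak_amplitude} at \code{peak_time}, followed by a
#' double-exponential washout. The tail is specified by relative amplitudes
#' \code{A1}, \code{A2} and decay rates \code{lambda1 > lambda2 > 0} and is
#' rescaled so the curve is continuous at the peak, i.e.
#' \deqn{C_p(t) = \frac{peak}{A_1+A_2}\left(A_1 e^{-\lambda_1(t-t_p)} +
#'       A_2 e^{-\lambda_2(t-t_p)}\right), \quad t \ge t_p.}
#'
#' Defaults give a bolus peaking at 30 s with a fast-clearing component
#' (half-life ~35 s) and a slow metabolic tail, a shape typical of
#' intravenous FDG injection. All activities are decay-corrected to injection
#' time, so no physical-decay term appears.
#'
#' @param A1,A2 relative tail amplitudes (> 0).
#' @param lambda1,lambda2 tail decay rates, 1/min; \code{lambda1 > lambda2 > 0}.
#' @param peak_time bolus peak time, minutes (> 0).
#' @param peak_amplitude bolus peak activity, kBq/mL (> 0).
#' @return An object of class \code{"input_function_params"}.
#' @export
input_function_params <- function(A1 = 0.9, A2 = 0.1,
                                  lambda1 = 1.2, lambda2 = 0.012,
                                  peak_time = 0.5, peak_amplitude = 100) {
  stopifnot(A1 > 0, A2 > 0, peak_time > 0, peak_amplitude > 0)
  if (!(lambda1 >= lambda2 && lambda2 > 0))
    stop("decay rates must satisfy lambda1 >= lambda2 > 0")
  structure(list(A1 = A1, A2 = A2, lambda1 = lambda1, lambda2 = lambda2,
                 peak_time = peak_time, peak_amplitude = peak_amplitude),
            class = "input_function_params")
}

#' Evaluate the simulated plasma curve
#'
#' @param params an [input_function_params()] object.
#' @param t non-negative, increasing time grid in minutes.
#' @return Plasma activity Cp(t) in kBq/mL, non-negative.
#' @export
plasma_curve <- function(params, t) {
  stopifnot(inherits(params, "input_function_params"))
  if (any(t < 0)) stop("time grid must be non-negative")
  scale <- params$peak_amplitude / (params$A1 + params$A2)
  tau <- t - params$peak_time
  out <- ifelse(
    t <= params$peak_time,
    params$peak_amplitude * t / params$peak_time,
    scale * (params$A1 * exp(-params$lambda1 * tau) +
             params$A2 * exp(-params$lambda2 * tau))
  )
  pmax(out, 0)
}

cum_trapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Discretized plasma input function
#'
#' Container for a plasma activity curve Cp(t) on a fine uniform grid, with
#' its running time-integral cached (the Patlak regressor
#' \eqn{\int_0^t C_p}). Optionally carries the fitted double-exponential tail
#' parameters.
#'
#' @param grid uniform, increasing time grid in minutes starting at 0.
#' @param Cp plasma activity in kBq/mL, same length as \code{grid}, >= 0.
#' @param tail_params optional named vector \code{c(A1, lambda1, A2, lambda2)}
#'   of the fitted absolute-time tail model.
#' @return An object of class \code{"plasma_input"} with elements
#'   \code{grid}, \code{Cp}, \code{cumint} and \code{tail_params}.
#' @seealso [plasma_input_from_params()], [assemble_input_function()]
#' @export
plasma_input <- function(grid, Cp, tail_params = NULL) {
  stopifnot(length(grid) == length(Cp), length(grid) >= 2)
  if (grid[1] != 0) stop("grid must start at t = 0")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  if (any(Cp < 0)) stop("Cp must be non-negative")
  structure(list(grid = grid, Cp = Cp, cumint = cum_trapz(grid, Cp),
                 tail_params = tail_params),
            class = "plasma_input")
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf("Plasma input function: %d samples on [0, %.2f] min, peak %.2f kBq/mL\n",
              length(x$grid), max(x$grid), max(x$Cp)))
  cat(sprintf("  integral to end of grid: %.2f kBq*min/mL\n",
              x$cumint[length(x$cumint)]))
  if (!is.null(x$tail_params))
    cat(sprintf("  tail: %.3g exp(-%.3g t) + %.3g exp(-%.3g t)\n",
                x$tail_params[["A1"]], x$tail_params[["lambda1"]],
                x$tail_params[["A2"]], x$tail_params[["lambda2"]]))
  invisible(x)
}

#' Tabulate the analytic plasma model on a fine grid
#'
#' @param params an [input_function_params()] object.
#' @param t_max end of the grid, minutes.
#' @param grid_step grid spacing, minutes.
#' @return A [plasma_input()] object.
#' @export
plasma_input_from_params <- function(params, t_max = 70, grid_step = 0.01) {
  grid <- seq(0, t_max, by = grid_step)
  plasma_input(grid, plasma_curve(params, grid))
}

#' Evaluate Cp or its running integral at arbitrary times
#'
#' Linear interpolation on the cached grid; \code{what = "cumint"} returns
#' \eqn{\int_0^t C_p}.
#'
#' @param Cp a [plasma_input()] object.
#' @param t times in minutes, within the grid span.
#' @param what \code{"Cp"} or \code{"cumint"}.
#' @return Numeric vector.
#' @export
eval_plasma <- function(Cp, t, what = c("Cp", "cumint")) {
  stopifnot(inherits(Cp, "plasma_input"))
  what <- match.arg(what)
  if (any(t < 0) || any(t > max(Cp$grid) + 1e-9))
    stop("evaluation times outside the input-function grid")
  y <- if (what == "Cp") Cp$Cp else Cp$cumint
  stats::approx(Cp$grid, y, xout = pmin(t, max(Cp$grid)), rule = 2)$y
}
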