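#' Closed-loop transfer-function coefficients of the continuous model
#'
#' The closed loop from the ATM input to the p53 output is second order,
#' \deqn{G(s) = \frac{p_{xy} p_{yz}}{s^2 + (p_y + p_z) s +
#'   (p_y p_z + p_{yz} p_{zy})}.}
#'
#' @param params a [continuous_params()] object (or coercible list).
#' @return Named numeric vector `c(gain, b, c)` with
#'   `G(s) = gain / (s^2 + b s + c)`.
#' @export
#' @examples
#' closed_loop_coeffs(continuous_params())
closed_loop_coeffs <- function(params) {
  p <- as_continuous_params(params)
  c(gain = p$p_xy * p$p_yz,
    b = p$p_y + p$p_z,
    c = p$p_y * p$p_z + p$p_yz * p$p_zy)
}

#' Steady-state error to a unit step disturbance on p53
#'
#' Final-value-theorem limit of the loop error signal when a sustained unit
#' step disturbance is injected on p53:
#' \deqn{e_\infty = \frac{p_{zy} p_y}{p_y p_z + p_{yz} p_{zy}}.}
#' Strictly decreasing in both `p_yz` (feedback strength) and `p_z` (p53
#' degradation): either stronger Mdm2 suppression of p53 or less stable p53
#' improves steady-state disturbance rejection.
#'
#' @inheritParams closed_loop_coeffs
#' @return Dimensionless steady-state error (positive scalar).
#' @export
steady_state_error <- function(params) {
  p <- as_continuous_params(params)
  p$p_zy * p$p_y / (p$p_y * p$p_z + p$p_yz * p$p_zy)
}

#' Natural frequency and damping ratio of the closed loop
#'
#' For the second-order closed loop,
#' \deqn{\omega_n = \sqrt{p_y p_z + p_{yz} p_{zy}}, \qquad
#'       \zeta = \frac{p_y + p_z}{2 \omega_n}.}
#' `zeta < 1` means the response to a disturbance overshoots (underdamped).
#'
#' @inheritParams closed_loop_coeffs
#' @return `natural_frequency()`: omega_n in the units of the rates;
#'   `damping_ratio()`: dimensionless zeta.
#' @export
natural_frequency <- function(params) {
  p <- as_continuous_params(params)
  sqrt(p$p_y * p$p_z + p$p_yz * p$p_zy)
}

#' @rdname natural_frequency
#' @export
damping_ratio <- function(params) {
  p <- as_continuous_params(params)
  (p$p_y + p$p_z) / (2 * natural_frequency(p))
}

#' Percent overshoot of a second-order step response
#'
#' For an underdamped system (`0 <= zeta < 1`),
#' \deqn{\%OS = 100 \exp\left(-\zeta\pi/\sqrt{1 - \zeta^2}\right),}
#' the peak excursion beyond the final value as a percentage of the final
#' value. Critically damped and overdamped responses (`zeta >= 1`) do not
#' overshoot, so the function returns 0 there.
#'
#' @param zeta damping ratio, >= 0 (vectorised).
#' @return Percent overshoot in `[0, 100]`.
#' @export
#' @examples
#' percent_overshoot(0)    # 100: undamped response doubles its final value
#' percent_overshoot(1)    # 0: critical damping, monotone response
percent_overshoot <- function(zeta) {
  if (any(!is.finite(zeta)) || any(zeta < 0))
    stop("zeta must be finite and >= 0", call. = FALSE)
  ifelse(zeta >= 1, 0, 100 * exp(-zeta * pi / sqrt(1 - zeta^2)))
}

#' p53 degradation rate minimizing the damping ratio
#'
#' As a function of `p_z`, the damping ratio has a unique interior minimum at
#' \deqn{p_z^* = p_y - 2 p_{yz} p_{zy} / p_y,}
#' provided `p_y^2 > 2 p_{yz} p_{zy}`; zeta decreases with `p_z` below this
#' value and increases above it. Above `p_z^*`, increasing p53 degradation
#' reduces the steady-state error *and* the overshoot simultaneously — the
#' regime the loop's measured operating point sits in, and the dynamical
#' advantage of post-translational suppression.
#'
#' @inheritParams closed_loop_coeffs
#' @return A list with `p_z_min` (the minimizer, or `NA` if no positive
#'   interior minimum exists) and `interior` (logical flag).
#' @export
zeta_minimizing_pz <- function(params) {
  p <- as_continuous_params(params)
  disc <- p$p_y^2 - 2 * p$p_yz * p$p_zy
  if (disc > 0) {
    list(p_z_min = p$p_y - 2 * p$p_yz * p$p_zy / p$p_y, interior = TRUE)
  } else if (disc == 0) {
    # minimum sits exactly at the origin of the admissible range
    list(p_z_min = 0, interior = FALSE)
  } else {
    list(p_z_min = NA_real_, interior = FALSE)
  }
}

#' Second-order summary of the continuous loop
#'
#' Convenience wrapper returning the four closed-form disturbance-rejection
#' metrics of a parameter set at once.
#'
#' @param object a [continuous_params()] object.
#' @param ... unused.
#' @return An object of class `"second_order_summary"`: a list with
#'   `omega_n`, `zeta`, `percent_os` and `ss_error`.
#' @export
summary.continuous_params <- function(object, ...) {
  z <- damping_ratio(object)
  structure(list(omega_n = natural_frequency(object),
                 zeta = z,
                 percent_os = percent_overshoot(z),
                 ss_error = steady_state_error(object),
                 units = attr(object, "units")),
            class = "second_order_summary")
}

#' @export
print.second_order_summary <- function(x, ...) {
  cat("Second-order closed-loop summary:\n")
  cat(sprintf("  natural frequency omega_n = %.4f %s\n", x$omega_n,
              if (identical(x$units, "per_min")) "min^-1" else "h^-1"))
  cat(sprintf("  damping ratio zeta        = %.4f\n", x$zeta))
  cat(sprintf("  percent overshoot         = %.4f %%\n", x$percent_os))
  cat(sprintf("  steady-state error        = %.4f\n", x$ss_error))
  invisible(x)
}

#' Open-loop p53 step response to a constant Mdm2 level
#'
#' With Mdm2 clamped at a constant level `Y`, the p53 equation integrates to
#' \deqn{z(t) = -\frac{p_{yz} Y}{p_z}\left(1 - e^{-p_z t}\right).}
#' The deviation is negative because the model omits basal p53 production;
#' the returned trajectory is the magnitude of the deviation, with the sign
#' recorded in the result. The response time — time to reach half the
#' steady amplitude — is `log(2) / p_z` and does not depend on `p_yz`:
#' only p53 degradation sets the speed, while `p_yz` sets the amplitude.
#'
#' @inheritParams closed_loop_coeffs
#' @param Y constant Mdm2 level (>= 0).
#' @param times non-negative, increasing time grid (hours).
#' @return A list with `times`, `z` (deviation magnitude), `amplitude`
#'   (steady magnitude `p_yz*Y/p_z`), `response_time` (`log(2)/p_z`) and
#'   `sign` (-1, the direction of the deviation).
#' @export
step_response_p53 <- function(params, Y, times) {
  p <- as_continuous_params(params)
  if (length(times) == 0) stop("time grid must be non-empty", call. = FALSE)
  if (any(times < 0) || is.unsorted(times, strictly = FALSE))
    stop("times must be non-negative and increasing", call. = FALSE)
  if (Y < 0) stop("Mdm2 level Y must be >= 0", call. = FALSE)
  amp <- p$p_yz * Y / p$p_z
  list(times = times,
       z = amp * (1 - exp(-p$p_z * times)),
       amplitude = amp,
       response_time = log(2) / p$p_z,
       sign = -1)
}

#' Unit step response of a standard second-order system
#'
#' Closed-form unit step response of
#' `omega_n^2 / (s^2 + 2 zeta omega_n s + omega_n^2)`, covering the
#' underdamped, critically damped, overdamped and undamped cases. Used to
#' check the percent-overshoot formula against an actual trajectory.
#'
#' @param omega_n natural frequency (> 0).
#' @param zeta damping ratio (>= 0).
#' @param times non-negative increasing time grid.
#' @return A list with `times`, `y` (response, final value 1 for
#'   `zeta > 0`), and `empirical_os` (observed overshoot in percent).
#' @export
second_order_step_response <- function(omega_n, zeta, times) {
  if (omega_n <= 0) stop("omega_n must be positive", call. = FALSE)
  if (zeta < 0) stop("zeta must be >= 0", call. = FALSE)
  if (length(times) == 0) stop("time grid must be non-empty", call. = FALSE)
  t <- times
  if (zeta == 0) {
    y <- 1 - cos(omega_n * t)
  } else if (zeta < 1) {
    wd <- omega_n * sqrt(1 - zeta^2)
    phi <- atan2(sqrt(1 - zeta^2), zeta)
    y <- 1 - exp(-zeta * omega_n * t) * sin(wd * t + phi) / sqrt(1 - zeta^2)
  } else if (zeta == 1) {
    y <- 1 - exp(-omega_n * t) * (1 + omega_n * t)
  } else {
    # distinct real poles
    s1 <- -omega_n * (zeta - sqrt(zeta^2 - 1))
    s2 <- -omega_n * (zeta + sqrt(zeta^2 - 1))
    y <- 1 + (s2 * exp(s1 * t) - s1 * exp(s2 * t)) / (s1 - s2)
  }
  list(times = t, y = y, empirical_os = max(0, (max(y) - 1) * 100))
}

#' Trade-off sweep: steady-state error versus percent overshoot
#'
#' Sweeps one rate of the continuous model over a grid and records the
#' (steady-state error, %OS) pair at each value. Sweeping `p_yz`
#' (transcriptional-strength axis) traces the classic feedback trade-off:
#' error falls while overshoot rises. Sweeping `p_z`
#' (post-translational axis) shows %OS rising then falling, with the turning
#' point at [zeta_minimizing_pz()]; past it both metrics improve together.
#'
#' @inheritParams closed_loop_coeffs
#' @param which which rate to sweep: `"p_yz"` or `"p_z"`.
#' @param grid strictly increasing positive grid of rate values. Defaults to
#'   50 evenly spaced points on `[0.5, 3]`, the range the trade-off is
#'   usually displayed over.
#' @return An object of class `"tradeoff_curve"`: a data.frame with columns
#'   `param_value`, `ss_error`, `percent_os`, plus attributes
#'   `swept_parameter` and `base_params`.
#' @export
tradeoff_sweep <- function(params, which = c("p_yz", "p_z"),
                           grid = seq(0.5, 3, length.out = 50)) {
  p <- as_continuous_params(params)
  which <- match.arg(which)
  if (any(grid <= 0)) stop("grid values must be positive", call. = FALSE)
  if (length(grid) > 1 && any(diff(grid) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  rows <- vapply(grid, function(v) {
    q <- p
    q[[which]] <- v
    c(steady_state_error(q), percent_overshoot(damping_ratio(q)))
  }, numeric(2))
  out <- data.frame(param_value = grid,
                    ss_error = rows[1, ],
                    percent_os = rows[2, ])
  structure(out, swept_parameter = which, base_params = p,
            class = c("tradeoff_curve", "data.frame"))
}

#' @export
plot.tradeoff_curve <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  nm <- attr(x, "swept_parameter")
  graphics::matplot(x$param_value, cbind(x$ss_error, x$percent_os / 100),
                    type = "l", lty = 1:2, col = c("black", "red"),
                    xlab = nm, ylab = "metric", ...)
  graphics::legend("topright", c("ss error", "%OS / 100"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  graphics::plot(x$ss_error, x$percent_os, type = "l",
                 xlab = "steady-state error", ylab = "%OS",
                 main = paste("trade-off over", nm))
  invisible(x)
}
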