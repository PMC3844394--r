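#' Simulate the discrete-time feedback model
#'
#' Iterates the difference equations of the loop,
#' \deqn{x(i) = x(i-1)}
#' \deqn{y(i) = w_{zy} z(i-1) - w_{xy} x(i-1) + w_y y(i-1)}
#' \deqn{z(i) = -w_{yz} y(i-1) + w_z z(i-1) + d(i),}
#' where the optional disturbance `d(i)` enters additively on the p53
#' update (the injection point of the disturbance-rejection analysis).
#'
#' @param params a [discrete_params()] object.
#' @param init named numeric vector `c(x =, y =, z =)` of initial levels.
#' @param n_steps number of update steps (>= 1).
#' @param disturbance optional numeric: either a single value applied at
#'   every step, or a vector of length `n_steps` (per-step disturbance on
#'   the p53 update).
#' @return A data.frame with columns `step` (0..n_steps), `x`, `y`, `z`.
#' @export
#' @examples
#' w <- discrete_params()
#' tail(simulate_discrete(w, c(x = 0, y = 0, z = 1), 50), 3)
simulate_discrete <- function(params, init = c(x = 0, y = 0, z = 0),
                              n_steps, disturbance = 0) {
  w <- as_discrete_params(params)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (!all(c("x", "y", "z") %in% names(init)))
    stop("init must name x, y and z", call. = FALSE)
  d <- if (length(disturbance) == 1) rep(disturbance, n_steps) else disturbance
  if (length(d) != n_steps)
    stop("disturbance must have length 1 or n_steps", call. = FALSE)
  x <- y <- z <- numeric(n_steps + 1)
  x[1] <- init[["x"]]; y[1] <- init[["y"]]; z[1] <- init[["z"]]
  for (i in seq_len(n_steps)) {
    x[i + 1] <- x[i]
    y[i + 1] <- w$w_zy * z[i] - w$w_xy * x[i] + w$w_y * y[i]
    z[i + 1] <- -w$w_yz * y[i] + w$w_z * z[i] + d[i]
  }
  data.frame(step = 0:n_steps, x = x, y = y, z = z)
}

#' Discrete-time steady-state error to a unit step disturbance
#'
#' Final-value-theorem limit of the discrete loop's error signal
#' (`e(i) = w_zy z(i) - w_xy x(i)`) under a sustained unit disturbance on
#' the p53 update:
#' \deqn{e_\infty = \frac{w_{zy}(1 - w_y)}{(1 - w_y)(1 - w_z) +
#'   w_{yz} w_{zy}}.}
#' Decreasing in `w_yz` (stronger suppression of p53) and increasing in
#' `w_z` (more stable p53): decreasing `w_z` corresponds to increasing the
#' continuous degradation rate `p_z`. Under the Euler substitution
#' `w_y = 1 - p_y T`, `w_z = 1 - p_z T`, `w_zy = p_zy T`, `w_yz = p_yz T`
#' this reduces exactly to the continuous [steady_state_error()].
#'
#' @param params a [discrete_params()] object.
#' @return Dimensionless steady-state error.
#' @export
dt_steady_state_error <- function(params) {
  w <- as_discrete_params(params)
  den <- (1 - w$w_y) * (1 - w$w_z) + w$w_yz * w$w_zy
  if (abs(den) < .Machine$double.eps * 16)
    stop("steady-state error is singular: (1-w_y)(1-w_z) + w_yz*w_zy = 0",
         call. = FALSE)
  w$w_zy * (1 - w$w_y) / den
}

#' Closed-loop transfer-function coefficients in the z-domain
#'
#' The discrete closed loop from ATM input to p53 output is
#' \deqn{G(z) = \frac{w_{xy} w_{yz}}{z^2 - (w_y + w_z) z +
#'   (w_y w_z + w_{yz} w_{zy})}.}
#'
#' @inheritParams dt_steady_state_error
#' @return Named numeric vector `c(gain, b, c)` with
#'   `G(z) = gain / (z^2 + b z + c)`; note `b = -(w_y + w_z)`.
#' @export
dt_closed_loop_coeffs <- function(params) {
  w <- as_discrete_params(params)
  c(gain = w$w_xy * w$w_yz,
    b = -(w$w_y + w$w_z),
    c = w$w_y * w$w_z + w$w_yz * w$w_zy)
}

#' Poles of the discrete closed loop
#'
#' Roots of the characteristic polynomial
#' `z^2 - (w_y + w_z) z + (w_y w_z + w_yz w_zy)`. A complex-conjugate pair
#' signals an oscillatory sampled response; pole magnitude < 1 means
#' stability.
#'
#' @inheritParams dt_steady_state_error
#' @return A data.frame of class `"pole_record"` with one row per pole:
#'   `re`, `im`, `magnitude`, `angle` (radians in (-pi, pi]), `zeta`,
#'   `omega_n` (rad/hr, using the sampling period `T`).
#' @export
char_poles <- function(params) {
  w <- as_discrete_params(params)
  b <- w$w_y + w$w_z
  c0 <- w$w_y * w$w_z + w$w_yz * w$w_zy
  disc <- b^2 - 4 * c0
  poles <- if (disc >= 0) {
    complex(real = (b + c(1, -1) * sqrt(disc)) / 2, imaginary = 0)
  } else {
    complex(real = b / 2, imaginary = c(1, -1) * sqrt(-disc) / 2)
  }
  pole_records(poles, w$T)
}

pole_records <- function(poles, T) {
  map <- t(vapply(poles, pole_to_damping, numeric(2), T = T))
  structure(data.frame(re = Re(poles), im = Im(poles),
                       magnitude = Mod(poles), angle = Arg(poles),
                       zeta = map[, 1], omega_n = map[, 2]),
            class = c("pole_record", "data.frame"))
}

#' Map a z-plane pole to an equivalent damping ratio
#'
#' Uses the standard z-to-s correspondence `p = exp(sT)`: with `r = |p|` and
#' `theta = arg(p)`,
#' \deqn{\zeta = \frac{-\ln r}{\sqrt{(\ln r)^2 + \theta^2}}, \qquad
#'       \omega_n = \frac{\sqrt{(\ln r)^2 + \theta^2}}{T}.}
#' zeta does not depend on the sampling period; positive real poles inside
#' the unit circle map to zeta = 1 (non-oscillatory), poles on the unit
#' circle to zeta = 0 (marginal), and negative real poles use theta = pi
#' (the fastest sampled oscillation).
#'
#' @param pole a complex (or real) pole; must be nonzero.
#' @param T sampling period in hours.
#' @return Numeric vector `c(zeta, omega_n)`.
#' @export
pole_to_damping <- function(pole, T = 0.11) {
  r <- Mod(pole)
  if (r == 0) stop("pole at the origin: damping ratio undefined", call. = FALSE)
  theta <- Arg(pole)
  lr <- log(r)
  s <- sqrt(lr^2 + theta^2)
  if (s == 0) return(c(zeta = 1, omega_n = 0))  # pole exactly at z = 1
  c(zeta = -lr / s, omega_n = s / T)
}

#' Monte-Carlo pole ensemble of the discrete loop
#'
#' Samples parameter sets from a [param_distribution()] (independent
#' Gaussians per weight, truncated to `[0, 1)` for the stability weights
#' and to `>= 0` for the coupling weights), computes the closed-loop pole
#' pair of each sample, maps every pole to a damping ratio, and summarises
#' the ensemble. This is the robustness analysis comparing the DNA-damage,
#' transcriptional-suppression and post-translational-suppression
#' conditions.
#'
#' @param dist a [param_distribution()].
#' @param n_samples number of parameter draws (default 100, the ensemble
#'   size the pole maps are drawn with).
#' @param seed integer seed; required for reproducibility.
#' @return An object of class `"pole_ensemble"`: list with `poles` (a
#'   `pole_record` data.frame of `2 * n_samples` rows, with a `sample`
#'   index column), `zeta_summary` (median and quartiles of zeta),
#'   `dist`, `n_samples`, `seed`.
#' @export
#' @examples
#' pe <- monte_carlo_poles(dna_damage_distribution(), n_samples = 100, seed = 1)
#' pe$zeta_summary
monte_carlo_poles <- function(dist, n_samples = 100, seed) {
  stopifnot(inherits(dist, "param_distribution"))
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  set.seed(as.integer(seed))
  draw <- function(nm, lower, upper) {
    m <- dist$mean[[nm]]; s <- dist$sd[[nm]]
    if (s == 0) return(rep(m, n_samples))
    x <- stats::rnorm(n_samples, m, s)
    bad <- which(x < lower | x >= upper)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), m, s)
      bad <- bad[x[bad] < lower | x[bad] >= upper]
    }
    x
  }
  wy <- draw("w_y", 0, 1)
  wz <- draw("w_z", 0, 1)
  wzy <- draw("w_zy", 0, Inf)
  wyz <- draw("w_yz", 0, Inf)
  recs <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    p <- suppressWarnings(discrete_params(w_xy = dist$mean[["w_xy"]],
                                          w_zy = wzy[i], w_yz = wyz[i],
                                          w_y = wy[i], w_z = wz[i],
                                          T = dist$T))
    r <- char_poles(p)
    r$sample <- i
    recs[[i]] <- r
  }
  poles <- do.call(rbind, recs)
  qs <- stats::quantile(poles$zeta, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(poles = poles,
                 zeta_summary = c(q25 = qs[1], median = qs[2], q75 = qs[3]),
                 dist = dist, n_samples = n_samples, seed = seed),
            class = "pole_ensemble")
}

#' @export
print.pole_ensemble <- function(x, ...) {
  cat(sprintf("Monte-Carlo pole ensemble: %d samples (seed %s)\n",
              x$n_samples, format(x$seed)))
  cat(sprintf("  damping ratio: median %.3f (IQR %.3f - %.3f)\n",
              x$zeta_summary[["median"]], x$zeta_summary[["q25"]],
              x$zeta_summary[["q75"]]))
  cat(sprintf("  poles inside unit circle: %.1f%%\n",
              100 * mean(x$poles$magnitude < 1)))
  invisible(x)
}

#' @export
plot.pole_ensemble <- function(x, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::plot(cos(th), sin(th), type = "l", lty = 2, asp = 1,
                 xlab = "Re(z)", ylab = "Im(z)",
                 main = "Closed-loop pole ensemble", ...)
  graphics::points(x$poles$re, x$poles$im, pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.6))
  graphics::abline(h = 0, v = 0, col = "grey")
  invisible(x)
}

#' Scale a weight distribution for a suppression condition
#'
#' Rescales the Fig-4A-style weight distribution to emulate stronger p53
#' suppression under normal (non-stressed) conditions, where Mdm2-mediated
#' suppression of p53 is 3.67-fold higher than under DNA damage.
#' Transcriptional suppression only strengthens the coupling: the `w_yz`
#' mean is multiplied by `fold`. Post-translational suppression also
#' destabilises the p53 protein: additionally the `w_z` mean is divided by
#' `fold`. Standard deviations are left unchanged in both modes.
#'
#' @param dist a [param_distribution()].
#' @param fold positive scaling factor (default 3.67, the measured ratio of
#'   ubiquitinated p53 between normal and DNA-damage conditions).
#' @param mode `"transcriptional"` or `"post_translational"`.
#' @param w_yz_mean,w_z_mean optional explicit overrides for the scaled
#'   means (the published pole maps quote 0.6708 and 0.0998, which differ
#'   slightly from the exact arithmetic 0.6078 and 0.0988).
#' @return A new [param_distribution()].
#' @export
scale_condition <- function(dist, fold = 3.67,
                            mode = c("transcriptional", "post_translational"),
                            w_yz_mean = NULL, w_z_mean = NULL) {
  stopifnot(inherits(dist, "param_distribution"))
  mode <- match.arg(mode)
  if (fold <= 0) stop("fold must be positive", call. = FALSE)
  m <- dist$mean
  m[["w_yz"]] <- if (is.null(w_yz_mean)) m[["w_yz"]] * fold else w_yz_mean
  if (mode == "post_translational")
    m[["w_z"]] <- if (is.null(w_z_mean)) m[["w_z"]] / fold else w_z_mean
  param_distribution(mean = m, sd = dist$sd, T = dist$T)
}
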