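#' Oscillatory weight set emulating pulsing single-cell dynamics
#'
#' A [discrete_params()] set whose closed-loop poles are a complex pair
#' just inside the unit circle (`|p|` about 0.998, angle about 0.126 rad),
#' so the loop produces slowly decaying oscillations with a period of
#' about 50 frames — 5.5 hr at the 0.11-hr sampling period, the order of
#' the p53 pulse period seen in single-cell movies after DNA damage.
#' Used as the default generating model for synthetic fluorescence series.
#'
#' @param T sampling period in hours.
#' @return A [discrete_params()] object.
#' @export
oscillatory_weights <- function(T = 0.11) {
  discrete_params(w_zy = 0.125, w_yz = 0.125, w_y = 0.99, w_z = 0.99, T = T)
}

#' Generate a synthetic two-channel p53/Mdm2 fluorescence time series
#'
#' Emulates the single-cell fluorescence quantifications the discrete-model
#' weights are tracked from: the discrete-time loop is iterated with a
#' known (possibly time-varying) weight schedule, independent Gaussian
#' measurement noise is added per channel, values are clipped at zero, and
#' each channel is affinely mapped to a positive fluorescence-like range
#' (default `[10, 1000]` arbitrary units, a nonzero background plus
#' dynamic range). The affine mapping and the exact generating schedule
#' are returned so recovery tests can invert them.
#'
#' @param weights a [discrete_params()] object giving constant weights
#'   (default [oscillatory_weights()], which reproduces pulsing dynamics),
#'   or a function `f(i)` returning the `discrete_params` in force at step
#'   `i` (1-based), for time-varying schedules.
#' @param n_frames number of samples (default 285, the frame count of the
#'   quantified movie).
#' @param T sampling period in hours (default 0.11 hr).
#' @param noise_sd measurement noise SD as a fraction of each channel's
#'   peak-to-peak amplitude (default 0.02).
#' @param init initial `(x, y, z)` levels; the default starts the loop off
#'   equilibrium so the channels oscillate.
#' @param fluor_range two-element target range of the affine mapping.
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return A list of class `"synthetic_series"` with `ts` (a
#'   [p53_timeseries()]), `raw` (the noise-free model states), `schedule`
#'   (data.frame of the weights at every step), `mapping` (per-channel
#'   `offset`/`scale` of the affine map), `diverged` (TRUE when the pole
#'   magnitude exceeded 1.05 in a sustained way) and `seed`.
#' @export
#' @examples
#' sim <- generate_timeseries(noise_sd = 0, seed = 1)
#' plot(sim$ts)
generate_timeseries <- function(weights = oscillatory_weights(),
                                n_frames = 285, T = 0.11, noise_sd = 0.02,
                                init = c(x = 0, y = 0.2, z = 1),
                                fluor_range = c(10, 1000), seed = NULL) {
  if (n_frames < 3) stop("n_frames must be >= 3", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise_sd > 0", call. = FALSE)
  wfun <- if (is.function(weights)) weights else function(i) weights
  n_steps <- n_frames - 1
  x <- y <- z <- numeric(n_frames)
  x[1] <- init[["x"]]; y[1] <- init[["y"]]; z[1] <- init[["z"]]
  sched <- matrix(NA_real_, n_steps, 5,
                  dimnames = list(NULL, c("w_xy", "w_zy", "w_yz", "w_y", "w_z")))
  maxmag <- 0
  for (i in seq_len(n_steps)) {
    w <- as_discrete_params(wfun(i))
    sched[i, ] <- c(w$w_xy, w$w_zy, w$w_yz, w$w_y, w$w_z)
    x[i + 1] <- x[i]
    y[i + 1] <- w$w_zy * z[i] - w$w_xy * x[i] + w$w_y * y[i]
    z[i + 1] <- -w$w_yz * y[i] + w$w_z * z[i]
    maxmag <- max(maxmag, max(char_poles(w)$magnitude))
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  addnoise <- function(v) {
    if (noise_sd == 0) return(v)
    v + stats::rnorm(length(v), 0, noise_sd * diff(range(v)))
  }
  map <- function(v) {
    r <- range(v)
    scale <- if (r[2] > r[1]) diff(fluor_range) / diff(r) else 1
    offset <- fluor_range[1] - r[1] * scale
    list(values = pmax(0, v * scale + offset), offset = offset, scale = scale)
  }
  zm <- map(addnoise(z))
  ym <- map(addnoise(y))
  ts <- p53_timeseries(zm$values, ym$values, sampling_period = T, atm = x)
  structure(list(ts = ts,
                 raw = data.frame(step = 0:n_steps, x = x, y = y, z = z),
                 schedule = as.data.frame(sched),
                 mapping = list(p53 = zm[c("offset", "scale")],
                                mdm2 = ym[c("offset", "scale")]),
                 diverged = maxmag > 1.05,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_series")
}

#' @export
print.synthetic_series <- function(x, ...) {
  cat(sprintf(
    "Synthetic p53/Mdm2 series: %d frames, noise %.1f%% of amplitude%s\n",
    nrow(x$ts), 100 * x$noise_sd,
    if (x$diverged) " [WARNING: divergent weight schedule]" else ""))
  invisible(x)
}

#' Generate a series with a known sustained step disturbance
#'
#' Iterates the discrete loop noise-free and injects a sustained additive
#' disturbance of the given magnitude into the p53 update from
#' `step_index` onward. For stable weights the p53 channel settles on a
#' plateau whose error-signal offset (`w_zy * z`) equals
#' `magnitude * dt_steady_state_error(weights)` — the time-domain
#' counterpart of the final-value-theorem result.
#'
#' @param weights a [discrete_params()] object.
#' @param n_frames series length.
#' @param step_index step (1-based) at which the disturbance switches on;
#'   must lie within the series.
#' @param magnitude disturbance size per step.
#' @param init initial `(x, y, z)` levels.
#' @return A list with `series` (data.frame `step, x, y, z`),
#'   `error_signal` (`w_zy*z - w_xy*x`), `plateau_offset` (mean
#'   error-signal over the final 10% of steps), `stable` (both pole
#'   magnitudes < 1) and `expected_offset`
#'   (`magnitude * dt_steady_state_error`, `NA` when unstable).
#' @export
generate_step_disturbance_series <- function(weights = discrete_params(),
                                             n_frames = 285,
                                             step_index = 50, magnitude = 1,
                                             init = c(x = 0, y = 0, z = 0)) {
  w <- as_discrete_params(weights)
  n_steps <- n_frames - 1
  if (step_index < 1 || step_index > n_steps)
    stop("step_index must lie within the series", call. = FALSE)
  d <- c(rep(0, step_index - 1), rep(magnitude, n_steps - step_index + 1))
  sim <- simulate_discrete(w, init = init, n_steps = n_steps, disturbance = d)
  err <- w$w_zy * sim$z - w$w_xy * sim$x
  stable <- all(char_poles(w)$magnitude < 1)
  tail_idx <- seq(from = floor(0.9 * n_frames), to = n_frames)
  list(series = sim,
       error_signal = err,
       plateau_offset = mean(err[tail_idx]),
       stable = stable,
       expected_offset = if (stable) magnitude * dt_steady_state_error(w)
                         else NA_real_)
}
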