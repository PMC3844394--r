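mech_rhs_core <- function(state, p, m1_lag, m3_lag) {
  P <- state[["p53"]]
  hill <- p$beta1 * P^p$n / (p$K1^p$n + P^p$n)
  mm <- p$gamma * P / (p$K2 + P) * state[["mdm2"]]
  c(mdm2_mrna = hill - p$alpha1 * state[["mdm2_mrna"]],
    mdm2 = p$beta2 * m1_lag - p$alpha2 * state[["mdm2"]],
    p53_mrna = p$beta3 - p$alpha3 * state[["p53_mrna"]],
    p53 = p$beta4 * m3_lag - p$alpha4 * P - mm)
}

mech_state <- function(x) {
  if (is.null(names(x))) names(x) <- c("mdm2_mrna", "mdm2", "p53_mrna", "p53")
  x[c("mdm2_mrna", "mdm2", "p53_mrna", "p53")]
}

#' Simulate the nonlinear mechanistic model
#'
#' Integrates the four-species model (mdm2 mRNA, Mdm2, p53 mRNA, p53):
#' Hill-activated Mdm2 transcription by p53, constitutive p53
#' transcription, linear translations and degradations, and
#' Michaelis-Menten Mdm2-mediated p53 removal
#' `gamma * p53 / (K2 + p53) * Mdm2`.
#'
#' @param params a [mech_params()] object (its `tau` is ignored here; use
#'   [simulate_mech_delay()] for the delayed system).
#' @param init non-negative initial state, ordered or named
#'   `(mdm2_mrna, mdm2, p53_mrna, p53)`.
#' @param t_end end time.
#' @param times optional explicit output time grid (overrides `t_end`).
#' @param rtol,atol solver tolerances (lsoda).
#' @return A data.frame with columns `time, mdm2_mrna, mdm2, p53_mrna, p53`.
#' @export
#' @examples
#' p <- mech_params(gamma = 1)
#' traj <- simulate_mech(p, c(0, 0, 0, 0), t_end = 50)
simulate_mech <- function(params, init = c(0, 0, 0, 0), t_end = 100,
                          times = NULL, rtol = 1e-8, atol = 1e-10) {
  p <- as_mech_params(params)
  y0 <- mech_state(init)
  if (any(y0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  if (is.null(times)) times <- seq(0, t_end, length.out = 501)
  f <- function(t, y, parms) {
    list(mech_rhs_core(y, p, m1_lag = y[["mdm2_mrna"]],
                       m3_lag = y[["p53_mrna"]]))
  }
  out <- deSolve::ode(y0, times, f, parms = NULL, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (lsoda istate ",
         attr(out, "istate")[1], ")", call. = FALSE)
  d <- as.data.frame(out)
  names(d)[1] <- "time"
  d
}

#' Simulate the mechanistic model with transcription-translation delay
#'
#' Same model as [simulate_mech()] but with an explicit delay `tau` between
#' transcription and translation: both translation terms read the mRNA
#' level at `t - tau`. The fixed points are unchanged by the delay, but a
#' long enough delay destabilises them and causes sustained oscillation.
#' Integrated with the R delay-differential solver (`deSolve::dede`), with
#' the history interpolated internally; the maximum step is capped at
#' `tau / 10` so the lag lookup stays well resolved.
#'
#' @inheritParams simulate_mech
#' @param history constant state on `[-tau, 0]` (the pre-time history),
#'   same layout as `init`; also the initial state at `t = 0`.
#' @return A data.frame as in [simulate_mech()]. At `tau = 0` this reduces
#'   to the plain ODE integration.
#' @export
simulate_mech_delay <- function(params, history = c(0, 0, 0, 0), t_end = 100,
                                times = NULL, rtol = 1e-8, atol = 1e-10) {
  p <- as_mech_params(params)
  y0 <- mech_state(history)
  if (any(y0 < 0)) stop("history must be non-negative", call. = FALSE)
  if (is.null(times)) times <- seq(0, t_end, length.out = 501)
  if (p$tau == 0) return(simulate_mech(p, y0, times = times,
                                       rtol = rtol, atol = atol))
  f <- function(t, y, parms) {
    if (t <= p$tau) {
      m1 <- y0[["mdm2_mrna"]]; m3 <- y0[["p53_mrna"]]
    } else {
      lag <- deSolve::lagvalue(t - p$tau, c(1, 3))
      m1 <- lag[1]; m3 <- lag[2]
    }
    list(mech_rhs_core(y, p, m1_lag = m1, m3_lag = m3))
  }
  out <- deSolve::dede(y0, times, f, parms = NULL, rtol = rtol, atol = atol,
                       control = list(mxhist = 1e5), hmax = p$tau / 10)
  d <- as.data.frame(out)
  names(d)[1] <- "time"
  d
}

#' Deterministic steady state of the mechanistic model
#'
#' Solves the fixed-point equations. p53 mRNA settles at `beta3/alpha3`;
#' the p53 level solves the scalar balance
#' `beta4*m3ss = alpha4*P + gamma*P/(K2+P)*Mdm2(P)` with
#' `Mdm2(P) = (beta2/alpha2) * (beta1/alpha1) * P^n/(K1^n+P^n)`, found by
#' root bracketing. The balance is strictly monotone in `P`, so the
#' positive fixed point is unique.
#'
#' @inheritParams simulate_mech
#' @param verify integrate briefly from the fixed point and check drift
#'   (default `FALSE`).
#' @return Named numeric steady state `(mdm2_mrna, mdm2, p53_mrna, p53)`.
#' @export
mech_steady_state <- function(params, verify = FALSE) {
  p <- as_mech_params(params)
  m3 <- p$beta3 / p$alpha3
  prod <- p$beta4 * m3
  mdm2_of <- function(P) {
    m1 <- p$beta1 * P^p$n / (p$K1^p$n + P^p$n) / p$alpha1
    p$beta2 * m1 / p$alpha2
  }
  bal <- function(P) prod - p$alpha4 * P - p$gamma * P / (p$K2 + P) * mdm2_of(P)
  hi <- prod / p$alpha4   # removal >= alpha4*P alone, so root is below this
  P <- stats::uniroot(bal, c(0, hi * (1 + 1e-9)), tol = 1e-12)$root
  ss <- c(mdm2_mrna = p$beta1 * P^p$n / (p$K1^p$n + P^p$n) / p$alpha1,
          mdm2 = mdm2_of(P), p53_mrna = m3, p53 = P)
  if (verify) {
    traj <- simulate_mech(p, ss, t_end = 10)
    drift <- max(abs(as.numeric(traj[nrow(traj), -1]) - ss) / pmax(ss, 1e-12))
    if (drift > 1e-4)
      warning("fixed point drifts under integration (may be unstable)",
              call. = FALSE)
  }
  ss
}

#' Step-disturbance response of the mechanistic model
#'
#' The disturbance-rejection protocol: equilibrate the model, then raise
#' p53 production by a small relative step (default +1%, applied to the
#' p53 transcription rate `beta3`; optionally to translation `beta4`), and
#' integrate to the new steady state. Reports
#' \deqn{\mathrm{ss\_error} = \frac{|SS_{old} - SS_{new}|}{SS_{old}}, \qquad
#'   \%OS = \frac{OS - SS_{new}}{SS_{new}},}
#' where `OS` is the extreme p53 level (in the direction of the step)
#' between the step and re-equilibration. Both metrics are fractions, not
#' percentages. With `tau > 0` the post-step transient is integrated as a
#' delay system; the steady states, and hence the steady-state error, do
#' not depend on the delay, while the overshoot grows with it.
#'
#' @inheritParams simulate_mech
#' @param step relative step on the production rate (default 0.01 = +1%).
#' @param target which production rate carries the step: `"beta3"`
#'   (transcription, default) or `"beta4"` (translation).
#' @param t_end integration horizon after the step; must reach the new
#'   plateau (checked, error if not converged).
#' @param ss_tol relative derivative tolerance declaring a plateau.
#' @return An object of class `"disturbance_metrics"`: list with `ss_old`,
#'   `ss_new`, `overshoot_level`, `ss_error`, `percent_os` (fraction),
#'   `step`, `target`, `tau` and the post-step `trajectory`.
#' @export
disturbance_response <- function(params, step = 0.01,
                                 target = c("beta3", "beta4"),
                                 t_end = 2500, ss_tol = 1e-8) {
  p <- as_mech_params(params)
  target <- match.arg(target)
  ss0 <- mech_steady_state(p)
  if (step == 0) {
    return(structure(list(ss_old = ss0[["p53"]], ss_new = ss0[["p53"]],
                          overshoot_level = ss0[["p53"]], ss_error = 0,
                          percent_os = 0, step = 0, target = target,
                          tau = p$tau, trajectory = NULL),
                     class = "disturbance_metrics"))
  }
  p2 <- p
  p2[[target]] <- p[[target]] * (1 + step)
  ss1 <- mech_steady_state(p2)
  times <- seq(0, t_end, length.out = 4001)
  traj <- if (p$tau > 0) {
    simulate_mech_delay(p2, history = ss0, t_end = t_end, times = times)
  } else {
    simulate_mech(p2, init = ss0, times = times)
  }
  P <- traj$p53
  n <- length(P)
  tail_drift <- abs(P[n] - ss1[["p53"]]) / ss1[["p53"]]
  if (tail_drift > 1e-4)
    stop("trajectory did not converge to the post-step steady state ",
         "(relative residual ", signif(tail_drift, 3),
         "); increase t_end or check for sustained oscillation",
         call. = FALSE)
  os <- if (step > 0) max(P) else min(P)
  structure(list(ss_old = ss0[["p53"]], ss_new = ss1[["p53"]],
                 overshoot_level = os,
                 ss_error = abs(ss0[["p53"]] - ss1[["p53"]]) / ss0[["p53"]],
                 percent_os = max(0, (os - ss1[["p53"]]) / ss1[["p53"]] *
                                    sign(step)),
                 step = step, target = target, tau = p$tau,
                 trajectory = traj),
            class = "disturbance_metrics")
}

#' Disturbance metrics from plateau and peak levels
#'
#' Direct arithmetic form of the step-disturbance metrics, for use when the
#' pre/post plateaus and the overshoot level are already known:
#' `ss_error = |SS_old - SS_new| / SS_old` and
#' `percent_os = (OS - SS_new) / SS_new` (a fraction).
#'
#' @param ss_old,ss_new pre- and post-perturbation p53 steady states (> 0).
#' @param overshoot_level extreme p53 level during the transient.
#' @return An object of class `"disturbance_metrics"`.
#' @export
#' @examples
#' disturbance_metrics(100, 100.5, 100.8)
disturbance_metrics <- function(ss_old, ss_new, overshoot_level) {
  if (ss_old <= 0 || ss_new <= 0)
    stop("steady states must be positive", call. = FALSE)
  structure(list(ss_old = ss_old, ss_new = ss_new,
                 overshoot_level = overshoot_level,
                 ss_error = abs(ss_old - ss_new) / ss_old,
                 percent_os = max(0, (overshoot_level - ss_new) / ss_new),
                 step = NA_real_, target = NA_character_, tau = NA_real_,
                 trajectory = NULL),
            class = "disturbance_metrics")
}

#' @export
print.disturbance_metrics <- function(x, ...) {
  cat(sprintf("Step disturbance (+%g%% on %s, tau = %g):\n",
              100 * x$step, x$target, x$tau))
  cat(sprintf("  SS_old = %.6g  SS_new = %.6g  overshoot level = %.6g\n",
              x$ss_old, x$ss_new, x$overshoot_level))
  cat(sprintf("  ss_error = %.6g  %%OS (fraction) = %.6g\n",
              x$ss_error, x$percent_os))
  invisible(x)
}

#' Sweep the Mdm2-mediated degradation rate gamma
#'
#' Runs the full step-disturbance protocol at every value of a gamma grid
#' (and optionally across Mdm2-level variants and delay values), tabulating
#' steady-state error and overshoot. Raising gamma — the post-translational
#' suppression axis — drives the steady-state error monotonically down
#' while the overshoot first rises then falls, mirroring the `p_z` sweep of
#' the linear model.
#'
#' @inheritParams disturbance_response
#' @param gamma_grid positive increasing grid (default 9 log-spaced points
#'   over 1e-2 to 1e2).
#' @param beta2_scale optional multiplier(s) on the Mdm2 translation rate,
#'   emulating varied Mdm2 levels (default 1).
#' @param tau_grid optional delay values (default the `tau` in `params`).
#' @return An object of class `"gamma_sweep"`: a data.frame with columns
#'   `gamma, beta2_scale, tau, ss_error, percent_os`, with attributes
#'   `monotone_error` (error strictly decreasing in gamma per condition)
#'   and `unimodal_os` (%OS rises then falls).
#' @export
gamma_sweep <- function(params, gamma_grid = 10^seq(-2, 2, length.out = 9),
                        beta2_scale = 1, tau_grid = NULL,
                        step = 0.01, target = "beta3", t_end = 2500) {
  p <- as_mech_params(params)
  if (any(gamma_grid <= 0)) stop("gamma grid must be positive", call. = FALSE)
  if (length(gamma_grid) > 1 && any(diff(gamma_grid) <= 0))
    stop("gamma grid must be strictly increasing", call. = FALSE)
  if (is.null(tau_grid)) tau_grid <- p$tau
  grid <- expand.grid(gamma = gamma_grid, beta2_scale = beta2_scale,
                      tau = tau_grid)
  res <- t(apply(grid, 1, function(g) {
    q <- p
    q$gamma <- g[["gamma"]]
    q$beta2 <- p$beta2 * g[["beta2_scale"]]
    q$tau <- g[["tau"]]
    m <- disturbance_response(q, step = step, target = target, t_end = t_end)
    c(m$ss_error, m$percent_os)
  }))
  out <- cbind(grid, ss_error = res[, 1], percent_os = res[, 2])
  base <- out[out$beta2_scale == beta2_scale[1] & out$tau == tau_grid[1], ]
  unimodal <- function(v) {
    d <- sign(diff(v))
    d <- d[d != 0]
    length(rle(d)$values) <= 2 && (length(d) == 0 || d[1] >= d[length(d)])
  }
  structure(out,
            monotone_error = all(diff(base$ss_error) < 0),
            unimodal_os = unimodal(base$percent_os),
            class = c("gamma_sweep", "data.frame"))
}

#' Detect sustained oscillation in a trajectory tail
#'
#' Examines the tail window of a trajectory: locates interior local maxima,
#' and declares the oscillation sustained when the tail peak-to-peak
#' amplitude exceeds `amp_tol` (relative to the tail mean) and consecutive
#' peak heights above the mean decay by less than `decay_tol`. The period
#' is estimated from the mean spacing of peaks.
#'
#' @param time,values numeric vectors of equal length (>= 10 points in the
#'   analysis window).
#' @param tail_frac fraction of the trajectory analysed (default 0.5).
#' @param amp_tol minimum relative peak-to-peak amplitude (default 0.01).
#' @param decay_tol maximum fractional decay between successive peak
#'   amplitudes still counted as sustained (default 0.05).
#' @return List with `sustained` (logical), `amplitude` (tail peak-to-peak),
#'   `period` (NA when fewer than two peaks).
#' @export
detect_sustained_oscillation <- function(time, values, tail_frac = 0.5,
                                         amp_tol = 0.01, decay_tol = 0.05) {
  n <- length(values)
  if (n != length(time)) stop("time and values must match", call. = FALSE)
  i0 <- max(1, floor(n * (1 - tail_frac)))
  t <- time[i0:n]; v <- values[i0:n]
  if (length(v) < 10) stop("analysis window too short", call. = FALSE)
  amp <- diff(range(v))
  m <- mean(v)
  rel_amp <- amp / max(abs(m), .Machine$double.eps)
  k <- which(diff(sign(diff(v))) == -2) + 1  # interior local maxima
  period <- if (length(k) >= 2) mean(diff(t[k])) else NA_real_
  sustained <- FALSE
  if (rel_amp > amp_tol && length(k) >= 3) {
    heights <- v[k] - m
    heights <- heights[heights > 0]
    if (length(heights) >= 2) {
      ratios <- heights[-1] / heights[-length(heights)]
      sustained <- all(ratios >= 1 - decay_tol)
    }
  }
  list(sustained = sustained, amplitude = amp, period = period)
}
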