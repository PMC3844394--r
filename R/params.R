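#' Parameters of the continuous linear feedback model
#'
#' The linear model of the p53--Mdm2 loop tracks three levels: ATM `x(t)`
#' (held constant under normal conditions), Mdm2 `y(t)` and p53 `z(t)`:
#' \deqn{dy/dt = p_{zy} z - p_{xy} x - p_y y, \quad
#'       dz/dt = -p_{yz} y - p_z z.}
#' All rates are first-order and strictly positive; the model omits basal
#' p53 production, which does not affect the disturbance-rejection analysis.
#'
#' @param p_xy ATM-to-Mdm2 suppression gain (h^-1).
#' @param p_zy p53-to-Mdm2 transcriptional activation gain (h^-1).
#' @param p_yz Mdm2-to-p53 suppression gain (h^-1).
#' @param p_y Mdm2 degradation rate (h^-1).
#' @param p_z p53 degradation rate (h^-1).
#' @param units Unit of the rates, `"per_hr"` (default) or `"per_min"`.
#'   Stored as an attribute; no silent conversion is ever performed.
#'
#' @details The defaults are the experimentally measured operating point of
#'   the loop: `p_yz = p_zy = 0.8` h^-1 and `p_y = p_z = 2.0` h^-1
#'   (protein half-lives of about 20 min). `p_xy` only scales the input
#'   channel and defaults to 1.
#'
#' @return An object of class `"continuous_params"`.
#' @seealso [steady_state_error()], [damping_ratio()], [summary.continuous_params()]
#' @export
#' @examples
#' op <- continuous_params()
#' summary(op)
continuous_params <- function(p_xy = 1, p_zy = 0.8, p_yz = 0.8,
                              p_y = 2, p_z = 2,
                              units = c("per_hr", "per_min")) {
  units <- match.arg(units)
  p <- c(p_xy = p_xy, p_zy = p_zy, p_yz = p_yz, p_y = p_y, p_z = p_z)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all rates of the continuous model must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(p), units = units, class = "continuous_params")
}

#' @export
print.continuous_params <- function(x, ...) {
  cat("Continuous p53-Mdm2 feedback parameters (", attr(x, "units"), "):\n",
      sep = "")
  cat(sprintf("  p_xy = %g  p_zy = %g  p_yz = %g  p_y = %g  p_z = %g\n",
              x$p_xy, x$p_zy, x$p_yz, x$p_y, x$p_z))
  invisible(x)
}

as_continuous_params <- function(x) {
  if (inherits(x, "continuous_params")) return(x)
  do.call(continuous_params, as.list(x))
}

#' Parameters of the discrete-time feedback model
#'
#' Per-step weights of the difference-equation form of the loop,
#' \deqn{y(i) = w_{zy} z(i-1) - w_{xy} x(i-1) + w_y y(i-1), \quad
#'       z(i) = -w_{yz} y(i-1) + w_z z(i-1),}
#' sampled every `T` hours. `w_y` and `w_z` are *stability* weights
#' (1 - w is the per-step degradation), so they act opposite to the
#' continuous degradation rates `p_y`, `p_z`.
#'
#' @param w_xy ATM-to-Mdm2 suppression weight (dimensionless, per step).
#' @param w_zy p53-to-Mdm2 activation weight.
#' @param w_yz Mdm2-to-p53 suppression weight.
#' @param w_y Mdm2 stability weight; `[0, 1)` for the nominal stable regime.
#' @param w_z p53 stability weight; `[0, 1)` for the nominal stable regime.
#' @param T sampling period in hours (default 0.11 hr, the frame interval
#'   of the single-cell movies the weights were estimated from).
#'
#' @details Defaults are the adaptive-filter estimates under the DNA-damage
#'   condition: `w_y = 0.8737`, `w_z = 0.3627`, `w_zy = 0.2662`,
#'   `w_yz = 0.1656`. Stability weights outside `[0, 1)` trigger a warning
#'   (the dynamics are then locally unstable) but are accepted, since the
#'   tracked weights fluctuate.
#'
#' @return An object of class `"discrete_params"`.
#' @seealso [simulate_discrete()], [char_poles()], [dt_steady_state_error()]
#' @export
discrete_params <- function(w_xy = 1, w_zy = 0.2662, w_yz = 0.1656,
                            w_y = 0.8737, w_z = 0.3627, T = 0.11) {
  w <- c(w_xy = w_xy, w_zy = w_zy, w_yz = w_yz, w_y = w_y, w_z = w_z, T = T)
  if (any(!is.finite(w))) stop("all weights must be finite", call. = FALSE)
  if (w_zy < 0 || w_yz < 0)
    stop("coupling weights w_zy and w_yz must be non-negative", call. = FALSE)
  if (T <= 0) stop("sampling period T must be positive", call. = FALSE)
  if (w_y < 0 || w_y >= 1 || w_z < 0 || w_z >= 1)
    warning("stability weights outside [0, 1): dynamics may be unstable",
            call. = FALSE)
  structure(as.list(w), class = "discrete_params")
}

#' @export
print.discrete_params <- function(x, ...) {
  cat("Discrete-time p53-Mdm2 feedback weights (T =", x$T, "hr):\n")
  cat(sprintf("  w_xy = %g  w_zy = %g  w_yz = %g  w_y = %g  w_z = %g\n",
              x$w_xy, x$w_zy, x$w_yz, x$w_y, x$w_z))
  invisible(x)
}

as_discrete_params <- function(x) {
  if (inherits(x, "discrete_params")) return(x)
  do.call(discrete_params, as.list(x))
}

#' Distribution of the discrete feedback weights
#'
#' Mean and standard deviation of each tracked weight, used for Monte-Carlo
#' sampling of pole ensembles. [dna_damage_distribution()] returns the published
#' adaptive-filter estimates for the DNA-damage condition.
#'
#' @param mean named numeric vector with entries `w_y`, `w_z`, `w_zy`,
#'   `w_yz` (and optionally `w_xy`, defaulting to 1 with SD 0).
#' @param sd named numeric vector of standard deviations, same names;
#'   all must be >= 0.
#' @param T sampling period in hours.
#'
#' @return An object of class `"param_distribution"`.
#' @seealso [monte_carlo_poles()], [scale_condition()]
#' @export
param_distribution <- function(mean, sd, T = 0.11) {
  need <- c("w_y", "w_z", "w_zy", "w_yz")
  if (!all(need %in% names(mean)) || !all(need %in% names(sd)))
    stop("mean and sd must both name w_y, w_z, w_zy, w_yz", call. = FALSE)
  if (any(sd[need] < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (!"w_xy" %in% names(mean)) mean <- c(mean, w_xy = 1)
  if (!"w_xy" %in% names(sd)) sd <- c(sd, w_xy = 0)
  structure(list(mean = mean[c(need, "w_xy")], sd = sd[c(need, "w_xy")], T = T),
            class = "param_distribution")
}

#' @rdname param_distribution
#' @export
dna_damage_distribution <- function(T = 0.11) {
  param_distribution(
    mean = c(w_y = 0.8737, w_z = 0.3627, w_zy = 0.2662, w_yz = 0.1656),
    sd   = c(w_y = 0.0830, w_z = 0.0825, w_zy = 0.0343, w_yz = 0.1169),
    T = T
  )
}

#' @export
print.param_distribution <- function(x, ...) {
  cat("Discrete weight distribution (mean ± SD), T =", x$T, "hr:\n")
  for (nm in c("w_y", "w_z", "w_zy", "w_yz"))
    cat(sprintf("  %-5s %.4f ± %.4f\n", nm, x$mean[[nm]], x$sd[[nm]]))
  invisible(x)
}

#' Parameters of the nonlinear mechanistic model
#'
#' Rates and constants of the four-species mechanistic model of the loop
#' (mdm2 mRNA, Mdm2, p53 mRNA, p53): Hill-type transcriptional activation of
#' Mdm2 by p53, linear transcription of p53, first-order degradations, and
#' Michaelis-Menten (MM) Mdm2-mediated p53 ubiquitination/degradation with
#' rate `gamma`. An optional transcription-to-translation delay `tau`
#' applies to both translation terms.
#'
#' @param beta1 Mdm2 transcription rate (Hill-saturated maximum).
#' @param beta2 Mdm2 translation rate.
#' @param beta3 p53 transcription rate (constitutive).
#' @param beta4 p53 translation rate.
#' @param alpha1,alpha2,alpha3,alpha4 first-order degradation rates of
#'   mdm2 mRNA, Mdm2, p53 mRNA and p53.
#' @param n Hill coefficient (>= 1).
#' @param K1 Hill dissociation constant of Mdm2 activation by p53.
#' @param K2 MM saturation constant of Mdm2-mediated p53 degradation.
#' @param gamma Mdm2-mediated p53 ubiquitination/degradation rate.
#' @param tau transcription-to-translation delay (time units, >= 0).
#'
#' @details Defaults are the parameter set used for the delay/oscillation
#'   simulations: all betas 1, `alpha1 = alpha3 = 1`,
#'   `alpha2 = alpha4 = 0.01`, `n = 2`, `K1 = 10`, `K2 = 100`, with `gamma`
#'   swept over 1e-2 to 1e2. Units are arbitrary concentration/time units.
#'
#' @return An object of class `"mech_params"`.
#' @seealso [simulate_mech()], [disturbance_response()], [gamma_sweep()]
#' @export
mech_params <- function(beta1 = 1, beta2 = 1, beta3 = 1, beta4 = 1,
                        alpha1 = 1, alpha2 = 0.01, alpha3 = 1, alpha4 = 0.01,
                        n = 2, K1 = 10, K2 = 100, gamma = 1, tau = 0) {
  p <- c(beta1 = beta1, beta2 = beta2, beta3 = beta3, beta4 = beta4,
         alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3, alpha4 = alpha4,
         n = n, K1 = K1, K2 = K2, gamma = gamma, tau = tau)
  if (any(!is.finite(p))) stop("all mechanistic parameters must be finite",
                               call. = FALSE)
  pos <- p[setdiff(names(p), "tau")]
  if (any(pos <= 0))
    stop("all mechanistic rates and constants must be strictly positive",
         call. = FALSE)
  if (n < 1) stop("Hill coefficient n must be >= 1", call. = FALSE)
  if (tau < 0) stop("delay tau must be >= 0", call. = FALSE)
  structure(as.list(p), class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("Mechanistic p53-Mdm2 model parameters:\n")
  cat(sprintf("  beta  = (%g, %g, %g, %g)   alpha = (%g, %g, %g, %g)\n",
              x$beta1, x$beta2, x$beta3, x$beta4,
              x$alpha1, x$alpha2, x$alpha3, x$alpha4))
  cat(sprintf("  n = %g  K1 = %g  K2 = %g  gamma = %g  tau = %g\n",
              x$n, x$K1, x$K2, x$gamma, x$tau))
  invisible(x)
}

as_mech_params <- function(x) {
  if (inherits(x, "mech_params")) return(x)
  do.call(mech_params, as.list(x))
}
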