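# Invert a synthetic series' affine fluorescence calibration back to the
# signed model states (the scale the discrete weights live on).
raw_states <- function(sim) {
  data.frame(
    p53 = (sim$ts$p53 - sim$mapping$p53$offset) / sim$mapping$p53$scale,
    mdm2 = (sim$ts$mdm2 - sim$mapping$mdm2$offset) / sim$mapping$mdm2$scale,
    atm = 0
  )
}

# Random positive continuous parameter set (reproducible under the caller's
# seed), kept away from zero so validation never trips.
random_cparams <- function() {
  continuous_params(p_xy = stats::runif(1, 0.2, 3),
                    p_zy = stats::runif(1, 0.2, 3),
                    p_yz = stats::runif(1, 0.2, 3),
                    p_y = stats::runif(1, 0.2, 3),
                    p_z = stats::runif(1, 0.2, 3))
}

# Euler discretisation of a continuous parameter set at sampling period T.
euler_weights <- function(p, T) {
  suppressWarnings(discrete_params(w_xy = p$p_xy * T,
                                   w_zy = p$p_zy * T,
                                   w_yz = p$p_yz * T,
                                   w_y = 1 - p$p_y * T,
                                   w_z = 1 - p$p_z * T,
                                   T = T))
}
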