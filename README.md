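# p53loop

Disturbance-rejection analysis of the p53–Mdm2 negative feedback loop.

The tumour suppressor p53 is held at a low, steady level in unstressed
cells by a negative feedback loop: p53 transcriptionally activates the E3
ubiquitin ligase Mdm2, and Mdm2 targets p53 for degradation. A striking
design feature of this loop is that Mdm2 suppresses p53
*post-translationally* (by degrading the protein) rather than
transcriptionally (by repressing its gene) — an energetically wasteful
"futile cycle" of simultaneous production and degradation. `p53loop`
implements a control-theoretic and stochastic analysis of why this design
wins: post-translational suppression achieves a better trade-off between
the steady-state error left by a sustained disturbance and the transient
overshoot that strong feedback provokes, at the price of amplified
stochastic noise.

The package is aimed at systems biologists and quantitative modellers who
want to reproduce, probe, or extend this analysis.

## What it computes

**Linear continuous model.** With ATM `x(t)`, Mdm2 `y(t)` and p53 `z(t)`,

    dy/dt =  p_zy z − p_xy x − p_y y
    dz/dt = −p_yz y − p_z z

the closed loop from input to p53 is second-order,
`G(s) = p_xy p_yz / (s² + (p_y+p_z)s + (p_y p_z + p_yz p_zy))`, with

- steady-state error to a unit step disturbance
  `e_∞ = p_zy p_y / (p_y p_z + p_yz p_zy)` (final value theorem),
- natural frequency `ω_n = √(p_y p_z + p_yz p_zy)` and damping ratio
  `ζ = (p_y+p_z)/(2ω_n)`,
- percent overshoot `%OS = 100·exp(−ζπ/√(1−ζ²))` for `ζ < 1`,
- the p53 degradation rate minimizing ζ: `p_z* = p_y − 2 p_yz p_zy / p_y`.

Sweeping `p_yz` (the transcriptional axis) trades error against overshoot;
sweeping `p_z` above `p_z*` (the post-translational axis) improves both.

**Discrete-time model and robustness.** The sampled counterpart
(`T = 0.11` hr) has closed loop
`G(z) = w_xy w_yz / (z² − (w_y+w_z)z + (w_y w_z + w_yz w_zy))`.
`monte_carlo_poles()` samples the tracked weight distribution
(`w_y 0.8737±0.0830, w_z 0.3627±0.0825, w_zy 0.2662±0.0343,
w_yz 0.1656±0.1169`), maps every pole `p` to a damping ratio
`ζ = −ln|p| / √(ln²|p| + arg²p)`, and contrasts the DNA-damage,
transcriptional (3.67-fold `w_yz`) and post-translational (additionally
`w_z`/3.67) conditions.

**NLMS weight tracking.** `nlms_track()` runs two normalized
least-mean-squares adaptive filters over a two-channel p53/Mdm2 time
series — one per difference equation — and returns per-step weight tracks
with mean ± SD summaries. `generate_timeseries()` produces synthetic
fluorescence-like input (285 frames at 0.11 hr, oscillatory, noisy) with
known ground-truth weights.

**Nonlinear mechanistic model.** Four species (mdm2 mRNA, Mdm2, p53 mRNA,
p53) with Hill-activated Mdm2 transcription, Michaelis–Menten
Mdm2-mediated p53 degradation (`γ P/(K₂+P)·Mdm2`), optional
transcription→translation delay τ. `disturbance_response()` applies the
+1% step protocol and reports `ss_error = |SS_old−SS_new|/SS_old` and
`%OS = (OS−SS_new)/SS_new`; `gamma_sweep()` and
`detect_sustained_oscillation()` map the γ and τ dependence.

**Stochastic simulation.** `build_reaction_system()` maps the mechanistic
model onto nine reactions; `gillespie_run()` samples exact (direct-method
SSA) trajectories via a compiled kernel; `noise_vs_gamma()` holds the
mean p53 level fixed by compensating its basal degradation rate and shows
that the noise statistic variance/mean grows with γ.

## Worked example

```r
library(p53loop)

op <- continuous_params()   # measured operating point, rates in h^-1
summary(op)
#> Second-order closed-loop summary:
#>   natural frequency omega_n = 2.1541 h^-1
#>   damping ratio zeta        = 0.9285
#>   percent overshoot         = 0.0388 %
#>   steady-state error        = 0.3448
```

At the measured rates (`p_yz = p_zy = 0.8 h^-1`, `p_y = p_z = 2 h^-1`)
the loop is barely underdamped: a sustained disturbance is attenuated to
34% of its open-loop effect while the transient overshoot is negligible
(0.04% of the final level).

```r
monte_carlo_poles(dna_damage_distribution(), n_samples = 100, seed = 1)
#> Monte-Carlo pole ensemble: 100 samples (seed 1)
#>   damping ratio: median 1.000 (IQR 0.976 - 1.000)
#>   poles inside unit circle: 100.0%

tr <- scale_condition(dna_damage_distribution(), 3.67, "transcriptional")
monte_carlo_poles(tr, n_samples = 100, seed = 1)
#>   damping ratio: median 0.638 (IQR 0.545 - 0.717)

pt <- scale_condition(dna_damage_distribution(), 3.67, "post_translational")
monte_carlo_poles(pt, n_samples = 100, seed = 1)
#>   damping ratio: median 0.940 (IQR 0.772 - 1.000)
```

Strengthening the feedback 3.67-fold through the transcriptional route
alone drops the median damping ratio from 1.0 to ~0.64 (oscillatory,
overshooting); pairing it with destabilised p53 — the post-translational
route — restores a median of ~0.94. The same comparison in the nonlinear
model:

```r
disturbance_response(mech_params(gamma = 1))
#> Step disturbance (+1% on beta3, tau = 0):
#>   SS_old = 4.9952  SS_new = 5.01533  overshoot level = 5.04036
#>   ss_error = 0.00402944  %OS (fraction) = 0.00499162
```

A +1% step in p53 production shifts the steady state by only 0.40% — the
feedback rejects most of it — with a 0.50% transient overshoot.

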