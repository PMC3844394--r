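---
title: "Methods: disturbance rejection in the p53-Mdm2 feedback loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disturbance rejection in the p53-Mdm2 feedback loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its models, the choices behind
their implementation, and what the accompanying tests do and do not
establish. It is written for a reader who wants to audit or extend the
analysis rather than merely run it.

## The scientific question

Unstressed cells keep p53 low and steady through negative feedback: p53
transcriptionally activates Mdm2, and Mdm2 promotes p53 degradation.
Feedback control theory frames the design question sharply. A sustained
disturbance on p53 leaves a *steady-state error* that stronger feedback
shrinks; but stronger feedback also lowers the loop's damping ratio, so
transients *overshoot* more — and an erroneous p53 excursion can trigger
cell-cycle arrest or apoptosis. The package quantifies how the two
suppression routes differ on this trade-off: a transcriptional route
changes only the coupling gain (Mdm2 to p53), while the
post-translational route used by the real loop changes the coupling gain
*and* the p53 degradation rate together.

## Linear continuous model

States are ATM `x` (constant under normal conditions), Mdm2 `y`, p53 `z`;
all five rates are strictly positive and carried in h⁻¹:

\[
\dot y = p_{zy} z - p_{xy} x - p_y y,\qquad
\dot z = -p_{yz} y - p_z z .
\]

The model deliberately omits basal p53 production; a constant source term
shifts the operating point but cancels out of the disturbance-rejection
algebra. A consequence is that the open-loop p53 step response to a
clamped Mdm2 level is negative (a suppression); `step_response_p53()`
reports the magnitude of the deviation and records the sign as `-1`
rather than silently flipping conventions.

Closed forms implemented (all hard-coded; there is no symbolic layer):
the second-order closed loop
\(G(s)=p_{xy}p_{yz}/(s^2+(p_y{+}p_z)s+(p_yp_z{+}p_{yz}p_{zy}))\),
the final-value steady-state error
\(p_{zy}p_y/(p_yp_z+p_{yz}p_{zy})\),
\(\omega_n=\sqrt{p_yp_z+p_{yz}p_{zy}}\),
\(\zeta=(p_y+p_z)/2\omega_n\),
\(\%OS = 100\,e^{-\zeta\pi/\sqrt{1-\zeta^2}}\) for \(\zeta<1\), and the
\(\zeta\)-minimising degradation rate \(p_z^* = p_y - 2p_{yz}p_{zy}/p_y\)
(valid when \(p_y^2 > 2p_{yz}p_{zy}\); at equality the minimum sits at
the origin of the admissible range, and below it no positive interior
minimum exists — `zeta_minimizing_pz()` distinguishes the three cases).

Two conventions worth noting:

- `percent_overshoot()` returns 0 for \(\zeta \ge 1\). The exponential
  formula is only meaningful for underdamped systems; critically damped
  and overdamped step responses are monotone, so zero is the physically
  correct extension (and the tests confirm it against simulated
  trajectories).
- Rates default to h⁻¹, the unit of the measured operating point
  (\(p_{yz}=p_{zy}=0.8\), \(p_y=p_z=2.0\); protein half-lives of about
  20 min). Published illustrations of the generic second-order response
  use min⁻¹ values; `continuous_params(units=)` carries the unit as an
  explicit attribute and the package never converts silently, because a
  silent 60-fold rescaling is precisely the kind of error unit
  attributes exist to prevent.

Trade-off sweeps default to 50 evenly spaced points on 0.5–3.0 h⁻¹, the
range over which the trade-off is conventionally displayed; both grid and
range are arguments.

## Discrete-time model and pole-ensemble robustness

The sampled model (period `T`, default 0.11 hr — the frame interval of
the single-cell fluorescence movies) uses *stability* weights:
`w_y`, `w_z` are the per-step retained fractions (so 1−w is degradation,
opposite in sense to `p_y`, `p_z`), and the closed loop is
\(G(z)=w_{xy}w_{yz}/(z^2-(w_y{+}w_z)z+(w_yw_z{+}w_{yz}w_{zy}))\).
Under the Euler substitution \(w=1-pT\) (stability weights) and
\(w=pT\) (couplings), the discrete steady-state error reduces *exactly*
to the continuous one; the test suite asserts this to machine precision
for random parameter sets, which pins down the sign conventions on both
sides at once.

Poles map to damping ratios through the standard \(z=e^{sT}\)
correspondence: \(\zeta = -\ln r/\sqrt{\ln^2 r + \theta^2}\) with
\(r=|p|\), \(\theta=\arg p\). Choices at the edges: positive real poles
give \(\zeta=1\); poles on the unit circle give \(\zeta=0\); negative
real poles use \(\theta=\pi\) (the fastest oscillation a sampled system
can express — the estimated distributions never actually produce them);
a pole at the origin is rejected as undefined.

Monte-Carlo ensembles draw each weight independently from a Gaussian
with the tracked mean ± SD, truncated to \([0,1)\) for the stability
weights and to \([0,\infty)\) for the couplings, by rejection. The
published description of the estimates is exactly "mean and standard
deviation per weight", so an independent truncated Gaussian is the
least-structured distribution consistent with it; truncation keeps every
draw in the physically meaningful range. The ensemble size defaults to
100 draws, the size of the published pole maps, and a seed is mandatory.

The 3.67-fold condition scaling multiplies the `w_yz` mean
(transcriptional mode) and additionally divides the `w_z` mean
(post-translational mode), leaving all SDs unchanged. The printed
normal-condition means (0.6708 and 0.0998) differ slightly from the
exact arithmetic (0.1656×3.67 = 0.6078; 0.3627/3.67 = 0.0988);
`scale_condition()` computes the arithmetic and accepts the printed
values as explicit overrides, so both variants are reproducible without
ambiguity about which was used.

## NLMS tracking

`nlms_track()` estimates the five weights from data by running one
normalized LMS filter per difference equation: the Mdm2 filter regresses
\(y(i)\) on \((z(i{-}1), -x(i{-}1), y(i{-}1))\), the p53 filter
regresses \(z(i)\) on \((-y(i{-}1), z(i{-}1))\). The minus signs live in
the regressors, so the tracked weights come out on the same positive
scale as the published table. Defaults: step size `mu = 0.5` (well
inside the NLMS stability range (0, 2], fast without the gradient noise
of `mu` near 1), regulariser `eps = 1e-6`, zero initial weights, burn-in
10% of the series. The exact settings behind the published weight table
are not in the main text, so these are the package's own defaults,
chosen for stability and exposed as arguments.

Two practical caveats the tests make explicit:

- Fluorescence units are arbitrary, so channels are min-max normalised
  by default. Normalisation (or any affine recalibration) changes the
  absolute scale of the recovered weights, because the difference
  equations have no intercept to absorb an offset. Ground-truth recovery
  tests therefore invert the generator's recorded affine mapping and
  track the signed model states with `normalize = FALSE`.
- The 10% default burn-in is right for summarising slowly varying
  weights, but a *recovery* test against known constant weights must
  exclude the convergence transient: on 285-frame series the filter's
  transient pollutes means until roughly step 200, so recovery tests
  summarise steps 201–284. With that window, noise-free recovery is
  within 10⁻³ absolute per weight, and with 5% measurement noise the
  means stay within 3 track-SDs of truth. Shuffling the frames destroys
  recovery, which guards the test itself against passing vacuously.

The ATM channel defaults to a constant (ATM is low and constant in
unstressed cells); with a zero ATM channel the `w_xy` weight is
structurally unidentifiable and simply stays at its initialisation — it
is excluded from recovery assertions.

## Synthetic fluorescence series

`generate_timeseries()` stands in for the single-cell movie
quantifications: 285 frames at 0.11 hr, two positive channels. It
iterates the discrete model under a known (constant or scheduled) weight
trajectory, adds independent Gaussian measurement noise per channel
(default SD 2% of the channel amplitude — Gaussian because fluorescence
readout noise, not molecule-counting noise, is being mimicked), clips at
zero and maps each channel affinely to [10, 1000] arbitrary units
(nonzero background plus camera-like dynamic range). The exact mapping,
schedule and seed are returned so tests can invert everything.

The default generating weights (`oscillatory_weights()`: couplings
0.125, stabilities 0.99) place the closed-loop poles at \(|p|\approx
0.998\), angle 0.126 rad — slowly decaying oscillations with a period of
about 50 frames (≈5.5 hr), the order of the p53 pulse period seen in
damaged cells. The tracked DNA-damage-condition means, by contrast,
give real poles and a monotonically decaying series; they remain
available but make a poor visual emulation and a degenerate (rank-one
excitation) tracking fixture. The true dynamic range and noise
statistics of the original recordings are not published numerically, so
these defaults are documented placeholders, not calibrated values.

What passing tests on this generator show: the estimator recovers the
model that generated the data, at realistic noise levels, and the
pipeline runs end to end. What they cannot show: that the published
weight table is reproduced from the original recordings — those
recordings and the exact filter settings live in supplementary material
only, so that reproduction is only attempted when such files are
supplied by the user.

## Nonlinear mechanistic model

Four species — mdm2 mRNA, Mdm2, p53 mRNA, p53 — with Hill-activated
Mdm2 transcription \(\beta_1 P^n/(K_1^n+P^n)\), constitutive p53
transcription \(\beta_3\), linear translations and degradations, and
Michaelis–Menten Mdm2-mediated p53 removal \(\gamma P/(K_2+P)\,M\).
Default parameters are the published oscillation-study set: all β's 1,
\(\alpha_1=\alpha_3=1\), \(\alpha_2=\alpha_4=0.01\), n = 2, K₁ = 10,
K₂ = 100, with γ swept over 10⁻²–10². In the delayed variant both
translation terms read their mRNA at \(t-\tau\) (the printed form of the
delayed p53 equation contains a stray multiplication sign; it is read as
the delayed argument, matching the Mdm2 equation's pattern).

The step-disturbance protocol: equilibrate, raise p53 production by 1%,
integrate to the new plateau, report
`ss_error = |SS_old − SS_new|/SS_old` and `%OS = (OS − SS_new)/SS_new`.
Both are *fractions* — the simulation-side overshoot definition, unlike
the linear-model formula, carries no factor of 100 — and the print
method labels them as such. Which production rate carries the step is
not specified by the source analysis; the package defaults to the
transcription rate β₃ (so the perturbation propagates through p53 mRNA)
with β₄ available via `target = "beta4"`. The overshoot level is the
extreme in the direction of the step; undershoot-only responses report
zero overshoot.

Numerical choices:

- Steady states are found algebraically: p53 mRNA is \(\beta_3/\alpha_3\)
  and the p53 fixed point solves a strictly monotone scalar balance,
  bracketed and solved by `uniroot` to 10⁻¹² — faster and better
  conditioned than integrate-until-flat, and uniqueness is guaranteed by
  monotonicity. Initial conditions for the protocol are therefore the
  exact pre-step fixed point (the original study's initial conditions
  are unstated; starting at equilibrium makes the protocol
  initial-condition-free).
- Transients are integrated with `lsoda` (rtol 10⁻⁸, atol 10⁻¹⁰); the
  delayed system with the standard R DDE solver (`deSolve::dede`), whose
  internal dense history interpolation replaces a hand-rolled
  method-of-steps loop; the maximum step is capped at τ/10 so lag
  lookups stay resolved. At τ = 0 the DDE path reduces to the ODE path
  (asserted to 10⁻⁶).
- `disturbance_response()` verifies that the trajectory actually reaches
  the post-step fixed point (relative residual < 10⁻⁴ at `t_end`,
  default 2500 time units ≈ 25 slow time constants) and errors
  otherwise — sustained oscillation or an unstable fixed point must not
  masquerade as a plateau.

One behaviour worth flagging: under the default parameter set the
overshoot-versus-γ curve rises through the whole 10⁻²–10² display range
and only turns over near γ ≈ 3×10³. The rise-then-fall shape is
therefore asserted on a grid extending to 10⁴ that contains the turning
point; the steady-state error is strictly decreasing in γ on any grid.
Delay leaves both fixed points — hence the steady-state error — exactly
unchanged while inflating the overshoot monotonically, and long delays
(τ of the order of the slow protein lifetime, ≳150–250 time units at
γ = 1) destabilise the loop into sustained oscillation, detected by
`detect_sustained_oscillation()` from undamped tail peaks (peak-to-peak
amplitude above 1% of the tail mean, successive peak decay below 5%).

## Stochastic layer

`build_reaction_system()` maps the mechanistic model onto nine reactions
whose summed drift reproduces the ODE right-hand side identically (a
test asserts this at random states). Hill and MM expressions are used
directly as propensities on copy numbers rather than expanded into
elementary binding steps: this matches common practice for
toolbox-style kinetic models and guarantees the deterministic limit is
the ODE model, at the cost of treating the saturating forms as exact at
low copy number. A system-size factor Ω scales concentrations to counts
(productions and K's multiply by Ω; first-order rates are unchanged), so
noise magnitudes are Ω-dependent and only trends are comparable across
volumes.

Trajectories are exact direct-method SSA samples. The hot loop is a
compiled (Rcpp) kernel for this fixed network, drawing from R's RNG so
`set.seed` fixes trajectories exactly; an interpreter-level R loop
remains as the reference engine (`engine = "R"`, and the only mode that
records every jump), and the two are cross-checked statistically in the
tests. Zero total propensity is treated as an absorbing state (flat
trajectory to the horizon).

The noise study holds the mean p53 level fixed while γ varies, by
solving the deterministic balance for the basal degradation rate α₄ in
closed form (`compensate_alpha4()`, verified by forward simulation); the
target defaults to the fixed point at the largest γ of the grid, which
guarantees a positive compensated α₄ across the whole grid. Ensemble
statistics pool p53 samples taken on a regular grid after burn-in across
independent runs; pooling, rather than one draw per run, is what makes
the variance/mean statistic estimable at desk scale, and per-run means
are returned alongside.

Study conditions (the source analysis states neither grid, volume nor
run count, so these are the package's choices, made once and kept):
γ on the linear grid 2, 4, 6, 8, 10 — across which the Mdm2-routed share
of p53 turnover spans roughly 20% to 100%, so every grid step changes
the feedback flux appreciably, whereas on a log grid reaching down to
10⁻² the lower decades differ only in a route that carries ~1% of the
flux and no statistic could separate them; Ω = 10, putting the held
p53 mean near 22 counts, where the deterministic fixed point
approximates the stochastic mean to ~2%; 600 runs of 1300 time units
with a 500-unit burn-in (≈5 slow time constants), sized so the
variance-of-variance of the slow Mdm2-driven component leaves the
monotone trend resolvable. Under these conditions variance/mean rises
strictly across the grid with compensated means within 10% of target
(the acceptance suite asserts both), reproducing the qualitative claim:
better disturbance rejection through Mdm2-mediated degradation is paid
for in stochastic noise.

## Problem sizes

The default test and analysis scales are: 100-draw pole ensembles
(matching the published maps; the convergence test uses 400 and 800),
285-frame synthetic series, nine-point γ sweeps for the deterministic
protocol, and the SSA conditions above (the SSA stage is the only
expensive one, a few tens of seconds). These sizes make every reported
number recomputable on a single CPU in well under a minute per stage.

## Known limitations

- The linear model is a local description; its metrics apply to modest
  disturbances around the operating point (the mechanistic model's
  near-linearity at a 0.5–2% step is itself a tested property, not an
  assumption).
- The published weight table cannot be reproduced without the original
  recordings and filter settings (supplementary-only); the tracking
  pathway is tested end to end on data of the same layout instead.
- The stochastic model has no delay (matching the source analysis), and
  its propensities inherit the macroscopic Hill/MM forms.
- Absolute noise values depend on the volume factor Ω; only the
  direction and ordering of the noise–γ relationship is a reproduction
  surface.
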