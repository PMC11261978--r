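---
title: "Information rates, the molecule-counting limit, and what E. coli's kinase encodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information rates, the molecule-counting limit, and what E. coli's kinase encodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemolimit)
```

## The question and the model

A chemotaxing *E. coli* cell climbing a shallow static gradient needs to
estimate one quantity: the rate of change of log attractant concentration
along its own trajectory, $s(t) = \frac{d}{dt}\log c = g\,v_x(t)$, where
$g$ is the gradient steepness ($d\log c/dx$) and $v_x$ the up-gradient
velocity of its run-and-tumble motion. Because runs decorrelate by
tumbling and rotational diffusion, $s(t)$ is well approximated in shallow
gradients by a stationary Gaussian process with autocorrelation
$g^2\sigma_v^2 e^{-|t|/\tau_v}$.

Two observation streams carry information about $s(t)$:

* **Molecule arrivals.** Ligand molecules reach the receptor cluster
  (treated as an absorbing disk of radius $l$) as a Poisson process with
  rate $r(t) = k_D c(t)$, $k_D = 4 D l$. This is the first physically
  measurable quantity, so the accuracy of the best causal estimate of
  $s(t)$ from past arrivals is the *physical limit* on chemosensing.
* **Kinase activity.** The cell's CheA kinase responds linearly to
  arrivals through a biphasic, perfectly adapting kernel
  $K_r(t) = G_r[\tau_1^{-1}e^{-t/\tau_1} - \tau_2^{-1}e^{-t/\tau_2}]$
  and carries slow internal Ornstein–Uhlenbeck noise with diffusivity
  $D_n$ and correlation time $\tau_n$, plus the filtered arrival noise
  itself.

Sensing accuracy is quantified in each case by a behaviorally-relevant
information rate: the rate at which new, currently-relevant information
about $s(t)$ accrues from the observation past. For stationary Gaussian
channels this transfer-entropy rate equals a predictive-information rate
and depends only on the stationary posterior variance
$\sigma^2_{s\mid\cdot}$ of the signal given the observation past:
$\dot I = \tau_v^{-1}\rho^2/(1-\rho^2)$ with
$\rho^2 = 1 - \sigma^2_{s\mid\cdot}/\sigma_s^2$. The headline quantity is
the ratio $\eta = \dot I_{s\to a}/\dot I_{s\to r}$: how close the cell's
internal encoding comes to the physical limit.

## The computational route: stationary Kalman–Bucy filtering

Small-signal closed forms exist (`info_rate_physical_smallsignal()`,
`info_rate_kinase_smallsignal()`), but all headline numbers come from an
exact numeric engine: each channel is expressed as a continuous-time
linear-Gaussian state-space model and its stationary filtering Riccati
equation is solved (`stationary_posterior()`), with the correlated
process/observation noise term included. The two routes — spectral
(causal Wiener) factorization and the algebraic Riccati equation — are
the same causal filtering solution; the Riccati form is numerically
robust and directly testable against a discrete-time recursive filter.

**Channel construction.** The arrival channel has states
$(s, L=\log c/c_0)$ with $\dot L = s$, observation
$r-r_0 = r_0 L + \sqrt{r_0}\,\xi$ (shot-noise intensity $r_0 = k_D c_0$).
The kinase channel, with the measured fast lobe treated as instantaneous
($\tau_1 = 0$; see below), has observation
$a - a_0 = -G_r u + n - G_r\sqrt{r_0}\,\xi$ where
$u = r_0 L - F/\tau_2$ combines $L$ with the adaptation filter state $F$.
We build the channel directly in the coordinates $(s, u, n)$ rather than
$(s, L, F, n)$: perfect adaptation makes the DC combination of $L$ and
$F$ unobservable, so the four-state form has a marginally stable
unobservable mode and no stabilizing Riccati solution, while the
three-state form is equivalent for the signal posterior and
unconditionally solvable. The shared shot noise $\xi$ appears in both the
state $u$ and the observation, which is the correlated-noise term.

**Numerical choices.** States are rescaled to comparable magnitudes
before solving (raw state variances span more than ten decades at
realistic parameters); the solution is obtained from the Hamiltonian
eigenvector method and polished by Newton (Kleinman) iterations to a
relative residual below $10^{-12}$, deterministically. The same scaling
is essential in the discrete-time filter used for signal reconstruction
(`causal_estimate()`); without it the signal block of the covariance is
lost to cancellation.

**$\tau_1 = 0$ convention.** The measured fast response time is
contaminated by reporter kinetics, and all calculations use
$\tau_1 = 0$: the fast lobe becomes an exact delta function, handled by
moving it into the observation's white-noise term (no tiny-$\tau_1$
regularization, no stiffness). This slightly overestimates the kinase
information rate; it is the convention under which all reported numbers,
including $\eta$, are computed.

**Vanishing-gradient limit.** Both rates scale as $g^2$ for small $g$, so
$\eta$ plateaus. The plateau is evaluated at $g = 10^{-4}\,$mm$^{-1}$ and
asserted against $g = 10^{-5}\,$mm$^{-1}$ (agreement < 1%). We do not use
$g = 10^{-3}\,$mm$^{-1}$ as the primary plateau point because of the
boundary-layer correction described next, which still moves $\eta$ by
about 1.3% between $10^{-3}$ and $10^{-4}$.

**Accuracy of the small-signal closed form.** The familiar asymptotic
$\dot I_{s\to r} \approx \gamma_r/(4\tau_v)$, with
$\gamma_r = 2 r_0 g^2 \sigma_v^2 \tau_v^3$, has a half-power correction:
eliminating the scalar Riccati system by hand gives
$\rho_{rs}^2 = \tfrac{\gamma_r}{4}\bigl(1 - 2\sqrt{\gamma_r} +
O(\gamma_r)\bigr)$. The $\sqrt{\gamma_r}$ arises because the spectral
factorization of the quartic observation spectrum has roots at
$\omega^2 \propto \gamma_r$, i.e. frequencies $\propto\sqrt{\gamma_r}$.
Consequently the engine and the closed form agree to 2% only for
$\gamma_r \lesssim 10^{-4}$; at $\gamma_r = 10^{-2}$ the exact rate is
about 17% below the asymptote. The engine is the accurate object — it
matches an independently coded Euler-discretized recursive filter to
better than 0.1% — and the acceptance suite documents the asymptote's
slow convergence rather than hiding it.

**Printed form of the kinase small-signal rate.** The literal algebraic
reading $\tfrac{1}{4\tau_v}\gamma_r/(1+\gamma_r/\gamma_a)^2$ does not
reduce to $\gamma_a/(4\tau_v)$ in the internal-noise-dominated limit,
while the interpolating form
$\tfrac{1}{4\tau_v}\gamma_a\gamma_r/(\gamma_a+\gamma_r)$ satisfies both
stated limits. Both are available behind the `form` argument of
`info_rate_kinase_smallsignal()`; neither is used for headline numbers,
which come from the engine.

## What the engine gives at the measured medians

With the packaged population-median parameters at $c_0 = 1\,\mu$M
($k_D = 1.2\times10^5\,$s$^{-1}\mu$M$^{-1}$, $\sigma_v^2 = 146$
$(\mu$m/s$)^2$, $\tau_v = 1.19\,$s, $k_D G_r = 2.28$, $\tau_2 = 7.4\,$s,
$D_n = 8.1\times10^{-4}\,$s$^{-1}$, $\tau_n = 8.7\,$s):

```{r eta}
p <- median_params(1)
eta(p$swim, p$kin, p$constants, g0 = TRUE)
```

i.e. the kinase channel encodes roughly 1.4% of the physically available
behaviorally-relevant information at the background nearest the receptor
dissociation constant — internal signal-processing noise, not molecule
counting, is what limits chemosensing here. $\eta$ rises with gradient
steepness because the physical limit saturates while the kinase channel
does not; at $g = 0.4\,$mm$^{-1}$, $c_0 = 1\,\mu$M the engine gives
$\eta \approx 0.12$. This slightly exceeds the nominal "up to
$\approx 0.1$" summary value; the excess is consistent with the
$\tau_1 = 0$ convention overestimating the kinase rate, and we report the
computed value rather than capping it.

## Agent-based simulation

`simulate_run_tumble()` implements 3-D (or 2-D) run-and-tumble motion:
exponential runs at rate `run_rate`, exponential tumbles during which the
cell does not advance, von Mises–Fisher reorientations with a configured
mean cosine, and rotational diffusion during runs. The default
configuration was calibrated once so that the full inference pipeline
(duration-weighted velocity autocorrelation, exponential fit over lags
0.1–10 s) returns the measured medians $\sigma_v^2 \approx 146$
$(\mu$m/s$)^2$ and $\tau_v \approx 1.19\,$s: speed 23.1 $\mu$m/s, mean
run 0.90 s, mean tumble 0.14 s, persistence 0.33, rotational diffusivity
0.062 rad$^2$/s ($P_{\mathrm{run}} = 0.865$). These are conventional
values for the organism; only the speed and run rate were adjusted in
calibration, and they were frozen before any acceptance measurement.

`simulate_arrivals()` draws Poisson counts at rate $k_D c(x(t))$ on an
exact exponential profile $c(x) = c_0 e^{g x}$ (feedback of behavior on
the signal is therefore included mechanically, though negligible in the
shallow regime). `simulate_kinase()` integrates the response kernel
driven by arrival excess plus exactly-discretized OU internal noise;
activity is clipped to $[0,1]$ only on output and the clipping fraction
is reported, since clipping signals departure from the linear regime.

**Chemotaxis readouts.** In `simulate_chemotaxis()` each agent modulates
its tumble rate linearly, $\lambda = \lambda_0(1 - \beta\,\hat x)$
(clipped at zero), around a standardized sensory readout $\hat x$. Three
readouts are provided: `"arrival"` — an ideal cell running the optimal
causal (extended Kalman) filter on its own molecule arrivals;
`"kinase_estimate"` — a cell applying the optimal causal filter to its
kinase activity, i.e. the estimator $\hat s_a$; and `"kinase"` — the raw
standardized kinase deviation $-(a - a_0)/\mathrm{sd}(a)$. The default
modulation gain $\beta = 0.4$ keeps rate modulation in the
shallow-response regime (clipping below ~5%).

The drift-speed prediction $v_a/v_r = \sqrt{\dot I_a/\dot I_r}$ is a
statement about cells that *use* the information their observations
carry. It holds in our simulations for the `"kinase_estimate"` readout,
which is what `drift_ratio_sweep()` uses; the raw `"kinase"` deviation
responds to the $\tau_2$-smoothed past signal rather than the current
one and climbs markedly more slowly than the information in $\{a\}$
allows, so it does not satisfy the square-root relation. Both modes are
kept because the raw deviation is the more literal model of the
signaling-to-motor pathway, while the filtered readout is the right
object for testing the information-to-drift theory. Absolute drift
speeds depend on the decision rule and $\beta$ and are not reproduction
targets; only the ratio is.

## Parameter inference

The fits mirror the measurement procedures:

* `velocity_autocorrelation()` computes per-cell non-centered
  autocorrelations of $v_x$ and averages them weighted by trajectory
  duration, after `prun_select()` restricts to cells within $\pm 0.01$ of
  the population-median run fraction (cells with fewer than two tumbles
  are discarded; the diffusivity-bias correction of the run-fraction
  distribution is exposed as a per-cell weight hook, uniform by default —
  a documented fidelity gap).
* `fit_exponential_autocorr()`, `fit_step_response()` and
  `fit_noise_params()` share one recipe: Gaussian likelihood, priors
  uniform in the logarithm of every parameter, MAP by simplex plus
  quasi-Newton polish in log space, and per-cell uncertainties as
  $1.4826\,\mathrm{mad}$ of draws from an affine-invariant ensemble
  (stretch-move) sampler. Only the robust spread of draws is contractual;
  chain settings are modest defaults. Up- and down-step responses are
  pooled after sign-flipping, weighted by per-timepoint SEM.
* `fit_noise_params()` computes the marginal likelihood of
  $(D_n, \tau_n, \sigma_m^2)$ by a scalar Kalman recursion over the
  exactly-discretized OU-plus-white-noise model. $\tau_n$ is constrained
  above twice the sampling interval: fluctuations faster than the
  sampling grid are indistinguishable from measurement noise, and the
  slow-noise model owns only the slow part. A step-response fast time
  below the sampling interval is likewise flagged and pinned to zero
  downstream.
* `population_summary()` implements the robust two-term uncertainty of
  the population median: cell-to-cell scatter
  $(1.4826\,\mathrm{mad})^2/N$ plus mean squared single-cell uncertainty
  $\sum_k\sigma_k^2/N^2$.
* `fit_mwc()` fits $k_D G_r = G_\infty/(c_0 + K_i)$ by least squares on
  logarithms (equalizing weights across order-of-magnitude different
  gains) with a deterministic multi-start. Fitting the three rounded
  published medians reproduces $K_i$ near 0.81 $\mu$M; exact
  re-generation of the printed gains is not expected because those fits
  used unrounded per-cell data.

## Synthetic data: what it emulates and what it does not

The generators (`gen_swim_population()`, `gen_step_response_experiment()`,
`gen_noise_traces()`) emulate the three experiment types with known
ground truth: trajectory populations with log-normal cell-to-cell
variability (default CV 0.3, a conventional scale for chemotaxis
phenotypes), FRET-style step-response schedules (7.5 s pre + 30 s post
per block, 10 up and 10 down blocks, 0.75 s sampling, saturating
bookends for `normalize_activity()`), and 1200 s constant-background
traces at 1 Hz. Default measurement noise makes a single step-response
block have SNR ≈ 2, so the block-averaging logic genuinely matters.
Defaults for the swimming experiment (4500 cells, mean trajectory 7.6 s)
give a *population* total trajectory time above $2.7\times10^4$ s; the
real experiment accumulated that much time within the median run-fraction
bin alone, which would require roughly an order of magnitude more cells
than is practical to hold in memory here — analyses at packaged scale
therefore carry more selection noise than the measurements. The
generators include no photobleaching, focal drift, segmentation
artifacts, tracking errors, or attractant consumption; passing recovery
tests show the estimators are correct for the stated stochastic models,
not that they are robust to those artifacts.

In the round-trip recovery tests, estimates are compared to truth within
twice a *combined* standard error: replicate-to-replicate scatter plus
the single-fit posterior spread. The fit spread alone is not a calibrated
sampling error for the autocorrelation and step-response fits, whose
residuals are correlated across lags/timepoints while the likelihood
treats them as independent (as the measurement procedures also do); the
replicate scatter supplies the honest scale.

## Problem sizes used in the packaged checks

Test-suite computations are sized for a single CPU: drift sweeps use 200
cells for 500 s per gradient steepness; round-trip recovery uses 20
replicates of 250-cell swimming populations and single-cell FRET-style
experiments; periodogram checks use $10^5$ s of simulated activity. The
engine itself is exact and runs in milliseconds per parameter set, so
information-rate tables over full background grids are cheap.

## Known limitations

* The engine covers the stationary, shallow-gradient (linear-Gaussian)
  regime only: no exact point-process filtering, no time-varying
  backgrounds, and information is summarized by the rate at zero lag.
* $\eta$'s population variability (the spread implied by single-cell
  parameter diversity) is not modeled; only uncertainty propagation of
  the median parameters via `error_propagation()` is provided.
* The kinase model is phenomenological linear response; no receptor-level
  MWC state dynamics or methylation kinetics beyond the gain formula.
* The chemotaxis decision rule is an implementation choice (linear rate
  modulation, small gain); conclusions are drawn only from ratios, at
  matched rules.
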