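# chemolimit

How much information does a chemotaxing bacterium actually encode about
its chemical environment, and how close is that to the physical limit set
by counting the ligand molecules that reach its receptors?

`chemolimit` answers this for *E. coli*-style run-and-tumble chemotaxis in
shallow static gradients. The behaviorally-relevant signal is the rate of
change of log concentration along the cell's own trajectory,
`s(t) = g·vx(t)`, a Gaussian process with autocorrelation
`g²σv²·exp(−|t|/τv)`. Two observation channels carry information about it:

* **molecule arrivals** — a Poisson stream with rate `kD·c(t)`,
  `kD = 4·D·l`, defining the physical limit;
* **CheA kinase activity** — a linear, perfectly adapting response to
  arrivals (gain `Gr`, adaptation time `τ2`) corrupted by slow internal
  Ornstein–Uhlenbeck noise (`Dn`, `τn`).

For each channel the package computes the behaviorally-relevant
information rate — the predictive-information (transfer-entropy) rate of
the stationary Gaussian channel,

    İ = (1/τv) · ρ² / (1 − ρ²),   ρ² = 1 − σ²(s|past observations)/σs²,

by solving the stationary Kalman–Bucy (causal Wiener) filtering problem
exactly, including the correlated process/observation shot-noise term.
Dimensionless SNRs `γr = 2·r0·g²·σv²·τv³` and
`γa = Gr²·r0²·g²·σv²·τv/Dn` give the small-signal forms
`İr ≈ γr/(4τv)`. The headline quantity is `η = İa/İr`, the fraction of
physically available information the cell's kinase actually encodes.

Beyond the engine, the package provides the surrounding workflow:
agent-based run-and-tumble/arrival/kinase simulation (Rcpp),
optimal causal signal reconstruction from either observation stream,
chemotactic drift-speed experiments testing `va/vr = √(İa/İr)`,
the single-cell parameter-inference procedures (velocity-autocorrelation,
step-response, noise and MWC-gain fits with robust population
summaries), and seeded synthetic-data generators that emulate the
underlying tracking and FRET experiments with known ground truth.

## Worked example

```r
library(chemolimit)

p <- median_params(1)          # population medians at c0 = 1 uM
p$constants
#> Physical constants of the arrival channel
#>   D  = 800 um^2/s, l = 0.06 um
#>   kD = 1.2e+05 s^-1 uM^-1

sw <- p$swim; sw$g <- 0.2      # a 0.2 /mm exponential gradient
info_rates(sw, p$kin, p$constants)
#> Behaviorally-relevant information rates
#>   physical limit  I_r = 0.1079 nats/s (gamma_r = 2.36)
#>   kinase activity I_a = 0.006864 nats/s (gamma_a = 0.0446)
#>   eta = I_a / I_r = 0.06359

eta(p$swim, p$kin, p$constants, g0 = TRUE)   # vanishing-gradient plateau
#> [1] 0.01402109
```

At the measured background nearest the receptor dissociation constant
(`c0 = 1` μM), the kinase channel encodes about 1.4% of the physically
available information in vanishingly shallow gradients — the cell is
internally limited, some 70-fold below the molecule-counting limit — and
η rises to only ~0.1 in the steepest gradient measured (0.4 /mm), where
the physical limit itself saturates.

The same comparison can be made on simulated data: reconstruct the
signal causally from each observation stream along one trajectory and
compare the accuracy of the two estimates,

```r
cmp <- estimator_comparison(sw, p$kin, p$constants, duration = 3000, seed = 1)
cmp$summary
#>   channel rho2_empirical rho2_engine
#> 1 arrival    0.093209350 0.113828443
#> 2  kinase    0.003588305 0.008102063
```

the kinase-based estimate is an order of magnitude less accurate, as the
engine predicts (empirical values carry sampling error and the
run-and-tumble signal is only approximately the Gaussian process the
filter assumes).

`drift_ratio_sweep()` runs the chemotaxis experiment: ideal cells
(filtering their own molecule arrivals) against cells driven by their
kinase activity, across gradient steepnesses, pairing the measured
drift-speed ratio with the engine's `√(İa/İr)`.

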