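# dgturnover

Simulation and analysis of **competitive neuronal and synaptic turnover in a
sparsely coded dentate gyrus (DG) network**.

The hippocampal DG is unusual on two counts: its granule cells are
continually replaced by adult neurogenesis, and its activity is extremely
sparse (a few percent of cells active). This package implements a
feedforward model that ties the two together. Binary entorhinal (EC)
context patterns with flip noise drive a randomly connected DG expansion
layer whose sparseness is set by an activation threshold; a CA3 readout is
trained each "day" by the Moore–Penrose pseudoinverse; and DG units then
compete for survival through the magnitude of their readout weights. The
package is for computational neuroscientists who want a tested, seeded,
scriptable implementation of this class of model — the turnover rules, the
signal-to-noise and context-bias analytics, and the singular-value
(dimensionality) analysis of the population code.

## Model in brief

For pattern $\mu$, DG unit $i$ receives $g_i^\mu = \sum_j J_{ij}\xi_j^\mu$
with $J_{ij}\sim N(0,1)$ and fires $S_i^\mu=\mathrm{sgn}(g_i^\mu-\theta)$;
$\theta=\sqrt{M}\,\Phi^{-1}(1-f)$ fixes the coding level $f$. Flip noise at
rate $\nu$ gives each prototype the noise-averaged activity
$\bar S=\mathrm{erf}\big((\bar g-\theta)/(\sqrt2\,\sigma_g)\big)$ with
$\bar g=g(1-2\nu)$, $\sigma_g^2=4M\nu(1-\nu)$. The readout solves
$W^T=\eta\bar S^{+}$. Turnover rules:

* **Model 1** — replace the `turnover_rate` fraction of units with the
  smallest $|W_i|$ by fresh random units (default 0.3/day);
* **Model 2** — multicontext version ranking by $\sum_c |W_{ic}|$;
* **Model 3** — per-synapse re-randomization with probability
  $p_i=\mathrm{clip}(1-s\,|W_i|/w_{\max},0,1)$ (slope $s=2.5$); a unit dies
  only when all of its synapses are targeted in one day.

Generalization error is measured on fresh noisy instances of the training
prototypes. The analysis stack provides the empirical and closed-form SNR,
the context-bias vector $\Psi=S\eta/P$, correlation/PCA diagnostics, the
spectral identity $W^T=P\sum_i\sigma_i^{-2}\hat\Psi_i^T$, readouts
restricted to the top spectral components, and material-turnover
accounting. See the methods vignette
(`vignettes/dg-turnover-model.Rmd`) for assumptions, conventions, and
design choices.

## Worked example

```r
library(dgturnover)
sim <- dg_simulate(days = 128, seed = 1)   # Model 1 at the default scale
summary(sim)
```

```
DG turnover simulation summary (model1)
  days:                  128
  error first/last:      0.267 / 0.114
  final SNR:             2.828
  realized f (last):     0.0459
  mean daily neuron turnover:  0.3
  mean daily synapse turnover: 0.3
  cumulative replacement of day-0 cohort:  0.978
```

Reading this: the random-projection baseline misclassifies 26.7% of fresh
noisy test patterns; 127 days of competitive turnover (30% of the 500 DG
units replaced daily) cut that to 11.4% while the CA3 signal-to-noise ratio
rose to 2.8. The realized coding level stays near the 4% target, and nearly
the whole day-0 population has been replaced at least once. `plot(sim)`
draws the learning curve; `coef(sim)` returns the final readout weights;
`predict(sim, patterns)` classifies new EC patterns.

Preset experiments and scans:

```r
ex <- run_experiment("fig2", replicates = 20, seed = 7)   # SNR, sparse vs dense
sc <- scan_parameter("turnover_rate", seq(0.05, 0.7, 0.05),
                     days = 128, replicates = 20, seed = 7)
attr(sc, "argmin")
```

A command-line wrapper with the same functionality is at
`inst/scripts/dgsim.R` (`Rscript dgsim.R run --preset fig1 ...`,
`... scan --param turnover_rate --grid 0.05:0.7:0.05 ...`).

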