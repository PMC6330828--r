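---
title: "Neuronal and synaptic turnover in a sparse dentate gyrus model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuronal and synaptic turnover in a sparse dentate gyrus model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgturnover)
```

## The model

`dgturnover` simulates a three-layer feedforward network — entorhinal cortex
(EC) inputs, a dentate gyrus (DG) expansion layer, and a CA3 readout — in
which adult neurogenesis is modelled as competitive replacement of DG units.
The scientific question it addresses is how the DG's two signature
properties, continual neuronal turnover and extremely sparse activity,
interact during the encoding of contextual memories.

A stimulus is a binary EC activity vector $\xi \in \{-1,+1\}^M$. Contexts
are groups of prototype patterns sharing one CA3 target code; environmental
variability is modelled by flipping each bit independently with probability
$\nu$. A DG unit $i$ receives the current
$g_i^\mu = \sum_j J_{ij}\xi_j^\mu$ through random weights
$J_{ij} \sim N(0,1)$, and fires as
$S_i^\mu = \mathrm{sgn}(g_i^\mu - \theta)$. The global threshold $\theta$
sets the coding level $f$, the expected fraction of active (unit, pattern)
pairs: since $g$ is $N(0, M)$ on random patterns,
$\theta = \sqrt{M}\,\Phi^{-1}(1-f)$. The CA3 current is
$h^\mu = \sum_i W_i S_i^\mu$ and the output code is its sign.

Averaging over flip noise, the current of a prototype has mean
$\bar g = g(1-2\nu)$ and variance $\sigma_g^2 = 4M\nu(1-\nu)$, giving the
expected activity
$\bar S = \mathrm{erf}\!\big((\bar g - \theta)/(\sqrt 2\,\sigma_g)\big)$.
Two sign conventions are possible for this expression; we use the
cumulative-distribution-consistent form, which is increasing in
$\bar g$ (a unit whose mean current is far above threshold is almost always
active).

The readout is trained each day by the Moore–Penrose pseudoinverse,
$W^T = \eta \bar S^{+}$: the minimum-norm least-squares solution mapping
each training column to its label. With more DG units than training columns
the residual is exactly zero; the interesting behaviour is how the *test*
(generalization) error on fresh noisy instances evolves as turnover reshapes
the population.

## The three turnover rules

* **Model 1 (neuronal).** Each day the `turnover_rate` fraction of units
  with the smallest $|W_i|$ are replaced by fresh randomly connected units.
  Ties at the cutoff are resolved by replacing older units first, then by
  index — a fixed, documented order so runs are reproducible.
* **Model 2 (multicontext).** With $C$ CA3 outputs and $2^C \ge$ contexts,
  units are ranked by $\sum_c |W_{ic}|$ and the bottom fraction replaced.
  With one output it reduces exactly to Model 1.
* **Model 3 (synaptic).** Competition acts on synapses rather than somata:
  each unit's input synapses are independently re-randomized with
  probability $p_i = \mathrm{clip}(1 - s\,|W_i|/\bar w,\ 0,\ 1)$, a linear
  transfer function of the readout-weight magnitude with slope $s$
  (default 2.5). A unit dies — and is counted as replaced, with its age
  reset — only when *all* of its connected synapses are targeted in the
  same day.

### The Model 3 transfer function

The linear transfer function needs a normalization $\bar w$ for $|W|$,
because the scale of the trained weights varies strongly with the coding
level; an unnormalized slope would make sparse and dense networks
incomparable. Two candidates are supported. Normalizing by the population
*mean* of $|W|$ turns out to be self-defeating: re-randomizing the weakest
units' synapses pushes them toward the population mean, the $|W|$
distribution tightens until no unit is below the $p = 0$ cutoff
($|W_i| \ge \bar w / s$), synaptic turnover collapses to a fraction of a
percent per day within about ten days, and the error freezes well above the
Model 1 level. Normalizing by the population *maximum* keeps the
competition anchored to the strongest unit: as training builds a bimodal
weight distribution, weak units remain well below $w_{\max}/s$ and continue
to turn over. Under max-normalization the model sustains realistic
dynamics — a daily neuron-death fraction in the range of a few per mille,
cumulative replacement of roughly 10–22% of the initial population over 128
days at coding levels from 0.04 to 0.5, more synaptic turnover in sparser
networks, and a clear interior optimum of the slope at 2.5. Max is
therefore the default (`weight_normalization = "max"`), with mean retained
as an option.

## Simulation loop and conventions

One iteration represents roughly one biological day. The order within a day
is **train → test → select → replace**: the day-$t$ error reflects the
readout trained on the day-$t$ population, and day 0 is the
random-projection baseline before any turnover. Ages advance at the start
of each day, so at the first selection every unit is one day old; the
survival of the age-1 cohort through the first selection therefore equals
$1 - \text{turnover rate}$, and its subsequent decline is an emergent
property of the competition. `sign(0)` maps to $+1$ everywhere — a single
convention covering thresholding and readout.

Randomness is split into independent streams (prototypes, input weights,
test noise, training noise, turnover) derived from one master seed, so
changing e.g. the number of test instances cannot perturb the turnover
trajectory. Traces are bit-reproducible given the seed.

Degenerate inputs are handled explicitly: $\nu = 0$ reduces the expected
activity to a hard threshold; an all-zero readout in Model 3 makes every
unit maximally unstable; a zero-noise class in the SNR is reported as an
infinite-SNR flag rather than an error. The pseudoinverse uses a relative
singular-value cutoff of `max(dim)` times machine epsilon; at these problem
sizes results are insensitive to a tenfold looser cutoff (checked by a
property test).

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `M`, `N`, `C` | EC units, DG units, CA3 outputs | 200, 500, 1 | reference network size |
| `P`, `n_contexts` | prototypes, contexts | 100, 2 | 50 patterns per context |
| `nu` | flip probability | 0.2 | input variability (0.05 in the 8-context preset) |
| `f` | target coding level | 0.04 | sparse DG regime |
| `turnover_rate` | Models 1–2 daily replacement | 0.3 | optimal at 128 days in the rate scan |
| `slope` | Model 3 transfer slope | 2.5 | interior optimum of the slope scan |
| `connectivity` | EC→DG connection fraction | 1 | partial connectivity via a per-row mask |
| `test_instances` | noisy test copies per prototype | 10 | error resolution of 1/(10 P) per day |

## Analysis stack

`context_bias()` computes $\Psi_i = f_i^+ - f_i^-$, a unit's response-rate
difference between contexts, both by direct counting and by the matrix form
$\Psi = S\eta/P$ (the two must agree exactly on balanced contexts, and a
property test checks this exhaustively on small instances).
`empirical_snr()` and `analytic_snr()` give the signal-to-noise ratio of
the CA3 current: the squared separation of class means over the summed
class variances, and its closed form in terms of $W$ and $\Psi$ — the two
agree within 10% on large test sets, where the closed form's
conditional-independence assumption holds for random projections.
`spectral_decomposition()` verifies the identity
$W^T = P\sum_i \sigma_i^{-2}\hat\Psi_i^T$ with
$\hat\Psi_i = u_i u_i^T \Psi$, expressing the trained readout as a weighted
sum of context-bias projections onto the left singular directions of the
activity matrix; `restricted_readout()` rebuilds the readout from the top
$d$ components (ranked by $|\alpha_i| = |u_i^T W|$) and reports the
cumulative performance $(0.5-\mathrm{err})/0.5$. Singular-value *ratios*
are taken from the per-unit centered activity matrix (they diagnose
dimensionality), while the readout identity uses the uncentered matrix the
pseudoinverse is defined on.

A note on $\Psi$ scaling: with balanced contexts the matrix form is written
here as $S\eta$ divided by the *total* pattern count, and the matching
factor appears in the reconstruction identity; some derivations write the
same identity with $2P$ where $P$ is the per-context count.

## What the generator emulates — and what it does not

All inputs are synthetic by design: independent equiprobable $\pm 1$
prototypes, independent flip noise, Gaussian input weights. This matches
the modelling assumptions (random, uncorrelated prototypes) but not real
entorhinal statistics: no spatial or temporal correlations, no
continuous-valued firing rates, no within-context prototype similarity.
Passing tests therefore certify the *mechanism* — that competitive turnover
plus sparseness reduces dimensionality and error under these idealized
statistics — not performance on naturalistic inputs. Likewise the model
omits immature-neuron maturation, inhibitory circuits (sparseness enters
only through $\theta$, held constant during training), and any plasticity
of the input weights other than wholesale re-randomization.

## Problem sizes and open choices

Test sets use 10 fresh noisy instances per prototype when the full learning
curve is of interest and 5 (with evaluation only on the day that feeds the
reported statistic) in parameter scans; with 100 prototypes and 20
replicates this resolves error differences of about 0.01, ample for locating
scan minima on the grids used. The test-set size is a free modelling
choice and is configurable. Whether test patterns should be noisy
instances of the training prototypes or of fresh prototypes is similarly
open; we use the training prototypes, matching the notion of generalizing
to unseen instances of a *known* context. The multicontext label codes use
the binary expansion of the context index mapped to $\pm 1$, which makes
codes distinct and runs reproducible. The `fig7` preset tracks material
turnover at coding levels $\{0.04, 0.1, 0.25, 0.5\}$, a sparse-to-dense
range over which the cumulative-replacement band is the 10–22% regime
discussed above; coding-level *scans* extend down to $f = 0.02$.

## Known limitations

* The Model 3 transfer function is defined up to its normalization
  (linear in |W| relative to the population maximum), so slope values
  should be compared within this package's convention, not across
  implementations with different weight scalings.
* The closed-form SNR ignores correlations between DG units induced by
  shared input noise; at $N = 500$ and large test sets the discrepancy is
  within a few percent, but it grows for small networks.
* The day-0 cohort's cumulative replacement is reported against the initial
  population only; units born later and subsequently replaced do not enter
  that particular statistic (they do enter the per-day turnover fractions).
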