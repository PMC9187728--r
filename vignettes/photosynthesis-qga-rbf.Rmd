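---
title: "Predicting net photosynthetic rate with a QGA-tuned RBF network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting net photosynthetic rate with a QGA-tuned RBF network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgarbf)
```

## The modelling problem

Greenhouse light-environment control needs a fast, accurate map from the
conditions a controller can set -- leaf temperature $T$ (degC), photon flux
density $I$ (umol m$^{-2}$ s$^{-1}$) and the blue fraction $b$ of a red+blue
LED source -- to the leaf's net photosynthetic rate $P_n$
(umol m$^{-2}$ s$^{-1}$). qgarbf implements that map as a three-layer radial
basis function (RBF) regression network whose single width hyperparameter
(the *spread*) is selected by a quantum genetic algorithm (QGA), together
with the preprocessing, baseline models and evaluation harness needed to
train and judge it on factorial gas-exchange campaigns.

## The RBF network

All inputs and the target are first min-max normalized to $[0,1]$,
$z' = (z - z_{\min})/(z_{\max} - z_{\min})$, with the extrema taken from the
training set only. The network is then

$$\hat{P}_n'(x) = \sum_{i=1}^{h} \omega_i \,
  \exp\!\left(-\frac{\lVert x - c_i \rVert^2}{2\sigma_i^2}\right),$$

with $x = (b, I, T)'$ normalized. The three ingredients are fitted in
sequence:

* **Centers** $c_i$: $h$ prototypes from a Lloyd k-means pass over the
  training inputs (initialized at $h$ distinct training rows, nearest-center
  assignment with ties to the lowest index, empty clusters re-seeded from
  the farthest sample). When $h$ equals the training-set size -- the
  default, following the rule that the hidden layer matches the sample
  count -- every sample is its own center and clustering is skipped.
* **Widths** $\sigma_i$: the self-organizing rule sets all widths to
  $c_{\max}/\sqrt{2h}$, where $c_{\max}$ is the largest inter-center
  distance. Because the single scalar *spread* is what the optimizer
  searches, two readings are offered: `spread_mode = "width"` (default)
  uses $\sigma_i = \mathrm{spread}$ directly, matching a sweep of one
  scalar width; `"scale"` multiplies the self-organizing width by the
  spread, preserving the rule's geometry. The default was chosen because a
  scalar sweep over roughly 0.1--15 only produces the characteristic
  U-shaped error curve when the spread *is* the width.
* **Output weights** $\omega$: linear least squares of the normalized
  targets on the hidden activations. With `ridge = 0` the solve is a QR
  factorization, falling back to the Moore--Penrose pseudo-inverse when the
  activation matrix is numerically rank deficient (wide kernels make the
  Gaussian kernel matrix ill-conditioned very quickly); the default
  `ridge = 1e-10` solves the regularized normal equations by Cholesky. An
  optional constant bias unit can be appended; it is off by default, so
  predictions far from every center decay to the denormalized zero.

Predictions are denormalized back to umol m$^{-2}$ s$^{-1}$.

The GRNN baseline is the corresponding kernel regression
$\hat{y}(x) = \sum_i y_i K_i / \sum_i K_i$ with isotropic Gaussian kernels
$K_i = \exp(-\lVert x - x_i\rVert^2 / 2\sigma^2)$ on the normalized inputs;
the exponent is max-shifted per query so that all-kernel underflow cannot
produce 0/0. Its predictions are convex combinations of stored targets and
therefore stay inside the training-target range.

## Selecting the spread

The spread is encoded as an $m$-bit binary string ($m = 20$ by default,
resolution $\approx 9.4\times10^{-6}$ on the default interval $[0.1, 10]$)
decoded by $s = lo + \mathrm{int}(x)/(2^m-1)\,(hi-lo)$. A candidate's
fitness is the mean squared error, on the normalized scale, of a model
trained on the training set and evaluated on the verification set. The
fitness set deserves a note: with $h = n$ and no search the network
interpolates its training data exactly, so a training-set fitness would be
minimized trivially by any vanishing spread; evaluating candidates on the
held-out set is what makes the search meaningful. A training-set option
remains available (`fitness_set = "training"`).

The QGA holds a population ($n = 20$) of qubit chromosomes, each gene an
amplitude pair $(\alpha_i, \beta_i)$ with $\alpha_i^2 + \beta_i^2 = 1$,
initialized at $(1/\sqrt2, 1/\sqrt2)$ so every bitstring is equally likely.
Each generation the chromosomes are *measured* (bit $=1$ when a uniform
draw exceeds $\alpha_i^2$), decoded and evaluated; the best-ever solution
is kept elitist (strict improvement only); and every chromosome is rotated
toward the best bits by the gate
$(\alpha,\beta) \mapsto (\cos\theta\,\alpha - \sin\theta\,\beta,\;
\sin\theta\,\alpha + \cos\theta\,\beta)$. The rotation policy is a
configurable table; the default rotates by $0.05\pi$ only where a bit
disagrees with the best, with the sign chosen to move the amplitude toward
the best bit's basis state and the angle clamped so the state is never
overshot -- without the clamp a fixed step makes $\beta^2$ oscillate around
1 instead of converging, which both breaks the intended monotone
convergence and slows the end game. Search stops after 50 generations or
10 without improvement; on the default synthetic data it typically
converges within 15--25 generations. A candidate whose objective is
non-finite is discarded with a warning rather than poisoning the elitist
best.

The classical GA baseline shares the encoding, bounds and stopping rule and
uses tournament selection (size 2), one-point crossover (rate 0.8),
per-bit mutation (rate $1/m$) and elitism of one.

## Preprocessing

Replicate triples are screened with Dixon's r10 ($Q$) test at
$\alpha = 0.05$: $Q = \mathrm{gap}/\mathrm{range}$ for the more extreme
value, compared against the tabulated critical value (0.970 at $n = 3$).
A flagged replicate deletes its whole condition group, because removal is
accounted in groups; surviving groups are averaged. Zero-range triples are
never flagged, so a noise-free campaign passes through intact -- the
default 5 temperatures x 15 light levels x 9 blue ratios design then
yields exactly 675 groups, and the 80/20 split (sizes rounded half away
from zero, normalization fitted on the training part only) gives exactly
540 training and 135 verification groups.

A limitation worth stating plainly: at $n = 3$ the $Q$ test has little
power. For a gross error of $20\,s$ injected into one replicate (noise
s.d. $s$), the test flags the group only when the two clean replicates
fall within about $1/32$ of the range of each other, an event of
probability $\approx 0.33$ whatever $s$ is -- the criterion is
scale-invariant. The test suite verifies this empirically: the cleaner
catches roughly a third of injected 20-sigma errors while keeping spurious
removals near the nominal 5%. Per-triple screening at this significance
level is a coarse safety net, not a guarantee; the acceptance suite
records this as a measured property of the method.

## The synthetic campaign

No gas-exchange dataset is shipped; a seeded generator emulates the
factorial campaign the pipeline assumes. The noise-free surface is a
non-rectangular hyperbola (NRH) in light,

$$P(I) = \frac{\alpha I + P_{\mathrm{eff}} -
  \sqrt{(\alpha I + P_{\mathrm{eff}})^2 -
        4\theta\,\alpha I P_{\mathrm{eff}}}}{2\theta} - R_d,$$

whose plateau $P_{\mathrm{eff}}$ is the product of a Gaussian temperature
response and a Gaussian blue-ratio response; the blue optimum shifts by
`b_tshift` per degree of $|T - T_{\mathrm{opt}}|$, so that leaves under
temperature stress favour a higher blue fraction -- the qualitative
behaviour the model family is meant to capture. As $\theta \to 0$ the NRH
reduces to the rectangular hyperbola
$\alpha I P_{\mathrm{eff}}/(\alpha I + P_{\mathrm{eff}}) - R_d$ (checked
numerically in the tests against that closed form).

Defaults describe a healthy cucumber seedling and are deliberately ordinary
for the species:

| parameter | default | units | meaning |
|---|---|---|---|
| `pmax0` | 20 | umol m-2 s-1 | light-saturated gross rate at both optima |
| `alpha0` | 0.06 | mol/mol | apparent quantum yield |
| `theta` | 0.8 | -- | NRH curvature |
| `rd` | 1.5 | umol m-2 s-1 | dark respiration |
| `t_opt`, `t_width` | 25, 8 | degC | temperature optimum and breadth |
| `b_opt`, `b_width` | 0.3, 0.35 | -- | blue-ratio optimum and breadth |
| `b_tshift` | 0.02 | per degC | stress shift of the blue optimum |
| `noise_sd` | 0.2 | umol m-2 s-1 | homoscedastic replicate noise |

Replicate noise is homoscedastic Gaussian because no error model is
specified for the instrument; a seeded generator makes identical parameters
give byte-identical datasets. Gross errors are injected as $\pm$ a stated
magnitude into one replicate of seeded, distinct condition groups, with a
manifest of what was corrupted returned for downstream checks. The default
design lists 15 photon flux densities; a 16-level variant (adding
300 umol m-2 s-1 to fill the 200--400 gap) reproduces the 720-group
variant used in the gross-error fixtures.

What the generator does *not* emulate -- CO2 and humidity responses (held
constant in the assumed campaign), stomatal dynamics, induction and
hysteresis, heteroscedastic or drifting instrument noise, leaf-to-leaf
variation -- bounds what passing tests show: they demonstrate that the
pipeline recovers a smooth, unimodal, NRH-shaped surface from noisy
factorial data, not that it would perform identically on any particular
instrument's output.

## Numerical and design choices

* **Rounding of split sizes**: half away from zero, so $0.8 \times 675$
  gives exactly 540.
* **Degenerate inputs**: a normalization feature with $z_{\max} = z_{\min}$
  is an error; values outside the fitted range map outside $[0,1]$ without
  clipping. Zero-range Dixon triples are never flagged. An empty prediction
  input returns an empty numeric vector.
* **Conditioning**: the Gaussian kernel matrix at $h = n$ becomes
  numerically singular once the spread is comparable to the data diameter;
  the pseudo-inverse fallback keeps the solve defined, and the validation
  objective steers the search away from such spreads. Exact-interpolation
  properties are therefore only meaningful at narrow spreads.
* **Tie-breaks**: nearest-center assignment breaks ties toward the lowest
  center index; the rotation direction at equidistant degenerate states is
  the positive one.
* **Seeds**: every randomized step (replicate noise, corruption, k-means
  initialization, the split, each optimizer) draws its own seed
  deterministically from one global seed via `derive_seed()`, so a whole
  run is reproducible from a single integer.
* **Problem sizes**: unit tests run on a reduced 3 x 6 x 3 design
  (54 groups) where the full campaign is not the point; end-to-end checks
  (spread-grid oracle, parameter recovery across five seeds) use the full
  675-group design. The spread-sweep default grid is the 16-point
  0.1--15.1 sequence.

## What the harness computes

`spread_sweep()` reproduces the spread-sensitivity table (verification MSE,
maximum and mean absolute error per spread). `compare_models()` trains the
six combinations RBF, GA-RBF, QGA-RBF, GRNN, GA-GRNN, QGA-GRNN on one
shared split and reports each one's verification metrics plus
predicted-vs-measured scatter; a failing row is flagged, not fatal.
`pn_metrics()` reports MSE, maximum and mean absolute error in original
units, the OLS line of predicted on measured (slope, intercept), the
coefficient of determination of that fit, and -- numerically identical for
a simple linear fit, emitted for transparency -- the squared Pearson
correlation. Wall-clock comparisons between models are deliberately out of
scope: they measure the host, not the method.

## Known limitations

* The Dixon screen's low power at $n = 3$, discussed above.
* The bias-free network decays to the denormalized zero far outside the
  training envelope; extrapolation beyond the factorial ranges is not
  meaningful.
* Only the scalar spread is searched, as in the modelling approach the
  package implements; centers and weights are not evolved.
* The hidden-layer-equals-sample-count rule makes training cost cubic in
  the training-set size; a few hundred groups is comfortable, tens of
  thousands would call for `h` well below `n`.
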