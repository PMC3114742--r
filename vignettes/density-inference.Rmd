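---
title: "Inferring parameter densities of heterogeneous cell populations from snapshot data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring parameter densities of heterogeneous cell populations from snapshot data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popsnap)
```

## The statistical model

Every cell in a clonal population is described by the same ODE model
$\dot x = f(x, u, \theta)$, $y = g(x)$, but with its own parameter
vector $\theta$, drawn independently from an unknown population
density $\Theta(\theta)$ on the unit box. The data are *population
snapshots*: at each measurement time $t_j$, a fresh set of $M_j$
cells is measured once (flow-cytometry style), yielding noisy outputs
$\hat y^{(i)}$. No cell is measured twice, so all single-cell data
points are independent, and a dataset is simply the collection
$\mathcal D = \{(t^{(i)}, \hat y^{(i)})\}_{i=1}^M$.

Measurement noise is multiplicative-plus-additive log-normal per
output dimension,
$\hat y_k = \eta^\times_k y_k + \eta^+_k$ with
$\eta^\times_k \sim \mathrm{LogN}(\mu^\times_k, \sigma^\times_k)$ and
$\eta^+_k \sim \mathrm{LogN}(\mu^+_k, \sigma^+_k)$. This captures the
two dominant error modes of fluorescence readouts: a relative
(gain-like) error and a strictly positive background.

The density itself is parameterized as a finite convex combination of
fixed *ansatz* densities — truncated Gaussians with centers on a
regular grid,

$$\Theta_\varphi(\theta) = \sum_{j=1}^{n_\varphi} \varphi_j
  \Lambda_j(\theta), \qquad \varphi_j \ge 0,\ \sum_j \varphi_j = 1 .$$

Inference over a function space thus becomes Bayesian inference over
the weight simplex. Because each cell contributes an independent
factor and each $\Lambda_j$ is fixed, the per-cell likelihood is a
scalar product $\langle c_i, \varphi\rangle$ with
$c_{ij} = p(\mathcal D^{(i)} \mid \Lambda_j)$, and the whole
unnormalized posterior costs $M$ scalar products to evaluate once
the conditional matrix $C = (c_{ij})$ has been computed. That
precomputation is the only place where the ODE model is simulated.

## The built-in TNF model

The package ships a four-state model of TNF signaling: relative
activities of active caspase-8 ($x_1$), active caspase-3 ($x_2$),
NF-κB ($x_3$) and I-κB ($x_4$). Interactions are Hill-type sigmoids
with exponent 2, $\mathrm{act}(x, a) = x^2/(a^2+x^2)$ and
$\mathrm{inh}(x, b) = b^2/(b^2+x^2)$: TNF ($u$) activates caspase-8
and NF-κB; C8a activates C3a; NF-κB inhibits C8a (via FLIP) and C3a
(via XIAP, threshold $b_3$) and induces its inhibitor I-κB
(threshold $a_4$); C3a antagonizes the survival branch. All nine
thresholds are dimensionless numbers in $(0,1)$; states are
normalized activities, and time is measured in units of the common
relaxation rate (all degradation terms are $-x_i$). Cell-to-cell
variability is placed on $b_3$ (univariate studies) or $(b_3, a_4)$
(bivariate studies), the two interactions reported as most variable
between cells.

The resting state — the steady state with zero caspase-3 activity at
$u = 0$ — is the origin for every admissible threshold vector, since
$\mathrm{act}(0, a) = 0$ propagates zeros through all four equations;
`steady_state()` nevertheless solves for it generically (damped
Newton with the C3a coordinate pinned to zero, stability verified
through Jacobian eigenvalues), so that other registered models are
not restricted to trivial resting states. The stimulus is a unit
step, $u(t) = 1$ for $t \ge 0$, the natural normalized choice given
that thresholds live in $(0,1)$; it is configurable. Under this
model the C3a response is monotone in $b_3$ — cells with weak XIAP
inhibition (large $b_3$) reach high caspase-3 activity — so a bimodal
$b_3$ population produces the bimodal output distributions the
inference is meant to detect.

## Numerical choices

**Noise density.** For $y > 0$ the conditional density is the
convolution integral
$p(\hat y \mid y) = \int_0^{\hat y} f_+(s)\, f_\times((\hat y - s)/y)\,
/y \; ds$, the parameterization of the compatibility line under which
$p(\cdot \mid y)$ integrates to one — the property the likelihood
actually requires (verified to $10^{-3}$ by quadrature in the tests).
The integral is evaluated by adaptive Simpson quadrature after
splitting the range at the two interior peak candidates, with the
integration variable switched to the multiplicative noise component
whenever $y\,e^{\mu^\times} < e^{\mu^+}$ (otherwise the additive
parameterization would contain a near-delta spike of width
$\mathcal O(y)$). For $y$ so small that the multiplicative
contribution is below $10^{-5}$ of the additive scale, the additive
log-normal is used directly. Default absolute tolerance is $10^{-10}$
for standalone density evaluation and $10^{-8}$ inside the
conditional matrix, where Monte Carlo error dominates long before
quadrature error.

**Fast path for large matrices.** Computing $c_{ij}$ for $M$ cells,
$n_\varphi$ components and $S_c$ draws needs
$M \cdot n_\varphi \cdot S_c \cdot m$ density evaluations. Above
$2\times 10^6$ evaluations the package switches to a bilinear
interpolation table of $p(\hat y \mid y)$ on a $400 \times 240$
log-log grid per output dimension (built from exact quadrature over
the observed data/simulation ranges). In the shipped studies the
interpolation error is a fraction of a percent — far below the Monte
Carlo error of the matrix entries — and is checked against the exact
path in the test suite.

**Monte Carlo sample semantics.** $S_c$ counts draws *per ansatz
component* (default 1000): each $\Lambda_j$ has its own integral to
approximate. Every drawn cell is simulated once over the union of
snapshot times and evaluated against all cells, which is what makes
the precomputation affordable.

**ODE integration.** A stiff-capable adaptive solver (lsoda) with
relative tolerance $10^{-8}$ and absolute tolerance $10^{-10}$; the
TNF derivatives are compiled. Tiny negative outputs from solver error
are clamped to zero.

**Priors.** The prior is a product of beta densities restricted to
the simplex. `beta_prior_from_extremum()` solves each $(\alpha_j,
\beta_j)$ numerically so that the beta *mode* sits at the requested
extremum and the variance equals $\sigma^2$; the mode (rather than
mean) reading keeps "extremum" literal, and for $\sigma^2 \le
0.285^2$ the solution always has $\alpha_j, \beta_j \ge 1$, which is
also what makes the MAP problem convex. At $\sigma = 0.285$ the
factors are nearly uniform ($\mathrm{Beta}(1,1)$ has variance
$1/12 \approx 0.289^2$), so that value marks the uninformative end of
the scale. The univariate demonstration uses the weakly informative
$\sigma^2 = 0.05$; the bivariate convergence study uses the strongly
informative $\sigma = 0.01$.

**MAP estimation.** The negative log posterior is convex on the
simplex for $\alpha_j, \beta_j \ge 1$. It is minimized in the
$n_\varphi - 1$ reduced coordinates by a logarithmic-barrier
interior-point method (`constrOptim`, analytic gradient), warm
started from expectation–maximization updates of the likelihood
part; under a flat prior the EM fixed point is itself the global
maximum-likelihood solution and is kept whenever it scores at least
as well. A likelihood floor of $10^{-300}$ is applied inside the
solver only (never in the sampler) to keep iterates in-domain when a
cell has zero likelihood under part of the basis. The reported `kkt`
value is the max-norm of the projected gradient over the active face,
scaled by $M$.

**Sampling.** Metropolis–Hastings with Gaussian proposals in the
first $n_\varphi - 1$ weights and the last weight set by the closing
condition; candidates with any negative coordinate have acceptance
probability zero. The closing index is fixed (configurable), and a
dedicated test checks that the chain law does not depend on which
coordinate is closed. Defaults: proposal covariance
$(0.05/\sqrt{n_\varphi})^2 I$, 10% burn-in, no thinning, optional
Robbins–Monro scale adaptation toward 23% acceptance during burn-in
only (frozen afterwards, preserving the Markov property). Chain
length defaults to $10^5$ at desk scale; the shipped study runs use
$10^4$, which the conjugate-oracle tests show is ample for the
marginal summaries reported here.

**Credible bands.** Percentiles are taken pointwise (per $\theta$ or
per output value $y$) with linear interpolation between closest ranks
(`type = 7`), at levels 80/90/95/99% by default. Bands are pointwise,
*not* simultaneous: the 95% band covers each density value separately
with posterior probability 0.95. Prediction bands reuse the
precomputed per-component output densities, so band computation is
pure algebra.

**Output densities.** Per-component output densities are kernel
density estimates with log-normal kernels (positivity-preserving) on
a log-spaced grid (default 201 points on $[10^{-3}, 3]$), bandwidth
from a Silverman-type rule applied in log space — the geometry in
which the kernels are Gaussian. The rule leaves the usual smoothing
bias of a few percent of the peak at $S = 10^3$–$10^4$ samples; this
matters when comparing predicted densities against sharp references
(below).

## The synthetic-data generator

`generate_snapshots()` draws fresh parameter vectors per snapshot
(cells are never reused across times, matching the measured-once
structure), simulates each cell from its resting state, reads the
output at that snapshot's time, and applies the noise model. Ground
truth (per-cell $\theta$, noise-free outputs) is returned alongside
but never consumed by the inference path.

The univariate study fixture uses an equal-weight mixture of two
truncated Gaussians in $b_3$ at 0.25 and 0.55 with sd 0.07 — a
synthetic stand-in with the qualitative features (bimodality, mass
concentrated below 0.6) of the corresponding published study, whose
exact generating density is available only graphically. The bivariate
fixture multiplies that mixture with a unimodal truncated Gaussian in
$a_4$ (center 0.5, sd 0.1). Both are configurable; nothing in the
inference machinery knows about them.

What the generator does *not* emulate: instrument-specific artifacts
(spectral spillover, gating), cell-cycle and division effects,
stochastic single-cell dynamics, or any dependence between cells.
Passing tests therefore demonstrate correct inference *under the
model's own assumptions*, not robustness to their violation.

A note on the average noise level: with
$\sigma^\times = 0.1$ and additive scale $0.05$, the nominal noise
magnitude at an output of order one is about 15%. The per-cell mean
of $|\hat y - y|/y$ over a simulated univariate dataset is
considerably larger (the acceptance script computes it afresh on
every run), because the TNF model's C3a outputs are well below one
for much of the population, so the additive background dominates the
relative deviation of dim cells. The statistic is reported as
computed; it is a property of the output scale, not of the noise
model implementation, which is verified independently by moment and
distribution checks.

## Checking prediction-band calibration

Prediction bands quantify exactly one source of uncertainty: the
posterior spread of $\varphi$. When checking whether the "true"
measured-output density falls inside them, the reference curve must
not carry sampling noise of its own — a KDE of a fresh finite sample
would, and its bandwidth bias differs from the components'. The
package therefore provides `true_output_density()` (exact
one-dimensional quadrature of the noise kernel against the true
parameter density; midpoint nodes keep threshold parameters strictly
inside their domain) and `smooth_lognormal()` to convolve that exact
curve with the same kernel bandwidth the components used, so the
comparison isolates inference error from estimator artifacts. Even
so, coverage of tight bands is limited by two structural effects
measured in the acceptance suite: at $t = 0$ all ansatz components
predict the same output density (the band degenerates to the frozen
Monte Carlo noise of the components), and at later times the bands
are deliberately narrow relative to the few-percent systematic error
a 600-cell dataset leaves in the estimate. The shipped calibration
test reports the measured pointwise coverage of the 95% band.

## Problem sizes used in the shipped runs

The test and demonstration runs are desk-scale by design: $S_c =
10^3$ draws per component and $S_\varphi = 10^4$ chain iterations for
the univariate study (600 cells, 15 components), $S_c = 200$ and MAP
only for the bivariate convergence study (up to $4\times 10^4$ cells,
100 components, three data realizations per cell count). All sizes
are arguments, and the conjugate and quadrature oracles in the test
suite quantify the Monte Carlo error at these sizes (matrix entries
scale as $S_c^{-1/2}$; chain summaries carry batch-means standard
errors).

## Known limitations

* The ansatz basis is fixed; no data-driven refinement. A density
  with features sharper than the component scale cannot be
  represented, and the estimate inherits the basis smoothing.
* Bands are pointwise percentiles; no simultaneous bands, no
  highest-posterior-density intervals.
* The noise model is log-normal multiplicative + additive per
  dimension with independent errors; no autofluorescence
  compensation, no per-snapshot drift.
* Exact quadrature references (`true_output_density()`) are
  implemented for one-dimensional parameter spaces; multivariate
  truths are scored through the IMSE of the parameter density
  instead.
* Convergence diagnostics beyond acceptance rate and the
  log-posterior trace (e.g. R-hat across chains) are left to
  downstream tooling.
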