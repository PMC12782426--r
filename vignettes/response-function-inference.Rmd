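---
title: "Inferring mechano-chemical response functions from cell trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mechano-chemical response functions from cell trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `waveresponse`, the assumptions and
numerical choices baked into its defaults, what the synthetic generator does
and does not emulate, and the package's known limitations.

## The model

Collectively migrating epithelial cells are treated as units that choose
their acceleration from local mechano-chemical inputs. Per axis (orthogonal
or parallel to the wound edge), the acceleration of a cell at frame $t$ is
modeled as

$$
\frac{dv}{dt}(t) \;=\; w_0 \;-\; w_1\,x_1(t)
\;+\; \sum_{i=2}^{5}\sum_{\tau=0}^{L-1} w_i(\tau)\, x_i(t-\tau),
$$

where $x_1$ is the cell's own velocity component, $x_2 = \partial
\mathrm{ERK}/\partial x$ the spatial gradient of ERK activity, $x_3 =
\partial\rho/\partial x$ the cell-density gradient, and $x_4, x_5$ the pure
second spatial derivatives of the velocity component along the two axes. The
lag kernels $w_i(\tau)$ are the *response functions*. Velocity deliberately
enters only at the current frame: acceleration is the time derivative of
velocity, so an unconstrained velocity history could reproduce the target
almost exactly and mask the contribution of every other input. The discrete
convolution absorbs the frame interval into the kernels; all internal
computation is in pixels and frames, with minutes applied only when
reporting (`derivatives_per_minute()`).

With $L = 1$ the model collapses to an instantaneous linear law whose
coefficients correspond, at a reference density and ERK level, to the
mechanics of a coarse-grained tissue model — friction modulated by ERK, an
ERK-dependent cell radius, bulk elasticity and tissue viscosity
(`continuum_coefficients()`). That mapping holds only in the high-density
regime, which is why the package fits the coefficients freely rather than
constraining them to mechanical values.

Key assumptions: linearity of the response, stationarity of the law over the
analyzed window, per-axis decoupling, and determinism — measurement noise
and intrinsic motility fluctuations appear only as residual error.

## Feature extraction

* **Temporal derivatives.** Positions are filtered with a centred
  second-order Savitzky–Golay window of 11 frames; velocity and acceleration
  are the analytic first and second derivatives of the local quadratic. The
  operator is exact on polynomials up to degree two. Frames lacking a full
  centred window are dropped rather than mirrored — mirroring would bias the
  very accelerations that become regression targets, and at 400-frame tracks
  losing 5 frames per end is immaterial.
* **Spatial derivatives.** At each cell, the full six-term 2D quadratic
  $b_0 + b_1 u + b_2 v + b_3 u^2 + b_4 uv + b_5 v^2$ is least-squares fitted
  to the neighbors within a radius of the focal cell (focal cell included),
  and differentiated analytically at the centre. Fits with fewer than six
  in-radius points, or rank-deficient designs (e.g. collinear neighbors),
  are flagged unusable and the record is dropped and counted — never imputed
  or zeroed. The ERK fit radius defaults to 10 px; the velocity-field radius
  is configurable separately and defaults to the same value, since only the
  ERK radius is pinned by the imaging protocol and the right velocity radius
  may differ per dataset. Density gradients reuse the scalar-field radius.
* **Density field.** $\rho$ is a Gaussian kernel-density estimate
  ($\sigma = 25$ px) evaluated *at the cell positions themselves*, then
  differentiated with the same local quadratic machinery. This cell-centric
  route means the entire pipeline needs only the track table, no raster. The
  focal cell's own kernel is included: the density a cell experiences
  includes itself, and excluding it would make $\rho$ depend on which cell
  asks. The estimate integrates to the cell count (verified to 1% by
  quadrature in the tests).
* **ERK per cell.** When FRET/CFP stacks are provided, each channel is
  smoothed with a $\sigma = 1$ px Gaussian (explicit separable convolution,
  kernel truncated at $3\sigma$, replicate padding), background-subtracted,
  and divided; non-positive denominators are masked and counted. ERK is read
  at the centroid each frame with no extra temporal filtering — temporal
  smoothing is left to the response function itself, which is the object
  under study.
* **Axis symmetry.** For the parallel axis the roles of $x$ and $y$ exchange
  consistently: the velocity component is $v_y$, ERK and density are
  differentiated along $y$, and the curvatures are those of $v_y$. The two
  axes are treated as mirror instances of one definition; nothing in the
  model distinguishes them except the data.
* **Trajectory filters.** Only tracks with $\ge$ 400 frames, no missing
  values and gap-free frame indices enter the regression (optionally also
  required to start at the first frame). Every removal carries a reason
  code.

## Fitting

The lagged design has one row per (cell, frame) with $L$ frames of history
*within that cell* — rows never span cells — and $2 + 4L$ columns. Fitting
minimizes $\lVert y - X\theta\rVert^2 + \lambda\lVert\theta_{\text{pen}}
\rVert^2$ with the bias unpenalized, so the $\lambda\to\infty$ limit is the
target mean rather than zero. Features are *not* standardized by default —
$\lambda$ then acts on raw-unit coefficients — with an opt-in z-scoring mode
that rescales the reported kernels back to raw units. The sign convention
reports $w_1$ as the negative of the fitted velocity coefficient, so positive
$w_1$ reads as friction-like damping.

$\lambda$ is selected by five-fold cross-validation in two stages: a broad
geometric grid $10^{-4}\ldots10^{4}$ (17 points), then one decade either
side of the broad minimum at 20 points per decade. Exact ties break toward
the larger $\lambda$ (more regularization). Folds are assigned sample-wise
by default; cell-wise grouping (whole cells held out together) is the
stability variant exposed by `grouped_cv_stability()`, which also reports
the pairwise cosine similarity of fold kernels. The solver is the explicit
penalized normal-equations form; per-fold Gram matrices are precomputed so
the λ search costs one small solve per candidate.

## Heterogeneity analysis

Per-cell response functions are fitted at the population-level $\lambda$ by
default — a per-cell CV would be dominated by noise at a few hundred usable
frames per cell, and sharing $\lambda$ makes the kernels comparable across
cells; callers can still supply any $\lambda$. Cells are ranked by the
Pearson correlation between observed and population-model-predicted
acceleration; degenerate cells (constant observed acceleration) score as
missing and rank last, and ties break by cell id. The similarity matrix uses
flattened kernel vectors in a fixed, versioned order; the bias $w_0$ is
excluded by default (it carries units of acceleration, not response shape)
while $w_1$ is included, and both choices are switchable because the
original analysis does not pin them down. PCA is performed on mean-centred,
unscaled vectors. Front-cell versus interior-cell cohorts run through the
identical code path with different input tables; cohort selection is the
caller's, via whatever region mask defined the tables.

## The spring-particle simulator

The forward model is a 1D chain of particles joined by springs with rest
length $R_i + R_{i+1}$:

$$
\dot v_i = -\mu_i v_i + k(x_{i+1}-x_i) - k(R_i+R_{i+1})
- k(x_i-x_{i-1}) + k(R_i+R_{i-1}),
$$

end cells coupling only to their single neighbor; an optional neighbor
viscosity $\eta(v_{i+1}-2v_i+v_{i-1})$ (one-sided at the ends) is off by
default, matching the chain model used for the wave experiments. Friction is
$\mu_i = \mu_0 e^{-\beta\,\mathrm{ERK}_i}$, and the radius follows either
the instantaneous rule $R_i = R_0(1+\alpha\,\mathrm{ERK}_i)$ or the
derivative rule $R_i = R_0(1+\alpha\,\partial\mathrm{ERK}_i/\partial t)$
motivated by the differentiator-like ERK kernel. The derivative is taken
analytically from the ERK kinetics, not finite-differenced, so it is exact
and step-size independent.

**ERK normalization.** Optogenetic activation is modeled as relaxation
toward the light pattern, $\dot{\mathrm{ERK}}_i = -\sigma(\mathrm{ERK}_i -
L_i)$ with $L_i\in\{0,1\}$: illuminated cells approach a *unit* plateau with
time constant $1/\sigma$. This normalization is a deliberate package choice:
with the gains used throughout ($\alpha = 1.5$ instantaneous, $\alpha = 10$
derivative, $\sigma = 0.1\,\mathrm{min}^{-1}$), radii stay within
$[0,\,2.5\,R_0]$ and both rules yield physical chains.
An un-normalized drive (plateau $1/\sigma = 10$) would scale radii by up to
$16\times$ under the instantaneous rule and make them *negative* behind the
wave under the derivative rule, which collapses neighboring cells onto each
other and trips the no-crossing invariant within minutes — the simulation
aborts, by design, whenever cell order is violated.

**Geometry and integration.** The illumination band (30 cells wide) is
defined in cell-index space and sweeps at 0.1 cells/min, right to left by
default; its centre starts at the rightmost cell, so the band enters from
the chain's edge. Cells start at rest, uniformly spaced at $2R_0$ (the
chain's equilibrium), with ERK $=0$. Integration is fixed-step classical
Runge–Kutta at $dt = 0.01$ min with a convergence self-check in the tests
(halving $dt$ moves final positions by $<10^{-3}$ relative); with
$\mu_0 = 0, \alpha = 0$ the spring forces telescope and total momentum is
conserved to round-off, end effects included, which the tests assert over
1000 steps.

With the instantaneous rule the simulated wave reproduces both published
signatures: interior cells end up displaced *against* the wave, and each
cell shows a transient excursion *toward* the wave as it arrives. Switching
to the derivative rule strongly suppresses that arrival excursion. In this
implementation the suppression is about eight-fold (the excursion ratio
computed by `scripts/acceptance.R` is ~12–13%, robust across cohort windows
and metrics), rather than complete elimination; the residual dip is the
elastic compression transmitted ahead of the front during the brief
radius pulse.

## The synthetic generator

`generate_linear_response_dataset()` draws each feature as a stationary
first-order autoregression (a discretized Ornstein–Uhlenbeck process),
initialized from its stationary distribution, with lag-1 autocorrelation
0.85 by default — a correlation time of ~6 frames (12 min), comparable to
the effective response window, because white-noise inputs would make kernel
recovery unrealistically easy by decorrelating the lagged design columns.
The target is the exact convolution of the ground-truth kernels with the
feature histories plus Gaussian noise scaled to a fraction (default 10%) of
the noiseless target SD. The default ground truth mirrors the qualitative
kernel shapes of interior cells: a biphasic differentiator-like ERK kernel
decaying within ~10 frames, a smoother sustained density kernel, and
delayed positive viscosity bumps. Dataset defaults (hundreds of cells, 400
frames, 2-min cadence) mirror the imaging scale.

What the generator does *not* emulate: segmentation and tracking errors,
microscope noise, cell division and extrusion, spatial correlation between
neighboring cells' features, and any feedback from motion onto ERK. Passing
the recovery benchmarks therefore demonstrates correctness of the
estimation machinery under the model's own assumptions, not robustness to
real-data pathologies; the trajectory-defect injector covers only the
filtering layer (short tracks, missing values).

Problem sizes used by the test suite and acceptance script — 300 cells ×
400 frames for recovery and fold-stability checks, 100-cell 7-hour chains
for the wave simulations, 30 + 30 planted cells for the heterogeneity
contrast — are the package's reference study conditions; smaller instances
back the unit tests.

## Numerical choices and degenerate inputs

* Ridge systems are solved from the Gram matrix; with $\lambda > 0$ the
  system is positive definite even when rows $<$ columns.
* Cosine similarity of a zero vector is undefined: flagged with a warning
  and returned as `NA`, never silently zeroed.
* Cross-correlations are true per-lag Pearson correlations (not the
  lag-0-normalized estimator), averaged over cells; constant windows yield
  `NA` and are excluded from the average. Series shorter than twice the lag
  range are skipped and counted.
* The model file is plain text at full (`%.17g`) precision, so fit →
  serialize → load round trips are bit-exact and repeated pipeline runs are
  byte-identical.
* All randomness in a pipeline run flows from the single configured seed.

## Known limitations

* The response model is linear; threshold, saturating or cooperative
  responses are outside its class.
* The law is assumed homogeneous within the fitted table; heterogeneity is
  *diagnosed* (similarity spectrum, PCA) but not modeled hierarchically.
* The simulator is one-dimensional and open-loop: mechanics do not feed
  back onto ERK, so it cannot generate ERK wave patterns itself.
* Feature extraction needs locally dense neighborhoods (≥ 6 cells within
  the fit radius); sparse cultures or sheet edges lose records, which the
  drop counters make visible.
* Derivative features inherit the Savitzky–Golay pass-band: dynamics faster
  than ~5 frames are attenuated before they reach the regression.
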