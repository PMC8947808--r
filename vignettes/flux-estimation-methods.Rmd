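---
title: "Isotope-assisted flux estimation with fluxnlp: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-assisted flux estimation with fluxnlp: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxnlp)
```

## The estimation problem

Stable-isotope metabolic flux analysis (MFA) estimates in-vivo reaction
rates from the isotope labeling patterns that a ^13^C-labeled substrate
imprints on intracellular metabolites. A network of reactions with known
carbon atom transitions predicts, for any candidate flux distribution, the
mass isotopomer distributions (MIDs) of measured fragments; the fluxes (and,
for isotopically nonstationary experiments, the metabolite pool sizes) are
chosen to minimize the variance-weighted sum of squared residuals (SSR)
between predicted and measured labeling:

$$ z \;=\; \sum_{n}\left(\frac{h_n\,m^{meas}_n - m_n}{\sigma_n}\right)^2
   \;+\; \sum_{r}\left(\frac{v^{meas}_r - v_r}{\sigma_{v,r}}\right)^2
   \;+\; \sum_{m}\left(\frac{p^{meas}_m - p_m}{\sigma_{p,m}}\right)^2 $$

subject to the model equations as equality constraints: the labeling
balances, metabolic steady state $S v = 0$, flux bounds and linear
inequality constraints, the tie between measurement- and fragment-level
scaling factors $h$, and the linear mapping $m = M x$ from labeling states
to simulated measurements. Scaling factors multiply the *measured* values,
accommodating incomplete or unnormalized MIDs; for complete normalized MIDs
they are fixed at 1.

## Labeling state models

Two state representations are supported behind a common interface:

* **Cumomers.** For each metabolite with $n$ tracked carbons there is one
  state per atom subset: the probability that all atoms in the subset are
  ^13^C. The weight-0 state is identically 1. Cumomer balances form a
  *weight cascade*: the balance of a weight-$w$ state is linear in weight-$w$
  states given all lower weights, because bimolecular (condensation) terms
  couple a product state only to strictly lighter reactant states. All
  $2^n$ states are enumerated per metabolite. Tandem-MS observables (joint
  parent/daughter mass distributions) are linear in cumomers, so tandem
  data require this framework.
* **Elementary metabolite units (EMUs).** States are the mass fractions
  $M{+}0 \dots M{+}w$ of the atom subsets reachable backward from the
  measured fragments; condensation convolves the MIDs of the two reactant
  units. The decomposition yields the minimal system needed to simulate
  single-MS measurements and is the economical choice for large networks.

Both models are stored as sparse arrays $Q$ (bimolecular production,
symmetric, with doubled diagonal entries so that the $\tfrac12 \sum Q x x$
form reproduces $s\,x_i x_j$ exactly), $P$ (unimolecular production and the
$-s$ diagonal consumption entries) and $P^{inp}$ (entry of fed compounds),
assembled directly from per-reaction atom maps. States of input metabolites
are carried in the composite vector and pinned to their tracer-determined
values.

A brute-force isotopomer model (`oracleSteadyState()`,
`oracleTrajectory()`) enumerates all $2^n$ isotopomer balances per
metabolite with no shared machinery; it is the package's independent
cross-check on small networks, and both pipelines are required to agree
with it to $10^{-8}$ in the test suite.

## Forward simulation and nonstationary transcription

At labeling steady state the cascade is solved level by level, one sparse
linear solve per weight. The labeling dynamics
$p_k\,\dot x_k = \sum_r v_r(\dots)$ are integrated either with classical
RK4 (the fixture generator's default, step 0.02) or with `deSolve::lsoda`.

For nonstationary fitting the ODE system is *transcribed* into algebraic
constraints with Radau IIA orthogonal collocation. The scheme of order
$2s-1$ ($s \in \{2,3,5\}$, orders 3/5/9) is constructed at run time from
first principles — nodes as the zeros of the right Radau polynomial
$P_s(2t{-}1)-P_{s-1}(2t{-}1)$, then Runge-Kutta matrix, weights and
integrated-Lagrange basis functions $B_\alpha(\tau)$ by exact polynomial
integration — rather than from hard-coded decimals; the unit tests verify
the 2- and 3-stage schemes against their classical closed forms and all
schemes against the stiff-accuracy identities. Radau IIA is used for its
L-stability: labeling experiments are stiff, with the fast transient at the
start, so grids should use short early intervals and can widen later
(`geometricTimeGrid()` encodes this shape). An over-wide early interval
degrades only that interval's approximation; later intervals still track
the true solution — this behavior is asserted in the tests.

Per time interval the stage equations inherit the weight cascade: given all
lighter states, the stage derivatives of one level satisfy a linear system
$(I_s \otimes \mathrm{diag}(p) - h\,(a \otimes P_v))\,k = \text{rhs}$, so
the transcribed system is solved *exactly*, level by level and interval by
interval (`solveTranscribed()`), and measurement times are evaluated with
the polynomial interpolant $x(\tau) = x_{\gamma-1} + h\sum_\alpha
B_\alpha(\tau)k_{\alpha\gamma}$. `transcriptionResiduals()` re-evaluates
the three constraint families from stored variables for auditing.

## How the equality-constrained program is solved

The estimation problem is posed with the model equations as equality
constraints (`assembleSteadyNLP()`, `assembleInstNLP()`;
`problemDimensions()` reports the size of the full system). The solver
eliminates the constraints exactly rather than handing them to a
general-purpose nonlinear programming backend:

* fluxes are parametrized on the affine space $\{v: S v = 0,\ v_{fixed}\}$
  through a full SVD null-space basis;
* pool sizes are optimized in logarithms with exact box bounds;
* labeling states are solved from the (transcribed) balances by the exact
  cascade at every candidate point, so the equality feasibility of any
  returned solution is at linear-algebra precision (well below the 1e-7
  feasibility tolerance of the solver contract);
* scaling factors are profiled analytically per fragment (and time);
* flux bounds and inequality rows enter as penalty residuals, scaled above
  the largest measurement weight and checked a posteriori.

The reduced problem — typically a handful of free fluxes plus log pools —
is minimized with Levenberg-Marquardt (`minpack.lm::nls.lm`). Two
robustness devices address the local-optimum structure of nonstationary
problems (pool/flux compensation along transit-time ridges): a measurement
homotopy (the fit is first solved with standard deviations inflated 25x,
which flattens narrow basins, then re-solved at the true weights from that
point), and a repair pass that re-centres pool sizes stranded at their
bounds, where the labeling transient carries no gradient. `multistart()`
additionally screens a batch of sampled feasible points by their objective
value — cheap, since states are solved directly — and launches the full
solve from the two best candidates of each restart.

The recommended workflow follows the two-stage refinement pattern: a
3rd-order multistart to locate the optimum cheaply, then `refineFit()`
re-transcribes at 9th order and re-solves from the best low-order solution.
Goodness of fit is judged against `chi2Acceptance(nMeas, nParams)`, the
0.95 chi-square quantile with `nMeas - nParams` degrees of freedom, where
the free parameters are the independent fluxes plus free pool sizes and
scaling factors. Judge acceptability on the *refined* SSR: the low-order
transcription inflates (or occasionally deflates, by overfitting noise) the
SSR by its discretization error.

Confidence intervals use a parametric bootstrap (`bootstrapCI()`):
measurements are resampled as $N(\hat m, \sigma)$ around the fitted values
and refit from the point estimate. Two details matter on weakly identified
(ridge-shaped) problems, where refits started exactly at the point estimate
converge to the nearest ridge point and understate the resampling spread:
the refits keep the homotopy stage, and each refit's starting point is
jittered (Gaussian, sd 0.3 in the reduced coordinates; well-identified
refits converge to their optimum regardless of the start, so the jitter
does not inflate tight problems). Nonparametric residual resampling is not
offered because time-series MIDs have no exchangeable residual blocks.

## Feasible starting points

`sampleFeasibleFluxesPools()` draws flux vectors by solving linear programs
with random-cosine objectives over the flux polytope (via `boot::simplex`,
after removing linearly dependent stoichiometric rows) and blending pairs
of vertex solutions with a random convex weight; pool sizes are drawn
log-uniformly within their bounds. Every draw satisfies
$\lVert S v \rVert_\infty \le 10^{-9}$ and all bounds. Seeds derive from a
single master seed by a counter, so each restart is reproducible in
isolation.

## The bundled synthetic study

`toyNetwork()` is a small synthetic nonstationary benchmark: substrate A
enters at a known rate (v0 = 1, encoded as `lb = ub`) and is converted to
product B by three pathways with distinct carbon rearrangements — an
intact, partly reversible route via C, and two cleavage/recombination
routes through a shared one-carbon pool D and two-carbon units E and F.
With a 100% U-^13^C feed and zero natural abundance the steady state is
uninformative (everything fully enriched), so all flux and pool information
sits in the labeling transient, and the three routes are distinguishable
because they place independently labeled one- and two-carbon units at
different positions of B — visible in the B[1,2], B[2,3] and B[1,2,3]
fragment MIDs. Intact-transfer-only pathway sets would be *unidentifiable*
under uniform labeling (atom permutations are invisible); the cleavage
signatures are what make this fixture estimable.

Generating conditions: fluxes (v1 net 0.25 with exchange 0.3, v3 = 0.3,
v5 = 0.45), pools A..F = (1.5, 4, 2, 0.5, 0.8, 0.6) in flux·time units,
measurements of the three B fragments at t = 2, 4, ..., 20 with Gaussian
noise of sd 0.01 (the sd recorded in the table, floored at 1e-4 when
simulating noise-free data), data generated by RK4 with step 0.02. The
default grid (`toyGrid()`) uses eight intervals, dense early (first
interval [0, 1]) because the fastest pool (D at 0.5 with throughput 0.75)
turns over in under a time unit; a first interval wider than the fast
transient leaves a visible discretization error that can split the optimum
into spurious nearby local optima.

What the generator emulates: labeling dynamics at metabolic steady state,
complete normalized MIDs, independent Gaussian measurement error. What it
does not: metabolic (flux) transients, correlated instrument error,
incomplete or unnormalized spectra (exercised separately through the
scaling-factor machinery), natural-abundance contamination of the toy data
(the toy sets natural abundance to zero; the correction machinery is tested
on other fixtures). Passing tests therefore demonstrate correctness of the
machinery under these idealized conditions, not instrument-level realism.

## Numerical choices and degenerate inputs

* Natural ^13^C abundance defaults to 0.0107 and is configurable; isotope
  tables for C, H, N, O, S and Si drive the natural-abundance convolution
  operator for non-backbone atoms, which is column-stochastic and is folded
  into the measurement mapping.
* Cumomer-to-isotopomer inversion is exact; isotopomer entries in
  $[-10^{-9}, 0)$ are clamped to zero with renormalization and a warning,
  larger negativity is an error (it indicates inconsistent cumomer values,
  not roundoff).
* Numerical rank (independent-flux counting, null-space construction) uses
  an SVD with tolerance $10^{-10}\,\sigma_{max}$.
* Zero-flux dead ends make a cascade level singular; the error names the
  unreachable states. Vertex starting points can zero out whole pathways,
  which is why interior blends are used for fixtures.
* A measurement exactly at a grid node belongs to the interval ending
  there ($\tau = 1$), avoiding duplicate rows.
* Reversible reactions are split into forward/backward parts with
  nonnegative fluxes and a per-direction upper bound (default 1000) that
  keeps the sampling polytope bounded; finite net-flux bounds become
  inequality rows.

## Problem sizes used by the test suite and acceptance script

Chosen to characterize the method at desk scale: oracle comparisons on
fixtures with at most 12 tracked carbons; convergence-order studies on 2 to
16 intervals; multistart robustness with 10 restarts on one toy study;
parameter-recovery coverage over 10 simulated studies, each estimated by a
2-restart multistart and 20 bootstrap resamples. The published benchmark
reproductions (the *E. coli* central-carbon model and its tandem/single-MS
data sets) require supplementary inputs that are not redistributable here;
the corresponding checks run whenever those files are placed under
`inst/extdata` (see `tests/testthat/test-acceptance.R` for the expected
file names).

## Known limitations

* The solver is a reduced (elimination-based) method: robustness against
  distant local optima relies on the homotopy, screening and multistart
  devices rather than on the merged-basin behavior that a simultaneous
  sparse NLP solver can provide; hard problems may need more restarts.
* At most two carbon-carrying reactants may contribute atoms to any
  product (trimolecular carbon condensations are rejected).
* Only carbon is tracked as the tracer atom; other elements appear only in
  the natural-abundance correction.
* Tandem fragments require the cumomer framework, and natural-abundance
  formulas are supported for single-MS fragments only.
* Bondomer/fluxomer representations, adaptive mesh refinement and
  profile-likelihood intervals are out of scope.
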