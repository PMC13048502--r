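---
title: "Emergent coexistence in random Lotka-Volterra communities: models, metrics and design choices"
author: "ecglv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent coexistence in random Lotka-Volterra communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecglv)
```

## The model and the question

Microbial community experiments routinely find stable multispecies
communities containing pairs of species that drive each other extinct when
cultured alone.  `ecglv` studies this *emergent coexistence* (EC) in the
generalized Lotka-Volterra (GLV) model.  After dividing abundances by
carrying capacities (relative yields $x_i = N_i/K_i$) and measuring
interactions relative to self-regulation, the dynamics are

$$\frac{dx_i}{dt} = r_i x_i \Big(1 - x_i + \sum_{j \ne i} A_{ij} x_j\Big),$$

where $A_{ij}$ (zero diagonal) is the effect of species $j$ on species $i$.
A pair is *excluding* when $A_{ij} < -1$ or $A_{ji} < -1$: competition
stronger than self-regulation precludes stable two-species coexistence.  A
stable state with $S^* \ge 3$ survivors and at least one excluding pair is
an EC state.  The package asks when EC arises in random interaction
ensembles, how much exclusion a community can carry, and which
indirect-effect mechanisms (collectivity, conditioning, feedback loops,
intransitivity) explain it.

Interior equilibria solve $(I - A^*)\,x^* = \mathbf{1}$ and are independent
of the growth rates $r_i$; a candidate community is *feasible* when all
components of $x^*$ are positive and *linearly stable* when all eigenvalues
of the Jacobian $J_{ij} = r_i x_i^* A^*_{ij}$ ($i \ne j$),
$J_{ii} = -r_i x_i^*$ have negative real part.

## What the synthetic ensembles emulate

All inputs are synthetic.  `ensemble_spec()` / `sample_matrix()` generate:

* **random** — i.i.d. Gaussian off-diagonals with mean $\mu$ and standard
  deviation $\sigma$ (the studied ranges are $\mu \in (-2, 0.5)$,
  $\sigma \in (0, 1)$), masked by an Erdős–Rényi connectivity $C$
  (default 1).  The mask applies independently per directed entry; a paired
  option realizes both directions together.
* **symmetric / antisymmetric** — pairwise mirrored or anti-correlated
  (centered correlation $\rho$, default $-1$) coefficients, used to test
  how reciprocity constrains EC.
* **triangular** — upper triangle random, lower triangle zero: a strict
  hierarchy in *who affects whom* without a hierarchy in strengths.
* **k_correlated** — random raw interactions $a_{ij}$ rescaled by
  heterogeneous carrying capacities $K_i \sim \mathcal U[0.5, 1.5]$,
  $A_{ij} = a_{ij} K_j / K_i$, so high-$K$ species impact others strongly
  and are weakly impacted.
* **crossfeeding** — single-resource competition with cross-feeding:
  $B_{ij} = C_{ij} - 2\gamma_j/(\gamma_i + \gamma_j) - \alpha_{ij}$ with
  consumption traits $\gamma \sim \mathcal U[0.3, 0.7]$ sorted decreasing
  (species order equals the competitive hierarchy), weak extra competition
  $\alpha \sim \mathcal N(0.1, \mathrm{sd} = 0.01)$ and cross-feeding
  benefits $C_{ij} \sim \mathcal U[0, 1]$.  In every Gaussian the second
  parameter is a standard deviation, never a variance.

Growth rates are $\mathcal N(1, \sigma_r)$ with non-positive draws
resampled; this truncates the distribution imperceptibly at the
$\sigma_r$ used here.  The generator is seeded and bit-reproducible.

What the ensembles deliberately do **not** emulate: saturating or
higher-order functional responses, demographic noise, migration, empirical
network topology beyond Erdős–Rényi connectivity, and time-series
measurement error.  Passing tests therefore demonstrate properties of the
GLV ensemble model, not of any particular real community.

## The simulation protocol and its numerical choices

`integrate_glv()` integrates the GLV equations with `deSolve::lsoda`
(relative tolerance $10^{-8}$, absolute $10^{-10}$) from random initial
conditions $x_i(0) \sim \mathcal U[0,1]$ for a transient $\Delta t_1 = 3000$
time units, then tests stationarity over a further $\Delta t_2 = 100$.
Choices that matter:

* **Extinction threshold** ($10^{-4}$ on relative yield, configurable).
  Species dipping below it at a checkpoint (every 50 time units) are
  hard-zeroed for the remainder.  The value sits at least two orders of
  magnitude below every feasible equilibrium in the studied parameter
  ranges and six above integrator tolerance.  It is deliberately not
  smaller: near-neutral losers are excluded at rates down to $10^{-4}$
  per unit time, and a much lower threshold leaves such doomed stragglers
  above threshold at $\Delta t_1$, misclassifying converged communities as
  non-stationary.
* **Stationarity** — maximum relative change of every surviving abundance
  across the window below $10^{-3}$ (relative to
  $\max(x_i(t_1), \text{threshold})$).  Bounded non-stationary outcomes
  (cycles, chaos, slow exclusions) are labelled `non_stationary` and
  excluded from EC counting; they are not errors.
* **Divergence** — any abundance reaching $10^6$ marks the run `diverged`
  (the mutualistic outgrowth regime has no finite attractor).  Growth is
  frozen at the cap inside the right-hand side so the solver reaches the
  next checkpoint cleanly instead of chasing a finite-time blowup.
* A trajectory that is stationary at $\Delta t_1 = 3000$ can still carry a
  slowly relaxing mode at amplitude above $10^{-4}$; where survivor
  abundances are compared against the algebraic equilibrium we integrate
  twice as long, which brings the agreement to $10^{-8}$.

`surviving_community()` re-verifies every dynamical outcome algebraically
(feasibility and linear stability of the survivor submatrix), and
`sample_stable_subsets()` finds stable states directly by uniform subset
sampling — the two routes agree exhaustively on small pools
(`enumerate_stable_subsets()`).  Stability uses a tolerance of $10^{-9}$
on the spectral abscissa; marginal spectra are reported and rejected.
Characteristic-polynomial coefficients are assembled from the eigenvalues
rather than by determinant expansion, which is numerically robust at the
community sizes (≤ 15) relevant here; the second Routh–Hurwitz quantity
$\Lambda_2 = C_1 C_2 - C_3 > 0$ is asserted for every accepted community.

## Analytic boundaries and bounds

**EC regime.** Exclusionary coefficients appear in the pool once
$P = 1 - \big(1 - \Phi(-(1+\mu)/\sigma)\big)^{S(S-1)}$ crosses one half
(boundary $\sigma_{1c}$, found by bisection; the crossing level is
configurable because the transition is sharp in $S$).  EC additionally
needs at least one mutually non-exclusionary pair to sustain an excluded
species, giving the upper boundary $\sigma_{2c}$ from
$1 - (1 - q)^{S(S-1)/2}$, $q = \Phi((1+\mu)/\sigma)^2$.  Both are
necessary, not sufficient — symmetric ensembles have exclusionary pool
elements yet provably no EC states, which the tests verify empirically
over thousands of stable symmetric communities.

**Fraction bounds.** An EC community of size $S^*$ carries at least
$2/(S^*(S^*-1))$ excluding pairs.  The upper envelope combines (i) a
maximum-diversity estimate and (ii) the pool fraction of exclusionary
pairs $f = 1 - \Phi((1+\mu)/\sigma)^2$, under the assumption that
surviving communities are statistically no more competitive than their
pool (states more competitive than the pool exist but are rare; the
envelope is a heuristic and the tests assert an exceedance rate below 5%
on dynamically assembled EC communities — directly sampled subsets run
slightly more competitive and are not the ensemble the bound addresses).

**Maximum diversity.** The estimate of the largest stable community for
pool statistics $(\mu, \sigma)$ was a genuinely open design point.  We use
a moderate-size argument: inside the multistability regime, stable-state
richness tracks the maximal clique of the pairwise-coexistence network,
an Erdős–Rényi graph with coexistence probability
$p = \Phi((1+\mu)/\sigma)^2$, whose maximum clique is asymptotically
$2 \ln S / \ln(1/p)$ (capped at the pool size $S$).  Eliminating $p$
between the two pieces gives the closed-form envelope
$f(S^*) = 1 - S^{-2/S^*}$ (`excluding_fraction_envelope()`): about 95% at
$S^* = 3$, 75% at $S^* \approx 6$, 60% at $S^* = 10$ for $S = 80$ — a
decaying curve consistent with the simulated communities.  A variant that
inverts the mean-corrected random-matrix stability criterion is available
(`method = "may"`) but collapses for $\mu \le -1$, where EC lives; the
clique estimate is the default.  `max_stable_diversity()` isolates the
formula so a refined one can be swapped in.

**May threshold.** For diagnostic purposes `may_threshold()` returns
$\mu_c = \sqrt{S^*/2}\,\sigma^* - 1$: classical random-matrix reasoning
expects instability once the mean interaction falls below it (both the
square-root and the literal product reading coincide at $\sigma^* = 0$,
where $\mu_c = -1$; the literal form is available behind a flag).
Moderately sized communities with strong competition are routinely stable
beyond this threshold — the package flags them (`violates_may`) rather
than rejecting them, and balanced feedback loops ($\Lambda_2 > 0$) account
for their stability.

## Collectivity, conditioning and the two experiments

The net effect of species $j$ on the equilibrium of species $i$ is element
$(i,j)$ of $(I - A^*)^{-1}$, the sum of the Neumann series
$I + A^* + (A^*)^2 + \dots$, which converges exactly when the spectral
radius $\phi$ of $A^*$ (the *collectivity*) is below 1.  Tests assert the
convergence contract on both sides ($\phi = 0.9$ versus $1.1$, tolerance
$10^{-6}$ at order 200).  Random-matrix estimates
$\hat\phi = \max\{(S^*-1)|\mu^*|,\ \sqrt{S^*-1}\,\sigma^*\}$ (square-root
circular-law scaling; the linear-in-$S$ variant is behind a flag) provide
envelopes over the parameter grid.  The condition number
$\kappa = s_M/s_m$ defaults to the operator actually inverted,
$I - A^*$, with $\kappa(A^*)$ selectable; its lower envelope across
EC-compatible statistics is estimated by Monte-Carlo minimum by default
(`kappa_min_bound()`), with an RMT singular-value heuristic as the
alternative.

Two experiments probe predictability:

* `prediction_error_experiment()` — communities with $\kappa(I-A^*)$
  within ±20% of a target are perturbed coefficient-wise by multiplicative
  Gaussian noise of relative sd 0.1 (zero entries stay zero; additive
  noise is a flag), and success means the perturbed matrix still predicts
  full-set feasibility and stability.  Success decreases steeply with
  $\kappa$, which is the mechanism the experiment demonstrates.  The
  absolute success levels depend strongly on protocol details that are
  genuinely underdetermined — noise law, scoring direction (conditioning
  on true coexistence versus on predicted coexistence), whether truth is
  scored algebraically or by re-running dynamics from random initial
  conditions, and the composition of the $\kappa$ band.  We examined all
  of these variants; they shift success by tens of percentage points
  while preserving the decay with $\kappa$.  The package keeps the
  simplest fully specified default and reports its honest numbers.
* `assembly_from_pairs_experiment()` — species sets whose every pair
  coexists in isolation are tested for full-set coexistence; the success
  rate is tabulated against the set's $\phi$ and drops as $\phi$ grows,
  quantifying when pairwise screening stops predicting community outcomes.

Across EC communities assembled by the dynamics, a little under half
(≈ 0.46 in our scaled-down ensembles) of the off-diagonal net effects are
positive even though all direct effects are competitive — indirect chains
with an even number of links flip signs.  The fraction rises slowly with
community size.

## Intransitivity

`exclusion_digraph()` orients each excluding pair winner → loser.  Pairs
exclusionary in both directions (bistable) have no model-defined winner:
the default rule lets the species hit by the larger-magnitude coefficient
lose (deterministic tie-break: the lower index wins), and an `unoriented`
rule excludes them from rank and upset counting while keeping them as
excluding pairs — the choice is an explicit sensitivity axis, since the
empirical counterpart (observed co-culture winners) has no model
equivalent.  Ranks are (wins − losses)/(S*−1); a low-rank exclusion (LRE)
is an edge whose winner ranks strictly below its loser (ties are not
upsets), reported both raw and corrected (only for communities with at
least four excluding pairs, since LRE motifs need that many).  A triplet
of three mutually excluding species is rock-paper-scissors (RPS) when its
edges form a directed 3-cycle; 2 of the 8 equally likely orientations are
cyclic, so the null fraction is exactly 0.25 (asserted by enumeration and
by Monte-Carlo calibration).  `intransitivity_scan()` compares random,
reshuffled (off-diagonal permutation of each found community — the
structure-free control), triangular, carrying-capacity-correlated and
cross-feeding ensembles: the hierarchical families show essentially zero
RPS while the reshuffled control sits near 0.25, demonstrating that EC
does not require intransitive competition.

## Problem sizes used by tests and the acceptance script

The original experiments run 100 systems of 80 species per grid cell over
hundreds of cells and $10^7$ subset draws per community size.  The package
validates the same pipeline at desk scale, a deliberate choice of study
size: phase-diagram assertions use 30 systems per cell at $S = 80$;
community harvests use a coarse 4 × 3 grid with 2500 subset draws per size
(3–10) per cell, yielding $\sim 10^4$ stable communities; the dynamical
EC ensemble uses 6 EC-regime cells × 14 systems with a doubled transient.
Statistical assertions are made at tolerances appropriate to these sizes
(binomial confidence bands, medians, orderings), and the acceptance script
recomputes its quantities from scratch at the same scale in a few minutes.

## Known limitations

* The maximum-diversity estimate and the $\kappa$ lower envelope are
  heuristics behind single swap points, not theorems.
* Absolute success levels of the measurement-error experiment are
  protocol-dependent (see above); only the decay with $\kappa$ is robust.
* Near-neutral species make stationarity classification at finite
  horizons intrinsically fuzzy; the extinction threshold and stationarity
  tolerance trade off misclassification directions, and both are exposed
  as parameters.
* Linear (local) stability only; no permanence or structural-stability
  analysis.
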