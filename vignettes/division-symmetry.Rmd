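---
title: "Division symmetry and homeostasis in a two-compartment stem-cell lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Division symmetry and homeostasis in a two-compartment stem-cell lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclineage)
```

## The model

`sclineage` studies the simplest cellular lineage: a compartment of stem
cells (SCs, count $I$) and one compartment of differentiated cells (count
$J$). At every update one of the following events may occur, with
population-level weights (each weight is the probability that *some* cell
performs the event in one update):

| event | weight | effect |
|---|---|---|
| symmetric differentiation | $L\,S\,P$ | $(I,J)\to(I-1,\,J+2)$ |
| symmetric proliferation | $L\,S\,(1-P)$ | $(I,J)\to(I+1,\,J)$ |
| asymmetric division | $L\,(1-S)$ | $(I,J)\to(I,\,J+1)$ |
| death of a differentiated cell | $D$ | $(I,J)\to(I,\,J-1)$ |
| exogenous SC influx (optional) | $E$ | $(I,J)\to(I+1,\,J)$ |

$L$ is the SC division rate, $S$ the probability that a division is
symmetric, $P$ the probability that a symmetric division differentiates,
and $D$ the death rate. All four are functions of the *scaled* populations
$x=\epsilon I$, $y=\epsilon J$; the parameter $\epsilon>0$ measures how
strongly the populations feed back on the rates, and equilibrium
populations scale as $1/\epsilon$. A *control network* is a choice of
these functions; its essential content at an equilibrium is the four
partial derivatives with respect to the counts,
$$q_x = \partial_I(L-D),\quad q_y = \partial_J(L-D),\quad
  p_x = \partial_I P,\quad p_y = \partial_J P,$$
each of order $\epsilon$. A positive control means "more cells of that
type promote the process", a negative one the opposite.

The mean-field (deterministic) limit is
$$\dot I = L\,S\,(1-2P) + E,\qquad \dot J = 2\,L\,S\,P + L\,(1-S) - D .$$

## Steady states

For a closed system ($E=0$) the *mixed-divisions* steady state solves
$P = 1/2$ and $L = D$: symmetric differentiation balances symmetric
proliferation, and total production balances death. Neither condition
involves $S$, so the equilibrium populations are independent of the
division symmetry — only stability and fluctuation size depend on it
(`solve_mixed()` checks this residual to $10^{-10}$). The *purely
asymmetric* state ($S=0$) needs only $L = D$; since asymmetric divisions
conserve $I$, the SC count is fixed by the initial condition, and
`solve_asymmetric()` flags the resulting one-parameter solution curve
unless the user pins `i0`.

Two closed presets instantiate minimal three-control networks:

* `make_model3()`: $L = (1-e^{-x})/(1-e^{-x}+y)$, $P = 1-e^{-3y}$,
  $D = 1-L$ — divisions promoted by SCs and damped by differentiated
  cells, differentiation promoted by differentiated cells
  ($q_x>0$, $q_y<0$, $p_y>0$; system #3).
* `make_model5()`: $L = 2\tanh x/(2\tanh x + 0.4)$,
  $P = \tanh(x+0.1y)$, $D = 1-L$ — divisions and differentiation promoted
  by SCs, differentiation also by differentiated cells
  ($q_x>0$, $p_x>p_y>0$; system #5). This wiring mirrors autonomous
  control in mouse interfollicular epidermis: short-range WNT signals from
  basal SCs promote division, long-range Dkk1 promotes differentiation,
  and suprabasal Notch activity further drives differentiation.

A third preset, `make_follicle_model()`, modifies the second: a division
rate with a 0.9 numerator coefficient, $D = h + 0.01y$ decoupled from
$L$, and an optional exogenous SC influx $E = 0.02/(1+x)$ that stands for
hair-follicle SCs migrating into the interfollicular pool — strongest
when the resident SC pool is depleted. Setting `influx = FALSE` models
hairless (paw/footpad) skin.

## Fluctuations: linear-noise variances

Expanding the master equation around the mixed equilibrium to leading
order in $\epsilon$ gives Gaussian stationary fluctuations with
$$\mathrm{Var}[I] = \frac{K_x}{4B\Delta},\qquad
  \mathrm{Var}[J] = \frac{K_y}{4B\Delta},$$
$$\Delta = q_xp_y - q_yp_x,\qquad B = 2L^*S^*(p_x-p_y) - q_y,$$
$$K_x = 2L^*S^*\Delta + q_y^2 + 8L^{*2}S^*p_y^2,\qquad
  K_y = 2L^*(2+S^*)\Delta + q_x^2 + 8L^{*2}S^*p_x^2 .$$
The equilibrium is stable iff $\Delta>0$ and $B>0$. Only $B$ involves
$S^*$, which yields the *critical symmetry*
$$S_c = \frac{q_y}{2L^*(p_x-p_y)} :$$
for $p_x>p_y$ the stable side is $S^*>S_c$, for $p_x<p_y$ it is
$S^*<S_c$, and for $p_x=p_y$ the threshold degenerates ($B=-q_y$,
independent of $S^*$; `stability()` reports a signed infinity). The test
suite verifies the closed forms against an independent brute-force solve
of the truncated moment system — including the first-derivative terms of
$L$, $S$ and $D$, which cancel because the first moments vanish.

Differentiating the variances in $S^*$ (only $K_x$, $K_y$, $B$ depend on
it, all linearly) gives
$$\frac{d\,\mathrm{Var}[I]}{dS^*}
   = \frac{L^*\,p_yq_y\,(q_y-q_x-4L^*p_y)}{2B^2\Delta},\qquad
  \frac{d\,\mathrm{Var}[J]}{dS^*}
   = \frac{L^*\,(p_xq_x-\Delta)(q_y-q_x-4L^*p_y)}{2B^2\Delta},$$
so each variance is monotone in $S^*$. `variance_sensitivity()` uses
exactly these expressions; the tests confirm them against central finite
differences of the variance formulas (step $10^{-4}$). Note that
$d\,\mathrm{Var}[I]/dS^*$ vanishes identically whenever $q_y=0$ or
$p_y=0$.

## Minimal control systems

`is_stabilizable()` decides, for a sign pattern of the four controls,
whether positive magnitudes, $L^*>0$ and $S^*\in(0,1]$ exist making
$\Delta>0$ and $B>0$. The decision is an exact sign calculus: $\Delta>0$
is achievable iff one of its two products can be positive, $B>0$ iff
$p_x>0$, $p_y<0$ or $q_y<0$, and free magnitudes decouple the two
conditions. A seeded sampling cross-check (1000 log-uniform magnitude
draws) agrees on all $3^4=81$ patterns. Enumeration finds exactly two
stabilizable two-control systems and three irreducible three-control
systems (irreducible: zeroing any single control destroys
stabilizability):

| system | signs | $\mathrm{Var}[I]$ vs $S$ | $\mathrm{Var}[J]$ vs $S$ | optimal mode |
|---|---|---|---|---|
| #1 | $q_x<0,\,p_y<0$ | constant | decreasing | symmetric |
| #2 | $q_y<0,\,p_x>0$ | constant | increasing | asymmetric |
| #3 | $q_x>0,\,q_y<0,\,p_y>0$ | increasing | increasing | asymmetric |
| #4 | $q_y>0,\,p_x<0,\,p_y<0$ | decreasing | decreasing | symmetric |
| #5 | $q_x>0,\,p_x>0,\,p_y>0$ | constant | decreasing | symmetric |

Within each system's stable regime these trends are sign-determined, so
`classify_network()` reports them from the pattern alone. The #4 pattern
deserves a note: it is the unique irreducible three-control pattern with
$q_x=0$ found by the enumeration, and it satisfies the expected #4
properties ($p_x>p_y$ attainable under stability, a genuine
$S_c\in(0,1)$ so that *reducing* symmetry can destabilize, and both
sensitivities negative).

The headline qualitative result: whether asymmetric divisions stabilize
or destabilize a lineage depends on the wiring. In #2 and #3 asymmetric
divisions minimize fluctuations; in #1, #4 and #5 symmetric divisions do.

## The stochastic simulator

`simulate()` performs one update attempt per time step. For the closed
$D=1-L$ presets the weights sum to exactly 1, so every update is an
event; in general, when the weight sum $W$ exceeds 1 the event is drawn
with normalized probabilities $w/W$, otherwise the weights are used as
literal Bernoulli probabilities and the update may be idle. Division
weights are zeroed at $I=0$ and the death weight at $J=0$, so counts stay
nonnegative. Runs start at the rounded-up mixed equilibrium (for influx
networks, at the influx-aware mean-field attractor, since the exogenous
source shifts the steady state and makes it $S$-dependent) and moments
are taken per step over the whole run (`burn_in = 0` by default).

The built-in presets run in compiled code; custom networks use an R
stepper with the identical random-number protocol, so preset
trajectories are bit-identical across engines for the same seed — a
cross-check the tests exercise. An exact event-time scheme (exponential
waiting times, no idle draws) is available for continuous-time readings.
Replicate sweeps derive cell seeds as
`seed + (cell - 1) * replicates + (replicate - 1)`.

Two perturbations model the epidermal case study:

* **Micro-injury** (`injury_config()`): with probability
  `update_fraction` an update instead removes
  `round(removal_fraction * J)` differentiated cells (variants: remove
  SCs, or multiply the death rate for that update). Injuring the
  differentiated compartment is the default — it faces the tissue
  surface, while SCs sit deeper. Defaults for the study conditions:
  0.01% of updates, 10% removal, with `make_model5(epsilon = 0.002)`.
* **Exogenous influx**: the follicle preset's $E>0$, with $h = 0.3$ and
  $\epsilon = 0.05$ (small populations, tens of cells, as appropriate
  for a single epidermal proliferative unit). With an influx, $I=0$ is
  not absorbing — the source can rescue the SC pool — so sweeps disable
  stop-on-extinction.

Two relative-fluctuation summaries are reported for $J$: the
variance-to-mean ratio `rel_sd_J` $=\mathrm{Var}(J)/E(J)$ and the
coefficient of variation `cv_J` $=\sqrt{\mathrm{Var}(J)}/E(J)$. They can
trend differently when the mean itself depends on $S$ (exactly the
influx case), and the CV is the measure used for the follicle
comparison, since "fluctuation size relative to the mean" is what
distinguishes the two tissue scenarios. The acceptance checks find, at
the study conditions above: under micro-injury both ratios *decrease*
with $S$ (symmetric divisions buffer random cell loss); with an influx
the CV *increases* with $S$ while without it it *decreases* — an
exogenous SC source favors asymmetric divisions, its absence favors
symmetric ones. This offers a mechanistic reading of why hairless,
abrasion-prone paw epidermis shows a higher symmetric-division fraction
(~40%) than hairy ear/tail skin (~20%).

## Numerical choices

* Mixed-equilibrium root: damped Newton on the scaled residual
  $(P-\tfrac12,\ L-D)$, initial guess $(1,1)$, multi-start on a
  log-spaced grid over $[10^{-3},10]^2$ as fallback, residual
  $<10^{-10}$; iterates are clamped to the nonnegative quadrant.
* Controls: analytic derivatives when the network supplies them
  (all presets do); otherwise central differences with step
  $10^{-6}\max(1,|{\rm coord}|)$ — controls are $O(\epsilon)$, so the
  step must scale with the coordinate, not the control.
* Mean-field integration: `deSolve::ode` (lsoda), `rtol = atol = 1e-9`,
  divergence guard at $10^9$ cells.
* Sensitivity cross-checks: central differences in $S^*$ with step
  $10^{-4}$; well-conditioned comparisons keep $\Delta, B$ away from the
  non-hyperbolic boundary, where the rational forms blow up.
* Injury removal count: nearest integer, floored at zero; one uniform
  per update decides injury, one decides the event — a fixed draw
  protocol shared by both engines.

## Problem sizes used by the test and acceptance suites

Equilibrium, enumeration and sensitivity checks are closed-form and run
in milliseconds. The simulation-versus-theory grid uses
$\epsilon = 0.005$, $S\in\{0.3, 0.5, 0.8, 1.0\}$, 20 replicates of
$2\times10^5$ updates per cell for both presets; the perturbation sweeps
use 9 symmetry values $\times$ 10 replicates of $2\times10^5$ updates.

## What the generator does and does not emulate

The simulator realizes exactly the update rules above: population-level
rates, one event per update, feedback through scaled counts. Passing
tests therefore demonstrate internal consistency of the stochastic
process, the analytic approximations, and the enumeration — not fidelity
to any particular tissue. Real epidermis adds spatial structure (basal
crowding, spindle orientation forcing some divisions asymmetric),
signaling detail beyond sign structure, and wound-scale perturbations;
none are modeled. Known quantitative limits, which the test suite itself
measures: the leading-order theory predicts means only up to an
$O(1)$-cell correction (a few percent at $\epsilon = 0.005$, so
sufficiently long simulations resolvably exceed $i_0$), and it
underestimates variances as the stability boundary is approached (the
SC-damped preset at $S = 1$, where $B$ is smallest, shows roughly twice
the predicted variance at $\epsilon=0.005$, converging toward the
prediction as $\epsilon$ decreases). Away from the boundary, simulated
variances match theory within a few percent to 20%.
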