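---
title: "Maximum-entropy flux inference conditioned on a transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy flux inference conditioned on a transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pheflux)
```

## The inference problem

A genome-scale metabolic model constrains the vector of reaction rates
(the fluxome, $v$, mmol/gDW/h) through mass balance at steady state and
through flux bounds.  With reversible reactions split into forward and
reverse components so that all fluxes are nonnegative, the feasible set is
the polytope

$$P = \{\, v \in \mathbb{R}_+^{N} : S v = 0,\; LB \le v \le UB \,\},$$

where $S$ is the stoichiometric matrix.  $P$ typically has many degrees of
freedom, and a transcriptome does not remove them: mRNA abundance $g_i$ is
a proxy for enzyme copy number, but turnover rates and condition-specific
kinetic attenuation are unobserved.  The method implemented here resolves
the remaining freedom by the principle of maximum entropy: among all
feasible fluxomes, select the one whose distribution of flux per enzyme
copy,

$$P_g(v_i) = \frac{v_i / g_i}{V}, \qquad V = \sum_i v_i,$$

has maximal Shannon entropy

$$H_g(v) = -\sum_{i=1}^{N} \frac{v_i}{V}
  \log \frac{v_i / g_i}{V}.$$

This is simultaneously the least biased choice (information-theoretic
reading) and the fluxome realizable in the greatest number of microscopic
ways (statistical-mechanical reading).  Factoring $V$ gives the identity

$$H_g(v) = -\frac{1}{V} \sum_i v_i \log\frac{v_i}{g_i} + \log V,$$

so at fixed total flux $V$ maximizing $H_g$ equals minimizing
$\sum_i v_i \log (v_i/g_i)$ — the forward Kullback–Leibler divergence
between the normalized fluxome $P(v_i) = v_i/V$ and the normalized
per-reaction expression $Q(g_i) = g_i/G$.  Both formulations are exposed
(`solve_pheflux()`, `solve_pheflux_kl()`) and the test suite verifies that
they return the same flux vector on every packaged fixture.

## Parameters that matter

* **Total flux $V$** (`V_total`, default 1000, mmol/gDW/h summed over split
  fluxes).  The entropy objective is only determined up to the scale of
  $v$, so the program is solved on the slice $\sum_i v_i = V$.  The default
  is large enough that no reaction is forced against its `[0, 1000]` bound
  in the bundled models, and small enough to keep the slice inside the
  polytope.  Note that the sum runs over split fluxes, so both directions
  of a cycle count toward $V$.
* **Smoothing $\epsilon$** (`epsilon`, default $10^{-8}$, dimensionless on
  the scale of $g$ and $v$).  $\log(v_i/(g_i V))$ is undefined when a flux
  or an expression value is zero, so $\epsilon$ is added to both $v_i$ and
  $g_i$ inside the logarithm, and expression values are additionally
  floored at $\epsilon$ during mapping.  The KL solve floors $g$ only; its
  objective extends continuously to $v_i = 0$ ($0 \log 0 = 0$), and its
  optimizer is strictly positive in every coordinate anyway.
* **GPR semantics** (`or` in `evaluate_gpr()`/`map_expression()`).  Enzyme
  complexes (AND) evaluate to the minimum of their subunits' expression —
  capacity is limited by the scarcest subunit; isozymes (OR) evaluate to
  the sum — parallel enzymes add capacity.  `or = "max"` is available
  because the literature is split on this convention, and the choice does
  change the inferred fluxome.
* **Median imputation.**  Reactions whose GPR is absent or evaluates to
  missing receive the median of the GPR-derived values (computed over
  GPR-assigned reactions only, avoiding a self-referential definition).
  Both split directions of a reversible reaction share one expression
  value: a single enzyme catalyzes both directions.

## How the program is solved

At fixed $V$ the objective is strictly convex on the box, so the optimum
is unique — this is what makes the method reproducible, in contrast to
flux-balance approaches whose optimal faces are typically degenerate.  The
implementation exploits separability rather than calling a generic NLP
solver: the Lagrange dual of

$$\min_v \sum_i f_i(v_i)\quad\text{s.t.}\quad A v = b,\; lb \le v \le ub,
\qquad A = \begin{pmatrix} S \\ \mathbf{1}^\top \end{pmatrix},\;
b = \begin{pmatrix} 0 \\ V \end{pmatrix}$$

is smooth and concave in the $M + 1$ multipliers, with gradient
$A\,v(y) - b$, where the inner minimizer $v(y)$ separates coordinate-wise:
closed form for the KL family ($v_i = g_i e^{-1 - c_i}$ clipped to the
box) and a safeguarded vectorized Newton iteration for the
$\epsilon$-smoothed entropy family.  The dual is maximized by L-BFGS-B and
polished with damped Newton steps using the Hessian $-A D A^\top$,
$D_{ii} = 1/f_i''(v_i)$ on interior coordinates.  Convergence is declared
when $\|A v - b\|_\infty \le 10^{-9} \max(1, \|b\|_\infty)$, an order
tighter than the $10^{-6} V$ the result object guarantees.  Because the
primal optimum is unique, the returned fluxes are independent of the dual
start; the tests run ten random starts per fixture and require agreement
to $10^{-4} V$ per coordinate.  An empty slice (the polytope misses
$\sum v = V$) is reported as `status = "infeasible"`, not as an error, so
cohort runs continue.

The same dual engine with a quadratic family solves the least-distance
problems used for feasibility detection and as a fallback for the
ℓ2 stage of the FBA baseline; `quadprog` handles the standard quadratic
programs, and the FBA linear program runs on `pracma`'s simplex with its
randomized pivot tie-breaking pinned to a fixed stream (and retried under
fresh pivot seeds) so that every solve is reproducible.

## Baselines

* **SPOT** maximizes $g^\top v$ over $P$ intersected with the unit
  Euclidean ball.  Over the steady-state cone $\{Sv = 0, v \ge 0\}$ the
  maximizer on the unit ball is the normalized projection of $g$ onto the
  cone, computed exactly as a quadratic program; finite bounds scale onto
  the ball and are released.  The solution is rescaled to $\sum v = V$ for
  comparability — Pearson scoring is scale-invariant, so this affects only
  readability.
* **FBA + min ℓ2** maximizes biomass (linear program), then fixes biomass
  at exactly its optimum and minimizes $\sum_i v_i^2$, whose strict
  convexity selects a unique, cycle-free representative.  It never reads
  expression, which is exactly why it serves as the expression-blind
  reference in the benchmark.

## What the synthetic benchmark emulates

Real genome-scale fluxomes cannot be measured, so the benchmark
manufactures ground truth: `sample_fluxomes()` draws uniform samples from
$P$ by hit-and-run (isotropic directions inside the null space of $S$,
uniform steps along the feasible chord, thinning 100 by default, burn-in
five thinning intervals, started from the analytic center of the polytope
— the log-barrier minimizer, computed by the same dual engine — which is
strictly interior whenever a relative interior exists).  `generate_expression()` then builds
a transcriptome in which a seed-determined fraction $\lambda$ of reactions
has expression exactly proportional to its flux magnitude, while every
other reaction draws from an exponential distribution — matching the
exponentially decaying shape of real expression profiles — whose mean
equals the mean flux magnitude, so both groups share a scale.  Reaction
values reach gene level through dedicated one-gene-per-reaction GPRs in
the synthetic models; multi-gene GPR randomness is deliberately out of
scope of the generator.

`run_lambda_sweep()` scores each method against the reference samples by
Pearson correlation at two scales: the full network and a carbon-core
subset selected by glycolysis/TCA subsystem labels.  One pool of reference
samples is shared across all $\lambda$ values: the expression-blind
baseline then produces literally identical correlations at every
$\lambda$ (a designed invariant), and method contrasts are paired across
$\lambda$, which removes sampling noise from the trend.

The default benchmark network (`make_synthetic_network()`) has 30 internal
reactions in a 4-layer, 3-metabolites-per-layer feeding structure plus
three uptakes (bound 10), three secretions and a biomass sink — 37
reactions, 20% of internals reversible.  The layered construction
guarantees a nonempty bounded polytope by design.  The suite runs 50
samples per $\lambda$ over the 11-point grid $\lambda = 0, 0.1, \ldots,
1$; the repository also ships a script that executes the identical
protocol at the published scale (1000 samples per $\lambda$) on the
*E. coli* iJO1366 model, with pinned seeds, for users who supply that
model file.

Passing these tests shows that the machinery — sampling, mapping,
optimization, scoring — behaves as specified under controlled conditions.
It does not certify accuracy on real transcriptomes, where expression is
measured with noise, GPRs are multi-gene, and the proportionality between
mRNA and enzyme levels is imperfect.

## Phenotype statistics

For cohort analyses the package computes the glucose-to-lactate yield
$v_{lac}/v_{glc}$ (absolute net secretion over absolute net uptake; the
reaction identifiers are explicit arguments because exchange naming varies
across models), and a pathway enrichment index: the mean net-flux
magnitude over a pathway's reactions normalized by the summed net-flux
magnitude of the network.  Net fluxes ($|v^f - v^r|$) are used so a
balanced thermodynamically infeasible cycle contributes nothing; a
configuration switch is not offered because split-direction magnitudes
would let such cycles dominate the index.  Both statistics are invariant
to uniform rescaling of the fluxome.  Group differences use a two-sided
Mann–Whitney U test with midrank ties: the null distribution is obtained
by exhaustive enumeration of group assignments up to combined $n = 20$
(exact even under ties) and by the tie-corrected normal approximation
beyond; no continuity correction is applied, which keeps the symmetric
identity (equal multisets give $p = 1$) exact.  When many pathways are
tested, Benjamini–Hochberg adjusted values are reported alongside raw
p values.

## Worked example

```{r toy, eval = FALSE}
net <- toy_tic_network()            # 2 metabolites, 4 reactions, one TIC
sp  <- split_reversible(net)
rx  <- map_expression(sp, toy_expression("tenfold"))

phe  <- solve_pheflux(sp, rx)       # entropy formulation
spot <- solve_spot(sp, rx)          # correlation-maximizing baseline

tidy(phe)
tidy(spot)
```

With the cycle enzyme expressed tenfold above the rest, SPOT routes the
entire budget into the internal cycle (exchange fluxes drop to zero),
while the entropy solution keeps strictly positive uptake and secretion —
the qualitative signature that motivates the method's robustness to
thermodynamically infeasible cycles.

## Numerical choices and degenerate inputs

* Equality systems are reduced to linearly independent rows before any
  factorization; conservation redundancies in $S$ are therefore harmless.
* `quadprog`'s active-set method occasionally misreports degenerate but
  feasible systems as inconsistent; every such call has the dual-engine
  fallback described above, and feasibility verdicts are always confirmed
  by an explicit residual check.
* A zero-dimensional polytope (all reactions fixed) is sampled as the
  single feasible point; an unbounded polytope is rejected with an error
  since uniform sampling is undefined there.
* Ties in the Mann–Whitney statistic use midranks everywhere, so the
  exact and approximate branches agree on their common domain to the
  stated tolerances.

## Known limitations

* Solutions are not guaranteed free of thermodynamically infeasible
  cycles; the entropy objective damps but does not eliminate them.
* Expression is taken as a proxy for enzyme abundance; protein-level
  inputs are not supported.
* The SBML reader covers the Level 3 core plus the FBC (bounds, gene
  products) and groups (subsystems) packages as used by the common model
  repositories; exotic constructs (e.g. nested stoichiometric math) are
  out of scope.
* The hit-and-run sampler is exact but unoptimized R; for networks beyond
  a few hundred reactions expect sampling, not optimization, to dominate
  run time.
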