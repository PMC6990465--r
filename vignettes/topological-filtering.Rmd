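---
title: "Topological filtering: model, heuristics, and numerical choices"
author: "topofilter authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological filtering: model, heuristics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofilter)
```

## The problem and the model

Mechanistic models of biochemical networks are rarely unique: beyond a core
of well-established reactions there is usually a set of *hypothetical*
mechanisms, and every subset of them defines a candidate model topology.
With $\tilde d$ hypothetical parameters there are $2^{\tilde d}$ candidate
submodels — far too many to fit one by one once $\tilde d$ reaches the
tens.

`topofilter` works on parametric ODE models
$$\frac{d\boldsymbol{x}(t)}{dt} = \boldsymbol{S}\,\boldsymbol{v}(\boldsymbol{x}(t);\boldsymbol{p}),
\qquad \boldsymbol{x}(0) = \boldsymbol{x}^0,$$
with $l$ species, $m$ reactions and $d \ge m$ parameters in a bounded box
$\mathcal{P}$.  Every rate law is required to be of the multiplicative form
$v_j = p_j\, r_j(\boldsymbol{x};\boldsymbol{p})$.  This form makes
structural model reduction a *parameter projection*: setting the
multiplicative kinetic constant $p_j$ to 0 deletes reaction $j$; other
parameters may project to different values (a Michaelis constant
"projects to infinity", represented here by a user-supplied large finite
surrogate, since numerical integrators need finite inputs).  A submodel is
therefore an index set $I$ of reducible parameters, and the whole model
space is the subset lattice over the reducible set.

A scoring function decides whether a parameter point describes the data
well enough.  By default the score is the negative log-likelihood under
independent Gaussian errors,
$$\ell = \Phi/2 + C, \qquad
\Phi = \sum_i \left(\frac{y_i - y^0_i}{\sigma_i}\right)^2, \qquad
C = \tfrac12\left(k\ln 2\pi + 2\sum_i \ln \sigma_i\right),$$
and the threshold is $s^0 = C + Q_{\chi^2_k}(q)/2$ with $q = 0.95$, i.e.
the standard goodness-of-fit bound $\Phi \le Q_{\chi^2_k}(q)$.  A point
(and thereby the submodel it witnesses) is *viable* when its score does
not exceed $s^0$; ties count as viable.  Two details are deliberate:

* residuals are divided by $\sigma_i$ **before** squaring.  Only this
  variance weighting makes $\Phi$ chi-squared distributed and produces the
  familiar $\pm 1.96\sigma$ band at $k=1$, which the test suite asserts;
* $C$ is accumulated in log space, so large $k$ cannot overflow a product
  of standard deviations.

The legacy alternative (`legacy_threshold()`) bounds $\Phi$ by
$k + 2\sqrt{2k}$, the mean plus two standard deviations of $\chi^2_k$.
Custom scores plug into the same `score <= threshold` contract; they may
consume predictions or raw parameter vectors, the latter allowing
likelihood-free objectives (e.g. scoring a synthetic circuit by a
performance measure) with no dataset at all.

## The search

Enumerating the lattice is hopeless; the search is a heuristic,
sampling-coupled recursion.  Each step, rooted at an already-viable
reduction, does:

1. **Point preparation** (`prepare_points()`): carried-over samples are
   re-validated under the current reduction — a point viable for the
   parent need not survive further projection — and, when fewer than
   $\lceil f\,n\rceil$ survive (default $f = 1/20$ of the per-step
   evaluation budget $n$), adaptive re-sampling is triggered.
2. **Rank-bounded exhaustive search** (`exhaustive_step()`): for every
   sample, every candidate reduction of rank up to $r$ is projected and
   scored.  There is *no pruning* inside this phase; the per-step cost is
   exactly $D \sum_{i=0}^{r}\binom{\tilde d}{i}$ (`evaluation_budget()`),
   linear in $\tilde d$ at $r=1$, quadratic at $r=2$.  Non-viable
   candidates are simply never used as union members or recursion roots.
3. **Union jump** (`union_step()`): per sample — never across samples —
   the union of its viable candidates is formed and, when its rank exceeds
   $r$, tested once against all samples.  This is how the search skips
   over intermediate lattice levels.
4. **Backtracking** (`backtrack_step()`, optional): when a union jump
   fails, the skipped intermediate-rank subsets are tested, in increasing
   size then lexicographic order.  By default backtracking triggers only
   when the union fails for every sample (the cheaper granularity);
   per-sample triggering is available.
5. **Root selection** (`select_recursion_roots()`): the enumeration level
   trades speed for coverage — conservative (0) recurses only into the
   inclusion-maximal viable projections of the step (within-step
   maximality; the cheapest choice when only the maximal reduction is
   wanted), balanced (1) into every per-sample union, aggressive (2) into
   every viable projection found, which is what systematically enumerates
   the model space near the root and is the right setting for model
   selection.

Every viable projection discovered in any phase is recorded in a registry
with one witness sample; the first discovery wins, duplicates are
identified by the coupling-closed canonical index set.  A visited-root set
prevents re-entering a reduction, so the recursion depth is bounded by
$\tilde d$ and termination is structural, not budget-dependent.

Parameter *couplings* are asymmetric and closed transitively: declaring
`kcat -> Km` means projecting `kcat` drags `Km` along, not conversely.
Coupling targets must themselves be reducible (they need projection
values); this keeps every registry entry inside the reducible set.  The
catalog validates this at load time rather than during the search.

## Sampling the viable subspace

The search only needs a sampler that satisfies a contract — seeded,
budgeted, returning exclusively viable points, with projected coordinates
frozen exactly — so the samplers here are deliberately simple, documented
simplifications rather than re-implementations of any particular published
sampler:

* `explore_walk()`: an adaptive Gaussian random walk in the reduced
  coordinate system.  Any viable proposal is accepted (no detailed
  balance; the goal is coverage, not a posterior).  Every 20 proposals the
  per-coordinate step scale is multiplied by 1.1 when the window
  acceptance rate exceeds 30% and by 0.9 otherwise.  Log-scaled
  parameters are walked in $\log_{10}$ space; proposals reflect at the box
  boundary.  The chain restarts from a random seed every 25 proposals so
  that disconnected viable islands all seed chains.
* `expand_ellipsoids()`: k-means clusters (default 2, capped by what the
  data supports) with per-cluster covariance ellipsoids.  The Cholesky
  factor is scaled by $\sqrt{d+2}$ — the covariance of points uniform in
  an ellipsoid is (axes$^2$)/$(d+2)$, so this makes the fitted ellipsoid
  match the support of its points — and then inflated by 1.5 by default.
  Proposals are drawn uniformly in the union of ellipsoids; degenerate
  covariances are regularized by a diagonal floor tied to the box range.

When re-sampling triggers, the walk is seeded with *all* previously known
viable points of the reduction (carried-over survivors plus the per-
reduction history pool), the budget is split half/half between walk and
ellipsoid phases (configurable via `walk_share`), and the result is capped
at `d_max` (default $10\lceil f\,n\rceil$) points.  No claim of uniform
coverage of the viable subspace is made — the samples witness viability;
they are not a posterior sample.

## Numerical choices

* Integration uses `deSolve::lsoda` (stiff-capable) at `rtol = 1e-6`,
  `atol = 1e-9`.  A trajectory that fails to integrate — stiff blow-up,
  non-finite states — scores as non-viable instead of aborting: projected
  submodels often have degenerate dynamics and the search must survive
  them.
* Negative concentrations above `-max(100*atol, 1e-7)` are clamped to 0
  (ordinary solver overshoot); anything more negative is treated as a
  failed evaluation.  The clamp tolerance is two orders looser than `atol`
  because production solvers routinely overshoot slightly beyond their
  absolute tolerance; tying the clamp to `atol` alone misclassifies
  healthy trajectories.
* Candidate reductions are ordered by size, then lexicographically on
  sorted indices, and all random draws descend from one master seed via
  per-(root, phase) derived child seeds — runs are bit-reproducible, and
  parallel level 1 provably coincides with the sequential run because
  randomness lives only in the (sequential) sampling phase.
* Parameters are addressed by name externally and by 0-based position
  only inside tight loops; every file and report uses names.
* The evaluation counter counts *every* score-backed call, including
  re-validations of carried-over points, matching the budget formula's
  convention.
* Rate-law and observable expressions come from a restricted grammar
  (names, numbers, `+ - * / ^`, parentheses).  Model files cannot execute
  code.

## The packaged test problems

The fixtures are first-class, tested code, and they define the study
conditions used throughout the test suite and the acceptance script.

**Ligand-reporter instance** (`ligand_reporter_problem()`): two species,
four reactions, closed-form solution (`ligand_reporter_closed_form()`).
Defaults: $x_1^0 = 10$, $\sigma_1 = 0.05\,x_1^0$, box
$[0.0117, 0.027]\times[1.3, 11.7]$ for $(k_1, k_2)$, one observation of
the reporter at $t^* = 1000$ — chosen so that the slowest in-bounds ligand
decay satisfies $e^{-k_1^{\min} t^*} \approx 8\cdot10^{-6}$ and the
near-steady-state premise holds quantitatively.  The datum equals $x_1^0$
exactly (deterministic variant; a seeded noisy variant exists), so the
"correct" model is the maximal reduction $k_1 = k_2 = 0$.  This instance
exhibits the central heuristic caveat: neither constant can be projected
to 0 alone, so a rank-1 search with 0-projections provably misses the
viable rank-2 reduction — the tests assert the miss as expected behavior —
while a rank-2 search finds it.

The `"epsilon"` variant derives finite surrogate projection values from
the closed form at build time.  With a single near-steady-state datum the
geometry is unforgiving: projecting $k_1 := \varepsilon_1$ from a
root-viable sample requires the residual ligand contribution
$x_1^0 e^{-\varepsilon_1 t^*}$ to stay below $1.96\sigma_1$, and once it
does, the $k_2$ surrogate must *compensate* that residual signal rather
than approximate 0.  The package therefore sets
$\varepsilon_1 = -\ln(\alpha)/t^*$ (default residual fraction
$\alpha = 0.12$, placing $\varepsilon_1$ below the $k_1$ box) and
$\varepsilon_2 = x_1^0 - x_1^0(e^{-\varepsilon_1 t^*} - e^{-t^*})/(1-\varepsilon_1)$,
which makes the fully reduced model reproduce the datum exactly.  With
these values the rank-2 reduction is reachable through two consecutive
rank-1 steps, which is what the tests assert; no claim is made that both
surrogates are close to 0.  The `"large"` variant instead projects $k_1$
far above its upper bound, after which $k_1$ alone is reducible.

**Lattice problems** (`lattice_problem()`, `union_jump_example()`): the
score depends only on which coordinates sit exactly at their projection
values, so the viable sublattice is known in closed form from a predicate
and the search mechanics can be tested against a $2^{\tilde d}$ brute-force
oracle, independent of sampling and integration.

**Random mass-action models** (`random_massaction_model()`): a connected
core backbone (synthesis, conversion chain, terminal degradation) plus
hypothetical random conversions/degradations, of which a random non-empty
subset is truly inactive.  Data are all states at 4 times in $[1,5]$ with
5% Gaussian noise (floored at 0.02), simulated from the ground-truth
submodel with a seeded generator.  Rates are drawn in $[0.5, 2]$ and
reducible bounds reach down to $10^{-3}$, so the root model with inactive
rates at their lower bound is viable while deleting an active reaction
moves trajectories far outside the noise.  These instances emulate the
*shape* of signaling case studies at desk scale; they do not emulate
real-data features such as correlated errors, partial observability,
model misspecification, or stiff multi-scale kinetics, so passing recovery
tests demonstrates the search machinery, not robustness on real data.

## Problem sizes used in the checks

The test suite and the acceptance script run: the ligand-reporter instance
with an 80-evaluation sampling budget and at most 20 points per step; 20
random monotone lattice problems with $\tilde d \in \{4,\dots,8\}$ at full
rank and aggressive enumeration against the exact $2^{\tilde d}$
enumeration; and a 6-state/10-reaction mass-action instance at the
conservative level with a 60-evaluation budget.  These sizes were chosen
as the smallest at which each qualitative behavior (the rank-1 caveat, the
union jump, exact lattice recovery, inactive-reaction recovery) is
exercised without slack.

## Known limitations

* The search is a heuristic: outside the exhaustive rank it can miss
  viable reductions, and the ligand-reporter instance is the canonical
  witness.  Wider bounds, higher rank, or surrogate projection values are
  the documented mitigations, each with its own cost.
* No posterior model probabilities or Bayes factors are computed; the
  registry records viability witnesses only.  Uniform post-hoc sampling of
  the discovered viable spaces is out of scope.
* Only ODE models: no DAEs, delays, or stochastic simulation.  Which
  parameters are multiplicative constants is declared by the user, never
  inferred from rate expressions.
* The SBML importer covers species, global parameters, reactions and a
  small MathML subset — enough to ingest toy models and cross-check
  stoichiometries; reducibility declarations always come from the native
  config, since SBML has no such concept.
* Parallel levels are implemented semantically (batched viability checks,
  per-root fan-out, independent repeats); on a single worker all levels
  reduce to well-defined sequential orders, and levels 0/1 are registry-
  identical by construction.
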