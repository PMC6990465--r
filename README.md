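# topofilter

Topological filtering for reduction and selection of ODE reaction-network
models.

## The problem

Dynamic models in systems biology usually combine confirmed reactions with
hypothetical mechanisms.  Every subset of the hypothetical reactions is a
candidate model topology, so `d̃` uncertain mechanisms span `2^d̃`
candidate submodels — 262 144 already at `d̃ = 18` — and fitting each one
separately is hopeless.  `topofilter` is for modelers who want all (or the
most compact) submodels of a parametrized ODE model that remain consistent
with their data, without enumerating the lattice.

The key reformulation: for a reaction network

```
dx/dt = S · v(x; p),   x(0) = x0,      v_j = p_j · r_j(x; p)
```

deleting reaction `j` is the same as projecting its multiplicative kinetic
constant `p_j` to 0 (other parameters may project to other values, e.g. a
large finite surrogate standing in for "project a Michaelis constant to
infinity").  Model space search becomes a walk over index sets `I` of
projected parameters.

A parameter point is **viable** when its score does not exceed a
model-independent threshold.  By default the score is the negative
log-likelihood under independent Gaussian errors,

```
ℓ = Φ/2 + C,   Φ = Σ_i ((y_i − y⁰_i)/σ_i)²,   C = ½(k·ln 2π + 2Σ_i ln σ_i)
```

with threshold `s⁰ = C + Q_χ²(0.95, k)/2`, i.e. the classical
goodness-of-fit bound `Φ ≤ Q_χ²(0.95, k)` (at `k = 1` the familiar
`±1.96σ` band).  The search starts from one viable parameter point of the
full (root) model and, per recursion step: re-validates / re-samples
viable parameter points, exhaustively tests all candidate reductions up to
rank `r`, jumps to the per-sample union of viable reductions, optionally
backtracks over skipped intermediate ranks, and recurses into new roots
chosen by an enumeration level (conservative / balanced / aggressive).
Every viable projection is recorded with one witness parameter sample.

## Worked example

The packaged ligand–reporter instance is a two-species network (ligand
`x1` degraded at rate `k1·x1` drives a reporter `x2` that is also produced
constitutively at rate `k2`), observed once near steady state, with data
generated by the maximally reduced model `k1 = k2 = 0`.  Neither constant
can be projected to 0 alone — a rank-1 search provably misses the rank-2
reduction — but with finite surrogate projection values derived from the
closed form, two consecutive rank-1 steps find it:

```r
library(topofilter)
lr  <- ligand_reporter_problem(projection = "epsilon")
cfg <- filter_config(rank = 1, enum_level = 1,
                     sampler = sampler_config(n_evals = 80, d_max = 20),
                     seed = 5)
res <- run_filter(lr$problem, cfg, lr$init_point)
print(res)
#> topological filtering result: 3 viable projections (incl. root)
#> maximal reductions: k1+k2
#> model evaluations: 97; samplings: 1; steps: 3
```

The registry shows the discovery path — the root model, then the `k1`
surrogate projection found in step 1, then the joint reduction found from
that new root in step 2:

```r
for (r in res$records)
  cat(sprintf("%-8s rank %d  phase %-14s step %d  score %.4f\n",
              r$reduction$id, length(r$reduction$index_set),
              r$phase, r$step, r$score))
#> (root)   rank 0  phase recursion-root step 0  score 0.2258
#> k1       rank 1  phase exhaustive     step 1  score 0.7443
#> k1+k2    rank 2  phase exhaustive     step 2  score 0.2258
```

Scores are negative log-likelihoods; the viability threshold of this
instance is `s⁰ ≈ 2.15`, so both recorded witnesses sit comfortably inside
the 95% χ² band.  (Occasional `small negative concentrations clamped to 0`
warnings are ordinary solver overshoot near `x1 = 0`.)  With
`projection = "zero"` the same search at `rank = 1` finds nothing beyond
the root, and at `rank = 2` it finds `k1+k2` directly — the package's
standard demonstration of why higher-rank exhaustive search and surrogate
projection values both exist.

Results can be written to disk (`write_results(res, "results/")`:
`viable_projections.csv`, `witnesses.csv`, `summary.json`, `run.log`), and
the same search is available from a shell via the thin CLI:

```sh
inst/cli/topofilter run --model model.yaml --data data.csv \
    --config run.yaml --rank 1 --enum-level 1 --seed 5 --out results/
```

with models in a declarative YAML format (see `?read_model_spec`; SBML
import via `?read_sbml_model`) and data as CSV/TSV tables
(`experiment, observable, time, value, sigma`).

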