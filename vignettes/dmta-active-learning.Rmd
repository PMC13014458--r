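---
title: "Simulating query strategies in the DMTA cycle"
author: "dmtasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating query strategies in the DMTA cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmtasim)
```

## The problem

Early drug-discovery projects iterate through Design-Make-Test-Analyze
(DMTA) cycles. Each cycle is expensive -- synthesising a new chemical
entity typically takes days to weeks before any assay result arrives -- so
the choice of *which* molecules to make next dominates how fast a project
learns. When a machine-learning model guides that choice, the selection
rule is an active-learning *query strategy*, and strategies differ
sharply in what they teach the model: exploitation (pick what the model
already likes) versus exploration (pick what the model knows least
about).

`dmtasim` closes this loop entirely in silico. A random-forest ensemble
predicts a docking-style binding score (kcal/mol, more negative =
better) for every candidate in a pool; a query strategy selects a batch;
an oracle "measures" the batch; validly scored molecules join the
training set; the model retrains. Because the oracle is cheap, the same
campaign can be replayed under every strategy, batch size and selection
window, with replicate seeds -- an experiment that would be unaffordable
in the laboratory.

## The model components

### Surrogate

The surrogate is a random-forest regressor over a fixed molecular
descriptor vector. Hyperparameters are chosen by a 5-fold inner
cross-validated grid search minimising mean squared error over ensemble
size (400, 500), maximum depth (10, 20, 30, 50) and minimum node size
(10, 20, 30); the number of descriptors tried per split is always
`floor(sqrt(p))`. Outer performance is estimated by Monte-Carlo
cross-validation: 50 random 70:30 train/test splits by default. The
model used for acquisition is always a refit on the full current
training set; MCCV is a reporting device only.

Two realisation details are worth noting. First, the forest backend is
`ranger`; its `min.node.size` is the closest control to a
minimum-samples-to-split rule and is what the `minSamplesSplit` grid
axis drives. Second, per-molecule uncertainty is the *population*
standard deviation of the per-tree predictions,

$$\sigma = \sqrt{\tfrac{1}{T}\sum_{t=1}^{T}(\hat y_t - \bar{\hat y})^2},$$

with divisor $T$, not $T-1$. Tests enforce this against brute-force
loops at $10^{-10}$.

### Query strategies

| code | rule |
|------|------|
| `R` | uniform random over the remaining pool |
| `MP` | best (most negative) predicted score |
| `MPO` | best multiparameter-optimisation score |
| `MU` | largest ensemble $\sigma$ |
| `RMP`, `RMPO`, `RMU` | uniform random inside the top `poolFraction` of the respective ranking (default 10%) |
| `MP:MU`, `RMP:RMU` | concurrent hybrids at a quota ratio (8:2, 5:5, 2:8) |

The MPO score is $-P_m / (1 + e^{\mathrm{PFIc}_m - 8})$, where $P_m$ is
the predicted score and PFIc the computed Property Forecast Index
(calculated log P plus aromatic ring count). The sigmoid halves the
reward at PFIc = 8 -- the same threshold the drug-likeness filters use --
and suppresses it beyond, steering selection away from "fat and flat"
molecules.

Several behaviours were genuinely open and are fixed here as package
decisions:

* **Sign convention.** "Best predicted score" means most negative,
  following the binding-affinity convention.
* **Window size.** Randomised windows hold
  `ceiling(poolFraction * poolsize)` molecules, guaranteeing a non-empty
  window for tiny pools. A window exactly equal to the batch size makes
  the strategy deterministic; a fraction of 1 makes it identical --
  draw for draw, because stochastic draws always sample from id-sorted
  candidate sets -- to plain random selection.
* **Hybrid overlap.** The first component fills its quota; its picks are
  removed; the second component then ranks (and windows) the *remaining*
  pool. A molecule attractive to both components is attributed to the
  first. Ratios quoted for batch 10 scale proportionally (8:2 at batch
  50 is 40:10) and must scale to integers.
* **Ties.** All rankings break ties by molecule id in C-locale order, so
  results are independent of input order and platform locale.

### Oracle

The default oracle is a synthetic docking-score landscape: a sparse
linear form over named descriptor dimensions passed through a smooth
transform, plus Gaussian observation noise, with a per-molecule failure
probability. The default failure rate, 0.3393, is calibrated to a
large-scale docking campaign in which 97,289 of 147,248 attempted
molecules returned a valid score. Failure and noise draws are keyed on
`(seed, id)`, so an oracle outcome is a property of the molecule, not of
when or with whom it was scored; re-scoring reproduces it exactly, and
batching cannot shift another molecule's draw.

A molecule that fails consumes its batch slot and is not replaced within
the iteration -- mirroring real DMTA, where a failed synthesis still
spends the slot -- and is never added to the training set.

Scores from real docking runs can be replayed from an `id,score` CSV
instead; molecules absent from the table fail. Adapters to live docking
engines are deliberately out of scope: the contract is "structures out,
`id,score` CSV back in".

### Hit evaluation

A *hit* is a molecule whose true score lies in the best 1% of all
validly scored molecules; the hit-set size is rounded half-up (97,289
valid scores give exactly 973 hits). The hit set is computed once,
retrospectively, from the noise-free landscape over the full candidate
pool. Each iteration, the 50 best-predicted molecules are intersected
with the hit set; the overlap count (and its percentage of 50) is the
strategy's enrichment measure. Prediction-error metrics use the
population conventions throughout, so the decomposition
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{SDEP}^2$ is exact (tested
at $10^{-9}$); Pearson R on a constant vector is reported as missing
rather than coerced to a number.

Uncertainty diagnostics use two binnings: predictions binned by $\sigma$
into `(0, 0.2], (0.2, 0.4], (0.4, 0.6], (0.6, 0.8], (0.8, Inf)`
(labelled very certain ... very uncertain; an exact 0 falls in the lowest
bin, which the open-interval labelling would otherwise leave
unassigned), and pool predictions binned by predicted score with the
mean $\sigma$ per bin -- the view that reveals whether the most
favourably predicted molecules are also the least trusted ones.

## The synthetic benchmark

`makeShiftedBenchmark()` builds the package's reference study
conditions. Descriptors are 16 standard-normal dimensions, four of which
carry signal through their sum $u$. The score surface is bimodal:

$$s(u) = -7.0 - 1.2\,e^{-(u-4)^2/4.5} - 2.8\,e^{-(u+4)^2/4.5}
\ \text{kcal/mol},$$

placing scores in the familiar docking range of roughly $-10$ to $-7$.
The initial training set (1,054 molecules, matching a realistic
project-start dataset) is drawn with its active dimensions centred at
$+1$, i.e. on the shoulder of the *shallow* well at $u = +4$; the
candidate pool (5,000 molecules) is centred at the origin and is the
only population that reaches the *deep* well at $u = -4$. A 500-molecule
hold-out set is "docked" up-front (failures dropped), and its best 100
true scores form the top-performing subset.

This geometry is the point: it reproduces, in two controllable wells,
the regime where the starting data come from known chemical matter that
is narrower than -- and offset from -- the candidate space. A forest
trained on the shallow mode cannot extrapolate to the deep one;
greedy selection keeps harvesting the shallow well it already believes
in, while uncertainty-driven selection is pulled toward unfamiliar
descriptor regions, finds the deep well, and ends up ranking the true
top-1% correctly. The benchmark assertions are deliberately
qualitative, decided before the suite was run: the final hit overlap of
`MU` is at least that of `MP` in at least 2 of 3 replicate seeds, and
under `MP` the internal (MCCV) RMSE does not increase from the first
three to the last three iterations while the hold-out RMSE does not
improve (0.05 kcal/mol slack).

What the generator does *not* emulate is equally important: real
descriptors are correlated, discrete and high-dimensional (hundreds of
2D descriptors, not 16 Gaussians); real docking failure is structural,
not i.i.d.; and real affinity landscapes have many modes with chemistry
constraints coupling them. Passing the benchmark shows the machinery
and the shift mechanism work; it does not certify performance on any
particular real campaign.

## Reproducibility and problem sizes

One global seed spawns independent named streams (oracle, acquisition,
surrogate fits, CV splits) via integer hashing, so changing how one
consumer draws cannot shift another's sequence. Replicate seeds vary the
oracle and acquisition streams; ensemble-construction randomness stays
keyed to the configuration, so a deterministic strategy under a
noise-free, failure-free oracle replicates identically -- replicate
spread then measures the stochasticity of the *campaign*, not of the
forest fit.

Desk-scale runs use a 5,000-molecule pool, batch 50, 20 iterations,
three seeds, MCCV reduced to 5 resamples, and a tuning grid collapsed
to a single point (400 trees, depth 30, node size 10); a collapsed grid
skips the inner search entirely. The full 24-point nested re-tune per
iteration is available (`tuningGrid()` defaults) and is the faithful
configuration for cluster-scale studies; it re-tunes at every
retraining by default.

```{r quick-example, eval = FALSE}
bench <- makeShiftedBenchmark(nPool = 1000, nTrain = 300, nHoldout = 200,
                              seed = 1)
cfg <- simConfig(acquisitionSpec("MU", batchSize = 20),
                 bench$initialTrain, bench$candidatePool, bench$landscape,
                 grid = tuningGrid(400, 30, 10), nIterations = 10,
                 holdout = bench$holdout, mccvResamples = 5, seed = 1)
reps <- runReplicates(cfg, seeds = 1:3)
head(reps$summary)
```

## Degenerate inputs and edge rules

* Non-finite descriptor values are imputed to 0 and logged, so tree
  ensembles never receive `NaN`; how a descriptor provider should handle
  values it cannot compute is not standardised anywhere, and this is the
  package's explicit choice.
* Filter thresholds are inclusive (`<=`), and a record missing a
  property is rejected with reason `missing_property` rather than
  silently passed.
* Grid-search ties resolve to the first point in ascending
  (`n_estimators`, `max_depth`, `min_samples_split`) order.
* An exhausted candidate pool truncates the trajectory with a warning;
  replicate trajectories of unequal length align on the shortest.
* Loaders reject malformed rows, duplicate ids and non-numeric scores
  with line numbers instead of coercing.

## Known limitations

The descriptor provider backed by OpenBabel offers a compact
physicochemical set, not the hundreds of 2D descriptors a full
cheminformatics toolkit would give; simulation studies normally use the
synthetic descriptor path. The toy R-group enumerator substitutes
fragments at two attachment points of one scaffold and performs no
tautomer, protonation or synthetic-accessibility reasoning. Only
random-forest surrogates are provided -- by design, since the package's
question is about query strategies, not learners -- and acquisition
rules beyond the listed zoo (expected information gain, Thompson
sampling, distance-based diversity) are out of scope.
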