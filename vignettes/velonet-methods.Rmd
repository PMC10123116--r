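---
title: "velonet: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{velonet: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`velonet` infers tissue-specific TF→gene regulatory networks by predicting
RNA velocity from TF expression and chromatin-accessibility-weighted TF
binding activity, with one small neural network per gene, soft multi-task
sharing within gene clusters, and attribution-based TF ranking. This
vignette is the package's own account of the method: what is modelled, why
each default is what it is, and what the synthetic benchmarks do and do not
demonstrate.

## The regression problem

RNA velocity is used as the regression target in place of expression
itself: a TF whose expression and promoter-level binding activity predict
how fast a gene's expression is *changing* is a better causal candidate
than one that merely co-varies with expression level. For each target gene
the inputs are, per TF: the summed activity score `a_sum`, the averaged
score `a_mean`, and the standardized log10 RPKM expression in the cell.
Velocity matrices have missing entries (velocity cannot be estimated in
every cell), so training sets are assembled per gene from the cells that
carry a value.

### Activity scores

A TF's binding sites (ChIP-seq intervals) are assigned to a gene when they
overlap the gene's promoter window by at least one base pair. The promoter
window is strand-aware, `[tss − upstream, tss + downstream)` on `+` genes
and mirrored on `−` genes, half-open in BED convention, clamped at
coordinate 0, with 3000 bp defaults on both sides — the common promoter
definition. A site overlapping several promoter windows is credited only to
the gene with the nearest TSS (distance from the site midpoint, ties broken
by gene id); this self-contained rule approximates the external
nearest-gene annotators used in practice and is documented as such — exact
concordance with any particular annotation package is not promised.

Open-chromatin peaks are sorted and merged per chromosome before any
overlap computation, so the covered length of a site is well defined and
the per-site score S — covered bp divided by site length — is guaranteed to
lie in [0, 1]. `a_sum` sums S over the gene's m sites, `a_mean` divides by
m; (TF, gene) pairs with no assigned site are simply absent and score 0,
which also avoids 0/0 in the mean. Scores are `log2(x + 1)` scaled once;
the object tracks the flag and refuses to scale twice. In per-cell mode
(jointly profiled accessibility + expression), each peak is traced back to
the cells whose reads produced it and the same computation runs per cell on
that cell's merged peaks; a cell owning every peak reproduces the
tissue-level result exactly.

Interval bookkeeping (sorting, merging, overlap detection) is delegated to
IRanges; the test suite checks the overlap fractions against an independent
per-basepair enumeration oracle on hundreds of random toy genomes.

### Preprocessing protocol

Genes with fewer non-missing velocity cells than a threshold are removed
(strict `<`), then cells left with no observed gene. Expression is
`log10(x + 1)` transformed — RPKM contains exact zeros, and the +1
pseudocount keeps zero at zero — then standardized per column to zero mean
and unit variance with the population (denominator n) standard deviation;
at thousands of cells the population/sample distinction is immaterial, and
constant columns map to zeros rather than NaN. Velocity is standardized the
same way over observed entries only; masked entries never enter any
statistic. Cells are split 9:1 into training and testing, and
standardization is performed **separately on the two splits**. That
protocol choice is deliberate and non-standard; the conventional
alternative (transform the test split with training statistics) is
available via `standardize_with_train_stats = TRUE` in `prepare_inputs()`,
default off.

## Model and loss

Each gene's network starts with a TF aggregation layer — one neuron per TF
computing g(w₁ₖ a_sum + w₂ₖ a_mean + w₃ₖ x), so the three signals of a TF
are mixed before anything else — followed by fully connected layers FC1
(64), FC2 (32), FC3 (16) and a linear scalar output. Within a gene cluster
the loss is

  Σ_tasks Σ_cells L(Y, f(·)) + λ Σ ‖W‖₁ + γ Σ_shared ‖W′‖\*

with L the squared error, the L1 term running over every task's layer
weights, and the trace norm ‖·‖\* (sum of singular values) applied to each
shared layer's stack W′ — the matrix whose columns are the flattened
weights of that layer across tasks. Only FC1 and FC2 are shared: lower
layers are more transferable, and FC3/output remain task-specific. The
trace-norm subgradient is UVᵀ from the thin SVD, recomputed at every
optimization step (stacks are a few thousand rows by tens of columns, so
the SVD is cheap); tiny singular values are kept since UVᵀ is stable
regardless. Biases are excluded from both penalties and from the stacks by
default (`penalize_biases` switches this).

### Batching, bootstrapping, repeats

Tasks in a cluster have different numbers of training cells. One epoch runs
`ceiling(C_max / b)` ensemble batches, where C_max is the largest task and
b the batch size; every ensemble batch contains one size-b batch per task.
Smaller tasks are resampled by cycling independently reshuffled
permutations of their examples — this realizes the bootstrapping idea while
*guaranteeing* that every example of every task is used at least once per
epoch, which sampling with replacement cannot. R² scoring repeats the whole
training three times (`repeats`) from derived seeds and averages per gene;
network construction instead runs `rounds` (default 5) independent
train+rank rounds and intersects the per-round top-k TF sets.

### Defaults and their rationale

| parameter | default | rationale |
|---|---|---|
| `lambda_l1` | 0.002 | The per-task squared-error term is normalized by its batch size (so penalty scales are batch-size independent). Under that normalization the conventional "0.01" L1 factor — calibrated for per-batch-sum losses — is effectively ~b times stronger and was observed to kill entire tasks (all-zero networks). 0.002 gives sparse aggregation weights without task death. |
| `gamma_trace` | 0.01 | Mild soft sharing; the sharing benchmark uses 0.1 (clearly-on) vs 0 for its contrast. |
| `batch_size` | 128 | Standard minibatch size; 32 is used in the 200-cell low-sample benchmark so an epoch still has several steps. |
| `epochs` | 100 | Past the loss plateau on the synthetic benchmark scale (≈1000 Adam steps at 2000 cells). |
| `learning_rate` | 0.01 | Adam; 1e-3 converges to the same solutions but needs several times more epochs at these problem sizes. |
| `activation` | `leaky_relu` (slope 0.01) | The architecture leaves g unspecified; plain ReLU can die wholesale under the L1 pull (a task whose aggregation layer goes all-negative has zero gradient forever), which leaky slopes prevent. `relu`, `tanh`, `linear` are available. |
| `share_layers` | FC1, FC2 | Lower-layer sharing only, as described above. |
| `repeats` / `rounds` / `top_k` | 3 / 5 / 50 | The evaluation and consensus protocol. |

The mean-per-batch MSE normalization itself is switchable
(`mse_batch_mean = FALSE` restores the raw per-batch sum).

Training runs in a compiled RcppArmadillo inner loop by default; a plain-R
implementation of the identical updates is kept (`engine = "r"`) and the
test suite verifies the two produce the same parameters to ~1e-10 on shared
batch streams. With γ = 0 the tasks decouple exactly: training a cluster
jointly equals training each gene alone (per-task RNG streams are derived
from the seed and the gene id only, never from cluster composition).

## Gene clustering

Sharing across all genes of a tissue would make the stacks huge and couple
unrelated programs, so genes are first partitioned into nearly equal-sized
clusters (default bounds 24–25) by k-means on their standardized velocity
profiles, with missing entries imputed as 0 — the post-standardization
column mean, hence neutral in Euclidean distance. The assignment step is
solved exactly as a min-cost transportation problem (successive shortest
paths with potentials, compiled), so every cluster size provably lies
within the bounds; the objective is non-increasing across the usual
centroid/assignment alternation, initialization is k-means++ from the seed,
and convergence is assignment-unchanged (cap 100 iterations). With bounds
0/n the procedure reduces to plain Lloyd k-means.

## TF ranking and networks

Attributions are computed against a single reference example: per-TF means
of the standardized training expressions (≈0 by construction) and exact
zeros for both activity blocks — "how does this cell's input move the
prediction relative to an average cell with no binding evidence". The
implementation backpropagates rescale-rule multipliers
(Δactivation/Δpre-activation, falling back to the derivative when the
denominator vanishes), which satisfies completeness exactly for piecewise
activations: per row, attributions sum to f(row) − f(reference). The
contract is enforced at runtime (tolerance 1e-3 relative; violation on
>1% of rows is an error) and tested, including the linear closed form
attribution = w·(x − ref). Reference means use training cells only,
avoiding test leakage; all training rows are attributed by default. A TF's
importance is the summed absolute attribution over its three features and
all rows — non-negative, additive over row sets, permutation-equivariant.

Consensus networks connect gene j to the TFs present in the top-k (default
50) importance ranking of *every* round; edge importance is the mean across
rounds (the aggregation is not prescribed anywhere, and the mean is the
obvious symmetric choice), ties in rankings break lexicographically for
reproducibility, and genes whose rounds disagree entirely get no edges.
Rounds differ by derived seed only; resampling the data per round is a
possible extension, not the default.

## Synthetic data: what it emulates, what it does not

`simulate_truth()` plants exactly `k_per_gene` regulators per gene with
effect sizes uniform on ±[0.5, 2]; `simulate_data()` draws standard-normal
latent TF drivers z, emits velocity y = Bᵀz + ε (ε Gaussian, sd 0.5 by
default) with per-gene missingness (30% default), and encodes raw RPKM as
10^(0.3 z + 1) − 1 clamped at 0, so the pipeline's log10(x + 1) recovers an
affine image of the driver and zeroing raw entries (`apply_dropout()`)
emulates capture drop-out upstream of the log transform. The toy genome
puts genes 20 kb apart on one chromosome, gives every true regulator a
binding site inside an open peak in its target's promoter, and gives
non-regulators promoter sites with no peak overlap — activity scores are
therefore informative, and the interval code runs on the same path as real
data. An optional `regulator_pool` restricts all genes' regulators to a
small TF subset, planting the shared low-rank structure that the
multi-task benchmark presupposes; a `tanh` link is available as a
nonlinearity stressor.

What this generator does **not** emulate: count noise and library-size
variation, overdispersion, velocity-estimation artifacts, correlated TF
expression, or chromatin dynamics. Passing the synthetic benchmarks
demonstrates that the machinery — scoring, training, sharing, attribution,
consensus — recovers planted structure under Gaussian, mostly linear
conditions; it does not certify performance on real tissues.

## Benchmark problem sizes

The standard recovery setup is 50 TFs × 30 genes × 2000 cells, 5
regulators per gene, noise sd 0.5, 30% missing velocities, 2 clusters, 3
rounds, top-10 consensus, scored as mean per-gene recall of planted
regulators among the top-5 ranked TFs (median over 3 seeds). The sharing
comparison uses 200 cells (low-sample regime) and an 8-TF regulator pool,
γ = 0.1 vs 0, median per-gene test R² per seed over 10 seeds. The drop-out
stressor reruns recovery with 60% of raw expression entries zeroed; random
top-5 selection would score recall 0.1 in expectation, and the activity
scores — unaffected by expression drop-out — are what keeps the ranking
far above that floor. These sizes keep a full run in minutes on one CPU
while leaving the conclusions stable across seeds.

## Known limitations

- Tissue-mode activity features are constant across cells within a task;
  they act as informative per-task intercept structure rather than per-cell
  signal (the per-cell mode exists precisely to lift this).
- The nearest-TSS promoter assignment is an approximation of external
  annotators, and promoter windows are not clamped at chromosome ends
  (sizes are not required as input).
- Precision of the recovered networks is deliberately not reported:
  ground-truth TF catalogs are incomplete, so predicted TFs absent from
  them are not necessarily false; recall and enrichment (upper-tail
  hypergeometric, log-space, with optional Benjamini–Hochberg adjustment
  across sets) are the supported metrics.
- The attribution is a single-reference rescale-rule method; interaction
  (pairwise) attributions and TF–TF co-regulation are out of scope.
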