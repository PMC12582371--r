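---
title: "Mosaic single-cell multi-omics integration with scmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosaic single-cell multi-omics integration with scmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem: mosaic integration

Single-cell experiments increasingly measure several molecular layers —
transcriptome (RNA), chromatin accessibility (ATAC), surface proteins
(antibody-derived tags), histone modifications — but rarely all of them in
every cell. A typical study collection is *mosaic*: batch 1 measured RNA and
protein in the same cells, batch 2 only RNA, batch 3 only protein. The
integration task is to place every cell from every batch into one coordinate
system in which biological cell states line up across batches and
modalities, and to fill in each cell's unmeasured modalities.

The key resource is the *bridge batch*: a batch that measured at least two
modalities in the same physical cells. Those cells provide ground-truth
cross-modal pairs — we know that row $i$ of the RNA matrix and row $i$ of the
protein matrix are the same cell — and that pairing is the only supervision
the method uses. For a mosaic collection to be integrable at all, the graph
whose nodes are modalities and whose edges are bridge batches must be
connected; `build_bridge_graph()` / `require_connected()` check this up
front and report the disconnected components when it fails.

`scmosaic` implements a two-part embedding model:

* an **aligned** space, in which the same cell measured in different
  modalities receives (nearly) the same coordinates — this is where
  cross-batch, cross-modality analysis happens; and
* a set of **modality-specific** spaces, which deliberately do *not* try to
  agree across modalities and instead spread cells apart within each
  modality, preserving signal that only that modality carries.

Missing modalities are then completed by nearest-neighbor transfer through
the aligned space, and the aligned and specific views are summarized into
consensus embeddings per cell.

## Preprocessing

Raw feature matrices are reduced per modality before any encoder sees them
(`prepare_inputs()`):

* **RNA / protein** — library-size normalization and `log1p`, applied only
  when the matrix is non-negative (count-like); z-scoring per feature; then
  a truncated SVD to `p` dimensions. Data that are already signed and
  continuous (for instance, simulated Gaussian features) skip the count
  transform, which would otherwise produce `log` of negative numbers.
* **ATAC** — TF–IDF weighting (term frequency per cell, `log1p` inverse
  document frequency) followed by an LSI projection, the standard treatment
  for near-binary accessibility matrices, with the conventional option to
  drop the depth-correlated first component.
* **passthrough** — no reduction, for inputs that are already embeddings.

Batch correction happens in the reduced space. The `center` method removes
each batch's mean per dimension and restores the global mean. It is exact
precisely for *additive* batch effects — each batch shifted by a constant
vector — which is also the regime in which its behavior can be tested
against ground truth (see the synthetic generator below). An adapter slot
for an external mutual-nearest-neighbor corrector exists in the interface,
but this build deliberately errors and points the caller at `center`/`none`
rather than silently substituting a different algorithm.

## The alignment loss

Each modality gets its own three-layer MLP encoder (ELU activations,
dropout 0.2 after the first two layers; hidden sizes 1024–512–256 for
RNA/ATAC and 512–2048–256 for protein) mapping the reduced features into a
shared 256-dimensional space. Training mini-batches are drawn from bridge
batches only, so every sampled cell has embeddings in at least two
modalities, row-aligned across the per-modality matrices.

With cosine similarity $s^{j,v}_{i,l}$ between cell $i$'s embedding in
modality $j$ and cell $l$'s embedding in modality $v$, and temperature
$\tau = 0.1$, the per-anchor objective for cell $i$ viewed in modality $j$
is

$$
\ell(i,j) \;=\; \sum_{p \neq j} \frac{s^{j,p}_{i,i}}{\tau}
\;-\; (M-1)\,\log \Bigg(
\sum_{v \neq j} \sum_{l=1}^{n} e^{s^{j,v}_{i,l}/\tau}
\;+\; \sum_{l \neq i} e^{s^{j,j}_{i,l}/\tau} \Bigg),
$$

and the loss is $-\frac{1}{Mn}\sum_{i}\sum_{j} \ell(i,j)$. The positives
are the anchor cell's own embeddings in the $M-1$ other modalities. The
denominator — shared across the anchor's positives — contains every
cross-modal similarity to every cell *plus* the anchor's similarities to
the $n-1$ other cells within its own modality. That last, intra-modality
term is the method's distinguishing ingredient: plain InfoNCE
(`infonce_loss()`, recovered exactly by setting
`include_intra_negatives = FALSE` with $M = 2$) only ever compares across
modalities, so it can minimize its loss while leaving each modality's
embeddings on its own separate manifold — the *modality gap*. Penalizing
within-modality neighbors forces the encoder to spend capacity spreading
cells apart rather than separating modalities, and the gap — measured by
`modality_gap()` as the mean distance between per-modality centroids of
the normalized bridge embeddings — shrinks. The package's acceptance suite
checks exactly this relative claim: same data, same seeds, gap smaller with
the intra-modality terms than without.

Two degenerate facts about the formula are useful for testing and worth
stating. For $M = 2$ and $n = 1$ the loss is identically zero whatever the
embeddings — the only denominator term is the positive itself. For
$M = 3$, $n = 1$, *identical* embeddings in all modalities, the shared
denominator still contains the two other modalities and the loss is exactly
$2\log 2$. Both are asserted in the test suite, alongside equivalence with
an independent scalar-loop implementation to $10^{-10}$ on random
mini-batches.

### Training without an autodiff framework

The package trains these encoders with analytic gradients in base R rather
than a deep-learning framework (none is available as a dependency, and the
model is small enough not to need one). The chain is: gradient of the loss
with respect to the *normalized* embeddings via the softmax-style
coefficient matrices, then backprojection through row normalization
($g \mapsto (g - \hat z\,\langle g,\hat z\rangle)/\lVert z\rVert$ per row —
which is also why the specificity loss's fixed diagonal is consistent: the
gradient of a row's cosine similarity with itself is identically zero), then
standard MLP backpropagation with dropout masks cached from the forward
pass, and Adam updates ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$). All log-sum-exp denominators subtract their row
maximum before exponentiation, since $\tau = 0.1$ puts exponents near
$\pm 10$. Analytic gradients are verified against central finite
differences in the test suite (relative error $\le 10^{-4}$, in practice
$\sim 10^{-7}$).

## The specificity loss

The modality-specific encoders (same architecture, separate weights) are
trained per modality on *all* cells measuring it — no bridge needed, and
each modality trains independently of the others:

$$
L \;=\; -\frac{1}{n} \sum_i \log
\frac{e^{1/\tau}}{\sum_l e^{\mathrm{sim}(\hat z_i, \hat z_l)/\tau}},
$$

where the self-similarity in the numerator (and the diagonal of the
denominator) is the constant $1$ by definition, not recomputed. The only
positive pair is the cell with itself, so the loss is minimized by pushing
all other cells away — an embedding that spreads cells out within the
modality and is free to encode whatever that modality alone distinguishes.

## Imputation and consensus

For a cell that lacks modality $m$, `impute_missing_embeddings()` looks up
the cell's *aligned* embedding in each modality it does have, finds its $k$
nearest neighbors (cosine by default, Euclidean optional; $k = 2$) among
the aligned embeddings of all cells that do measure $m$, averages those
neighbors' *specific* embeddings, and finally averages the per-source
estimates with equal weight. Neighbor ranking is deterministic: similarity
descending, then candidate index ascending, so exact ties (e.g. duplicated
profiles) resolve reproducibly. `impute_missing_features()` applies the
same matching to raw feature rows instead, and — being a convex combination
— maps non-negative inputs to non-negative imputations.

Consensus construction differs between the two views, matching their
meanings. The aligned consensus (`consensus_align()`) averages each cell's
embeddings over its *measured* modalities with weights that default to a
fixed preference order (RNA if measured, else protein, else equal weights;
any explicit weight vector is renormalized over the measured subset). The
specific consensus (`consensus_specific()`) is an unweighted mean over
*all* modalities, measured or imputed — it is only defined after
imputation has completed every modality for every cell.

## Evaluation

`evaluate_mosaic()` scores an integration along three axes:

* **Biological conservation** — cluster the consensus embedding (shared
  nearest-neighbor graph, Jaccard edge weights pruned below $1/15$, Louvain)
  and compare to reference cell-type labels by NMI (arithmetic-mean
  normalization) and the Hubert–Arabie adjusted Rand index. Rather than
  clustering at one arbitrary resolution, the default scans resolutions
  0.1–2.0 and keeps the partition maximizing NMI — the convention
  established by the scIB benchmark, which decouples the score from the
  resolution hyperparameter. (A fixed-resolution mode remains available.)
* **Mixing** — graph iLISI: each cell's inverse Simpson's index of label
  proportions over a Gaussian-kernel neighborhood fitted to a fixed
  perplexity (neighborhood size / 3), averaged and rescaled to $[0,1]$ so
  that 0 means labels fully separated and 1 perfectly mixed; computed for
  batch labels and for measured-modality-set labels.
* **Cross-modal alignment** — on bridge pairs: FOSCTTM reported as
  $1 -$ (fraction of samples closer than the true match), so 1 is perfect;
  and a matching score, the row-normalized $k$-NN indicator's mass on the
  true match, both directions.

`aggregate_scores()` turns a methods-by-metrics table into headline scores:
min–max scale each metric across methods (a constant column scores 0.5 for
everyone, since the scaling is undefined), average into $S_\text{bio}$,
$S_\text{batch}$, $S_\text{modAlign}$, and combine with weights 0.6/0.4
(no alignment metrics) or 0.4/0.3/0.3.

## The synthetic benchmark and what it can test

`simulate_mosaic()` generates mosaics with known truth: discrete cell types
as latent centroids (s.d. 3) with unit within-type jitter in a
low-dimensional state space; per-modality linear read-out maps with
Gaussian feature noise; *additive* per-batch, per-feature shifts; and a
missingness pattern with at least one bridge batch. Options cover
batch-private cell types (composition shift), bridge downsampling (scarce
bridge data), and a Poisson counts mode for testing count-like paths.
`easy_mosaic()` fixes the canonical configuration used throughout the test
suite: 700 cells, 4 types, one RNA+protein bridge batch (300 cells) plus an
RNA-only (200) and a protein-only (200) batch, 300 RNA and 40 protein
features.

The generator's realism is deliberately limited, and that is the point: it
produces exactly the structures the algorithms claim to handle — linear
modality maps, additive batch effects, a known pairing — so every claim
can be tested as a property. The additive shifts are the regime where
`center` correction is provably exact; the known pairing grounds FOSCTTM
and the matching score; the latent types ground ARI/NMI. It does not model
count overdispersion, zero inflation, doublets, or nonlinear
modality relationships, so absolute scores on it do not transfer to real
data; only the relative and exactness properties are meaningful.

## Numerical and scale choices

Tests and examples run the benchmark with a reduced preset — 20 reduced
dimensions, mini-batches of 128, 30 alignment epochs (the specific stage
keeps its usual 10) — chosen a priori for a 700-cell problem on one CPU:
the defaults (`default_config()`: $p = 100$, batch 512, 100 epochs) are
sized for datasets in the tens of thousands of cells, and a 512-cell batch
would exceed the 300-cell bridge batch entirely. All training is
single-threaded, deterministic base-R linear algebra; every stage's
randomness derives from one global seed via fixed per-stage offsets, so
stages are individually re-runnable and two runs with the same
configuration agree to floating-point noise.

## Running the pipeline

```{r, eval = FALSE}
library(scmosaic)

sim <- easy_mosaic(seed = 1)
cfg <- load_config(list(
  seed = 1,
  preprocess = list(p = 20, correction = "center"),
  align = list(train = list(batch_size = 128, epochs = 30)),
  specific = list(train = list(batch_size = 128))
))
res <- run_pipeline(sim$dataset, cfg, out_dir = "run1", evaluate = TRUE)
res$metrics
```

The same pipeline is exposed as a command-line tool (`inst/exec/scmosaic`)
with `simulate`, `preprocess`, `align`, `spec`, `run` and `evaluate`
subcommands, a `--config` YAML file, and `--seed`/`--out` plumbing.

## Known limitations

* The harness is CPU-only and intended for datasets up to a few tens of
  thousands of cells; there is no GPU path and no out-of-core support.
* `center` is the only built-in batch corrector; non-additive batch
  effects are out of scope for this implementation.
* Similarity search is exact and dense ($O(n^2)$); for very large
  candidate sets an approximate index would be needed.
* The generator validates algorithms, not biology (see above).
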