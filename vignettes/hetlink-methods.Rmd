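---
title: "Methods: node representation and link prediction in heterogeneous molecular association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: node representation and link prediction in heterogeneous molecular association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular biology produces large catalogues of pairwise relationships —
miRNA–disease associations, protein–protein interactions, drug–target
bindings, and so on — each curated in isolation. `hetlink` treats them as one
heterogeneous *molecular association network* over five entity types (miRNA,
lncRNA, protein, drug, disease) joined by nine relation types, and asks the
completion question: given the known edges, which unobserved pairs are likely
true associations?

The model scores a candidate pair from a node representation with two halves:

* an **attribute vector** (64 dims) derived from what the node *is* —
  its sequence, its position in the disease vocabulary, its chemical
  structure;
* a **behavior vector** (64 dims) derived from what the node *does* —
  its edges, embedded by factorizing the network adjacency matrix.

A pair is represented by concatenating its two endpoint vectors (256 dims in
the combined mode) and scored by an ensemble classifier trained on the known
edges plus an equal number of sampled non-edges.

## Attribute encoders

**Sequences.** ncRNA sequences are encoded as normalized 3-mer frequencies
over `{A, C, G, U}` (`T` is read as `U`): entry *m* is the number of windows
equal to 3-mer *m* divided by the number of valid windows, so the vector lies
on the 64-simplex. Windows containing any other symbol are skipped rather
than rejected — real annotation files contain ambiguity codes, and skipping
keeps the denominator honest. Proteins are first reduced to a 4-letter
alphabet by side-chain polarity (G1 = AVLIMFWP, G2 = GSTCNQY, G3 = RKH,
G4 = DE) and then encoded the same way, again giving 64 dimensions.

**Diseases.** A disease is located in the MeSH hierarchy by its tree numbers;
ancestors are prefixes. Each term *t* of the resulting DAG contributes
`delta^depth(t)` to the disease, where depth is the fewest child-to-parent
steps from one of the disease's own terms — the "max" form of the attenuated
contribution rule, with the disease itself contributing exactly 1. Similarity
between two diseases is the generalized Jaccard ratio: the contributions both
DAGs assign to their shared terms, over the sum of their total semantic
values. The attenuation factor defaults to `delta = 0.5`, the standard value
in the MeSH-similarity literature; it is exposed as a parameter. A disease's
raw attribute is its full similarity row against all diseases.

**Drugs.** The raw attribute is a binary substructure fingerprint. Bitstrings
are accepted directly so that no chemistry stack is needed; SMILES input is
supported through the optional ChemmineR/ChemmineOB back-end.

**Unifying dimensions.** Disease similarity rows (length = number of
diseases) and fingerprints (e.g. 1024 bits) are compressed to 64 dimensions
by a sparse autoencoder; sequence encoders already emit 64 dimensions and
bypass it. One autoencoder is trained per node type, since the input
dimensions differ.

## The sparse autoencoder

A single hidden layer of 64 units is the smallest architecture delivering the
required code size. The training objective has three terms: mean half-squared
reconstruction error; a KL-divergence penalty `alpha * sum_j KL(rho ||
rho_hat_j)` pulling every hidden unit's mean activation `rho_hat_j` towards
the sparsity target `rho`; and weight decay `beta * ||W||^2`. Defaults:
`rho = 0.05`, `alpha = 1`, `beta = 1e-4`, 100 epochs of mini-batch gradient
descent (batch 32, learning rate 0.01), seeded uniform (−0.05, 0.05)
initialization.

Two numerical choices deserve a note. First, the hidden activation is the
sigmoid: the KL term is only defined for activations interpretable as rates
in (0, 1), which a ReLU hidden layer would not give; the output layer is ReLU.
Second, the decoder bias is initialized at the per-feature mean of the
(min-max scaled) data, so no output unit starts dead on the flat side of the
ReLU. Inputs are min-max scaled to [0, 1] per feature — a no-op for
similarity rows and bit vectors, which already live there. Analytic gradients
are verified against central finite differences in the test suite.

## Graph factorization

Behavior vectors come from factorizing the symmetric 0/1 adjacency matrix
`Y`: minimize

```
f(Z) = 1/2 * sum_{(i,j) in E} (Y_ij - <Z_i, Z_j>)^2
       + lambda/2 * sum_i ||Z_i||^2
```

by sequential stochastic gradient descent: edges are visited in a fresh
seeded shuffle each sweep, the learning rate is `1/sqrt(t)` under a global
step counter that never resets, and training stops when the squared Frobenius
change of `Z` between sweeps falls to `epsilon` (default `1e-4`) or at
`max_epochs` sweeps. The sum runs over observed edges only, so each sweep
costs O(|E|).

Design points:

* **Regularizer sign.** The per-edge update is applied in the *descent*
  direction, `Z_i += eta * ((Y_ij − <Z_i,Z_j>) Z_j − lambda Z_i)`. Writing
  the regularizer with a plus sign inside the bracket — as the update is
  sometimes printed — would ascend the penalty term and contradict the
  gradient of `f`; with `lambda = 0` the two coincide.
* **Both endpoints move.** Each undirected edge is stored once; updating only
  the stored head row would make the result depend on storage order, so both
  endpoint rows take the step (the second using the first's pre-step value).
* **Sweep budget.** Under the `1/sqrt(t)` schedule the effective step decays
  quickly once `t` passes `|E|`, so late sweeps are cheap fine-tuning;
  with only 50 sweeps the factorization is still visibly underfit on
  networks of a few thousand edges (training loss an order of magnitude above
  its plateau). The default cap is therefore 500 sweeps; in practice the
  Frobenius test stops default-scale runs around 300.
* **Initialization.** Rows start uniform on `(−0.5/sqrt(r), 0.5/sqrt(r))`,
  seeded per row index, so appending isolated nodes to a graph does not
  perturb the other nodes' trajectories. Isolated nodes keep their
  initialization — every node has a behavior row, as required when test
  splitting leaves a node with no training edges.
* Defaults `rank = 64`, `lambda = 0.01`; a divergence guard aborts if the
  loss exceeds ten times its initial value.

## Classification and negative sampling

All known relationships are positives; an equal number of unobserved pairs is
drawn as negatives, stratified by relation type (per-type negative counts
match per-type positive proportions) with endpoints uniform over the legal
types, so the classifier cannot score on type priors alone. Pair features are
the concatenation of the endpoint representations in canonical
(lower-global-index-first) order; element-wise products or averages were
rejected because they discard per-node information. The default classifier is
a random forest (100 trees, Gini, unlimited depth, probability output);
extremely randomized trees, L2 logistic regression (ridge penalty `1/n`) and
Gaussian naive Bayes are available for comparison, all with explicitly pinned
hyperparameters rather than library defaults. The decision threshold for
confusion-matrix metrics is 0.5.

## Evaluation protocols

All protocols share the leakage discipline: whenever behavior information is
computed, the tested edges have already been removed from its input, and this
is asserted at run time, not assumed.

* **k-fold cross-validation** (default k = 5): the balanced labeled set is
  dealt into near-equal folds stratified by label; per fold, the embedding is
  re-fit on the training positives only, the classifier on the training
  pairs, and metrics (accuracy, sensitivity, specificity, precision, MCC,
  trapezoidal AUC, average-precision AUPR) are reported per fold with mean
  and standard deviation. One global negative set is drawn and then split
  across folds; negatives are classifier-only — the factorization consumes
  positive edges exclusively.
* **Feature ablation**: attribute-only, behavior-only and combined modes
  under identical negatives, folds and per-fold embeddings.
* **Proportion sweep**: 20/40/60/80% of edges retained as the known network;
  behavior-only 64-dim representations; training on the retained share (plus
  a matching share of negatives), testing on the complement.
* **Classifier comparison**: the four families on identical per-fold
  features.
* **Local vs global**: on one target relation (default miRNA–disease), four
  pipelines share folds — attributes only; attributes + Gaussian
  interaction-profile similarity rows (bandwidth normalized by the mean
  squared profile norm) compressed to 64 dims by the autoencoder; attributes
  + factorization of the target sub-network only; attributes + factorization
  of the whole network. The GIP autoencoder is re-fit inside each fold
  because interaction profiles depend on the training edges.
* **Leave-one-disease-out**: every association between one disease and the
  candidate node type is removed — the disease keeps its edges of the other
  relation types, which is exactly what leaves its behavior vector informed —
  then embedding and classifier are re-fit and all candidates of that type
  are ranked. Sampled negatives pairing the held-out disease with the
  candidate type are dropped from classifier training, since those pairs are
  the prediction targets.

Attribute vectors are computed once and shared across folds: they depend only
on node payloads, never on edges, so re-fitting them per fold cannot affect
leakage.

## The synthetic generator

Because the curated network cannot be redistributed with the package, a
seeded generator produces networks with the statistical structure the method
assumes. Every node receives a latent vector `u ~ N(0, I_8)`; a legal pair of
a relation type becomes an edge with probability

```
(1 - noise) * plogis(a * <u_i, u_j> + b_rel) + noise * density
```

with the intercept `b_rel` calibrated per relation so the expected density
hits its target. Attribute payloads are tilted by the same latents: sequences
are concatenations of 3-mer tokens from a softmax emission tilted by a fixed
random map of `u` (mixing weight `s`), fingerprint bits are
`Bernoulli(plogis(s * <w_b, u>))`, and diseases are laid out on the leaves of
a synthetic 3-level hierarchy ordered by a latent coordinate, so tree
proximity weakly tracks latent proximity. Setting `s = 0` or `a = 0` switches
the attribute or behavior channel off independently — the controllable
analogue of the feature-ablation experiment.

Default conditions: node counts 120/100/150/80/90 (≈540 nodes, ≈5,400 edges
at density 0.05 — mean degree close to the curated network's), latent
dimension 8 (well under the embedding rank, so factorization capacity is
never the bottleneck), `a = 3` and `noise = 0.02`. The slope and noise were
chosen so that the planted signal is strong — the Bayes-optimal score
separates held-out edges at AUC ≈ 0.95, the operating regime reported for
the method on the real network — while a small random edge mass mimics
unconfirmed-relationship contamination. Sequence lengths are drawn from
200–1000 nt/aa; fingerprints use 256 bits. A per-relation logistic intercept
(rather than thresholding a Gram matrix) keeps density controllable
independently of signal strength. All stages derive their streams from one
master seed.

**What passing on synthetic data does and does not show.** The generator
reproduces low-rank structure, type heterogeneity, controllable
attribute/behavior signal and density — it does not reproduce the heavy
degree skew, modular pathway structure or literature-driven ascertainment
bias of real curated networks. Synthetic results validate the machinery and
its orderings (combined ≥ single modes, ensembles ≥ linear ≥ naive Bayes,
global ≥ local, monotone gain with training proportion), not the absolute
performance numbers reported on the curated dataset.

## Problem sizes and determinism

Shipped tests run the full pipeline at the default ≈540-node scale for the
end-to-end checks and on a ≈130-node network for unit-level protocol tests;
these sizes give stable orderings while keeping a complete run to minutes on
one CPU. Every stochastic step — negative sampling, fold assignment,
embedding initialization and edge order, autoencoder initialization and
batching, tree classifiers — is seeded from explicit integer seeds, and
end-to-end runs are bitwise reproducible (the command-line layer writes a
YAML snapshot with which any run can be replayed).

## Known limitations

* The factorization constrains observed edges only; with `lambda > 0`
  unobserved pairs are pushed towards zero only indirectly, and embedding
  quality saturates on sparse graphs regardless of extra sweeps.
* Gaussian naive Bayes on 256 strongly dependent features is expected to be
  the weakest family — that is the point of including it in the comparison.
* The MeSH encoder assumes tree numbers as input; it does not parse MeSH XML
  releases or resolve descriptor names.
* Scores are probabilities under a balanced training prior; on the true,
  extremely unbalanced pair universe they are rankings, not calibrated
  probabilities.
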