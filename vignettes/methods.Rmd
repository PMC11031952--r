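---
title: "Graph-attention motif discovery: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-attention motif discovery: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Open-chromatin assays (ATAC-seq) followed by footprint calling yield short
genomic windows that are enriched for transcription-factor binding sites
(TFBSs). Two questions follow: given a fixed-length window, does it contain
a binding site at all, and across all bound windows, what are the recurring
sequence patterns (motifs) — possibly several, of different lengths?

`gatmotif` answers both with a single trained model. Labeled 101-bp
sequences (positives from footprints, negatives produced by shuffling each
positive's nucleotides) are decomposed into overlapping k-mers. Sequences
and k-mers become the two node types of a heterogeneous graph, a two-layer
graph attention network (GAT) classifies the sequence nodes, and the
model's own attention coefficients — not a separate scanner — are mined for
binding-site instances.

## The heterogeneous graph

With `lenk = 5` (the default), every sequence of length $L = 101$
contributes $L - lenk + 1 = 97$ k-mer occurrences; the $m$ distinct k-mers
observed across the dataset become k-mer nodes. Three edge families
connect them:

* **Similarity edges** (k-mer/k-mer): $W_{sim}(x,y) = (lenk - d_H(x,y)) /
  lenk$ when the Hamming distance $d_H$ is at most `sim_max_mismatch`
  (default 1), else 0. With the default cutoff, similarity edges connect a
  k-mer exactly to its single-mutation variants, which is what lets
  information from a mutated motif instance reach the consensus k-mer's
  embedding.
* **Coexisting edges** (k-mer/k-mer): $W_{co}(x,y)$ is the fraction of
  positive sequences containing both $x$ and $y$. Negatives are excluded
  by default (`positives_only = TRUE`): they are per-sequence shuffles and
  would only add compositional noise.
* **Inclusive edges** (k-mer/sequence): $W_{inclu}(x,z)$ is the raw
  occurrence count of $x$ in $z$. No TF–IDF-style rescaling is applied;
  the learned projection of the second layer can absorb any rescaling.

These three weight definitions, and the coexisting probability below, are
this package's own concrete definitions; they were chosen so that each
matrix plays the role its layer requires, and all of them are exposed as
parameters or documented behavior rather than hidden conventions.

Both k-mer/k-mer matrices are exactly symmetric with zero diagonals, and
the support of each inclusive column is exactly the sequence's distinct
k-mer set — the test suite verifies all three against brute-force
constructions.

## The network

**Layer 1 (k-mer embeddings).** In each k-mer subgraph, the initial
embedding of node $x$ is its weight column normalized by total neighbor
weight, $h(k(x)) = W(:,x) / \sum_{y \in N(x)} W(x,y)$, so entries sum to 1
over the neighbor support. Raw pair scores are
$e(x,y) = \mathrm{LeakyReLU}(a^\top [W^{p} h(k(x)) \,\|\, W^{p} h(k(y))])$
with a shared $d_k \times m$ projection $W^{p}$ and a $2d_k$ attention
vector $a$ per subgraph; scores are softmax-normalized over each node's
neighbor set and the embedding is the ReLU of the attention-weighted sum of
projected neighbor embeddings. One attention head per subgraph; the
LeakyReLU negative slope is 0.2 (the common graph-attention default; the
slope is configurable).

**Layer 2 (sequence embeddings).** The initial sequence embedding projects
the inclusive column, $h_{seq}(z) = W_{inclu}(:,z)^\top W^{inclu}$ with
$W^{inclu} \in \mathbb{R}^{m \times d_{seq}}$, $d_{seq} = d_k$. Each
k-mer occurring in $z$ is scored by the inner product of $h_{seq}(z)$ with
its similarity-side and coexisting-side embeddings (LeakyReLU, then
softmax separately per side over the sequence's k-mer set), and the
sequence embedding aggregates both sides:
$E_{seq}(z) = \mathrm{ReLU}(\sum_x \beta_{sim}(z,x) E_{sim}(x) +
\beta_{co}(z,x) E_{co}(x))$. Because the coefficients and both embedding
matrices are entrywise nonnegative, this final ReLU never clips; it is
kept for structural symmetry.

**Layer 3 (classifier).** A single fully connected layer with sigmoid
output; probabilities above 0.5 are called bound.

An important consequence of this architecture: the only sequence-specific
input is the k-mer count column. Positional arrangement within a sequence
does not reach the classifier (it re-enters in motif extraction, below).

## Training

Full-batch Adam against binary cross-entropy, defaults `epochs = 300`,
`learning_rate = 0.02`, dropout 0.3 and a per-epoch decay rate of 0.001.
The decay is interpreted as exponential learning-rate decay
($\eta_t = \eta_0 e^{-0.001 t}$) by default; an additive L2 weight-decay
reading is available via `decay_type = "weight"`. Dropout is applied to
the normalized attention coefficients (standard GAT practice) and to the
sequence embedding before the classifier. Parameters are initialized
Glorot-uniform from a seeded RNG; training is deterministic given
`gat_config(seed = )`. Model selection keeps the parameters of the epoch
with the best validation F1. Isolated k-mer nodes (no edge in a subgraph)
receive a unit self-loop so the initial-embedding normalization stays
defined; their count is reported.

Gradients are derived analytically for every tensor (the attention
softmaxes, both aggregation layers, the projections and the classifier)
and are validated in the test suite against central finite differences to
$10^{-5}$. The forward pass of every layer is additionally checked against
an explicit scalar-loop oracle.

The graph weight matrices are stored sparse (`Matrix`), but the trainer
materializes dense masked matrices per subgraph: at `lenk = 5` the k-mer
vocabulary is at most $4^5 = 1024$, so an $m \times m$ dense matrix is
~8 MB and masked-softmax plus BLAS products make a full-batch epoch run in
about a second, where per-neighbor-set sparse loops in R would be far
slower. For substantially larger `lenk` this choice would need revisiting.

## Motif extraction

The inclusive attention coefficients are collected for all labeled
sequences (without dropout), split by label into positive matrices
$B^1_{sim}, B^1_{co}$ and negative matrices $B^0_{sim}, B^0_{co}$. The
mean negative coefficient — averaged over inclusive-edge cells only, since
non-edges carry no coefficient — is subtracted from the positive matrices:
$dnB^1 = B^1 - \mathrm{mean}(B^0)$. Any (positive sequence, k-mer) cell
with $dnB^1_{sim} > 0$ **or** $dnB^1_{co} > 0$ (strictly) marks that k-mer
as a seed; because one k-mer can occur at several offsets, a qualifying
pair emits one seed per occurrence so positions are preserved.

Seeds are then chained positionally. The *coexisting probability*
$P(y \text{ at } o{+}1 \mid x \text{ at } o)$ — estimated from adjacent
occurrences in positive training sequences — decides whether two seeds at
consecutive offsets join; the threshold `theta_co` defaults to 0.5.
Offset gaps larger than one always break chains, because the adjacency
statistic is defined for immediate succession only. Maximal chains become
candidate sites spanning first offset to last offset + `lenk`; overlapping
candidates within a sequence are unioned (via `IRanges::reduce`) into
disjoint instances, which is how sites of multiple lengths emerge.
Instances are grouped by exact width (widths differing by one are not
pooled — the simplest faithful grouping for "motifs of different
lengths"); groups with at least `min_support = 5` instances yield a
position probability matrix with additive pseudocount 0.01. A junction
whose left k-mer never occurs in positive training sequences has no
adjacency estimate and never chains. Motifs export to MEME minimal format
(background = empirical positive-sequence composition), instances to BED.

`theta_co`, `min_support` and the pseudocount are deliberate knobs with no
single principled value; they are recorded in the run's provenance JSON.

## The synthetic benchmark

`generate_synthetic()` emulates the footprint-derived study design:
positives are i.i.d.-background 101-bp sequences, each receiving (with
probability `occurrence_rate`, default 1) one instance sampled column-wise
from a planted PPM at a uniform offset; negatives are mononucleotide
shuffles of the positives, exactly as in the real pipeline. The bundled
default motif is an AP-1-like 8-mer (consensus `TGACTCAG`) with
dominant-base probability 0.92, i.e. about 1.5 bits of information per
column — a strongly informative single motif. Generation is
bit-reproducible given a seed, and the generator returns the ground-truth
occurrence map for evaluation.

What the generator does **not** emulate: positional bias of sites within
footprints, multiple distinct motifs per dataset, dinucleotide background
structure, GC heterogeneity between sequences, and cooperative/composite
sites. Passing the planted-motif tests therefore demonstrates that the
machinery recovers a strong single motif from clean data; it does not by
itself establish performance on real ATAC-seq footprints.

### What the benchmark can and cannot reach

On the bundled study (500 positives + 500 negatives, `d_k = 32`, 100
epochs, seed 1) the pipeline recovers the planted motif essentially
perfectly: a width-8 motif with ~140 supporting instances whose PPM
correlates with the planted PPM at $r > 0.99$ at the best alignment.
Held-out classification accuracy, however, plateaus just below 0.8–0.86.
This is a property of the task, not of the optimizer: the classifier's
entire input is the k-mer count vector, and at ~1.5 bits/column the count
representation saturates around 0.85 accuracy — ridge logistic regression
trained on 12,000 sequences, gradient-boosted trees, and a likelihood
scorer built from the *true* planted PPM all land at 0.84–0.85 on the same
features. Raising the planted motif's information content (dominant base
$\geq 0.95$) makes the classification task correspondingly easier; the
default is kept at the stated study strength. The motif-extraction half of
the pipeline is unaffected because it uses positions, which carry the
information the bag-of-k-mers classifier cannot see.

## Numerical choices and degenerate inputs

* Softmax rows subtract their row maximum before exponentiation.
* Binary cross-entropy is computed from logits in the
  $\log(1+e^{-|u|})$ form; training aborts with a diagnostic on
  non-finite loss.
* Ties in ROC ordering are credited $\tfrac12$ (the trapezoid over
  distinct thresholds), making the AUC equal the pairwise-ordering
  probability; PRC is step-wise average precision. Both are
  oracle-checked.
* BED intervals are 0-based half-open; window center is
  $\lfloor (start+end)/2 \rfloor$ and a 101-bp window spans center ± 50
  inclusive. Windows running past a chromosome end are skipped and
  counted.
* Sequences containing ambiguous bases (N) are dropped with a logged
  count.
* A sequence whose k-mers are all absent from the training vocabulary
  cannot be embedded and raises an error rather than silently predicting.
* Dataset splitting is stratified by label (each part keeps the class
  ratio within one record) because the attention-background estimate
  assumes negatives are well represented; the split is deterministic
  given its seed.
* `epochs = 0` returns the seeded initialization unchanged, which makes
  initialization reproducibility testable.

## Problem sizes used by the bundled checks

The layer-by-layer oracle comparisons run at $m \le 10$, $n \le 6$,
$d_k \le 8$, where explicit scalar loops are practical; graph builders are
brute-force-checked at $m \le 50$, $n \le 20$; the end-to-end study uses
500 + 500 sequences at $d_k = 32$ for 100 epochs, which completes in a few
minutes on one CPU. The same study is what `scripts/acceptance.R`
recomputes.

## Known limitations

* Bag-of-k-mer classification cannot exploit positional structure; on
  weakly informative motifs its accuracy ceiling is well below what a
  positional scanner could reach.
* The dense-matrix trainer targets `lenk` around 5–6; vocabulary growth is
  $4^{lenk}$.
* Motif grouping by exact width can split one underlying motif across
  adjacent widths when chaining lengths vary; the MEME export keeps them
  separate motifs.
* Attention-based seeding inherits the classifier's calibration: if
  training collapses (e.g. all-positive predictions), denoised
  coefficients lose meaning. The pipeline surfaces stage counts (seeds,
  instances, motifs) to make such failures visible.
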