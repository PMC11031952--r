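# gatmotif

Graph-attention discovery of transcription-factor binding motifs in
ATAC-seq-derived sequences.

## What it does and who it is for

ATAC-seq footprinting produces fixed-length (101 bp) windows enriched for
transcription-factor binding sites (TFBSs). `gatmotif` is for regulatory
genomicists who want, from a labeled set of such windows (positives plus
per-sequence nucleotide-shuffled negatives), both:

1. a **TFBS classifier** — does a held-out window contain a binding site? —
   and
2. **multiple variable-length motifs**, as position probability matrices
   (PPMs), extracted from the trained model itself rather than from a
   separate scanner.

Sequences and their constituent k-mers form a heterogeneous graph with
three edge families: *similarity* edges between near-identical k-mers
(weight $(lenk - d_H)/lenk$ under a Hamming-distance cutoff), *coexisting*
edges between k-mers that co-occur in positive sequences, and *inclusive*
edges connecting each k-mer to the sequences containing it (occurrence
counts). A two-layer graph attention network learns k-mer embeddings
(layer 1, per subgraph):

$$h(k(x)) = \frac{W(:,x)}{\sum_{y \in N(x)} W(x,y)}, \qquad
e(x,y) = \mathrm{LeakyReLU}\!\left(a^\top[W^p h(k(x)) \| W^p h(k(y))]\right),$$

$$\alpha(x,y) = \mathrm{softmax}_{y \in N(x)}\, e(x,y), \qquad
E(k(x)) = \mathrm{ReLU}\Big(\sum_{y} \alpha(x,y)\, W^p h(k(y))\Big),$$

then sequence embeddings over the inclusive subgraph (layer 2), and a
fully connected sigmoid classifier (layer 3). For motif discovery, the
inclusive attention coefficients of positive sequences are denoised by
subtracting the mean coefficient of the negatives
($dnB^1 = B^1 - \mathrm{mean}(B^0)$); every k-mer occurrence with a
strictly positive denoised coefficient on either branch becomes a seed;
seeds at consecutive offsets are chained when the k-mer *coexisting
probability* $P(y \text{ follows } x)$ clears a threshold; overlapping
chains are unioned into binding-site instances of multiple lengths, and
each width group becomes a PPM, exported in MEME minimal format.

A synthetic planted-motif generator (known PPM, known offsets, shuffled
negatives) is included as a first-class, tested component for
benchmarking.

## Worked example

The bundled benchmark plants an AP-1-like 8-mer (consensus `TGACTCAG`,
~1.5 bits/column) in 500 random 101-bp positives, shuffles each into a
negative, then runs the whole pipeline — split, graph, training, metrics,
motif extraction:

```r
library(gatmotif)

spec <- planted_motif_spec(default_planted_ppm())   # TGACTCAG, 0.92/column
res <- run_pipeline(out_dir = "demo_run", motif_spec = spec,
                    n_pos = 500, seq_len = 101, lenk = 5,
                    d_k = 32, epochs = 100, seed = 1)
print(res)
#> <gatmotif_run>
#> <metric_report> n=100 precision=0.764 recall=0.840 F1=0.800 ACC=0.790 AUC=0.917 PRC=0.938
#>   23998 seed(s) -> 957 instance(s) -> 14 motif(s)

cors <- sapply(res$motifs, function(m) ppm_correlation(m$ppm, spec$ppm))
print(res$motifs[[which.max(cors)]])
#> <motif_model> width=8 support=142 consensus=TGACTCAG
round(max(cors), 3)
#> [1] 0.999
```

Reading the output: of 100 held-out windows, 79% are classified correctly
(AUC 0.92 — see the methods vignette for why accuracy saturates near this
level on bag-of-k-mer features at this motif strength), and among the 14
extracted motifs the width-8 one, supported by 142 independent
binding-site instances, reproduces the planted PPM almost exactly
(best-alignment mean per-column Pearson correlation 0.999). `demo_run/`
contains `metrics.tsv`, `motifs.meme`, `tfbs.bed`, `checkpoint.json` and a
`provenance.json` recording every parameter and seed.

Real data enters either as a labeled FASTA (`read_seq_fasta()`, headers
`id|1` / `id|0`) or as BED footprint intervals plus a reference FASTA
(`cut_windows()`).

## Command line

A thin Rscript wrapper lives at `inst/cli/gatmotif`
(`<library>/gatmotif/cli/gatmotif` after installation):

```sh
gatmotif all --seed 7 --out-dir run7          # simulate + full pipeline
gatmotif simulate --n-pos 500 --out-dir data
gatmotif prepare --fasta data/sequences.fasta --out-dir work
gatmotif train --fasta data/sequences.fasta --out-dir work --epochs 300
gatmotif find-motifs --fasta data/sequences.fasta --out-dir work
gatmotif evaluate --fasta data/sequences.fasta --out-dir work
```

Runs with the same configuration and seed reproduce their outputs
byte-for-byte.

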