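---
title: "Residue-embedding pre-filtering for protein homology search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-embedding pre-filtering for protein homology search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protscout)
```

## The problem

Sensitive homology search tools (profile HMM packages and their relatives)
spend most of their time on alignments that are ultimately rejected. A
*pre-filter* sits in front of the expensive stage: given a query protein and a
large target set, it must rapidly discard the vast majority of unrelated
targets while retaining essentially every pair the downstream aligner would
score well. `protscout` implements such a pre-filter built on learned
*residue embeddings*: a small convolutional network maps every residue of a
protein to a d-dimensional vector such that two residues likely to share a
column in a trusted pairwise alignment end up with high cosine similarity,
and unrelated residues end up near-orthogonal.

## The embedding model

The network is deliberately minimal. An input lookup table assigns each of
the 21 alphabet symbols (20 canonical amino acids plus `X` for everything
else) a learnable d-vector; a stack of `n_blocks` 1D residual blocks then
mixes local context. Each block computes

$$x \mapsto x + \mathrm{Conv}_2(\sigma(\mathrm{Conv}_1(\sigma(x))))$$

where both convolutions have the same hyper-parameters (d channels in and
out, odd kernel width, symmetric zero padding) but independent weights, and
$\sigma$ is the ELU activation. There are no normalization layers, no
pooling, and no attention: the output keeps exactly one row per residue, and
row $i$ depends only on residues within the receptive field
$1 + 2\,n_\text{blocks}(k-1)$ of position $i$ — 97 residues for the default
configuration (d = 256, 8 blocks, kernel 7; 7,349,504 parameters). This
locality is a feature: it makes embeddings cheap, streaming-friendly, and
interpretable as *alignment seed* detectors rather than whole-sequence
summaries.

Because the gap between blocks is purely convolutional, two design points
were genuinely open and resolved as follows:

* **Input encoding.** A learnable lookup table feeding the first block —
  the simplest encoder whose parameter count is dominated by the blocks
  themselves. No extra projection layers surround the stack.
* **Boundaries.** Symmetric zero padding of $(k-1)/2$ per side in every
  convolution, so per-residue output length is preserved; no boundary rule
  of any other kind is applied.
* **Initialization.** Fan-in-scaled normal weights (sd $=1/\sqrt{dk}$),
  zero biases, standard-normal lookup entries, under a caller-supplied seed.
  Every structural property (length preservation, locality, determinism)
  holds for any initialization, and the tests exercise random ones.

## Training: masked N-pair loss

Training consumes pairs of homologous sequences with a trusted residue-level
alignment. For a pair $(A, B)$ the alignment defines a sparse binary target
matrix $T$ with $T_{ij}=1$ exactly when $A_i$ and $B_j$ share a column. Both
sequences are embedded *independently*, and the raw dot products
$D_{ij} = \vec a_i \cdot \vec b_j$ enter an N-pair contrastive objective: for
every aligned pair, the negative log softmax of $D_{ij}$ against all
residues $w$ of $B$,

$$\mathcal{L} = \sum_{i,j} -R^a_i R^b_j\, T_{ij} \log
  \frac{e^{D_{ij}}}{\sum_w e^{D_{iw}}}
  \;+\; \frac{\gamma}{n}\Big(\sum_i R^a_i \lVert \vec a_i\rVert^2
  + \sum_i R^b_i \lVert \vec b_i\rVert^2\Big).$$

Although the loss touches only aligned pairs, its gradient is dense: every
unaligned residue of $B$ appears in the softmax denominator, so minimizing
the loss simultaneously pulls aligned embeddings together and pushes
unaligned embeddings toward orthogonality. The repeat-mask bits $R$ (0 in
repetitive or low-complexity regions) silence loss signals that would
otherwise teach the model that compositionally biased segments "align".

Decisions where the objective leaves room, and how this package resolves
them:

* The softmax denominator ranges over **all** residues of $B$, masked or
  not; the mask multiplies only the outer term. An optional symmetrized mode
  (averaging the $A{\to}B$ and $B{\to}A$ directions) exists but is off by
  default.
* The L2 normalizer $n$ is the number of unmasked residues in the pair
  ($\sum R^a + \sum R^b$), making the penalty a per-residue average that is
  stable across crop lengths.
* Batch loss is the mean over pairs, so learning-rate semantics do not
  depend on batch size.
* Cropping to the training sequence length (default 256): a window on $A$ is
  chosen by picking a random aligned column and a uniform window containing
  it; the window on $B$ is centered on the span of columns aligned into the
  $A$ window and clamped to the sequence. This guarantees at least one
  aligned column per cropped pair while keeping windows unbiased in the
  common case. Exact uniformity over the union of all valid windows was not
  worth the bookkeeping.

Optimization uses AdamW (decoupled weight decay; $\beta_1=0.9,
\beta_2=0.999, \epsilon=10^{-8}$), implemented in the package along with the
network's backpropagation — both are verified against finite differences in
the test suite. Defaults mirror the full-scale recipe: 24,000 steps, batch
512, learning rate $10^{-5}$, weight decay $10^{-2}$, $\gamma = 5\cdot
10^{-3}$. Training aborts with a diagnostic if the loss becomes non-finite.

## Search: gated k-NN and score accumulation

At search time every unmasked residue embedding of the target set is
L2-normalized and placed in a vector index with a back-reference to
(sequence, position). Each unmasked query residue retrieves its `k` (default
150) nearest neighbours by cosine similarity. Random d-dimensional vectors
produce chance cosine similarities with standard deviation roughly
$1/\sqrt d$, so each retrieved similarity is *noise-gated*:

$$f(A_i, B_j) = \max\!\Big(0,\; \cos(\vec a_i, \vec b_j) -
\frac{\delta}{\sqrt d}\Big),$$

with $\delta = 3$ by default — three standard deviations, removing an
expected 99.9% of noise at any dimensionality (the package exposes the
exponent on $d$ as a configuration escape hatch). The pre-filter score of a
(query, target) pair is simply the sum of gated scores over all retrieved
residue matches between them; duplicates into the same target residue all
count, as each is an independent alignment seed. Hits are ranked per query
by score (ties broken by target id).

Two backends satisfy the index contract. The `exact` backend performs a full
cosine scan (top-k with deterministic lexicographic tie-breaking) and is the
reference the tests compare against. The `quantized` backend mirrors the
inverted-file + product-quantization family: k-means coarse clustering with
about $\sqrt N$ lists, a quarter of which are probed per query, and
per-subspace k-means codebooks for approximate scoring, re-ranked with exact
cosines. Its recall against the exact backend is *measured* on given data
(`backend_recall()`), never assumed. A `reversed` mode builds the index over
the queries and streams target residues against it; hits are keyed
(query, target) either way, and with exhaustive `k` the two orientations
give identical scores.

Masking applies at three points: silencing training loss, excluding target
residues from the index, and excluding query residues from lookup. External
masker output is ingested as lower-case FASTA or BED intervals; the built-in
fallback masks any residue covered by a length-16 window whose Shannon
entropy is at most 1.5 bits — enough to flag homopolymers and short-period
repeats while leaving typical sequence untouched. Bit-exact reproduction of
any specific repeat-masking program is out of scope.

## Benchmarking

Evaluation follows the recall-versus-filtration paradigm. Decoys are
shuffled copies of the true targets (uniform residue permutation: length and
composition preserved, homology destroyed). Truth strata come either from
the simulator or from user-supplied E-value tables, cut at $10^{-10}$
(strong), $10^{-3}$ (weak, includes strong), and $\ge 10$ (low-similarity
decoys); pairs between the weak and decoy cuts are excluded from both
numerators. Sweeping a threshold over the observed hit scores yields curve
points (recall among true pairs, filtration among decoys); pairs absent from
the hit list count as score $-\infty$, i.e. always filtered. The curve is
monotone by construction and `recall_at_filtration()` reads it as a step
function without interpolation.

## The simulator

`sim_config()` defines the synthetic study conditions: an ancestor drawn
uniformly over the 20 amino acids (default length 128), two descendants
derived independently with per-residue substitution probability 0.15
(uniform over the 19 alternatives) and indel initiation probability 0.02
with geometric lengths of mean 3 — about 72% pairwise identity at aligned
columns, comfortably inside the twilight-zone-adjacent range where a
pre-filter must work, while keeping ground-truth alignments exact by
construction. The simulator writes standard FASTA, training-pair TSVs and
truth tables, so the entire pipeline composes from files.

What the simulator does *not* emulate: realistic substitution matrices
(BLOSUM-style exchangeability), domain architecture, cluster structure of
real protein databases, or length heterogeneity. Passing tests on simulated
data therefore demonstrate that the training objective and search pipeline
behave as designed — not that the package matches any published large-scale
benchmark on natural sequences.

One empirical observation worth recording: even an *untrained*, randomly
initialized network separates simulated homologs from shuffled decoys at
these divergence levels, because a random convolutional map sends
near-identical local windows to near-identical vectors — the architecture's
locality bias alone provides signal against composition-preserving decoys.
Training's measurable contribution in the test suite is the strong
separation between aligned and unaligned residue pairs of *homologous*
sequences (roughly three orders of magnitude in mean gated similarity after
the small training run below), which is what matters against biological
decoys rather than shuffled ones.

## Problem sizes used in the tests

The test suite trains a scaled-down model: d = 32, 2 residual blocks
(receptive field 25), 300 AdamW steps at batch 16 and crop length 128 on 500
simulated pairs, with learning rate $10^{-3}$ — a larger step size than the
full-scale recipe, proportionate to a model four orders of magnitude
smaller; descent is clearly established within those steps. The search
benchmark uses 50 queries against 50 homologous targets plus 50 shuffled
decoys. On these conditions the smoothed loss falls by a factor of about
four, and recall at 90% decoy filtration is far above the 10% no-skill
level.

## Numerical notes and limitations

* Softmax terms use the log-sum-exp trick; losses and gradients are exact to
  brute-force summation at double precision.
* Ties in k-NN and hit ranking are broken lexicographically by
  (sequence id, position) / target id, so all outputs are deterministic
  given a seed.
* Degenerate inputs fail loudly: empty sequences, non-alphabetic residues,
  empty indexes, masks of the wrong length, non-monotone alignments and
  out-of-range columns are all errors, not silent fixes.
* Scores are sums of gated cosines, not calibrated statistics: no E-value is
  attached, and score scales are comparable only within one model and gate
  setting. Downstream alignment is expected to re-score survivors.
* The quantized backend trades recall for speed in a data-dependent way;
  measure `backend_recall()` on your own data before relying on it.
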