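---
title: "Calling m6A from nanopore signal and trace data: methods and design notes"
author: "nanodrach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m6A from nanopore signal and trace data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

N6-methyladenosine (m6A) is deposited on mRNA almost exclusively at DRACH
motifs (D = A/G/U, R = A/G, H = A/C/U; 18 distinct 5-mers). In Oxford
Nanopore direct RNA sequencing (DRS), a methylated adenosine perturbs both
the ionic current through the pore and the basecaller's per-timestep base
probabilities ("trace"). `nanodrach` turns per-read current samples, trace
rows and basecaller move flags into site-level m6A calls and per-site
modification stoichiometries, and ships a synthetic data generator that
reproduces the statistical structure of that data so the entire pipeline is
trainable and testable without any external download.

A site is treated as a *bag* of 20–1000 reads in the multiple-instance
learning (MIL) sense: the bag carries the label (modified site or not), the
individual reads do not.

## Data model and normalization

A raw read holds a current sample stream, an integer trace matrix (8 classes
A, C, G, U, AA, CC, GG, UU; values 0–255; one trace row per 10 current
samples) and a 0/1 move flag per trace row marking where the basecaller's
CTC decoder emitted a new base. RNA is represented in the DNA alphabet
(U ≡ T), matching reference FASTA conventions.

Signal is standardized per read by the median-based modified Z-score

$$z_i = \frac{0.6745\,(x_i - \tilde{x})}{\mathrm{MAD}(x)},$$

whose constant is the 75th normal percentile; it is invariant under positive
affine transforms and robust to current spikes. A constant read (MAD = 0) is
an error by default (`mad_zero = "epsilon"` substitutes machine epsilon);
silent infinities would poison training downstream.

Trace rows are collapsed to the four standard bases, $q_i = p_i + p_{ii}$,
then divided by 255 and clipped at 1. The divisor is a design choice — the
integration rule guarantees values in $[0, 510]$ and dividing by 255 keeps
an uninformative row comparable with a confident one while guaranteeing the
stated $[0,1]$ range; clipping is only reachable when both the mono- and
di-nucleotide class are near-saturated.

## Trace-based resquiggling

Feature extraction needs to know which trace rows (hence which current
samples) belong to each reference base. The resquiggler proceeds in four
steps:

1. **Move mapping.** Every move = 1 row opens a segment.
2. **Splitting.** One pass over the segment lengths: any interval longer
   than 1.5× the median is split at its floor midpoint. This adds candidate
   boundaries for bases the basecaller merged; it is deliberately a single
   pass of the stated rule, not an iterated change-point search.
3. **Aggregation.** Each segment is summarized by the mean of its
   normalized 4-base trace rows.
4. **Realignment.** A dynamic programme over (segment *n*, base *m*)
   assigns segments to bases monotonically, at most one base advance per
   segment, every base receiving at least one segment.

The per-cell score uses the match probability
$P(n,m) = \langle \text{trace}_n, \text{onehot}(\text{ref}_m)\rangle$ and an
alignment score $A = W\,(S_\text{match} - S_\text{mismatch})$, with
$W = 1$, $S_\text{match} = 1$, $S_\text{mismatch} = 0$ by default (all
exposed as arguments). Moving into base $m$ at segment $n$ scores
$A \cdot P(n, m)$; *not* moving is the complementary decision about the same
event — does this segment start the next base? — and scores
$A \cdot (1 - P(n, m{+}1))$, with $P(\cdot, M{+}1) := 0$ past the end of the
aligned interval. Scoring the stay branch against the *current* base instead
provably misassigns segments in simple noiseless cases (a split segment
matching the next base is rewarded for idling), which is why the
move-target reading is used. Ties prefer the transition, guaranteeing full
reference coverage.

Trace scores cannot localize boundaries inside homopolymer runs — every
segment of the run matches every base of the run equally. The basecaller's
move flags are direct evidence of base starts, so transitions whose segment
begins at a move boundary receive a bonus of `move_bonus` × A (default 2,
i.e. larger than any per-step trace score). In effect the path places base
transitions on move boundaries whenever enough of them exist, and the trace
scores arbitrate among candidates and fall back to split-added boundaries
where moves are missing. With the bonus disabled (`is_move = NULL`) the
recursion is the pure trace scoring, which the brute-force enumeration tests
exercise. On noiseless synthetic reads the full procedure recovers 100% of
per-base boundaries; recovery stays at ~100% down to trace sharpness 0.6.

The dynamic programme is run full-matrix (no banding): reads at desk scale
are short and correctness is easier to audit than a banded heuristic.

## Read features and site bags

For every DRACH site covered by a read, the five contiguous per-base
segments centred on the A give a five-channel window: normalized signal
(10 samples per trace row) and the four trace channels, the trace rows
expanded 10× so all channels share one length. Each channel is standardized
to 256 values by linear interpolation (shorter) or index interpolation
(longer) — the simplest rule that preserves endpoints and monotonicity —
and concatenated in the fixed order signal, A, C, G, U into a read feature
of length 1280. Reads that do not cover the full 5-nt window are skipped
for that site, not errors.

Sites with fewer than 20 covering reads are dropped; sites with more than
1000 are subsampled without replacement under a fixed seed. Internal
coordinates are 0-based half-open; emitted site tables are 1-based, BED
intervals 0-based half-open.

## Model

**Encoder.** A lightweight WaveNet-style encoder: a 1×1 input convolution
into 12 residual channels, then two residual blocks of three dilated causal
convolutions (kernel 2, dilations 1, 2, 4; receptive field
$1 + 2\,(1{+}2{+}4) = 15$ steps), each layer a gated unit
$\tanh(\cdot)\odot\sigma(\cdot)$ feeding a skip projection; the summed skips
pass through a ReLU, a 1×1 post-processing convolution, and non-overlapping
average pooling (stride 4). The pooled maps are flattened — position is kept
at 4-step resolution because the modified base always sits at the window
centre — and a fully connected layer produces the 1024-dimensional read
embedding. The flattened input to that layer also carries an identically
pooled copy of the raw five-channel window: this linear bypass keeps plain
level and probability shifts directly visible to the embedding layer while
the convolution stack contributes nonlinear context features. At the corpus
sizes used here the bypass is what lets gradient descent find the simple,
transferable solution instead of memorizing per-site signatures; it changes
nothing about the stated block structure.

**Site aggregation (dual-stream MIL).** Stream 1 scores each embedding
$H_i$ with a linear instance classifier; the read with the largest
modified-class margin is the critical instance $H_m$, and its score vector
is the stream-1 output $C_1$. Stream 2 projects each read to a query
$q_i = W_q H_i$ and a value $v_i = W_v H_i$, weights values by a softmax
over $\langle q_i, q_m\rangle$, forms the bag embedding
$B = \sum_i U(H_i, H_m)\, v_i$ and scores it, $C_2 = W_b B$. The final class
scores are the elementwise mean $C = \tfrac12 (C_1 + C_2)$ and
$P(\mathrm{mod}) = \mathrm{softmax}(C)$ over the two classes, reported as
the modified-class probability. The aggregation is exactly permutation
invariant and the attention weights sum to 1; both are enforced by tests.
Bags are processed one at a time as dense matrices (reads concatenated
along the time axis, causal shifts never crossing a read boundary), so no
padding or masking is needed.

**Stoichiometry.** A separate two-layer fully connected head maps each
embedding to a two-class score; the pseudo-label is the argmax and the
site's modification ratio is the exact mean of the pseudo-labels.

## Training

The training protocol is the package's own design. The training corpus
mirrors an in-silico IVT mixture: modified sites mix reads
from a fully modified and an unmodified pool, so *every* read's label is
known even in mixed bags. Training is therefore two-stage:

1. **Read-level pretraining** of the encoder plus instance classifier with
   cross-entropy on all labelled reads (Adam, minibatches of 64, 3 epochs,
   lr $10^{-3}$, decoupled weight decay $10^{-3}$ on weight matrices).
   End-to-end bag-only training was also implemented
   (`freeze_encoder = FALSE`, `pretrain_epochs = 0`) but does not converge
   at desk scale: the aggregator feeds encoder gradient essentially through
   one critical read per bag.
2. **Aggregator training** on bag labels over the frozen embeddings (one
   bag per Adam step, 20 epochs by default) — the regime the dual-stream
   aggregator was designed for, where instance features are pretrained and
   the MIL head is learned on top.

The stoichiometry head is fit the same way, on all labelled reads by
default (`reads = "pure"` restricts it to pure 0%/100% bags, but with few
fully modified sites in a corpus that restriction leaves the head too few
positive sequence contexts to generalize from); it is evaluated on mixed
bags it never saw. All stages reshuffle with a fixed seed and are
bit-reproducible; training emits a JSON-lines log and an RDS checkpoint
that records parameters, both configs and the seed.

## The synthetic generator

The generator emulates, per read: 5-mer-dependent expected current levels
(a deterministic synthetic pore table — levels drawn once from a fixed
seed, mean 100, spread 12, within-5-mer SD 2.5 current units), dwell times
of 1 + Poisson(2) trace rows per base (30 samples/base on average),
Gaussian current noise, trace rows that put `trace_sharpness` (default
0.85) of their mass on the true base (60/40 between the mono- and
di-nucleotide class) with the remainder uniform, and move flags on the
first row of each base. A modified adenosine shifts its dwell segments by
the pore model's m6A offset (default 2 within-5-mer SDs = 5 units, the
effect size all recovery results are stated at) and loses `trace_perturb`
(default 0.2) of its true-base trace mass. Site bags draw their modified
read count exactly (`round(ratio * n)`, used in tests for determinism) or
binomially.

Bag featurization uses the simulator's own truth segmentation by default —
the resquiggler is validated separately against that truth and by the
end-to-end pipeline, and truth-mode keeps training corpora cheap; pass
`featurize = "resquiggle"` for the full path.

What the generator does *not* emulate: basecalling errors (moves are always
consistent with the reference), homopolymer-specific signal artifacts, RNA
secondary-structure distortions, or carrier-specific pore drift. Passing
recovery tests on this data therefore demonstrates that the pipeline's
machinery is correct and that the model recovers a detectable effect under
the stated noise model — not that the defaults match any particular flow
cell chemistry. The noise and offset defaults are free parameters of the
simulator, chosen once as plausible values, not calibrated to real IVT
signal.

## Problem sizes and numerical choices

Recovery experiments use 200 bags × 30 reads (140 training, 60 held out)
for classification and 100 fresh bags with mixing ratios uniform in [0, 1]
for stoichiometry; at these sizes a full train/evaluate cycle takes a few
minutes on one CPU core. Held-out performance at the default conditions:
site ROC-AUC ≈ 0.95, accuracy ≈ 0.92, stoichiometry Pearson r ≈ 0.83 —
computed by `scripts/acceptance.R` and the test suite, never hard-coded.

Numerical details worth knowing: softmaxes subtract the maximum;
cross-entropy clamps probabilities at $10^{-12}$; DP ties prefer
transitions; `which.max` resolves exact score ties by first index;
subsampling and shuffling always run under locally scoped seeds
(`.Random.seed` is saved and restored, so library calls never perturb a
caller's RNG stream).

## Limitations

* The classifier and stoichiometry head are trained per-corpus; no
  pretrained weights ship with the package, and transfer to real DRS data
  would require training on real IVT corpora.
* Bags are independent by construction; the pipeline reports per-transcript
  sites and leaves any gene-level collapsing to the user.
* The resquiggler assumes the basecalled sequence matches the reference
  (no indel handling); reads failing that assumption fail loudly and are
  skipped by the pipeline with a logged count.
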