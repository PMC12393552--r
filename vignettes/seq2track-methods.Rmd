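---
title: "seq2track: model, training protocol, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seq2track: model, training protocol, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Predicting functional genomic signal — chromatin accessibility (ATAC-seq,
DNase-seq) and histone-mark ChIP-seq coverage — directly from DNA sequence
requires models that see both local motif content and interactions between
sequence elements tens of kilobases apart. `seq2track` implements a
simplified Enformer-style sequence-to-track network and, around it, the
complete experimental machinery used to study such models on a budget:
Poisson-likelihood training, architecture ablations, pretrain→fine-tune
transfer with head replacement and trunk freezing, homology-aware data
splits, and a track-count generalization/specialization sweep. A synthetic
regulatory-grammar generator provides desk-scale datasets with the
statistical structure the method assumes, so every experiment runs in
minutes on one CPU.

## Model

The network maps a one-hot encoded window of `sequence_length` bp
(A=[1,0,0,0], C=[0,1,0,0], G=[0,0,1,0], T=[0,0,0,1], N=[0,0,0,0]) to a
`(output_bins, num_tracks)` matrix of strictly positive Poisson rates at
`bin_size` bp resolution:

1. **Convolutional stem and tower** — `num_conv_blocks` residual blocks
   (stem kernel 15, tower kernels 5, each with a pointwise residual
   convolution); the first `num_pooling_stages` blocks end in a 2× pooling
   stage, so `2^num_pooling_stages = bin_size` closes the resolution
   arithmetic. Pooling is softmax-weighted ("attention") pooling with a
   learned per-channel logit scale, selectable to max pooling. Widths grow
   geometrically from `model_width/2` at the stem to `model_width`.
2. **Attention stack** — `num_attention_blocks` pre-norm transformer blocks
   (layer norm; multi-head attention with a learned symmetric
   relative-position bias added to the logits; feed-forward with GELU).
3. **Optional final pointwise convolution** to `2 × model_width` channels.
4. **Central crop** to `output_bins` (crop computed, never hard-coded) and a
   **linear head** per track with a softplus output nonlinearity, which
   guarantees positive rates (a floor of 1e-8 additionally protects the
   logarithm in the loss).

The two ablation flags structurally remove layers rather than zeroing them:

* `use_final_pointwise = FALSE` removes stage 3 entirely.
* `use_attention_linear = FALSE` removes one linear layer from each
  attention block. Which linear layer is ambiguous in the architecture
  family's informal description, so both readings are implemented and
  selectable via `attention_linear_site`: the default
  `"output_projection"` removes the post-attention projection — the
  concatenated heads then feed the residual stream directly, which forces
  `num_heads × head_dim = model_width` — while `"ffn_second"` removes the
  second feed-forward linear (the feed-forward becomes a single
  width-preserving linear plus GELU). Neither reading is asserted to be
  canonical; parameter counts decrease strictly under either.

Weights initialize from uniform Kaiming-style bounds (±1/√fan-in, the
framework default the protocol assumes), reproducibly from a single seed.
The forward and backward passes are written directly on BLAS matrix
operations; the backward pass of every layer and every structural variant
is verified against central finite differences in the test suite.

## Training protocol

The objective is the Poisson negative log-likelihood
`mean(λ − y·log λ)` — the `log(y!)` term is dropped as it does not affect
optimization, so reported losses are comparable only within this toolkit.
The reduction is the mean over bins and tracks, keeping single- and
multi-track losses on one scale. In multi-track mode the loss averages over
all tracks; in single-track mode only `track_index` contributes.

Optimization uses AdamW (β₁=0.9, β₂=0.999, ε=1e-8, decoupled weight decay
1e-4) at batch size 1, for a fixed 10 epochs, with a piecewise-linear
learning-rate schedule: 0 → `peak_lr` across the first (warmup) epoch, then
linearly back to 0 at the final step. Interpolation is per iteration, not
per epoch — the wording of the protocol fixes only the endpoints, and the
per-iteration choice is smoother. Shuffling (and dropout, when enabled) is
seeded per epoch from `shuffle_seed`, making loss trajectories
bit-reproducible on a fixed platform.

Evaluation is the Pearson correlation, computed per track by pooling all
bins of all examples into one prediction/target vector pair, then averaged
over tracks; constant tracks are skipped and listed. Pooling across
examples (rather than correlating per example and averaging) is a
documented convention of this package, not a claim about any external
implementation; a test constructs a case where the two conventions disagree
and pins the pooled one.

## Transfer machinery

Checkpoints store the parameter collection (partitioned into `trunk.*` and
`head.*` groups with stable names), the full architecture config (so a
model rebuilds from the file alone), a format version, and provenance.
Optimizer state is deliberately excluded: fine-tuning restarts with a fresh
optimizer. `replace_head()` deletes the linear head and installs a freshly
seeded one at the new track count, leaving the trunk numerically untouched;
`set_frozen()` reversibly restricts updates to the head; `finetune()`
composes load → replace head → optional freeze → train.

`run_ablation()` trains a list of architecture variants under a paired
design — identical initialization seed, data order, and evaluation set —
and reports parameter counts, loss trajectories, and final correlations.

`track_sweep()` studies the generalization/specialization trade-off: for
each `(additional-track count, replicate)` cell it samples additional
tracks (uniform, without replacement, never the track of interest), trains
a fresh model in multi-track mode, evaluates, then fine-tunes on the single
track of interest at a much smaller learning rate and re-evaluates. Cell
seeds mix `(base_seed, count, replicate)`, so extending the count grid
never perturbs existing cells. By default each replicate resamples the
track subset along with the initialization (`resample_tracks = FALSE`
freezes the subset per count).

## Data pipeline

Coordinates are 0-based half-open (BED convention) everywhere; 1-based
formats are converted at the rtracklayer boundary. `make_regions()` tiles
chromosomes into fixed windows; `partition_regions()` assigns
train/validation/test with largest-remainder sizes and a seeded
permutation; `homology_reassign()` moves every region named in a homology
table into train (eliminating evaluation leakage toward external training
data) and moves an equal number of seeded, non-homologous,
originally-train regions out to the labels the homologs came from —
"approximately equal" is implemented as exactly `min(k, available)`, with
any shortfall logged, and provenance flags record every move so either
audit direction is possible. Homology *detection* is out of scope; the
table is an input.

Targets are extensive coverage counts, so binning sums per-bp signal (never
averages). Sequences and targets are taken from the forward strand only;
no reverse-complement augmentation. Raw counts are used as targets — no
clipping or squashing transform is applied. Datasets round-trip through a
versioned container (`write_dataset()`/`read_dataset()`) and export to
FASTA/BED/bedGraph for interchange.

## The synthetic benchmark

`grammar_spec()` defines a motif vocabulary (6–10 bp consensus strings with
per-position mutation rates), per-track additive weights, optional pairwise
interaction terms, and a baseline rate. For a given sequence the per-bin
rate of a track is

```
lambda(bin) = baseline
            + sum_m  w[m, track] * #{occurrences of motif m overlapping bin}
            + sum_(i,j) w_ij * #{(i, j) co-occurrences within max_distance,
                                  credited to both partner bins}
```

floored at 1e-3. The rate model is *additive* rather than exponential so
planted effect sizes map linearly to coverage and every oracle stays
hand-checkable. Occurrences are counted by scanning the realized sequence
(mismatch-tolerant consensus matching), which makes `rate_profile()` a pure
function of `(sequence, spec)`: with noise disabled, a predictor that
computes `rate_profile` from the sequence achieves Pearson exactly 1, so
the generator's ceiling is known by construction. With noise enabled,
targets are independent Poisson draws at those rates. Motif instances are
planted at seeded uniform positions with Poisson-distributed counts and
per-position mutation; overlapping plants are allowed and both are counted.

`task_family()` builds two grammar members over one vocabulary with an
exact support overlap (e.g. overlap 0.75 of 8 motifs ⇒ 6 motifs weighted in
both members), emulating related "species" tasks. `make_transfer_pair()`
materializes a many-track pretraining dataset from member A and a
fine-tuning dataset from member B with disjoint sequence seeds.
`make_distractor_tracks()` appends unlearnable or unrelated tracks
(permuted real tracks, an independent-vocabulary grammar, or pure Poisson
noise) for the sweep.

What the generator does **not** emulate: real genomic background
composition and repeats, nucleosome positioning and chromatin biophysics,
strand asymmetries, experimental coverage biases, or homology structure
between sequences. Tests passing on this benchmark show that the machinery
behaves as specified on data matching its assumptions — not that any
particular accuracy will be reached on real assays.

## Desk-scale study conditions

All training-based tests and the acceptance script use one geometry, chosen
so each 10-epoch run finishes in seconds-to-minutes on a single CPU:
512 bp windows at 32 bp bins (5 pooling stages, 16 output bins), a
32-channel trunk with 5 conv blocks and 2 attention blocks (2 heads × 16).
The experiments use:

* **Memorization**: 8 examples of a fixed 4-motif single-track grammar,
  200 epochs, peak LR 1e-3, 3 seeds.
* **Transfer**: families of 8 motifs at overlap 0.75, weights U(2, 4),
  ~4 occurrences per motif per window; 20 pretraining tracks, 1
  fine-tuning track; 256 pretraining, 96 fine-tuning-train, 64 validation
  examples; 10 epochs at peak LR 1e-3; 3 paired seeds.
* **Sweep**: 4 informative tracks plus 64 permuted distractors, 96/64
  train/validation examples, additional-track counts {1, 4, 16, 64} × 3
  replicates; multi-track training at peak LR 2e-4 and post-hoc
  single-track fine-tuning at 2e-5.

Two learning-rate choices deserve explanation. The package default
(`peak_lr = 3e-5`) is the protocol's genome-scale setting, tuned for runs
of ~3×10⁵ optimization steps; a desk-scale run takes ~10³ steps, over
which 3e-5 cannot move the weights appreciably, so the desk experiments
raise the peak to 1e-3 (2e-4 for the sweep's multi-track phase). Second,
the sweep's post-hoc fine-tuning uses a rate 10× below its training rate,
mirroring the protocol's use of a much smaller fine-tuning rate for the
track of interest: fine-tuning should refine the head and nudge the trunk,
not retrain it — at desk scale, larger fine-tuning rates simply continue
training and wash out the track-count effect under study, while the
multi-track phase is kept mildly underfit (peak 2e-4) so refinement has
headroom in every cell.

## Numerical choices and degenerate inputs

* Softplus is evaluated as `log1p(exp(x))` with a linear branch above 30;
  its floor plus the 1e-8 guard inside the loss logarithm keeps the NLL
  finite for any finite input.
* Layer norm uses ε = 1e-5 over channels per position.
* Attention logits subtract their row maximum before exponentiation.
* Max pooling breaks ties toward the earlier position; softmax pooling has
  no ties.
* Constant tracks are skipped (with a listing) during evaluation; a fully
  constant dataset is an error.
* A non-finite training loss aborts with the epoch/step/example indices.
* Degenerate schedules (warmup 0) start at the peak rate; `epochs = 0`
  returns the model unchanged with an empty history.

## Known limitations

* Batch size is 1 per optimization step (the protocol's setting); larger
  `batch_size` accumulates gradients but there is no batched forward, so
  throughput is linear in examples.
* The relative-position schemes are a learned per-distance bias and a fixed
  exponential-decay basis; the exact positional basis functions of the
  original Enformer lineage are a non-goal.
* Training is CPU-only and hence practical up to a few thousand
  desk-scale steps; the full-scale geometry (196,608 bp, 896 bins) is
  supported for forward passes and parameter accounting, not for training
  runs of realistic length.
* Checkpoints and dataset containers are R-serialized (versioned); they
  are not interchange formats. Use the FASTA/BED/bedGraph exports for
  interoperability.
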