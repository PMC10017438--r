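---
title: "somnostage: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{somnostage: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somnostage is an automatic sleep-stage classifier for polysomnographic
(PSG) recordings.  It assigns one of the five AASM stages — Wake (W), N1,
N2, N3, REM — to every 30-s epoch of a night, from any combination of EEG
channels and/or a left/right EOG pair.  This vignette explains the model,
the preprocessing chain, the training procedure, the synthetic data used
for testing, and the design decisions that were genuinely open, so that a
reader can judge what a passing test suite does and does not establish.

## The signal model and preprocessing chain

Sleep stages express themselves spectrally: sustained occipital alpha
(8–12 Hz) in relaxed wake, theta (4–7 Hz) in N1, sleep spindles
(11–16 Hz bursts) and K-complexes in N2, high-amplitude slow oscillations
(< 2 Hz) in N3, and low-amplitude mixed-frequency EEG with large, slow,
conjugate eye movements in REM.  Everything the classifier needs lives
below 30 Hz, so the preprocessing chain is:

1. **Band-pass FIR, 0.3–30 Hz** — one-pass, zero-phase (group-delay
   compensated) Hamming windowed-sinc filter.  Transition bandwidths
   follow the common M/EEG heuristic (`min(max(f/4, 2 Hz), edge
   distance)`): 0.3 Hz on the low side, 7.5 Hz on the high side, giving a
   filter of about 11 s at typical rates, 53 dB stopband attenuation and
   0.0194 passband ripple (the standard Hamming figures).  The tests
   assert behaviour (stopband < 1 % leakage, passband within 3 %, DC
   removed), not a bit-exact kernel, because filter length conventions
   differ across toolboxes.
2. **Per-channel, per-recording z-transform** (population denominator;
   the n vs n−1 difference is negligible at overnight lengths and is
   fixed by declaration).
3. **HEOG derivation** — the right EOG channel is subtracted from the
   left to form a single horizontal-EOG channel, which replaces the
   monopolar pair as the network's EOG input.  The difference of two
   z-scored channels has sd ≈ √2 when L/R are weakly correlated, so the
   derived channel is re-standardized; all network inputs are then on
   one scale.
4. **Resample/epoch to 2,560 samples per 30 s.**  The binding constant is
   the sample count: the target rate is defined as exactly 2560/30 Hz
   (85.33 Hz in print).  Resampling is polyphase rational resampling with
   a Kaiser anti-aliasing low-pass, applied to the whole recording;
   epoch k is samples (k−1)·2560+1 … k·2560, and a trailing partial epoch
   is discarded.  Input already at 2560/30 Hz passes through unchanged.

The chain is deterministic, ordered exactly as listed, and its parameters
are fingerprinted into trained models; inference refuses data prepared
with a different fingerprint.

## The network

Three stages, one parameter set for every channel combination:

1. **Signal encoders.**  One 1D residual CNN per signal type (EEG, EOG).
   Each of five stride-2 stages halves time resolution (2,560 → 80
   samples) while widening channels (16, 32, 64, 128, 256); each stage is
   followed by residual blocks — four for EEG, one for EOG, reflecting
   the much lower complexity of ocular signals.  An adaptive average pool
   to 5 time points and a flatten yield a 1,280-feature vector per epoch.
   Convolutions use group normalization and ReLU.  The exact filter
   counts/kernels are declared defaults of this package: the printed
   constraints (input 2,560, output 1,280, four blocks per downsampling
   stage, shallow EOG) pin the shape but not every width.
2. **Mixer/compressor.**  The EEG and EOG vectors (2 × 1,280) are
   concatenated and compressed by three linear layers to a 512-dim "mix"
   vector.  When a signal is absent its slot is filled by a learned
   missing-embedding, so single-EEG, single-EOG and combined inputs all
   flow through the same parameters.  This mechanism is not specified by
   the source description; it is the minimal one that lets one model
   serve all permutations.
3. **Two heads.**  A context-free head (three linear+ReLU layers, then a
   linear layer to 5 log-softmax outputs; its penultimate activation is
   the 512-dim context-free latent) and a context head: a bidirectional
   GRU (hidden 512 per direction) whose per-epoch output is projected to
   512 (forward projection alone in forward/streaming mode, the sum of
   forward and backward projections in offline bidirectional mode) and
   mapped to 5 log-softmax outputs.

Stage order is fixed (W, N1, N2, N3, REM); argmax ties break toward the
lower index, deterministically.

## Training

Dual-mode training follows the stated procedure: each PSG is divided into
contiguous batches of roughly equal size; for each batch both heads'
losses are computed from one shared trunk forward pass, both are
backpropagated, and the optimizer (AdamW, β₁ = 0.9, β₂ = 0.999) steps
once.  The GRU hidden state starts at zero for each PSG and is carried —
detached, so backpropagation truncates at batch boundaries — across the
batches of a night.  The loss is class-weighted cross-entropy
(W 1, N1 2.4, N2 1, N3 1.2, REM 1.4) with weighted-mean reduction;
`UNKNOWN` epochs pass through the forward pass (to keep the recurrent
context honest) but are masked out of the loss.  Each PSG is traversed
once per signal permutation (each EEG channel alone, HEOG alone, each
EEG+HEOG pair, optionally with independent polarity flips), which is what
makes the trained model montage-agnostic.

Two points were genuinely open and are this package's own choices:

* **Both GRU directions are trained.**  Training the backward direction
  "later, at inference time only" is not possible — untrained backward
  weights would make offline bidirectional inference worse than forward
  inference, inverting the expected mode ordering.  Each direction scans
  every batch (the backward direction right-to-left), with its own
  carried hidden state.  This is exactly what a stock bidirectional GRU
  layer does under sequential batching.
* **Direction dropout.**  On a random 25 % of batches the context head
  trains forward-only.  Without this, forward/streaming inference sees a
  projection distribution (missing the backward term) it never
  encountered during training and underperforms even the context-free
  head.  With it, one head supports all three inference modes.

Checkpoint selection balances MCC and macro F1 by rank sum (ties to the
later epoch) — the balancing rule is not formalized in the source and the
rank-sum form is a declared choice — and the selected checkpoints' weights
are averaged elementwise.

### Desk-scale (reduced) configuration

The full architecture and schedule are sized for thousands of nights on a
GPU.  The test suite instead uses `reduced_model_config()` /
`reduced_train_config()`: two encoder stages (widths 8/16, strides 8/4),
mix length 64, dropout 0.25, learning rate 1e-3, 5 training epochs, 5
contiguous batches per 100-epoch night, no polarity flips, and a global
gradient-norm clip of 1.  The learning rate and batch count were chosen
once on a 25-night calibration set for optimization robustness (3e-5
simply does not move a tiny model in 5 epochs); the clip suppresses the
rare recurrent-training instabilities that otherwise make individual
seeds stall.  Dropout is applied after dense/GRU layers only — 0.5 after
every convolution would cripple training at this scale, and the source
does not specify conv-internal placement.

## Inference, certainty, consensus

Three modes: `bidirectional` (full-sequence GRU both ways — offline
scoring), `forward` (forward direction only, hidden carried —
reproducible epoch-by-epoch with `stream_step()` for BCI use), and
`context_free` (single epochs).  The certainty of an inference is the
cross-entropy of the length-5 log-softmax output against its own argmax,
i.e. −log p(inferred stage): 0 is maximal certainty.  The permutation
consensus runs every channel view and adopts, independently per epoch,
the view with the smallest certainty value; per-epoch (not per-night)
selection is deliberate, since certainty is defined per inference, and
certainties are compared across views without calibration.

## The synthetic PSG generator

`generate_hypnogram()` samples a five-state Markov chain with dwell-heavy
diagonals; N3 is reachable only from N2, REM returns mostly to itself.
`generate_psg()` renders each epoch from a per-stage spectral recipe
(alpha for W; theta with a variable amplitude and an alpha residue for
N1; spindle bursts and K-complexes over a theta background for N2;
0.6–1.2 Hz slow oscillations for N3; low-amplitude 3–8 Hz EEG with large
0.3–0.8 Hz anti-phase EOG deflections for REM).  The EOG pair carries the
anti-phase deflections plus an in-phase EEG bleed, so the HEOG difference
amplifies the ocular signal and cancels the bleed — giving the EOG-only
pathway genuine information.

These signatures are deliberately stronger and cleaner than real
physiology: no artifacts, no inter-subject variability, no scorer noise,
stationary recipes within an epoch.  A green learning test therefore
establishes that the implementation can extract stage-specific spectral
structure and exploit temporal context — not that the package reaches
clinical-grade accuracy on real PSGs.  N1 is intentionally the ambiguous
class (variable amplitude, overlapping bands with W and REM), which is
what makes context genuinely useful, mirroring where real classifiers
struggle.

## Numerical choices and degenerate inputs

* All gradients are hand-written and verified against central finite
  differences (the suite checks every parameter tensor across the three
  input permutations).
* Encoder normalization is group normalization (group size about 8
  channels, ε = 1e-5): statistics are computed per epoch, never across a
  batch.  This is deliberate, not cosmetic.  Training batches are
  *contiguous* 30-s epochs, so a batch is often dominated by one sleep
  stage; batch-norm statistics then encode the label and the network
  learns to read them, which looks fine in training mode and collapses in
  evaluation mode (observed directly during development: evaluation
  accuracy peaked mid-training and then fell while the training loss kept
  improving).  Per-sample statistics remove the leak and also make
  streaming inference exactly equal to batch inference.
* Weighted CE reduction divides by the summed weights of the batch.
* Zero-variance channels, empty hypnograms, missing montage channels,
  non-multiple-of-30 annotation durations, fingerprint mismatches and
  permutations over absent channels all raise explicit errors.
* Argmax ties (exactly equal log-probabilities) go to the lower stage
  index; `which.min` ties in the consensus go to the earlier permutation
  in the deterministic enumeration order.

## Known limitations

* The encoder internals are declared defaults of this package; externally
  published sleep-stager checkpoints cannot be loaded.
* EMG is not used anywhere (dropped by design in the source method).
* The EDF writer is fixture-grade (integer rates, 1-s records,
  per-channel linear scaling); EDF+ annotations are not parsed.
* Real-data benchmark accuracies (NSRR/DREEM corpora) are out of scope:
  they require the original corpora and GPU-scale training.
* Training assumes recordings fit in memory; no out-of-core path.
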