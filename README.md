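# somnostage

Automatic sleep staging for polysomnography (PSG) in R.

Human sleep is scored in 30-second epochs into five stages — Wake (W),
N1, N2, N3 and REM — by experts reading EEG and EOG traces for alpha
rhythm, theta activity, sleep spindles, K-complexes, slow oscillations
and eye movements.  Manual scoring takes hours per night and scorers
agree only 70–80 % of the time.  somnostage implements a deep
sleep-stage classifier for researchers who need reliable, reproducible,
fully local staging: offline scoring of EDF recordings, real-time
(streaming) inference for brain-computer interfaces and closed-loop
stimulation, and training on their own data — with any combination of
EEG channels and/or a left/right EOG pair.

## The model

Each preprocessed 30-s epoch (band-passed 0.3–30 Hz, z-scored,
resampled to 2,560 samples) is encoded by a 1D residual CNN per signal
type — deep for EEG, shallow for EOG — into a 1,280-dim feature vector
x_sig.  A three-layer mixer compresses the pair (2 × 1,280, with a
learned embedding standing in for an absent signal) into a 512-dim
vector m_t.  Two heads map m_t to a log-softmax distribution over the
five stages:

* context-free: three fully-connected layers, p(y_t | m_t);
* context-aware: a bidirectional GRU, h_t = GRU(m_t, h_{t-1}), giving
  p(y_t | m_1..m_T) offline or p(y_t | m_1..m_t) in streaming mode.

Training minimizes class-weighted cross-entropy
(w = 1, 2.4, 1, 1.2, 1.4 for W, N1, N2, N3, REM) for **both** heads from
one shared forward pass per contiguous batch (AdamW, one step per
batch), traversing every *signal permutation* of the montage — each EEG
channel alone, the horizontal-EOG difference channel alone, and each
pair, optionally with polarity flips (a two-EEG + EOG montage yields 14
views).  At inference, the *permutation consensus* scores every view and
adopts, per epoch, the view with the highest certainty, where certainty
is the cross-entropy of the output distribution against its own argmax,
c_t = −log p(ŷ_t); the most certain view has the smallest c_t.

Evaluation follows the field's conventions: per-PSG Matthews correlation
coefficient (multiclass, Gorodkin form), per-stage and macro F1,
accuracy, Cohen's kappa, confusion matrices, stage-proportion and
transition-rate discrepancies, and a 4-class "light sleep" (N1+N2
merged) analysis — aggregated across PSGs by medians.

A synthetic PSG generator (Markov-chain hypnograms + stage-dependent
spectral signatures) makes the whole pipeline testable with no clinical
data; see `vignette source in vignettes/somnostage-methods.Rmd` for the
model, its assumptions, and what green tests do and do not establish.

## Worked example

```r
library(somnostage)

## a synthetic overnight recording with one EEG channel and an EOG pair
hyp <- generate_hypnogram(100, seed = 7)
rec <- generate_psg(hyp, montage = list(eeg = "C3", eog = c("EOGL", "EOGR")),
                    sfreq = 100, seed = 8)
prep <- preprocess_psg(rec, hyp)          # filter -> z-score -> HEOG -> epochs
prep$epochs
#> <epoched_signals> 100 epoch(s) x 2 channel(s) x 2560 samples

## train the desk-scale model on 20 synthetic nights
train <- synth_psg_set(20, 100, sfreq = 100, seed = 101)
fit <- fit_model(train, tcfg = reduced_train_config(seed = 1),
                 mcfg = reduced_model_config())

## offline scoring with the permutation consensus
res <- infer_consensus(fit$model, prep$epochs, mode = "bidirectional",
                       polarity_flips = FALSE)
cm <- confusion(hyp, res$hypnogram)
round(c(accuracy = accuracy(cm), f1_macro = f1_macro(cm), mcc = mcc(cm)), 3)
#> accuracy f1_macro      mcc 
#>        1        1        1

## real-time (BCI-style) staging, one epoch at a time
inp <- apply_permutation(prep$epochs, signal_permutation("C3", TRUE))
step <- stream_step(fit$model, list(eeg = inp$eeg[, , 1], eog = inp$eog[, , 1]))
step$stage; round(step$certainty, 4)
#> [1] "W"
#> [1] 2e-04
```

The accuracy/F1/MCC line says the trained model recovers every epoch of
this held-out synthetic night; `step$certainty` is the certainty value
(0 = maximally certain, here essentially certain the first epoch is
wake) for the first streamed epoch.  Numbers are from an actual run
of this script; the synthetic signatures are deliberately cleaner than
real physiology, so ceiling-level accuracy here does not imply
clinical-grade accuracy on real PSGs.

## Command line

```sh
somnostage simulate --nights 10 --epochs-per-night 100 --seed 1 --out data/
somnostage train    --config cfg.yaml --data-dir data/ --out model.ckpt
somnostage score    data/night_001.edf --model model.ckpt \
                    --mode bidirectional --out hyp.csv
somnostage eval     --true data/night_001_hypnogram.csv --pred hyp.csv \
                    --light-sleep --out report.json
```

(The script lives at `inst/cli/somnostage`; equivalently call
`somnostage_main(c("score", ...))` from R.)

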