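---
title: "Compressed-domain classification of multi-sensor gait: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-domain classification of multi-sensor gait: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitcs)
```

## The signal model

A body-area network carries `J` inertial sensors, each producing five
channels (3-axis accelerometer, 2-axis gyroscope) at a fixed sampling rate.
A sample is one fixed-length window stacked sensor-major into a `(5J) × h`
matrix. For compression, the `J` sensors' signals are modelled as a JSM-2
ensemble: every signal is sparse in a common orthonormal basis `Ψ` with one
*shared* support and sensor-specific coefficient values,
`x_j = Ψ θ_j`. The shared support captures the fact that all sensors watch
the same underlying movement; the differing coefficients capture where on
the body each sensor sits.

Each sensor owns a random measurement block `Φ_j` (M × N) and transmits
`y_j = Φ_j x_j`; the implied full operator is block-diagonal, so no
inter-sensor communication is needed at compression time. The compression
ratio `CR = (N − M)/N × 100%` is computed on the per-channel window length
`h`: a `(5J) × h` window maps to a compressed vector of length `5JM` by
applying the sensor's block to each of its five channel rows and
concatenating channel-major. This per-channel reading is the minimal
consistent bridge between per-vector compression mathematics and
five-channel sample matrices; it also means one `Φ_j` serves all five
channels of sensor `j`, as a real sensor node would implement it.

Classification never reconstructs. Compressed training windows become the
columns of an over-complete dictionary, grouped by class and normalized to
unit length; a compressed test sample `Y` is coded over the dictionary with
one coefficient column per sensor under a shared row support (the mixed
`l2/l0` row-sparsity constraint), and labelled by the class whose atoms
alone reconstruct `Y` best (minimal residual rule). The measurement scheme
is drawn once per experiment and shared by training and test data — the
compressed domain only makes sense if both sides live in the same
measurement space.

## Neighbour pruning (SRCC)

With `n` training atoms the joint solver costs `O(w²n)`; pruning the
dictionary per test sample to `m` atoms per class cuts this to `O(w²m)` and
empirically improves accuracy. The criterion ridge-regresses each sensor's
test block on the corresponding rows of all atoms,

`ŵ_j = (A_jᵀA_j + λI)⁻¹ A_jᵀ y_j`,

scores each atom by the mean of `|ŵ_j|` over sensors, and keeps the
`min(m, n_i)` best per class. Scoring per sensor and averaging is the
symmetric way to turn per-sensor ridge problems into one neighbour set; a
pooled variant (one ridge on the full stacked vector) is available via
`pooled = TRUE` for comparison. Selection is invariant to positive
rescaling of the test vector, since ridge coefficients scale linearly.

## Solvers

* **Greedy (default).** Simultaneous orthogonal matching pursuit across
  the sensor tasks: at each of at most `k` iterations the atom with the
  largest sum over sensors of squared normalized residual correlations is
  added, and each task is refit by least squares on the selected set.
  Selection is nested, so per-task residual norms are non-increasing.
* **MBCS.** A hierarchical Gaussian model: task noise with common unknown
  precision, zero-mean Gaussian priors on coefficients with per-atom
  precisions *shared across tasks* — sharing is what couples the tasks and
  induces a common row support. Hyperparameters are estimated by evidence
  maximization; atoms whose precision diverges above `1e8` are pruned;
  iteration stops when the relative change in log-precisions falls below
  `tol` (default `1e-6`, cap 200 sweeps). Non-convergence is flagged on
  the result and warned about, never an error: a usable posterior mean
  still exists.

With one task MBCS reduces to a single-task relevance-vector solver, which
the tests exploit as a consistency check against the greedy path.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `window_len` (h) | 200 samples | window length; 10 s at 20 Hz |
| `overlap_fraction` | 0.5 | sliding-window overlap |
| `filter_order`, `filter_cutoff` | 5, 30 Hz | Butterworth low-pass denoising |
| `cr` | 50% | compression ratio, per channel |
| scheme `kind` | `sparse_binary` | two ones per column; cheapest to implement on-node |
| `lambda` | 1e-3 | SRCC ridge penalty; small, stabilizes the closed form without distorting ranking |
| `m` | 40 | neighbours kept per class |
| `k` | 20 | row-sparsity bound of the greedy solver; small relative to `L·m = 360` so row-sparsity is meaningful |
| `outer_folds`, `inner_folds` | 10, 9 | subject-wise CV layout |

A 30 Hz cutoff cannot be realized at a 20 Hz sampling rate (Nyquist
10 Hz). Rather than erroring — which would make the nominal configuration
unusable — `lowpass_filter()` warns and passes the signal through
unchanged whenever `filter_cutoff >= sampling_rate / 2`. Users who want
actual denoising at 20 Hz should set a cutoff below 10 Hz.

Sparse-binary blocks use unnormalized ones: dictionary atoms are
re-normalized to unit length downstream, so any common column scaling of
the blocks is immaterial.

## Numerical choices

* All argmax/argmin ties break towards the smallest index, everywhere;
  combined with explicit seeds this makes every code path deterministic.
* The SRCC ridge is solved through whichever of the primal (`n × n`) or
  dual (`d_j × d_j`) normal system is smaller — an exact algebraic
  identity — and the Cholesky factor per sensor is reused across all test
  samples of a CV fold.
* Zero-phase filtering runs one Butterworth pass forward and one backward,
  each initialized at the DC steady state of its first sample, over a
  mirror-padded extension (`30 × order` samples per side). This keeps
  constants exactly fixed and confines startup transients to the trimmed
  padding; signals with a strong linear trend incur a small kink artefact
  at the edges, which is irrelevant for quasi-periodic inertial channels.
* Greedy least-squares refits use QR; rank-deficient selections yield zero
  coefficients for the dependent atoms rather than failures.
* A class with no atoms in a pruned dictionary receives residual
  `‖Y‖₂` (all-zero mask), so relabelling and degenerate prunings behave
  continuously.
* Segmentation stride is `round(h (1 − overlap))`, never below 1; a
  recording shorter than one window yields an empty result with a warning
  rather than an error.

## The synthetic generators

`simulate_jsm2_ensemble()` draws the JSM-2 model exactly as assumed: a
uniformly random shared support of size `k`, independent standard-normal
nonzero coefficients per sensor (scale-free, the conventional choice in
compressed-sensing simulation), optional i.i.d. Gaussian noise, and returns
the ground-truth model so recovery can be checked bit-for-bit.

`simulate_gait_dataset()` emulates the *shape* of a multi-subject wearable
activity database: per class and channel a smooth quasi-periodic template
(a sum of 2–4 random-phase sinusoids below a class-specific cutoff, scaled
by `class_sep`), a per-subject perturbation (±5% channel gains and a small
circular time shift), and i.i.d. Gaussian window noise. It deliberately
does *not* model biomechanics, sensor dropout, clock drift, axis
miscalibration, within-subject variability over time, or heavy-tailed
artefacts. Passing the end-to-end benchmark therefore demonstrates that the
pipeline is implemented correctly and that compressed-domain joint coding
separates band-limited quasi-periodic classes under noise — it does not
certify accuracy figures on real recordings, which depend on how strongly
real activities separate.

The benchmark conditions fix 20 subjects × 9 classes × 10 windows (1800
windows; 1620 per training split of the ten-fold subject-wise plan), 5
sensors, 200-sample windows, `class_sep = 1`, `noise_sd = 0.5` — noise on
the order of half the template amplitude scale, chosen once as a
moderately hard operating point — and seed 42 in the test suite. At these
conditions the SRCC-JSRC classifier at CR = 50%, `m = 40` attains pooled
CV accuracy well above the 90% bar, and accuracy at CR = 95% never exceeds
accuracy at CR = 50%; with only 10 of 200 samples per channel surviving,
degradation is expected, though on cleanly separated synthetic classes
both settings can saturate.

## Evaluation conventions

Confusion-table recall is the diagonal entry over its row total and
precision over its column total, both in percent; zero-denominator classes
are undefined (`NA`), not zero. For balanced classes accuracy equals the
unweighted mean of per-class recalls, which the tests assert as an exact
identity. Cross-validation is subject-wise: folds partition subjects, so no
subject contributes both training and test windows, and any leakage is an
internal error rather than a silent bias. The nested inner partition is
drawn and stored for hyperparameter tuning, though the shipped experiments
use fixed settings. Timing columns are recorded with the process clock and
are informational only — they are never asserted, being hardware-bound.

The bundled reference table (`gait9_confusion()`) ships verbatim; two of
its rows sum to slightly more than the nominal 200 windows per class, so
the recalls derived from those two rows are not internally consistent with
their nominal totals and are excluded from the reproduced set.

## Known limitations

* No convex `l1` or mixed-norm solver is provided; greedy pursuit and MBCS
  cover the use cases, and reconstruction quality is explicitly not the
  goal.
* Dictionary atoms are raw compressed training samples; no dictionary
  learning.
* The WARD-style reader expects the documented CSV layout
  (`Subject<s>/a<class>t<trial>.csv`, sensor-major columns); it does not
  parse binary `.mat` trial files.
* MBCS cost grows with the cube of the pruned dictionary size per sweep;
  it is intended for use after SRCC pruning, not on thousands of atoms.
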