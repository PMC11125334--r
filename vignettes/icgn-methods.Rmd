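---
title: "Recurrent classification of block-design fNIRS signals with contextual gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent classification of block-design fNIRS signals with contextual gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgn)
```

This vignette is the package's account of its models and the design choices
behind them: what the ICGN cell computes and why its state is bounded, how
raw two-wavelength fNIRS measurements become labeled training windows, what
the synthetic generator does and does not emulate, and the numerical
decisions (initialization, tolerances, tie-breaks, clipping) that a
maintainer would otherwise have to reverse-engineer from the code.

## 1. The cells

### LSTM baseline

The package implements the standard LSTM recurrence directly
(`lstm_step()`), with input, forget and output gates
$i_t, f_t, o_t = \sigma(W_x x_t + W_h h_{t-1} + b)$, a tanh candidate
$\tilde c_t$, the additive state update
$c_t = f_t \odot c_{t-1} + i_t \odot \tilde c_t$ and hidden state
$h_t = o_t \odot \tanh(c_t)$. Nothing here is novel; it exists so that the
contextual cell can be compared against a baseline that shares every other
line of code (initialization, head, optimizer, windowing).

### The integrated contextual gate cell

`icgn_step()` modifies the recurrence in two ways:

1. **Cell-state context in every gate.** Each gate pre-activation gains a
   term $w_{c\cdot} c_{t-1}$, so gating decisions see the memory content
   directly, not only through $h_{t-1}$ (which is already masked by the
   previous output gate). The candidate receives the same context term by
   default.
2. **Gate-sum memory update.**
   $c_t = (f_t + i_t + o_t) \odot \tilde c_t$: the memory cell is the
   candidate scaled by the summed gate activations, and there is **no**
   direct $c_{t-1}$ carry term. The previous state influences the present
   exclusively through the gates and the candidate.

Because each gate lies in $(0,1)$ and the candidate in $(-1,1)$, the update
implies $|c_t| < 3$ and $|h_t| < \tanh(3) \approx 0.995$ for *any* weights
and inputs. The recurrence is therefore self-stabilizing — states cannot
blow up over long sequences the way an unsaturated additive carry can —
at the price of giving up the LSTM's untransformed memory path. Both
properties are asserted by randomized tests. One floating-point caveat: the
bounds are strict in exact arithmetic, but when a gate pre-activation
exceeds roughly 37, `sigmoid()` rounds to exactly 1.0 in double precision
and a fully saturated cell attains $|c_t| = 3$ exactly; the tests check the
strict bound at ordinary magnitudes and the closed bound at deliberately
saturated ones.

### Faithfulness flags

The published description of this cell family is ambiguous in three places,
and the constructor exposes one flag per ambiguity rather than silently
picking a side:

* `share_candidate_with_forget` — the candidate equation is written with
  the forget gate's weight symbols. Read literally, the candidate has no
  parameters of its own. The default is `FALSE` (separate candidate
  parameters, the universal recurrent-network convention, and necessary for
  the cell to be able to store something different from what it forgets);
  `TRUE` reproduces the literal equations, and the trainer folds the
  candidate gradients onto the forget parameters accordingly.
* `output_context_shared_with_forget` — the output gate's context term is
  printed with the forget context matrix $w_{cf}$, almost certainly a typo
  for a distinct $w_{co}$. Default: distinct matrix; flag for literalness.
* `candidate_uses_cell_context` — the candidate equation includes a
  $c_{t-1}$ term, but the accompanying cell diagram states the internal
  state depends on the input and previous hidden state only. The default
  follows the equation (`TRUE`); setting `FALSE` follows the diagram.

Context matrices are full $H \times H$, matching the equations'
matrix-product notation; `diagonal_context = TRUE` gives the classic
peephole-LSTM diagonal convention instead (the diagonal constraint is
preserved under training by masking the gradients).

### Gradients

`cell_gradients()` implements backpropagation through time for both cells,
including every flag combination. Correctness is defined by contract —
agreement with central finite differences ($\varepsilon = 10^{-6}$) to a
relative error below $10^{-5}$ in double precision — and enforced by tests
over both cells, several shapes ($T \le 8$, $H \le 4$) and all flag
variants. The relative-error denominator is floored at $10^{-4}$ so that
parameter entries whose true gradient sits at the finite-difference noise
floor (about $10^{-10}$ absolute) do not report spurious disagreement.

## 2. The classifier and its training

All three model kinds (`lstm`, `icgn`, `bilstm`) share one head:
recurrent layer → dropout → dense ReLU layer → dense output. The shared
head is deliberate: accuracy differences between model kinds should reflect
the recurrent layer alone. For the bidirectional model the feature is the
concatenation of the forward cell's final state and the backward cell's
final state (the backward cell reads the window reversed), giving a $2H$
feature; "units" counts per direction.

Defaults: 64 recurrent units, dropout 0.2, 64 dense units, softmax output
with categorical crossentropy, Adam at learning rate 0.001, batch 32,
100 epochs. These sit in the best-performing region of the usual
neurons × dropout × learning-rate × loss grid for this problem class;
`hyperparameter_sweep()` re-runs any such grid. Mean squared error and a
sigmoid output head are available as options. Plain SGD is available
(`optimizer = "sgd"`).

**Gradient clipping.** Batch gradients are rescaled to a global L2 norm of
at most `clip_norm` (default 5). This was added after observing a concrete
failure mode: on synthetic subjects, Adam occasionally destabilized late in
training (validation accuracy ~97% at epoch 75 collapsing to ~68% by epoch
100 as the loss jumped from 0.28 to 0.7). Norm clipping is the standard
guard against exploding recurrent gradients and removed the instability
entirely; `clip_norm = Inf` disables it.

**Windowing.** Recurrent cells need sequences, while block-design labels
attach to time points. Each labeled sample becomes the causal window of
`window_length` consecutive samples ending at it (default 20, about 2 s at
10.1725 Hz) — this keeps the per-condition sample counts identical to the
time-point bookkeeping below. Windows never cross a condition boundary: at
a segment start the first in-segment sample is replicated as padding, so no
window mixes activity and rest samples and no label leaks across the
boundary.

Everything stochastic — initialization, shuffling, dropout masks — is
driven by explicit seeds; identical configuration plus seed reproduces the
training history bitwise. Dropout is inverted (masks scaled by
$1/(1-p)$ during training) and disabled at inference.

## 3. Preprocessing

**Beer–Lambert conversion.** `mbll_convert()` solves the $2\times 2$
extinction system per time point and channel:
$[\Delta HbO, \Delta HbR]^T = E^{-1}[\Delta A_{\lambda_1}, \Delta
A_{\lambda_2}]^T/(l d)$ with $l$ the source–detector distance (default
3 cm) and $d$ the differential path-length factor. The DPF default of 6.0
is the conventional adult-head value; it is a plain scale factor, so it
affects amplitudes but not classification. The extinction defaults for
760/850 nm are widely used literature values in μM⁻¹cm⁻¹; because vendors
differ in their tables, `extinction_table()` is fully configurable, the
matrix conditioning is checked (warning above condition number $10^6$), and
every test uses synthetic tables so no result depends on the default.
`inverse_mbll()` is the exact algebraic inverse (round trip below
$10^{-10}$, tested), which lets the synthetic generator emit raw-style
absorbance and exercise the full conversion path.

**Filtering.** A 4th-order Butterworth band-pass (0.01–0.2 Hz) applied
forward–backward (`signal::filtfilt`) for zero phase, per channel. Only the
passband is externally specified; order and realization are this package's
choice, checked against the designed response in tests (1 Hz attenuated
below 5% RMS, 0.05 Hz passed at 80–110%, in-band peak lag ≤ 1 sample). The
direct band-pass realization is numerically stable at these band edges and
sampling rate; this was verified empirically before choosing it over a
cascaded high-pass/low-pass form.

**Segmentation and counting.** The default paradigm is 30 s rest,
10 × (10 s activity + 20 s rest), 30 s rest — 360 s. At 10.1725 Hz the
per-condition sample counts are defined as
$N_c = \lfloor D_c f_s \rfloor$ with $D_c$ the condition's *total*
duration, distributed over that condition's segments by largest-remainder
apportionment (ties broken in schedule order); samples are 0-based with
half-open segments. This is the one simple rule consistent with the
canonical counts 610 (baseline) / 1017 (activity) / 2034 (rest) = 3661 —
note $\lfloor 360 \cdot 10.1725 \rfloor = 3662$, so per-condition flooring
leaves exactly one trailing sample unused. Baseline (initial/final rest) is
excluded from classing; inter-trial rest is class 1 and activity class 2;
multi-task schedules (`build_multiclass_paradigm()`) map `taskK` to class
K with inter-trial rest excluded.

**Splitting.** The published protocol picks equal numbers of both classes
at random, from every trial. With 1017 activity vs 2034 rest samples,
"balanced partitions" and "partitions exhaust all labeled samples" cannot
hold simultaneously, so `split_dataset()` offers both readings:
`balance_classes = TRUE` (default) first subsamples the majority class
evenly across trials, then splits each class 80/10/10 stratified by trial —
every partition balanced to within one sample; `FALSE` keeps all labeled
samples and splits each class proportionally (exhaustive, imbalance
inherited, test partition of 305–306 at the canonical counts). Both paths
are seeded and tested.

## 4. The synthetic generator

`generate_subject()` builds the noiseless ΔHbO activation by convolving
each task condition's boxcar with a canonical double-gamma HRF
(`canonical_hrf()`: peak 6 s, undershoot 16 s, undershoot ratio 1/6,
truncated at 32 s, peak-normalized to the configured amplitude in μM —
conventional canonical values; the gamma shapes are chosen so each gamma's
mode equals its configured delay). The activation projects onto channels
through a per-class weight matrix (default: half the channels respond, with
weights tapering 1 → 0.5; the rest are silent). ΔHbR is $-\tfrac13$ of
ΔHbO, the typical empirical inversion, before noise. Noise comprises white
sensor noise (default SD 0.1 μM, i.e. 10% of the default HRF amplitude —
a high-SNR regime), sinusoids at Mayer (~0.1 Hz), respiratory (~0.3 Hz)
and cardiac (~1.0 Hz) frequencies with random per-channel phases, and a
slow linear drift. `generate_cohort()` adds multiplicative log-normal
jitter ($\sigma = 0.2$) on HRF amplitude and noise SD across subjects, with
per-subject seeds derived deterministically from a master seed.

Ground-truth labels come from `segment_and_label()` applied to the emitted
series, so generator and preprocessing agree by construction — an
invariant the tests assert rather than assume.

What the generator does **not** emulate: motion-artifact spikes, optical
coupling changes, superficial (scalp) hemodynamics, spatial correlation
structure between channels, habituation of the response across trials, or
any photon-transport physics. Passing the recovery tests therefore shows
that the pipeline extracts a linearly decodable hemodynamic pattern from
realistic stationary noise — it does not certify performance on recorded
data, where those unmodeled effects dominate the difficulty. The
sanity-check ordering in the tests reflects this: a logistic model on
window means and slopes must already separate the synthetic classes before
the recurrent classifiers are held to the ≥85% recovery bar.

## 5. Cohort statistics

`one_way_anova()` computes the classical fixed-effects decomposition
directly (between/within sums of squares; $F$ on $(k-1, N-k)$ degrees of
freedom) and is cross-checked in tests against `anova(lm(...))` to
$10^{-10}$ relative; `tukey_hsd()` computes pairwise mean differences with
adjusted p-values from R's studentized-range distribution (`ptukey`),
cross-checked against `TukeyHSD()`. The two-sample t-test defaults to the
pooled-variance Student form (Welch by flag). For $k = 2$ groups,
$F = t^2$ to $10^{-8}$ relative — a property test.

The bundled 20-subject accuracy table reproduces its published summary
statistics: $F = 28.7319$ (printed as 28.731 — the comparison tolerance is
one unit in the last printed digit, accommodating truncation), Tukey mean
differences 6.39 / 2.437 / −3.953, LSTM column 84.89 ± 3.91, ICGN SD 1.60,
Bi-LSTM SD 1.96. The table's own printed ICGN and Bi-LSTM averages (91.23,
88.82) differ in the second decimal from the exact column means of its
values (91.28, 88.84); the package always reports exact column statistics
and the regression tests target only quantities that recompute verbatim.

## 6. Problem sizes and limitations

The test suite and `scripts/acceptance.R` run the full design paradigm
(360 s, 20 channels, 10.1725 Hz) but scale the learning problem to what a
laptop-class check warrants: 8 recurrent units, batch 64, one subject at
20 epochs in the tests and a five-subject cohort at 100 epochs in the
acceptance script; the shuffled-label chance control averages three
independent shuffles because overlapping windows make single-shuffle test
accuracies noisy (roughly ±10 percentage points). These sizes are the
package's verification choices, not statements about the sizes a study
should use.

Known limitations: training is plain R matrix algebra — adequate at these
sizes, but not a GPU deep-learning stack; no early stopping, class
weighting, or truncated-BPTT variants; a bidirectional ICGN wrapper is
structurally possible with the existing pieces but is not a configured
model kind; and no reader for HDF5-based container formats is included —
series travel as delimited text with JSON sidecar metadata.
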