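---
title: "Models and methods: smFRET analysis of telomere overhang dynamics"
author: "telodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: smFRET analysis of telomere overhang dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telodyn)
```

## The system and the measurement

Human telomeres end in a single-stranded (TTAGGG)\(_n\) overhang that can
fold into a G-quadruplex (G4) and is bound by the shelterin protein POT1,
while TRF2 binds the adjacent telomeric duplex. Single-molecule FRET
(smFRET) reports the distance between a donor (Cy3) and an acceptor (Cy5)
dye placed on such a construct as a per-frame efficiency
\(E \approx I_A / (I_A + I_D)\) in \([0, 1]\): a folded G4 on a
four-repeat (4R) overhang reads \(E \sim 0.65\); POT1 binding unfolds it to
\(E \sim 0.3\); transient looping of the POT1-bound overhang against the
TRF2-bound duplex produces excursions up to \(E \sim 0.9\).

`telodyn` implements the full trace-analysis chain for this class of
experiment — and, because no raw data are deposited for it, a synthetic
trajectory generator whose presets encode the experimental scenarios, so
every analysis stage can be validated by parameter recovery.

## The generative model

**State dynamics.** A molecule occupies one of a small number of FRET
states; switching is a continuous-time Markov chain (CTMC) specified by a
conservative rate matrix \(Q\) (`state_model()`). Trajectories are drawn
with the Gillespie algorithm: exponential holding times with rate
\(-Q_{ii}\), jumps by the embedded chain. Stationary occupancies come from
the null space of \(Q^\top\).

**Camera model.** `render_trace()` converts a trajectory into frames of
0.1 s (the frame integration time of the experiment). Within each
donor-excitation frame the state means are *time-weighted* (not point
sampled), so transitions faster than a frame blur into intermediate
apparent FRET exactly as a camera would show them. The channel model is

\[ I_D = (1 - \bar E)\, I_{tot}, \qquad
   I_A = \bar E\, I_{tot} + l\, I_D, \]

plus a constant background and additive Gaussian read noise per channel
(the standard EMCCD approximation; variance is state-independent, which
keeps the Gaussian-emission HMM well specified). The leakage coefficient
\(l\) is expressed as a fraction of the *detected* donor signal — the
convention under which the standard ratiometric correction
\(E = (I_A - l I_D)/(I_A + I_D - l I_D)\) is the exact inverse of the
renderer, donor-only molecules read exactly \(E = 0\), and the median of
\(I_A / I_D\) over donor-only molecules is an unbiased estimator of
\(l\).

**Excitation.** Frames follow an alternating-laser (ALEX) pattern of 10
green, 1 dark and 10 red frames; short histogram movies repeat the cycle,
long kinetic movies use one leading block followed by continuous green
excitation. Red (direct acceptor excitation) frames identify molecules
without an active acceptor (`flag_donor_only()`); the dark frame carries
the background. Because one dark frame per molecule estimates background
with an error equal to the full channel noise SD, ensemble analyses pool
dark frames across molecules (`ensemble_background()`, used by
`process_traces()`).

**Photobleaching** is single-step (no blinking, matching the oxygen
scavenger/trolox imaging buffer): after a drawn donor bleach time both
channels fall to background; after acceptor bleach the donor rises to the
full intensity and the red frames go dark. Bleaching is off in the
analysis-validation presets and available for realism tests.

### Preset calibration

Defaults encode the study conditions; values not reported by the
experiment are invented calibration constants, chosen once:

| Parameter | Default | Why |
|---|---|---|
| frame interval | 0.1 s | stated integration time |
| total intensity \(I_{tot}\) | 1000 counts/frame | typical EMCCD single-molecule signal |
| noise SD | \(I_{tot}/12\) ≈ 83 counts | gives per-frame FRET noise ≈ 0.07, the visual noise level of published traces |
| leakage | 0.08 | typical Cy3→Cy5 channel crosstalk; recovery tests must pass for \(l \in [0, 0.12]\) |
| background | 50 counts/frame | typical camera offset |
| trace length | 600 frames (60 s) equilibrium, 2000 frames flow | published trace windows |

State presets (`preset()`): free G4 0.65; POT1-bound 4R 0.30; Dynamic-I
oscillation 0.2 ↔ 0.55 with mean dwell 2.51 s in each state; Dynamic-II
spikes from a 0.25 baseline to 0.85 with spike dwell 0.63 s and baseline
dwell 3 s (the baseline dwell is unreported; 3 s reproduces the "sharp
stochastic spikes" appearance); monomer-POT1 2R oscillation 0.6 ↔ 0.3
with dwell 2.31 s; TRF2+POT1 stepping ladders with looped levels
0.35/0.55/0.70/0.85 (4-repeat duplex) or 0.55/0.80 (2-repeat duplex),
nearest-neighbour steps with 0.8 s mean dwell, plus a rarely visited
unlooped ~0.2 level (entry 0.01 s\(^{-1}\), dwell 0.8 s — the unlooped
state is described as an occasional excursion, and these rates keep its
occupancy near 1%). Two choices here depart from a literal reading of the
figure annotations and are deliberate: the Dynamic-I high state is set to
0.55, strictly inside the "~0.2–0.6" oscillation band, because a state
placed exactly at the 0.6 Dynamic-II threshold is unclassifiable even
without noise; and mixture presets POT1-only (40/35/25
steady/Dynamic-I/Dynamic-II) and POT1+TRF2 (20/45/35) reproduce the
reported population splits. Equilibrium titrations
(`simulate_titration()`) draw each molecule bound with Langmuir
probability \(c/(c + K_D)\), with \(K_D\) = 1.5 nM (4R) and 1.4 nM (2R).
Flow assays switch from the unbound to the bound model at an exponential
waiting time with rate \(k_{on} c\) after the flow moment
(\(k_{on}\) = 0.08 nM\(^{-1}\)s\(^{-1}\), an invented default of the right
order for the titration range); the PIFE variant instead multiplies both
channels by 1.4 at a binding time drawn at 0.13 s\(^{-1}\).

What the generator does *not* emulate: spectral crosstalk beyond
single-direction leakage, fluorophore blinking, gamma ≠ 1 detection
imbalance, intensity drift, and surface heterogeneity. Passing recovery
tests therefore demonstrates correctness of the analysis chain under the
stated noise model, not robustness to every artifact of real movies.

## Trace processing

`compute_fret()` subtracts background, applies the leakage correction,
masks frames with non-positive totals, truncates at a detected photobleach
step, and clips to \([0,1]\) for histogramming (raw values are kept for
diagnostics). Bleach detection (`detect_bleach()`) uses the least-squares
single change point on total green intensity — the split minimising the
two-segment sum of squares — with noise estimated robustly from the MAD of
first differences (one step cannot move it); a step is accepted only when
the post segment sits within 3 noise SDs of background and stays there.
The same change-point primitive locates PIFE enhancement steps, where the
cusum extremum was found to drift by many frames when the step sits early
in a long window.

## Classification of dynamic behaviour

`classify_trace()` reduces a trajectory to excursions from its baseline
(the histogram mode, refined by averaging within ±0.05 — robust to
excursions occupying much of the trace, unlike the mean):

1. median filter (3 frames) — removes single-frame shot-noise spikes;
2. candidate excursions: runs of \(|E - \text{baseline}| > A\)
   (default \(A = 0.15\)) of at least 2 filtered frames, the
   camera-limited detection floor; baseline returns shorter than the
   floor are absorbed, so the floor acts symmetrically and noise flickers
   cannot split one excursion in two;
3. confirmation (hysteresis): at least one frame must deviate by
   \(1.5 A\). Detection thresholds near 3 noise SDs otherwise produce a
   measurable false-dynamic rate on steady traces (~40% per 600-frame
   trace); the confirmation level sits near 4.5 SDs while every preset
   excursion amplitude (≥ 0.3) clears it, and dwell timing still uses the
   single-\(A\) crossing;
4. class: no excursions → steady; all excursion plateaus below
   \(H = 0.6\) → Dynamic-I; only high excursions → Dynamic-II; both →
   Dynamic-I+II (folded into Dynamic-II for three-way charts). The
   plateau is the *median* of the filtered segment and must clear \(H\)
   by 2 standard errors of that median: a segment extreme always exceeds
   0.6 on long noisy excursions, which would misread essentially every
   Dynamic-I trace.

The per-trace fraction of time in excursions is the violin-plot statistic;
`summarize_fractions()` adds seeded bootstrap intervals, and
`compare_fractions()` is the classical equal-variance two-tailed t test
(with an epsilon guard so degenerate zero-variance arms behave).

## Dwell times

Excursion durations are wall-clock times between threshold crossings
(bridging dark/red blocks, which would otherwise truncate any excursion
spanning them). Events still open at the trace end are returned as
right-censored; events already open at the first frame are complete draws
by memorylessness. `fit_exponential()` fits a single exponential by
maximum likelihood with three corrections that measurably matter at these
time scales:

- **left truncation** one frame *above* the 2-frame detection floor
  (0.3 s at 0.1 s frames): camera discretization piles true sub-floor
  events onto the floor bin, and truncating exactly at the floor biases
  \(\hat\tau\) ~10% low for \(\tau = 2.5\) s;
- **geometric (frame-aware) MLE** \(\hat\tau = -\Delta / \log(S/(S+n))\):
  frame counts of an exponential are geometric, and the continuous-time
  formula is biased low by about half a frame. The estimator was selected
  on a lattice simulation oracle (exact frame-overlap measurement of
  exponential intervals), where it is unbiased across
  \(\tau \in \{0.63, 2.31, 2.51\}\) s and threshold-crossing coverages
  0.25–0.5; that oracle is frozen into the test suite;
- **censored exposure**: right-censored durations enter the numerator
  (survival treatment). Long dwells are length-biased towards hitting the
  trace end; dropping them clips the tail and costs another ~10%.

The conventional binned least-squares fit of \(A e^{-t/\tau}\) is retained
(`method = "binned_lsq"`) for literal reproduction. Even with these
corrections, recovered decay constants on 60-s traces sit 5–8% below the
generating values (e.g. 2.25–2.37 s for a 2.51 s Dynamic-I dwell): dwells
that *complete* inside a finite observation window are a down-biased
sample, which affects the real experiment identically and is well inside
the reported uncertainties.

## Ensemble histograms and equilibrium binding

Histograms pool the first 10 valid green frames per molecule (the green
ALEX block; only green frames carry FRET) at bin width 0.02. The
figure-level "bin size 0.2" is treated as the coarse display binning of
the dynamic-range heatmap histograms and is available via `bin_size`; a
0.2 bin cannot resolve peaks at 0.30 versus 0.35 and is not used for
fitting. Gaussian mixtures are fitted to the binned density by
least squares with unrestrained centers (`fit_gaussians()`, mirroring how
such histograms are conventionally fitted), peak-based or user-supplied
initial centers, and an optional common-width constraint: for strongly
overlapping peaks of one construct (2R: 0.6 versus 0.8, ~3 noise SDs
apart) an unconstrained broad component swallows its neighbour's weight,
while the shot-noise argument says the widths should match.

`bound_fraction()` sums component weights inside the bound window
(4R: \([0.15, 0.45]\) around the 0.3 peak; 2R: \([0.5, 0.7]\)), and
`estimate_kd_app()` fits the Langmuir isotherm \(f = c/(c + K_D)\) — the
estimator behind the apparent-\(K_D\) figures; the exact published
estimator is not stated, and the half-saturation identity
\(f(K_D) = 1/2\) is recovered exactly on clean input. Titration designs
place concentrations to bracket the expected \(K_D\)
(0.1–50 nM, log-spaced around ~1.4 nM), the standard design for a
half-saturation estimate. Observed binding rates at low concentration come
from `bound_fraction_timecourse()`
(\(f(t) = f_{max}(1 - e^{-k_{obs} t})\)), at high concentration from
per-trace `time_to_first_binding()` (first crossing of the bound/unbound
midpoint that persists ≥ 10 frames — "irreversible" is unquantified in the
source and 1 s is the package's window); `fit_kon()` fits the
concentration series through the origin (no dissociation is observed on
these time scales).

## HMM, transition density plots, and discrete steps

`fit_hmm()` is a stationary Gaussian-emission hidden Markov model fitted
by scaled Baum–Welch (Rcpp; k-means initial means, 5 restarts, variance
floor \(10^{-4}\) flagged on degenerate convergence), with the most-likely
path by Viterbi. The field-standard HaMMy optimiser is deliberately not
re-created; its practice of offering more states than expected is kept in
`select_states()`, which fits \(k = 2..8\) and then collapses. Model
choice among the per-\(k\) fits is by BIC: raw likelihood is monotone in
\(k\) (extra states absorb emission noise into sub-states separated by
more than any reasonable merge tolerance, so merging alone cannot undo
overfitting). After selection, states closer than `merge_tol` = 0.07
(below the smallest reported inter-state gap of 0.15) merge
occupancy-weighted, and states under 2% Viterbi occupancy are discarded
with their frames reassigned — which is also what keeps the ladder's rare
unlooped ~0.2 state out of collapsed models, matching how the experiment
reports four TDP states while acknowledging a fifth unlooped level.

`extract_transitions()` absorbs path segments shorter than 2 frames
(transitions faster than 0.2 s are camera-unresolvable) and emits
(FRET-before, FRET-after, dwell) records; `build_tdp()` bins them on
\([0,1]^2\) (ascending transitions in the upper-left triangle — looping;
raw counts by default, per-transition normalization optional).
`count_tdp_levels()` clusters pooled transition endpoints by 1D
mean-shift with a *uniform* kernel of radius equal to the merge tolerance
(a Gaussian kernel of that bandwidth is already unimodal over levels 0.15
apart and merges them), and ignores clusters holding under 5% of
endpoints: discrete states are read from the dense spots of a TDP, and
sparse stray endpoints are noise.

## Numerical choices and degenerate inputs

Nonlinear fits (Gaussian sums, Langmuir, exponential saturation) use
Levenberg–Marquardt (`minpack.lm`) with bounded parameters; ties in the
baseline mode go to the lower bin; all-background traces report bleach at
frame 0; traces shorter than 50 valid frames return an `unclassified`
sentinel excluded from fractions; `fit_exponential()` refuses fewer than
10 events and flags zero-spread (degenerate) samples; `estimate_kd_app()`
refuses titrations that do not span the transition. Every stochastic
function takes an explicit integer seed and derives child seeds below
\(2^{31}\); identical seeds reproduce byte-identical traces and pipeline
outputs.

## Problem sizes

The package's validation uses ensembles of 300–500 molecules of 600
frames for classification and dwell recovery, 500 molecules per
concentration for titrations, 500-molecule short movies for histogram
peaks, 60 molecules for HMM/TDP level counting, and 200 flow traces for
PIFE kinetics; the test suite exercises the same chains at reduced counts
chosen so each check still meets its stated tolerance.

## Known limitations

- Gamma is fixed at 1 (ratiometric FRET without gamma calibration);
  distances are never computed.
- The HMM assumes state-independent Gaussian noise; strongly
  intensity-dependent (shot-noise-limited) traces would need emission
  variances tied to the level.
- Dwell recovery inherits the finite-window completion bias discussed
  above.
- The dynamic/steady split is threshold-based; classes are reproduced at
  the stated defaults and for amplitude thresholds in \([0.12, 0.18]\),
  but a molecule whose excursions all sit near the threshold is
  intrinsically ambiguous.
- File support covers the TSV dialect and the legacy interleaved 16-bit
  binary; HDF5 layouts are not read or written by this build.

## A small worked example

```{r example, eval = FALSE}
ts <- simulate_preset("POT1_TRF2", 100, seed = 1)
ft <- process_traces(ts)
cls <- classify_traces(ft)
summarize_fractions(cls, seed = 1)
fit <- fit_exponential(extract_dwells(ft, cls), seed = 1)
fit
```
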