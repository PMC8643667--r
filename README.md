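# telodyn

Single-molecule FRET (smFRET) analysis of telomere-overhang dynamics in R.

Human telomeres end in a single-stranded (TTAGGG)ₙ overhang, folded into a
G-quadruplex and bound by the shelterin protein POT1 while TRF2 binds the
adjacent duplex. smFRET time traces of donor/acceptor-labelled telomeric
constructs report these conformations as a per-frame efficiency
E ≈ I_A/(I_A + I_D): a folded G-quadruplex reads E ≈ 0.65, the POT1-bound
overhang E ≈ 0.3, and transient looping of the POT1-bound overhang against
the TRF2-bound duplex produces stepwise excursions through discrete levels
(≈0.35/0.55/0.70/0.85) up to E ≈ 0.9.

`telodyn` is for single-molecule biophysicists who need the full analysis
chain for this class of experiment:

- **Simulation** — continuous-time Markov chain (CTMC) trajectories with a
  camera-level emission model (frame averaging, Gaussian read noise, donor
  leakage, ALEX excitation, single-step photobleaching, flow injection,
  PIFE), with named presets for every construct/condition
  (`simulate_preset()`, `simulate_titration()`, `simulate_flow_trace()`);
- **Trace processing** — ratiometric FRET with leakage correction
  E = (I_A − l·I_D)/(I_A + I_D − l·I_D), donor-only exclusion from the
  red-excitation block, change-point photobleach truncation
  (`process_traces()`, `compute_fret()`, `estimate_leakage()`,
  `flag_donor_only()`, `detect_bleach()`);
- **Ensemble histograms** — normalized FRET histograms, Gaussian mixture
  fits with unrestrained centers, bound fractions, time-resolved and
  event-synchronized heatmaps (`build_histogram()`, `fit_gaussians()`,
  `bound_fraction()`, `build_heatmap()`, `fret_range_heatmap()`);
- **Classification** — steady / Dynamic-I (slow oscillations below ~0.6) /
  Dynamic-II (sharp spikes above ~0.6) with population fractions,
  bootstrap intervals and two-sample t comparisons (`classify_trace()`,
  `summarize_fractions()`, `compare_fractions()`);
- **HMM / TDP** — Gaussian-emission hidden Markov models by Baum–Welch
  (Rcpp), BIC state selection with merging, transition density plots and
  discrete-level counting by mean-shift (`fit_hmm()`, `select_states()`,
  `extract_transitions()`, `build_tdp()`, `count_tdp_levels()`);
- **Kinetics** — dwell-time extraction with a truncation- and
  censoring-corrected exponential MLE, time-to-first-binding, bound-fraction
  time courses, k_on slopes, Langmuir K_D estimation, and PIFE step
  detection (`extract_dwells()`, `fit_exponential()`, `estimate_kd_app()`,
  `pife_binding_rate()`).

The pipeline can be driven end to end from a declarative configuration
(`run_config()`, `run_pipeline()`) writing one structured results file per
stage plus a manifest with hashes, or from the thin CLI in
`inst/cli/telodyn`.

## Worked example

Simulate the POT1+TRF2 condition (a 20/45/35 mixture of steady, Dynamic-I
and Dynamic-II molecules), classify, and fit the dwell kinetics:

```r
library(telodyn)

ts  <- simulate_preset("POT1_TRF2", 100, seed = 1)   # 100 traces, 60 s each
ft  <- process_traces(ts)                            # leakage + background corrected FRET
cls <- classify_traces(ft)
summarize_fractions(cls, seed = 1)
#> class_fractions (n = 100 ):
#>           fraction ci_lo ci_hi
#> steady        0.17  0.10  0.25
#> dynamicI      0.43  0.33  0.53
#> dynamicII     0.40  0.31  0.50
#> dynamic total: 0.830 [0.750, 0.900]

fit_exponential(extract_dwells(ft, cls, class_filter = "dynamicI"), seed = 1)
#> dwell_fit (mle): tau = 2.489 s [2.276, 2.737], n = 424
fit_exponential(extract_dwells(ft, cls,
                               class_filter = c("dynamicII", "dynamicI_II")),
                seed = 1)
#> dwell_fit (mle): tau = 0.667 s [0.612, 0.733], n = 502
```

83% of the molecules are dynamic (the generating mixture held 80%), and the
two dwell-time constants recover the generating Dynamic-I (2.51 s) and
Dynamic-II (0.63 s) kinetics from 60-second movies. `plot()` methods exist
for traces, histograms, Gaussian fits, heatmaps, HMM fits and TDPs; see the
vignette in `vignettes/telomere-overhang-smfret.Rmd` for the models,
parameter defaults and numerical choices.

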