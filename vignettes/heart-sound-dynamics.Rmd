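---
title: "Nonlinear dynamics modelling of phone-collected heart sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear dynamics modelling of phone-collected heart sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiodyn)
```

## The problem and the modelling idea

Valvular heart disease is screened by auscultation, which restricts
detection to audible murmurs, while confirmation requires echocardiography.
`cardiodyn` implements an alternative analysis route: treat a heart-sound
recording (a phonocardiogram, PCG) as the output of a low-dimensional
dynamical system driven by hemodynamic turbulence, extract invariants of
that system — the maximal Lyapunov exponent (MLE), the correlation
dimension (DCorr), sample and Rényi entropy, the Hurst exponent, and
fractal dimensions — alongside classical acoustic features, and map a small
number of *unweighted* feature combinations ("predictors") to
echocardiographic outcomes with a logistic (binary diagnosis) or linear
(indexed aortic valve area, AVAi) model.

The pipeline deliberately concentrates its discriminative power in the
extracted features rather than in the fit: predictors are plain signed sums
of z-scored features chosen by a minimum-entropy search, and the final
regression only orients and calibrates three such sums. Three predictors
are used because reported correlation dimensions for heart-sound dynamics
sit at or below 2.5, which doubles (delay-embedding style) to at most five
effective degrees of freedom; at 10 outcome events per degree of freedom
this also fixes the sample-size arithmetic (50 training events per
condition, 65 subjects per condition, 260 subjects across four groups —
see `effective_df()`, `peduzzi_min_events()`, `enrollment_target()`).

## Pipeline stages

1. **Audio standardization** (`preprocess()`): resampling, optional linear
   detrending, a zero-phase spectral band-pass, and normalization.
2. **Feature extraction** (`nld_features()`, `acoustic_features()`,
   `cohort_features()`): the seven dynamical invariants plus Welch band
   powers, spectral shape statistics and low-quefrency cepstral
   coefficients, per recording, with site/source-suffixed names.
3. **Chaos screen** (`chaos_screen()`): a recording qualifies when
   MLE > 0 and DCorr < 3.
4. **Cohort design** (`cluster_subjects()`, `split_cohort()`,
   `tuning_split()`): k-means clustering on demographics, body
   measurements and dynamics (blind to diagnosis), an 80/20
   cluster-by-diagnosis stratified split with largest-remainder rounding,
   and a tuning set of `ceiling(0.8 * n_train)` subjects. The split
   carries a firewall: every model-building function refuses rows tagged
   with test-set ids.
5. **Quality control** (`ks_screen()`, `nmi_paired()`): two-sample
   Kolmogorov–Smirnov agreement between train and test feature
   distributions, and rank-binned normalized mutual information between
   personnel- and subject-collected recordings.
6. **Modelling** (`build_predictors()`, `fit_logistic()`,
   `fit_linear_avai()`, `choose_threshold()`): simulated-annealing search
   for three signed feature sums minimizing the conditional label entropy,
   a logistic or linear map fitted on the tuning set only, and a Youden-J
   operating threshold.
7. **Evaluation** (`evaluate_model()`, `report_summary()`): confusion
   counts at the frozen threshold, sensitivity/specificity/accuracy with
   exact ratios rounded to three decimals (half away from zero, the
   convention that reproduces printed diagnostic tables), and rank-based
   AUC.

## Estimator choices

The quantities named above do not pin down algorithms; the package uses the
field-standard estimator for each and exposes its tuning knobs:

* **MLE** — Rosenstein nearest-neighbour divergence: embed, find each
  point's nearest neighbour outside a Theiler window, and fit the initial
  slope of the mean log-divergence curve. The fit range is chosen
  automatically from the curve's rise toward saturation; a curve that
  never rises by 0.5 nats is treated as non-expanding and fitted whole,
  which correctly reports near-zero exponents for periodic signals.
* **DCorr** — Grassberger–Procaccia correlation sums under the Chebyshev
  norm with Theiler exclusion. The scaling region is selected
  automatically as the longest radius window with stable local slopes,
  restricted to radii with at least 20 supporting pairs and a correlation
  sum below 0.25 (saturation radii bias the slope down); the chosen radius
  range is attached to the estimate for audit.
* **Embedding parameters** — delay by the first local minimum of
  histogram-based average mutual information, with an independence-floor
  shortcut (shuffled surrogates at a fixed internal seed) so white noise
  selects delay 1; dimension by Kennel false nearest neighbours with both
  ratio and attractor-size criteria.
* **Sample entropy** — Richman–Moorman counts with `m = 2`,
  `r = 0.2 sd(x)`, self-matches excluded.
* **Hurst** — rescaled-range analysis with the Anis–Lloyd finite-sample
  expectation subtracted (so white noise is centred on 0.5); DFA-1 is
  available as an alternative.
* **Fractal dimensions** — Higuchi (`k_max = 16`) and Katz.
* **Power spectrum** — Welch averaging with 1-second Hann segments and 50%
  overlap; band powers integrate the density over octave-ish default edges
  (25, 50, 100, 200, 400, 800 Hz).

All estimators are deterministic given their inputs, and the test suite
verifies them against independent oracles: the logistic map's exact
exponent `ln 2`, a Benettin variational integration for the Lorenz flow,
brute-force correlation sums for the Hénon attractor, synthesized
fractional Gaussian noise for the Hurst exponent, and direct template
counting for sample entropy.

### Filtering

Band-pass filtering is spectral: mirror-padded FFT multiplication by a
response that is exactly 1 across the pass band with raised-cosine
transitions (default 10 Hz). Exact passband unity makes repeated
application idempotent and leaves dynamical invariants free of ripple or
phase distortion; the hard stopband is what a murmur-band analysis needs
when powerline or handling noise sits close to the band edge. The cost is
edge transients confined to the clip boundaries, which is immaterial for
whole-clip features.

### Which series feeds which features

Acoustic features are computed on the full audio band (default 25–900 Hz).
The dynamical invariants are estimated on the low-frequency hemodynamic
band (default 20–200 Hz, resampled to 500 Hz) at embedding dimension 3.
Two observations force this separation. At audio rates the divergence
curve of a PCG saturates within a single step, so the sign of the fitted
exponent is numerical noise; beat-scale dynamics are only resolvable at
beat-scale sampling. And broadband murmur noise dominates fine-scale
correlation sums, driving the dimension estimate toward the embedding
dimension regardless of any low-dimensional structure; the coarse-scale
dimension of the hemodynamic band, probed at `m = 3` (comfortably above
the ≤ 2.5 dimensions reported for heart-sound dynamics), is the quantity
the chaos screen is meant to bound. Both configurations are exposed
(`cohort_features(pre_cfg, nld_cfg, dim)`), so broadband or FNN-selected
analyses remain reachable.

## The predictor search

`conditional_entropy_objective()` discretizes the three predictor columns
into equal-frequency bins (4 per axis by default, 64 joint cells) and
returns the conditional Shannon entropy of the class label given the cell.
Zero means perfect separation; label-independent predictors score near the
marginal label entropy minus a small finite-sample bias. The simulated
annealer (geometric cooling over 2000 iterations, 3 restarts by default)
moves by adding, dropping, replacing or sign-flipping one feature in one
predictor; candidate features are pre-ranked by univariate two-sample KS
separation and the top 20 retained. Ties between states are broken toward
fewer total features, then lexicographically, making the search
deterministic for a fixed seed. On pools of six features the annealer
provably (by exhaustive enumeration in the tests) reaches the global
optimum.

Because equal-frequency binning is rank-based, flipping every sign in one
predictor or monotonically transforming a feature leaves the objective
unchanged; signs matter only once features are *summed* within a
predictor, and orientation is finally resolved by the logistic fit.

## The synthetic cohort

No public heart-sound corpus accompanies the modelling conventions above,
so the package ships a generator that emulates the study population it is
tested against: four groups of 69 (aortic stenosis, AS), 24 (moderate or
severe mitral regurgitation, MR), 73 (other structural heart disease) and
82 (controls); AS severity mixed 20.3/53.6/26.1% mild/moderate/severe.
Age, BMI and BSA are drawn from skew-normal distributions fitted to each
group's quartiles (AS subjects are a decade older than controls, median 77
vs 67 years); sex is Bernoulli with group-specific female prevalence.
AVAi (cm²/m²) is drawn per severity — severe 0.5 (sd 0.08), moderate 0.75
(0.1), mild 1.0 (0.12), non-AS 1.3 (0.2) — values chosen to respect the
clinical severity ordering rather than copied from any table.

Each subject yields three recordings — aortic/personnel,
axillary/personnel and aortic/subject, the last with 20% extra handling
noise — built from jittered RR intervals (72 bpm, 5% jitter), decaying S1
and S2 tone bursts, and a murmur modelled as band-limited noise (150–600
Hz) under a crescendo–decrescendo (AS) or holosystolic (MR) envelope,
scaled by a severity-linked gain (0 / 0.3 / 0.6 / 1.0 for none / mild /
moderate / severe) and attenuated away from the lesion's site. Murmur
noise is drawn even at gain zero so that clips differing only in gain are
otherwise identical at a fixed seed.

What the generator does *not* emulate: real tissue transfer functions,
diastolic murmurs, arrhythmia, respiration, or genuinely chaotic
hemodynamics — its murmurs are stochastic. Passing tests therefore
demonstrate that the pipeline recovers a severity-linked band-power and
regularity signal through the full chain (screen, split, firewalled
search, tuning-set-only fit), not that real recordings are chaotic, and
the chaos screen's behaviour on these synthetic clips characterizes the
estimators' operating regime rather than cardiac physiology.

## Problem sizes and numerical conventions

The shipped tests exercise the full default cohort (248 subjects, 744
recordings) with 6-second clips at 2000 Hz analysed at 1400 Hz, and ten
split/search seeds over a fixed feature table; benchmark estimator checks
use 2000–20000 samples. These sizes were chosen so the whole suite runs on
a laptop-class single core while every stage still operates at study
scale in the subject dimension. Other conventions: series are 0-based
with half-open windows; scores at the decision threshold count positive;
reported ratios are rounded half away from zero to 3 decimals; neighbour
searches cap their point sets by striding (default 2500–3000 embedded
points) and rescale slopes back to per-sample units; a global pipeline
seed fans out to per-stage seeds by hashing stage names, so stages are
reproducible independently.

## Known limitations

* The entropy functional, binning scheme and metaheuristic of the
  software behind the published modelling conventions are proprietary;
  this package fixes transparent, tested choices (conditional label
  entropy over equal-frequency bins; simulated annealing) without any
  claim of numerical equality with that software's feature values.
* The chaos screen on stochastic synthetic signals reflects estimator
  behaviour (coarse-scale dimension at `m = 3`), not evidence of chaos.
* MR modelling is structurally supported but the default cohort's 24 MR
  subjects sit at the edge of the 10-events-per-class requirement for the
  search, mirroring the underpowered condition it emulates.
* Paired-source NMI on the synthetic cohort is well below 1: independent
  noise realizations shared only through subject-level parameters carry
  less common information than two recordings of the same physical heart.
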