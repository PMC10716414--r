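---
title: "Methods: quantifying vocal muscle performance and its behavioural consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying vocal muscle performance and its behavioural consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syrinxlab)
```

`syrinxlab` chains five analyses that together characterize syringeal
(vocal) muscle and its behavioural output: in vitro force metrics, section
morphometry with fibre typing, song acoustics, label-free proteomics, and
operant preference statistics. This vignette documents the models and
procedures, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generators do and do not emulate.

## Muscle physiology

Contraction speed is summarized by the full width at half-maximal force
(FWHM, also written t₅₀₋₅₀) of a single twitch: the time from the first
upward crossing of `baseline + 0.5 * (peak − baseline)` to the first
subsequent downward crossing. Implementation details that matter:

* **Baseline.** The mean force over the 10 ms preceding stimulus onset
  (`baseline_window`, configurable). A pre-stimulus window must exist; when
  it does not, the first five samples stand in.
* **Sub-sample crossings.** Crossing times are linearly interpolated
  between the two bracketing samples, so FWHM precision is much finer than
  the 20–40 kHz sampling grid. On two-exponential transients the estimator
  agrees with a 1 MHz crossing-scan oracle to well within 0.1%.
* **Sessions.** The in vitro protocol collects seven twitches and three
  100 ms tetani per preparation. Because it is unstated whether speed is
  reported per representative twitch or as an average,
  `summarize_twitch_session()` emits both the per-twitch metrics and their
  arithmetic mean.
* **Errors.** A trace whose maximum does not exceed baseline raises
  "no contraction"; a missing half-max crossing on either flank raises
  "incomplete twitch".

Maximal isometric stress (MIS, mN/mm²) is the global maximum of the
baseline-subtracted tetanic force divided by the muscle cross-sectional
area; no plateau fitting is attempted since the plateau of a 100 ms tetanus
is effectively flat. CSA comes from preparation geometry:
`CSA = dry_mass × 5 / (1060 kg·m⁻³ × L0)` with dry mass in mg and L₀ in mm,
yielding mm². Units are SI internally and reported as mN, ms, mm², mN/mm².

## Fibre morphometry

Muscle fibres appear as dark interiors enclosed by bright laminin-stained
borders. `segment_fibres()` runs, in order: optional rescale (the full-section
workflow rescales ~20,000×30,000 px montages to 10,000 px height; synthetic
desk-scale images skip this), CLAHE contrast equalization (8×8 tiles),
masking, a global Otsu threshold **reduced by 15%** (`threshold_reduction`,
sensible range 0.10–0.20 — the reduction captures faint borders), removal of
components and holes below 30 px, diamond closing (radius 1), a Euclidean
distance transform, and a watershed with H-minima suppression depth 2
(`EBImage::watershed`'s `tolerance` is exactly this depth on the distance
map). Regions touching the image border or the mask boundary are discarded:
an unbounded dark field is not a laminin-enclosed fibre. Ties in the
distance map are resolved deterministically by the watershed's scan order,
so segmentation is exactly reproducible.

Per-label features are measured in µm via `microns_per_pixel`: area,
perimeter, eccentricity and ellipse axes from image moments, solidity
(pixel count over the convex-hull area of the pixel squares), and
circularity `4πA/P²`. Feature constraints remove false detections; the
defaults — area in [50, 2500] µm², solidity ≥ 0.80, circularity ≥ 0.30 —
are package choices (the originating workflow used constraints without
publishing values) and are configurable and logged.

Fibre typing is a strict threshold on mean MY-32 (anti-fast-MyHC) staining
intensity: **fast if > 50, superfast if ≤ 50** on an 8-bit scale; other bit
depths are rescaled to 0–255 first so the cutoff keeps its meaning. The
hemisyrinx summary reports counts, medians, the superfast fraction,
fixed-bin-width probability density estimates (50 µm² and 5 intensity units
by default; density × bin width sums to 1, correcting for different fibre
counts between sections), and total muscle CSA as the area of the union of
all fibres after diamond dilation of radius 10 px, which fills the
inter-fibre space the watershed leaves out.

## Song acoustics

Recordings are calibrated to pascal with a 1 Pa / 1 kHz tone and bandpass
filtered once with a 2nd-order Butterworth, 200–12,000 Hz, applied
forward-backward (zero phase: an impulse's peak does not move). Features
are computed per 4 ms window advanced in 0.5 ms steps:

* **Power and source level.** Mean squared pressure;
  `SL = 10·log₁₀(power / (20 µPa)²)` dB re 20 µPa (at 1 m via the
  calibration chain). A 1 Pa RMS tone reads 94.0 dB. Silent frames carry
  `-Inf` and a missing f₀.
* **Wiener entropy.** `10·log₁₀` of the ratio of geometric to arithmetic
  mean of the 512-point Hann-windowed power spectrum, floored at 1e-12
  after normalization, and restricted to the passband bins: since the
  mandatory bandpass empties out-of-band bins, including them would drive
  the geometric mean to the floor for any signal; within the passband the
  estimator keeps its meaning (≈0 dB for white noise, strongly negative
  for tones).
* **Yin f₀.** Difference function over an integration window equal to the
  maximum lag, cumulative-mean-normalized difference, absolute threshold
  0.15, then parabolic interpolation; search range 300–8000 Hz by default,
  with the analysis segment extended beyond the 4 ms bin as the maximum lag
  requires. **Aperiodicity** — not formally defined in the source
  literature — is taken as the normalized-difference minimum at the chosen
  lag (0 = perfectly periodic), which is the quantity Yin itself thresholds.
* **Motif detection.** Normalized (mean-removed) cross-correlation between
  the template's RMS envelope and the recording's, peaks above 0.5 with
  one-template-length suppression; candidates are then shifted to the lag
  (±10 ms) maximizing the correlation of their source-level trace with the
  strongest detection, and optionally filtered to the modal syntax key
  (syllable count plus durations quantized to 20 ms).
* **Syllable segmentation.** A fixed per-individual source-level threshold
  (a required setting; it has no universal default) binarizes frames; sound
  runs shorter than 30 ms are removed **first**, then interior silence runs
  shorter than 40 ms are merged (the order is a documented package choice;
  both rules are exposed). The rule applier is idempotent and matches a
  brute-force scanner on random envelopes. Motif duration is the sum of
  syllable and gap durations, exactly.
* **f₀ statistics.** Within a syllable the trace splits at adjacent-frame
  jumps over 100 Hz, segments shorter than 5 ms are dropped, and a syllable
  whose surviving frames cover less than 50% of its frames (the robustness
  criterion is unquantified in the source literature; 50% is this package's
  flagged default) is marked non-robust and excluded from f₀ statistics.
  Note that the ~4 ms analysis window averages fast frequency sweeps, so
  the min/max of a steep chirp pull inward by roughly the sweep rate times
  half the window; means are essentially unbiased.
* **Pre/post comparison.** Per-syllable unpaired two-sided t-tests on mean
  f₀, f₀ range and mean Wiener entropy, categorized increase / decrease /
  ns at α = 0.05 (calibrated: same-distribution data flags ~5%); per-animal
  paired two-sided t-tests on mean motif duration and motif source level,
  the latter an energy-weighted mean of frame levels (the source literature
  does not say mean or max; energy mean is the package default). The post
  condition should be restricted to the 0–2 h window after release from
  singing prevention, before song-system error correction kicks in.

## Proteomics

One sample at a time, `quantify_and_normalize()` performs: exact-match
exclusion of the five red-blood-cell contaminant accessions (nucleated
avian erythrocytes contaminate unperfused samples); pooling of peptides
flagged as shared across the fast/developmental MyHC gene cluster into a
single `MYH-fast` pseudo-protein (MYH13 stays separate — the flag is an
input column because peptide-to-genome mapping is out of scope);
de-duplication keeping the largest area per (protein, peptide); top-3
quantification (sum of the three largest peptide areas, or all areas when
fewer); then both normalizations computed after exclusion — to the total
peak sum (Histone H4 included in the denominator by default, configurable)
and to Histone H4 itself.

`differential_abundance()` takes paired intact/treated profiles. The
phrase "paired Welch's t-test" is internally inconsistent (Welch's test is
the unpaired unequal-variance form), so the default is a paired two-sided
t-test on per-pair log₂ differences, with `method = "welch"` available.
The default abundance measure is `rel_h4`: under broad down-regulation the
total-sum measure is compositional and distorts per-protein fold changes,
whereas the housekeeping anchor preserves them. Raw p-values are reported
(matching the source convention); Benjamini-Hochberg sits behind
`bh = TRUE`. Fold changes are geometric means of per-pair ratios and are
exact on noiseless data.

## Preference analysis

Stimulus motifs are matched within 4 ms of the condition's mean duration
and 2 dB of its mean source level ("1–2 dB" in the source is resolved as a
single configurable window, default 2 dB), widening to 30 ms / 6 dB when
either eligible set is empty; one motif per condition is drawn uniformly
under a seed. Stimulus bouts are assembled by `splice_motif()` with 5 ms
raised-cosine cross-fades (the fade length is a package invention).

Keypecks over a 4-day test are mapped to stimuli through the
nightly-switching key assignment (events are assigned by test-day date) and
pooled — per-day homogeneity is not tested first, matching the pooled
"sum over 4 days" preference definition. The pooled counts are tested
against 50% with the G-test and Williams' correction in the standard
k-cell goodness-of-fit form, `q = 1 + (k² − 1)/(6n(k − 1))`, i.e.
`1 + 1/(2n)` for two cells; the corrected statistic is referred to χ²₁.
The correction always shrinks a positive G and vanishes as n grows.

## Synthetic data: what it emulates, and what it does not

Generator defaults are anchored to the study conditions: twitches tuned to
FWHM 4.89 ms (tuning is a closed-form rescale of the two-exponential shape,
so the truth is exact); sessions of 7 twitches + 3 × 100 ms tetani;
sections with a 66% superfast fraction, superfast areas 200–1000 µm² and
fast areas 100–400 µm²; MY-32 intensities N(20, 8²) vs N(120, 30²) clipped
to [0, 255] — invented (only the cutoff and area ranges are published) but
chosen to straddle the cutoff with realistic overlap; harmonic stacks of
6–10 partials with 1/k rolloff on the 0.5 ms grid; a proteome whose myosin
pool is 92% MYH13; Bernoulli keypecks at p = 0.66 over 4 days with nightly
switches. Every generator takes a seed, restores the caller's RNG state,
and returns its ground truth alongside the data; identical seeds give
identical outputs.

The generators reproduce the statistical and geometric structure the
pipeline consumes — not photorealistic histology (no uneven staining,
tears, vessels or out-of-focus regions beyond a smooth illumination gain
and Gaussian pixel noise) and not naturalistic birdsong timbre (no
frequency jitter, amplitude modulation or reverberation). Passing the
recovery tests therefore demonstrates correctness of the algorithms under
known truth, not segmentation or pitch-tracking robustness on degraded
real-world recordings; the configurable preprocessing (CLAHE tiles,
threshold reduction, H-minima depth, Yin threshold) exists precisely for
that tuning on real data.

Tessellation uses a jittered grid with one fibre per cell, sized so fibres
never touch; star-convex blobs are area-renormalized in polar form and
targets are drawn 8% inside the range edges so pixelation keeps every
truth area in range. Real sections pack fibres against each other; the
watershed's neck-splitting is exercised by the closing/dilation chain but
touching-fibre recovery rates on real tissue will be lower than the
near-perfect IoU on synthetic sections.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale: 100 random
twitches against the 1 MHz oracle, one 200-fibre and ten 300-fibre
sections (~700×700 px at 1 µm/px), 20 harmonic stacks, 500 random
envelopes for the segmentation-rule equivalence, 400–1000 simulated
syllables for the type-I calibration, and 50 seeds of 3-pair proteome
recovery. These sizes make every check rerunnable in seconds to a couple
of minutes on one CPU while keeping the statistical assertions
well-powered; all are parameters, not limits.

## Known limitations

* The watershed pipeline assumes closed laminin borders; broken borders
  merge fibres and only the feature constraints catch the result.
* Yin's windowing biases f₀ extremes on steep sweeps (documented above);
  syllable-mean f₀ is the robust quantity.
* Motif source-level alignment assumes the template and its instances
  share tempo; time-warped renditions are only coarsely aligned.
* The proteomics stage trusts its input flags (`myh_fast_cluster`) and
  performs no peptide-level inference; PSM-level FDR and modification
  handling belong to the upstream search engine.
* `rel_total` is compositional; cross-condition comparisons should use
  `rel_h4` unless total abundance is itself the quantity of interest.
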