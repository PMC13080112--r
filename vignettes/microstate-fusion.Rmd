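---
title: "Multi-paradigm EEG microstate analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-paradigm EEG microstate analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mstatefusion` implements a complete EEG microstate analysis across two
recording paradigms — eyes-closed resting state and a trial-averaged
cognitive task — and fuses the resulting features for two-group
classification (healthy controls, HC, versus mild cognitive impairment,
MCI, with MCI as the positive class). Because clinical EEG of this kind
is rarely shareable, the package also contains a synthetic cohort
generator with known microstate ground truth, so that every stage of the
pipeline is testable end to end. This vignette documents the models, the
parameters that matter, and the design decisions taken where several
defensible options existed.

## The microstate model

EEG microstates treat the multichannel scalp potential
$u(t) \in \mathbb{R}^n$ (here $n = 62$ electrodes) as visiting a small
set of quasi-stable topographies. The analysis has four stages.

**Global field power.** At each sample,
$\mathrm{GFP}(t) = \sqrt{\tfrac1n \sum_j (u_j(t) - \bar u(t))^2}$, the
population standard deviation across electrodes. Topographies are most
stable at strict local maxima of GFP, so only peak-time maps enter
clustering. Peaks are strict interior maxima; plateaus are not peaks,
and a constant GFP series yields an empty peak set with a warning.

**Polarity-invariant modified k-means.** Peak maps are assigned to the
template with the highest absolute spatial (Pearson) correlation —
polarity is ignored, because the dipolar generators of a microstate
reverse sign within an oscillation. The template update is the dominant
eigenvector of the assigned maps' outer-product sum; maps enter the
update with their amplitude, which weights them by squared GFP and
keeps noise-dominated low-amplitude peaks from dragging the templates.
The number of classes is fixed at $k = 4$ (the canonical A-D model),
with 20 random restarts; the restart with the highest global explained
variance (GEV) wins, ties going to the earlier restart. Convergence is
declared when assignments stabilize or GEV changes by less than 1e-6,
with a cap of 100 iterations. Emptied clusters are re-seeded from the
worst-fit map. Fitted templates receive their A-D labels by globally
optimal bijective matching (all 24 permutations) against built-in
prototype maps: A with a left-anterior/right-posterior polarity axis, B
its mirror image, C anterior-posterior, D a fronto-central peak against
an occipito-temporal surround.

**Backfitting.** Every sample of the preprocessed data is labelled with
the template of highest absolute correlation. No temporal smoothing or
minimum-duration rule is applied: abnormally brief states are possible
pathology and must survive into the features. Zero-variance samples
(which cannot be correlated with anything) inherit the previous label,
class A at the first sample, and are flagged.

**GEV.** $\mathrm{GEV} = \sum_p \mathrm{GFP}_p^2 r_p^2 / \sum_p
\mathrm{GFP}_p^2$, where $r_p$ is the correlation between peak map $p$
and its assigned template. GEV is computed at GFP peaks (an all-samples
variant exists through `model_gev()` on arbitrary maps but is not the
default), and segment-level GEV is evaluated against each segment's own
peaks.

## The 26 features

From the merged label sequence (consecutive identical labels collapsed,
e.g. "AAAAABBBAAB" to "ABAB") the package computes, per segment and
paradigm: mean duration (MD, ms), coverage (COV, fraction), and
occurrence (OC, 1/s) for each of the four classes; the 12 ordered
distinct-pair transition probabilities (TP); the segment GEV; and the
Lempel-Ziv complexity (LZC) of the merged sequence — 26 features, named
`rA-MD`, `tC→D`, `r-GEV`, and so on, with `r`/`t` marking the paradigm.
An ASCII dialect (`rA.B`) is available for tools that reject non-ASCII
headers.

Two conventions deserve note. The TP denominator is the number of
transitions *leaving* a state, so observed rows sum to one exactly; a
state that only ends the sequence has an undefined (missing) row rather
than a fabricated zero. LZC uses exhaustive-history parsing: scanning
left to right, the counter increments whenever the current word extended
by the next symbol has not occurred earlier; the trailing, possibly
reproducible, word counts as a component. The raw count is reported (a
normalized variant is available but non-default). Absent states
propagate missing values, which are imputed with training-fold medians
only at the modeling boundary — imputing zeros would fabricate exactly
the short-duration signature the pipeline is supposed to detect.

These definitions satisfy exact conservation identities used as tests:
coverages sum to 1, observed TP rows sum to 1, and
$\mathrm{OC}_k \cdot \mathrm{MD}_k / 1000 = \mathrm{COV}_k$ on the same
merged runs.

## Preprocessing and augmentation

Order: zero-phase band-pass, resample, common average reference,
epoching, amplitude rejection. The 2-20 Hz band keeps theta/alpha while
excluding drift and EMG-dominated bands; the filter is a Butterworth of
total order 4 (order 2 per band edge) run forward and backward, which
doubles attenuation and cancels phase — topography timing must not
shift. Filter design comes from `signal::butter`; the forward-backward
pass runs through a compiled kernel with odd-reflection edge padding.
Amplitude rejection drops an epoch when its absolute maximum over all
channels *strictly* exceeds 100 µV — the stricter global reading of the
per-epoch rule, applied after CAR.

Augmentation produces ten analysis segments per subject and paradigm:
ten contiguous non-overlapping 20-s epochs from the start of the 200-s
resting recording, and ten random balanced blocks of trial-averaged
correct-incongruent task epochs (0-1000 ms, baseline-corrected against
-200-0 ms). Every segment carries its source subject identifier; the
cross-validation below never separates a subject's segments.

## Screening, ranking and classification

Per paradigm, each feature is screened for a group difference:
Shapiro-Wilk on both groups and Levene's test (mean-centred) decide
between the pooled-variance t-test and the Mann-Whitney U test; p-values
are Benjamini-Hochberg adjusted within the paradigm's feature family and
retained at FDR < 0.05. The statistical unit is the subject (segment
means), because a subject's ten augmented segments are not independent;
segment-level testing is available but not default. Screening runs
inside each training fold by default; `paper_mode = TRUE` reproduces
full-data screening, which is simpler but optimistically biased.

Retained features are ranked by mRMR in the difference form: greedily
maximize $I(x; C) - \tfrac{1}{|S|}\sum_{s \in S} I(x; s)$, with plug-in
mutual information on three z-score bins (cut at ±0.5 SD, learned on
training data). Ties break by feature name for determinism.

Classification uses a support vector machine inside stratified
subject-grouped 5-fold cross-validation repeated 5 times. For each
feature count $F = 1..10$ the top-$F$ mRMR prefix is evaluated with the
full protocol. Hyperparameters (linear or RBF kernel,
$C \in \{0.01, 0.1, 1, 10, 100\}$,
$\gamma \in \{0.001, 0.01, 0.1, 1, 10\}$ for RBF) are optimized once
per training fold by an inner subject-grouped 5-fold grid search on the
OFS-cardinality mRMR prefix, and the winning configuration is reused
along that fold's F curve — tuning is fold-local (leakage-free) without
re-searching a 30-cell grid at every curve point, whose selections are
in practice identical across neighbouring F. The optimal feature subset
(OFS) is the best prefix with $F \le 5$, ties to the smaller $F$.
Metrics are segment-level accuracy, sensitivity (recall of MCI) and
specificity (recall of HC), reported as mean ± SD over the 25
fold-repeats, with subject-level majority-vote accuracy alongside.
Fusion concatenates the per-paradigm screened features by (subject,
segment); the MoCA covariate, when included, joins the candidate pool
directly (replicated across a subject's segments) and competes in mRMR
like any other feature. Inner-loop predictions are computed directly
from the fitted support vectors (equality with `predict()` is asserted
in the test suite).

The named OFS reported for presentation is re-derived on the full data
set after performance estimation, mirroring how a single feature list
is usually quoted; the quoted metrics always come from the
cross-validated runs, never from that full-data selection.

## The synthetic cohort

`make_cohort()` / `run_pipeline()` generate 31 HC and 32 MCI subjects.
Microstate dynamics are semi-Markov: run lengths are gamma distributed
(shape 2, scale mean/shape, rounded to at least one sample) and
successors follow a distinct-state transition matrix, so duration,
coverage, occurrence and TP all have known targets; empirical coverage
converges to the stationary occupancy $\pi_s d_s / \sum_j \pi_j d_j$ of
the embedded chain. Sequences start in the embedded chain's stationary
distribution.

Rendering places the active template under a 10 Hz sinusoidal carrier
(phase offset 0.3 rad so no sample is exactly zero) plus white Gaussian
noise at SNR 5 (signal RMS over noise RMS), then applies CAR. The
carrier's rectified magnitude is the positive amplitude envelope of the
topography; its polarity alternation is invisible to the
polarity-invariant analysis. The carrier must live *inside* the 2-20 Hz
analysis band: a strictly positive envelope concentrates topographic
power at DC, and the band filter's 2 Hz high-pass edge then smears each
state's map over its neighbours for 100-200 ms, capping template
recovery around |r| = 0.87-0.92. With the in-band carrier, pooled
clustering at SNR 5 recovers all four templates at |r| > 0.99.

Default mean dwell times are at the canonical source scale — rest:
57.6/64/68/76.4 ms (HC) versus 69.2/64/68/65.6 ms (MCI) for A-D; task:
42.8/56/85.8/60 versus 55.6/40/60/40 ms — with transition preferences
that lower the MCI stationary occupancy of D at rest and raise A (and
lower C) in the task. These reproduce the qualitative group contrasts
reported for MCI (longer resting A runs; reduced resting D duration,
coverage and occurrence; in the task, longer and more prevalent A,
shorter and less prevalent C). The contrasts are directions and ratios,
not absolute values: observed MDs after unsmoothed backfitting are much
shorter than source dwell times, because label noise fragments runs —
which is also why the generator's durations are not set to
backfit-scale values. MoCA is sampled per group at 25.48 ± 1.48 (HC)
versus 19.16 ± 1.48 (MCI), rounded and clamped to 0-30.

The task paradigm emulates a trial-locked evoked response: one 1-s
evoked label sequence per subject, repeated across that subject's 150
correct-incongruent trials (1.2 s each including a 200 ms noise-only
baseline), with independent noise per trial — so block averaging raises
SNR exactly as trial averaging is meant to. Between-subject variability
in task features is therefore dominated by the single evoked-sequence
draw, which is realistic for short ERP windows but makes task screening
power at small cohort sizes low.

What the generator does *not* emulate: ocular/muscle artifacts, 1/f
background spectra, volume-conduction forward modeling, bad channels,
or inter-electrode noise correlation. Passing tests therefore
demonstrate the correctness and internal consistency of the algorithms
under band-limited, artifact-free conditions with a known four-class
structure — not robustness to real-world artifacts, nor the paper-level
accuracy of any clinical data set. Stages whose real-data counterparts
handle artifacts (ASR, ICA, bad-channel interpolation) are represented
by a no-op hook, since they are established external algorithms and the
synthetic data contain nothing for them to remove.

## Numerical choices and degenerate inputs

* Clustering templates are sign-fixed (largest-magnitude element
  positive) for bit-reproducibility; assignments break correlation ties
  toward the lowest class index.
* Pooled clustering uses up to 1000 GFP-peak maps per subject
  (uniformly subsampled); a 20-s epoch supplies roughly 400 peaks, so
  the cap keeps the pooled problem near 63k maps without biasing any
  subject's contribution.
* Clustering is performed once on peak maps pooled across *all*
  subjects, not per group: group-specific templates would inject the
  diagnosis into feature extraction. The clustering is unsupervised and
  never sees labels, so fold-wise refitting is unnecessary for leakage
  safety; per-group clustering remains available as a reporting mode by
  running the cohort's groups separately.
* Every stochastic stage draws a named seed from the run seed; the
  registry is stored in the report and its artifacts, and a rerun with
  the same configuration is bit-identical.
* Degenerate cases signal explicitly: no surviving epochs, no qualifying
  trials, empty peak sets, zero retained features, and constant feature
  columns all produce warnings, messages, or errors naming the problem
  rather than silent empties.
* Reference problem sizes: the default cohort (63 subjects, 200 s rest,
  150 task trials), 600-s sequences for parameter-recovery checks, and
  the exhaustive LZC validation over all 4-symbol sequences up to
  length 10.

## Known limitations

Sensitivity hinges on which class is "positive"; MCI-positive is the
convention here and is configurable. The per-paradigm FDR family is a
choice (a pooled family across paradigms is one flag away). The paper
screened on the full data set; the default here is fold-wise screening,
so headline numbers from `paper_mode = TRUE` runs are slightly
optimistic by construction. Accuracy estimates on the synthetic cohort
depend on the planted effect sizes and are not comparable to clinical
results; only their ordering (fusion at or above the best single
paradigm; adding a strong covariate at or above fusion) is a stable
property.
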