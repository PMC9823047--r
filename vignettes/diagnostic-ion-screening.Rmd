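---
title: "Diagnostic fragment ion screening of phthalate metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic fragment ion screening of phthalate metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phthalscreen)
```

## The screening model

Phthalate monoesters (monophthalates) are the urinary biomarkers of phthalate
exposure. In negative electrospray they are observed as deprotonated anions
[M−H]⁻, and the monophthalate skeleton — an aromatic ring carrying one free
carboxylate and one ester — fragments into a small set of *diagnostic ions*
that is nearly independent of the side chain:

* m/z 121.0295 (C₇H₅O₂⁻), 147.0088 (C₈H₃O₃⁻), and 165.0193 (C₈H₅O₄⁻) — the
  native trio. Candidacy requires at least **two of these three** ions in a
  feature's MS/MS spectrum; features with one or none are false positives.
* m/z 134.0377 — a supplementary ion specific to pure-alkyl-chain
  monophthalates. It flags the subclass but never counts toward the
  two-of-three rule.
* m/z 124.0397, 151.0223, 169.0329 — the corresponding trio of the
  ring-¹³C₄-labelled internal standards used for QC. These constants are
  stored as published rather than derived from a labelling model: the printed
  values sit ≈0.0001 above a uniform ¹³C₃/¹³C₄ substitution of the native
  trio and the labelling positions are not public.

All m/z arithmetic uses monoisotopic atomic masses to ≥ 8 decimals
(¹²C = 12 exactly, ¹H = 1.00782503207, ¹⁶O = 15.99491461956,
¹³C = 13.00335483507) and includes the electron mass (0.00054857990) in the
anion m/z; this is required to reproduce 4-decimal diagnostic masses from
first principles.

The workflow screens two acquisition designs of the same sample:

* **DIA** — full-scan runs at fixed in-source collision energies (0, 20,
  40 V; scan range 150–1000 m/z at CE 0, 50–500 in the fragment channels).
  EICs of the diagnostic ions in the fragment channels are peak-picked and
  aligned across channels; each consensus retention time nominates precursor
  ions from the nearest CE = 0 full scan. Because in-source fragmentation is
  precursor-blind, candidacy is only decided after a targeted MS/MS re-run of
  the nominated ions (driven by the exported inclusion list).
* **DDA** — TopN-5 ddMS2 (2×10⁵-count trigger, 1.5 m/z isolation, 3.0 s
  dynamic exclusion, NCE 15/35/50, MS1 150–800 m/z). Every MS2 scan is
  matched against the trio directly, so the two-of-three rule applies
  immediately.

Nominated ions pass three filters, each recorded with a machine-readable
reason so that filter counts reconcile: an intensity threshold of 5×10⁵
counts on the full-scan centroid (five times the typical S/N of spiked
samples), elemental-composition restrictions (below), and the procedural
blank rule (a feature must be at least 3× its mean intensity across blank
replicates; blank-absent features are kept; the boundary is inclusive and
`max` aggregation is available as a stricter option).

## Formula enumeration under elemental restrictions

Candidate compositions are enumerated exhaustively over the CHO grid with
the monophthalate restrictions: C 8–30, H 6–60 (applied to the ion's
hydrogen count), O 4–10, no other elements, charge −1, RDBE 6–12, mass
tolerance 5 ppm (closed window). Two conventions required a decision:

* **Even-electron rule.** For CHO-only anions the only consistent reading of
  an even-electron requirement is that the ion is the deprotonation product
  of an even-electron neutral, i.e. the ion hydrogen count is odd.
* **RDBE on the reconstructed neutral.** RDBE is evaluated on M (ion + 1 H),
  so monoethyl phthalate scores exactly 6 — the phthalate skeleton's ring
  (4) plus two carbonyls — matching the stated lower bound. Evaluating it on
  the ion instead would shift every value by 0.5 and misclassify the whole
  class.

Results are ranked by absolute ppm error; ties break toward fewer oxygens,
then lexicographic (C, H) — an invented but deterministic convention, since
ties have no published precedent. A `min_spectral_fit` threshold of 10 is
carried in the constraint object for completeness but never evaluated: it is
an isotope-fit score of proprietary vendor software whose algorithm is not
public, and isotope-pattern scoring is outside this package's scope.

## Peak detection and cross-channel alignment

No vendor peak picker is available, so detection is deliberately simple and
deterministic: 3-point moving-average smoothing, local maxima extended to
valley bounds, noise estimated as the sigma-scaled median absolute deviation
of the trace outside detected peaks (floor 1 count), S/N = raw apex / noise
with the S/N ≥ 3 acceptance threshold. This is parameter-light and
scale-free (peak counts are invariant under uniform intensity scaling), at
the price of not deconvolving shoulders — two analytes closer than roughly
four peak sigmas merge into one apex (see *Limitations*).

Cross-channel alignment is single-linkage chaining of apex RTs with a 0.1
min tolerance (invented; the emulated workflow aligns channels visually),
with the consensus RT taken as the intensity-weighted mean. Whether the DIA
stage should already demand co-elution of ≥ 2 diagnostic-ion EICs before
formula generation is ambiguous in the emulated workflow; it is exposed as
`dia_min_coeluting_ions` (default 1, i.e. every co-elution group nominates).

## Annotation and confidence levels

Confirmed candidates are annotated on a three-level confidence ladder:

* **Level 1** — accurate mass (5 ppm) *and* retention time (|ΔRT| ≤ 0.1 min,
  an invented tolerance; the level-2 value below is the published one) match
  to a reference standard, with ≥ 2 diagnostic ions.
* **Level 2** — probable structure: exactly one suspect-list structure whose
  *predicted* RT lies within 0.2 min of the observation.
* **Level 3** — tentative candidate: formula plus diagnostic evidence,
  isomer unresolved. Two or more isomers inside the prediction window are
  reported as ambiguous and stay level 3 rather than being tie-broken.

The multi-descriptor RT regression used with real data is not public, so
`make_rt_predictor()` fits a documented surrogate: a linear model of
standard RTs on a single logP-like hydrophobicity proxy,
`(C − 8) − 1.2 · (O − 4)` of the neutral formula (side-chain carbons
increase retention; polar oxygens beyond the ester core decrease it).
Structures present in the training standards return their library RT
exactly; `predict_rt()` also accepts a named vector of externally supplied
predictions so a full descriptor model can be plugged in. The shipped
standards library (24 native + 14 labelled entries) and 75-entry suspect
mass list are **synthetic reconstructions** — flagged as such in their file
names — of common monophthalates and oxidized metabolites; they are
fixtures, not measured reference data.

## Differential analysis

Group comparison uses the fold change of raw-intensity replicate means and a
two-sided t-test on log₁₀ intensities, with labels `up`/`down` for fold
> 2 (or < 1/2) at p < 0.05 and no multiple-testing correction by default
(Benjamini–Hochberg behind a flag), matching the emulated reporting style.
The test pools the group variances. This was a genuinely open choice: with
n = 3 per group the Welch–Satterthwaite approximation is measurably
conservative (empirical size ≈ 0.03 at nominal 0.05 on null log-normal
data), while the pooled test is exact under the equal-variance log-normal
replicate model — the right model for replicate injections of the same
pooled extract. `var_equal = FALSE` restores Welch for unequal-variance
designs. Features present in only one group report an infinite (or zero)
fold and are labelled only when the present group's minimum replicate
exceeds the detection floor; no p-value is fabricated from absent data.
Whether published fold changes are ratios of means or single pooled
measurements is not stated; ratios of replicate means are used.

## The synthetic acquisition generator

The simulator exists so that every stage is verifiable against ground truth
without access to raw instrument files. It emulates:

* Gaussian elution profiles (σ = 0.05 min by default) sampled on a 2 s scan
  grid over a 16 min run;
* CE-dependent in-source fragmentation: a fraction CE/40 (saturating at
  40 V) of each analyte's ion current is redistributed over its
  fragmentation template, conserving total ion current per scan exactly
  before noise — an invented, configurable response model, since no
  fragmentation-efficiency model is published;
* TopN ddMS2 scheduling with the intensity trigger, isolation-window
  co-isolation, and dynamic exclusion, with a per-selection event log for
  auditing; centroids closer than the mass accuracy are merged before
  precursor selection, as a real centroided spectrum would show them;
* isotope-labelled standards (precursor shifted by n·(¹³C−¹²C); fragment
  channels moved to the labelled trio constants), single-diagnostic-ion
  decoy interferents, non-fragmenting matrix interferents, a sparse uniform
  noise floor, and per-analyte carryover into procedural blanks.

The default panel holds 10 real monophthalates (monoethyl phthalate at its
6.78 min standard RT), 5 decoys whose masses pass the elemental
restrictions — so they are only rejected by the two-of-three rule, the
property the decoys exist to test — and 14 ring-¹³C₄ labelled standards.
Apexes (8×10⁵–5×10⁷ counts) sit above both modes' thresholds so that the
DDA/DIA recovery comparison is meaningful; replicate variation is log-normal
at CV 5%; planted group effects are one 25-fold and three 2.5-fold
increases; blank carryover is 5% (safely below the 1/3 that the blank rule
tolerates). Native-trio emitters are spaced ≥ 0.3 min apart because the
detector does not deconvolve shoulders. The study fixture (three replicates
per group, three blanks, a spiked QC sample, a DIA channel set, and truth
tables) is fully determined by the seed (default 20221108). The targeted
MS/MS follow-up of DIA prioritization is generated on demand from the QC
sample's configuration with the inclusion list produced by the screen, since
it is an output of the analysis, not an input.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: chromatographic tailing and drift, ion
suppression, isotope envelopes beyond the monoisotopic peak, profile-mode
peak shapes, mass-accuracy drift, and chimeric MS2 beyond simple
co-isolation within the window. Recovery rates on this simulator are upper
bounds on real-data performance.

## Problem sizes and numerical conventions

Default test and validation runs use the 16-min/2-s grid (481 full scans per
run, ~29 panel species, ten DDA runs plus three DIA channels per fixture)
and 2,000-feature matrices for test calibration — sizes chosen so the whole
suite exercises every stage end-to-end in seconds on a laptop. ppm windows
are closed intervals; multiple centroids in one window sum; RT is minutes
end-to-end (mzML seconds are converted on read); percent values round
half-up (one decimal for labelled-standard rates, integer for feature-level
rates, the two published styles). DIA channels are separate mzML files (one
per CE); the channel CE travels in the `_ce<NN>` file-name suffix because
plain mzML has no standard slot for a run-level in-source CE on MS1 scans.

## Known limitations

* Co-eluting analytes closer than ~4σ in RT merge into one EIC apex; the
  smaller one is invisible to the DIA screen (DDA, being precursor-specific,
  still resolves them — the same asymmetry reported for real acquisitions).
* Mass-list screening is accurate-mass only; `mzVault`-style spectral
  matching and fragmentation prediction are out of scope, so "database hit"
  here means suspect-mass-list hit.
* The RT surrogate is a one-descriptor linear proxy; its predictions are
  only as good as the hydrophobicity ordering of the training standards.
  Plug in external predictions for anything quantitative.
* The blank rule compares against the mean (or max) of blank replicates
  only; no drift or carryover modelling between injections.
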