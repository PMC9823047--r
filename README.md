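# phthalscreen

Non-targeted analysis (NTA) of phthalate metabolites in negative-mode
LC-HRMS data. Human exposure to phthalate plasticizers is monitored through
the urinary monoester metabolites (monophthalates); discovering *which*
metabolites are present — including oxidized forms absent from spectral
libraries — requires screening acquisitions without a fixed analyte list.
`phthalscreen` implements a diagnostic-fragment-ion screen for this class
and the scaffolding to validate it: readers and writers for centroided mzML,
EIC peak detection, precursor prioritization for both DIA and DDA
acquisitions, constrained molecular-formula enumeration, QC statistics,
confidence-level annotation, group differential analysis, and a
deterministic acquisition simulator that provides ground truth for all of
it.

## The method in brief

Monophthalates fragment into a side-chain-independent set of diagnostic
ions:

| ion | composition | m/z |
|-----|-------------|-----|
| native trio | C₇H₅O₂⁻ / C₈H₃O₃⁻ / C₈H₅O₄⁻ | 121.0295 / 147.0088 / 165.0193 |
| supplementary (pure alkyl chains) | — | 134.0377 |
| labelled trio (¹³C-labelled standards) | — | 124.0397 / 151.0223 / 169.0329 |

A feature is a **candidate** phthalate metabolite only if its MS/MS spectrum
contains at least two of the native trio; features with one or none are
false positives. Candidates must further (i) exceed a 5×10⁵-count full-scan
intensity threshold, (ii) admit a CHO formula under the monophthalate
elemental restrictions — C 8–30, H 6–60, O 4–10, charge −1, even-electron,
RDBE 6–12 on the reconstructed neutral, 5 ppm — and (iii) be at least 3×
their procedural-blank level. Surviving candidates are annotated at
confidence level 1 (standard match in mass and RT), 2 (predicted RT within
0.2 min of a single proposed structure), or 3 (tentative, isomer
unresolved). In DIA (in-source CE channels at 0/20/40 V) candidacy is
decided after a targeted MS/MS re-run of the prioritized ions; in DDA
(TopN-5 ddMS2) the MS2 spectra are already in hand. Group differences are
called at fold change > 2 with p < 0.05 (t-test on log₁₀ intensities).

See `vignettes/diagnostic-ion-screening.Rmd` for the full model, parameter
rationale, and the simulator's scope.

## Worked example

Simulate the default study fixture (10 monophthalates, 5 single-ion decoys,
14 labelled standards; 3 replicates per group, blanks, spiked QC), run the
DDA screen on the QC sample, and annotate:

```r
library(phthalscreen)

round(anion_mz("C7H5O2"), 4)
#> [1] 121.0295

fx <- make_study_fixture(simulation_config())
cand <- prioritize_dda(fx$dda_runs$qc_spiked, sample_id = "qc_spiked")
table(cand$status)
#>      candidate false_positive
#>             10              5
```

All ten planted monophthalates are candidates; the five decoys — which emit
exactly one diagnostic ion — are rejected by the two-of-three rule. The
`false_positive` rows carry the machine-readable reason
`lt2_diagnostic_ions`. Annotation against the shipped (synthetic) standards
library and 75-entry suspect mass list:

```r
std <- read_standards(); ml <- read_mass_list()
ann <- assign_level(cand, std, ml, make_rt_predictor(std))
ann[, c("mz", "rt_min", "proposed_name", "level")]
#>          mz    rt_min                         proposed_name level
#> 1  251.0561  5.005556        mono-3-carboxypropyl phthalate     3
#> 2  179.0350  5.872222                 mono-methyl phthalate     1
#> 3  193.0506  6.772222                  mono-ethyl phthalate     1
#> 4  265.1081  8.205556         mono-5-hydroxyhexyl phthalate     3
#> 5  221.0819  8.572222                mono-n-butyl phthalate     1
#> 6  263.0925  9.405556             mono-5-oxohexyl phthalate     2
#> 7  255.0663 10.572222                 mono-benzyl phthalate     1
#> 8  293.1394 11.038889 mono-2-ethyl-5-hydroxyhexyl phthalate     2
#> 9  291.1238 12.005556     mono-2-ethyl-5-oxohexyl phthalate     3
#> 10 277.1445 12.538889           mono-2-ethylhexyl phthalate     1
```

Level 1 means the candidate matched a reference standard in accurate mass
and retention time; level 2 means a single proposed structure's predicted RT
fell within 0.2 min; level 3 candidates have formula and diagnostic-ion
evidence but unresolved isomery. The mode comparison report assembles the
Table-style counts with its internal consistency chain asserted:

```r
build_comparison_report(list(list(mode = "DDA", sample_id = "qc_spiked",
                                  candidates = cand, annotations = ann)))
#> Acquisition-mode comparison
#> mode  sample        precursor  candidate   false+  level1  level2  level3
#> DDA   qc_spiked            15         10        5       5       2       3
```

Differential analysis across the fixture's two groups recovers the planted
fold changes (here the 25× and one of the 2.5× effects):

```r
nat <- subset(fx$truth$analytes, !labelled & !is_decoy)
mat <- measure_feature_matrix(fx$dda_runs[fx$sample_ids], nat)
res <- differential_analysis(mat, fx$groups, "fertile", "infertile")
cbind(nat[c(2, 3), c("name", "fold_change")],
      round(res[c(2, 3), c("fold_change", "p_value")], 4))
#>                     name fold_change fold_change p_value
#> 2   mono-ethyl phthalate        25.0     25.1222   0e+00
#> 3 mono-n-butyl phthalate         2.5      2.3738   2e-04
```

The DIA path is symmetric: `prioritize_dia()` on the CE channel set produces
provisional ions and an inclusion list (`export_inclusion_list()`); a
targeted ddMS2 re-run (`simulate_dda(..., inclusion_mz = )` on synthetic
data) feeds `confirm_candidates()`. A command-line wrapper for the
simulate/prioritize/report stages is installed at
`inst/scripts/phthalscreen`.

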