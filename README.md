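# spliceamp

Quantitative analysis of how alternative splicing, coupled to
nonsense-mediated mRNA decay (NMD) and protein-stability control, amplifies
the tissue and developmental specificity of a gene's functional protein
output. The motivating system is mouse *Trim46*, an axon-specification
gene in which two cassette exons act as independent safeguards: inclusion
of an NMD exon ("E8") routes the transcript to degradation, while skipping
of a coding exon ("E10") produces an unstable protein isoform. The same
arithmetic applies to any AS-NMD-regulated cassette-exon gene.

The package is aimed at RNA biologists who have splice-junction counts
(e.g. from STAR) and gene-level TPM for a tissue panel or time course, plus
optional NMD-knockout contrasts and cycloheximide-chase protein decay data.

## The model

**PSI from junction reads.** Each inclusion molecule spans two inclusive
junctions, each skipping molecule one exclusive junction, so with inclusive
reads *I* and exclusive reads *E*:

PSI = 100 · (0.5 *I*) / (0.5 *I* + *E*),  exclusion = 100 − PSI.

**Isoform-level output.** Steady-state TPM is decomposed per sample:
productive (NMD-exon-skipping) isoform = TPM × exclusion(E8)/100; NMD
isoform = TPM − productive; long coding isoform = TPM × PSI(E10)/100.

**NMD-corrected transcriptional output.** The NMD isoform is degraded
λ-fold relative to the productive isoform, with λ estimated as the
(geometric) mean of the NMD-isoform fold changes in NMD-knockout vs control
contrasts. The transcription level implied by steady state is

output = productive + λ · (total − productive).

**Tissue specificity.** τ = Σᵢ(1 − x̂ᵢ)/(n − 1) with
x̂ᵢ = xᵢ/max(xᵢ) and xᵢ = log2(TPMᵢ + 1), after averaging the brain
tissues' log values into a single panel entry. τ = 1 means single-tissue
expression, τ = 0 uniform expression.

**Protein kinetics.** Cycloheximide-chase courses are fit by log-linear
least squares (half-life t½ = ln 2 / k); steady-state isoform abundance
scales as synthesis × t½. The axonal polarity index is
P = (Iₐ − I_d)/(Iₐ + I_d).

A seeded generative simulator (`sim_config()`, `simulate_tissue_panel()`,
`simulate_nmd_ko_contrast()`, `simulate_development_course()`,
`simulate_decay_course()`) emulates all study inputs with recorded ground
truth, so every estimator is testable by parameter recovery.

## Worked example

```r
library(spliceamp)

# Reconstruct the published effective-output arithmetic from the reported
# tissue-panel group means:
ref <- reference_output_analysis()
ref$lambda
#> NMD degradation factor lambda = 7.692 ( geometric mean of 2 fold change(s) )
ref$corrected
#>      brain non_neural
#>     288.93      55.57
ref$folds[, c("metric", "fold", "fold_nearest", "fold_nearest_ten")]
#>   metric           fold      fold_nearest fold_nearest_ten
#> 1 total_tpm        8.5625              9               10
#> 2 productive_tpm  39.5556             40               40
#> 3 coding_long_tpm 44.0000             44               40
#> 4 corrected_output 5.1994              5               10
```

The degradation factor is the geometric mean of the knockout fold changes
8.7 and 6.8 (7.69, reported as 7.7). Correcting the brain and non-neural
group means (68.5 and 8.0 TPM total; 35.6 and 0.9 TPM productive) for
λ-fold NMD degradation yields transcriptional outputs of ~289 and ~56 TPM —
only a ~5-fold difference — while the productive and long-coding isoform
levels differ ~40- and 44-fold: splicing amplifies a modest transcriptional
bias into near-binary protein output.

The same analysis runs end to end on simulated data:

```r
out <- run_pipeline(sim_config(), seed = 1, output_dir = "run1")
out$lambda$lambda        # 8.74 (true value 7.7, two noisy contrasts)
out$tau$tau              # 0.38 (total), 0.69 (productive), 0.64 (coding), 0.21 (corrected)
out$decay_fits$half_life # 1.91 h and 4.41 h (true 1.9 / 4.3)
```

`run1/` then contains `psi.csv`, `isoform_output.csv`,
`group_comparison.csv`, `tau.csv`, `decay_fit.csv`, `summary.json`, and a
`manifest.json` with the config snapshot and output checksums (identical
seeds give identical checksums).

## Vignette

`vignettes/splicing-nmd-output.Rmd` documents the model assumptions, the
generative simulator and its defaults, numerical choices, and limitations.
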