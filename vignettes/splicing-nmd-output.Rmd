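---
title: "Methods: splicing- and NMD-aware quantification of gene output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing- and NMD-aware quantification of gene output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceamp)
```

## The problem

A gene can be well transcribed yet produce almost no functional protein if
alternative splicing routes its transcripts into unproductive fates. The
archetype handled here is a gene with two independently regulated cassette
exons: an NMD exon whose inclusion creates a premature termination codon,
so the inclusion isoform is degraded by nonsense-mediated decay; and a
coding exon whose skipping shifts the C-terminal frame and yields a
short-lived protein isoform. Steady-state mRNA then *understates*
transcription (the NMD isoform is partly gone before it is measured) and
*overstates* functional output (part of what remains encodes unstable
protein). This package quantifies each layer and how together they
sharpen tissue and developmental specificity.

## Model and estimators

### PSI from junction reads

An inclusion molecule contributes one read to each flanking inclusive
junction; a skipping molecule contributes one exclusive read. The 0.5
weight in

$$\mathrm{PSI} = 100\,\frac{0.5\,I}{0.5\,I + E}$$

converts read counts back to molecule fractions: for any molecule
population $(m_\mathrm{incl}, m_\mathrm{excl})$ emitting
$I = 2m_\mathrm{incl}$, $E = m_\mathrm{excl}$, PSI equals
$100\,m_\mathrm{incl}/(m_\mathrm{incl}+m_\mathrm{excl})$ exactly. The
informative depth is $0.5I + E$; estimates below `min_informative` (default
10, on that scale) are flagged `low_coverage`, and PSI is `NA` at zero
depth. The default threshold is a guard against degenerate ratios at
vanishing coverage, not a published value, and is configurable. Undefined
PSIs propagate as missing values and are excluded from downstream means,
never zero-filled.

Replicates are handled by computing PSI per replicate and averaging
arithmetically within tissue — never by pooling reads — matching how the
reference two-replicate tissue panel was summarized.

### Isoform decomposition and the degradation factor

Per sample, with PSI$_8$ the NMD-exon inclusion and PSI$_{10}$ the coding-exon
inclusion:

- productive TPM $=$ total TPM $\times (100-\mathrm{PSI}_8)/100$,
- NMD TPM $=$ total $-$ productive (conserved exactly),
- long-coding TPM $=$ total TPM $\times \mathrm{PSI}_{10}/100$.

The degradation factor $\lambda \ge 1$ is the fold by which the NMD
isoform is degraded relative to the productive isoform. It is estimated
from NMD-knockout vs control contrasts: within each contrast the
NMD/non-NMD isoform ratio (here $\mathrm{PSI}/(100-\mathrm{PSI})$,
replicates aggregated by geometric mean) is formed per condition, the
knockout/control ratio of ratios is the per-contrast fold change, and
fold changes are aggregated across contrasts. The default aggregation is
the geometric mean — fold changes live on a ratio scale — and it
reproduces the reported one-decimal factor from the published stage-wise
fold changes (geometric mean of 8.7 and 6.8 is 7.69 → 7.7), which the
arithmetic mean (7.75 → 7.8) does not. Both methods are exposed.

The NMD-corrected transcriptional output

$$\mathrm{output} = \mathrm{productive} + \lambda\,(\mathrm{total} -
\mathrm{productive})$$

is the transcription level implied if the NMD isoform had not been
degraded. It is linear, so it commutes with group averaging; the package
computes per-sample outputs first and averages afterwards (mean of
products). Note that group means of PSIs and group means of isoform TPMs
are then *not* mutually consistent (the mean of products is not the
product of means); reports carry the per-sample route. The model assumes
NMD acts only on the inclusion isoform of the NMD event and that
$\lambda$ is tissue- and stage-invariant.

Fold changes between tissue groups are ratios of arithmetic means of
per-tissue (replicate-averaged) values, reported at full precision plus
nearest-fold and nearest-ten-fold roundings, since headline values in this
field are conventionally rounded.

### Tissue specificity

$$\tau = \frac{\sum_{i=1}^n (1-\hat x_i)}{n-1}, \qquad
\hat x_i = \frac{x_i}{\max_i x_i}, \qquad x_i = \log_2(\mathrm{TPM}_i+1)$$

The brain tissues are collapsed to a single panel entry by averaging their
$\log_2(\mathrm{TPM}+1)$ values (mean of logs, exactly as the metric is
defined for this panel — not the log of mean TPM). The pseudocount
defaults to 1 and is recorded in output metadata. Because the maximum is
value-based, ties need no tie-breaking. A gene silent in every tissue has
no well-defined $\hat x$; the package returns $\tau = 0$ with a `silent`
flag. Which tissues constitute "brain" is a required analysis input, not a
default, since the reference panel does not name them.

### Protein kinetics and polarity

Chase courses (translation shut off at $t=0$, remaining fraction
normalized to 1) are fit by ordinary least squares on
$\log(\mathrm{fraction})$ vs time with a free intercept. A single
exponential with no plateau is the minimal model under complete
translational shutoff, and the free intercept absorbs normalization error;
the fitted model is recorded in the result. Non-decaying courses
(non-negative slope) are an error state, never a negative half-life.
Courses are assumed pre-normalized (loading control, then $t=0$); no
densitometry is performed. The published single-timepoint remnants (31%
and 6% at 12 h) are inconsistent with pure exponentials at the published
half-lives (14.5% and 1.26%), so the package validates half-life
estimation by parameter recovery on synthetic courses rather than by
refitting unpublished gel data.

Steady-state abundance follows synthesis/degradation, so the isoform
abundance ratio is `synthesis_ratio * t½(a)/t½(b)`. The polarity index
$P = (I_a - I_d)/(I_a + I_d)$ is computed per cell and averaged
arithmetically per group; cells with zero total intensity are excluded.

## The generative simulator

`sim_config()` encodes the emulated study conditions:

- **Tissue panel**: 3 neural + 9 non-neural tissues, 2 biological
  replicates each. Group-level transcription (288.9 / 55.7 TPM) and
  transcription-level PSIs (NMD exon 87.7% / 98.4%; coding exon 96% / 27%)
  were derived once by inverting the steady-state model
  $s = (p/\lambda)/(p/\lambda + 1 - p)$, total
  $= T[(1-p) + p/\lambda]$ at $\lambda = 7.7$, so the noiseless panel
  reproduces the reference group means (total 68.5 / 8.0; productive
  35.6 / 0.9; coding 66 / 1.5 TPM).
- **Junction sampling** happens at *post-decay* isoform proportions,
  because RNA-seq measures steady-state RNA — precisely why steady-state
  levels understate transcription of NMD targets. Informative molecule
  totals are Poisson around `junction_depth` (default 500), split
  binomially, each inclusion molecule emitting two inclusive reads.
  `junction_mode = "exact"` (or `sim_config(noise = FALSE)`) emits
  expected counts, giving the deterministic limit used for closure tests.
- **Dispersions**: tissue-level transcription is lognormal (sdlog 0.5),
  replicate TPM noise lognormal (sdlog 0.2), tissue PSIs beta with
  concentration 80. No dispersion estimates are published for the
  reference panel; these are placeholder values chosen once to give
  qualitatively similar group spreads, and are labelled as such.
- **Development course**: five stages (EB day 8 to DIV 7) with the NMD
  exon falling (85 → 12) and the coding exon rising (8 → 75) against a
  rising transcription baseline — the opposing-trajectory regime — with
  four-isoform joint abundances generated under independence of the two
  exons (the empirically supported relationship); an optional NMD-exon
  knockout condition sets inclusion to zero.
- **Knockout contrast**: two stages (E14.5, P1); wild type simulated at
  $\lambda_\mathrm{true}$, knockout at $\lambda = 1$ with identical
  transcription and PSIs, so the noiseless fold change is exactly
  $\lambda_\mathrm{true}$.
- **Decay courses**: $0.5^{t/t_{1/2}}$ at 0, 1, 3, 6, 12, 24 h with
  multiplicative lognormal noise ($\sigma = 0.1$), $t=0$ anchored at 1.

All draws derive from one seed (`withr::with_seed`); identical
(config, seed) yields byte-identical output files. In `run_pipeline()`
the panel uses the master seed and the contrast and decay stages use
documented offsets (+1, +2, +3), so stages can be regenerated
independently.

What the simulator does **not** emulate: read-level artifacts (mapping
bias, positional coverage, FASTQ generation), overdispersion beyond
Poisson-binomial junction sampling, correlated replicate noise,
inter-gene competition in TPM normalization, and any dependence between
the two exons (a dependence mechanism can be emulated by editing the
four-isoform abundances, but the default is independence). Passing
recovery tests therefore demonstrates estimator correctness under the
stated generative model, not robustness to all features of real data.

## Numerical choices

- PSI at zero informative depth is `NA`, not an error; boundary PSIs
  (0/100) produce non-finite NMD ratios and are dropped with a warning in
  contrast aggregation.
- CSV reports serialize doubles at 12 significant digits — enough to
  round-trip values, and stable so write → read → write is
  byte-identical.
- `corrected_output` requires $\lambda \ge 1$ and
  productive $\le$ total; violations are errors, not clamped.
- Noiseless closure is asserted at tolerance 1e-9 (floating-point
  round-trip through ratios), exact identities (PSI molecule oracle,
  conservation) at machine precision.

## Problem sizes

The shipped tests exercise: the full PSI/molecule identity on all
populations up to 200 molecules; 100 simulated panels for the τ-ordering
property; 20 contrast simulations per true λ in {2, 7.7, 15} at depth 500;
and 200 noisy decay courses per half-life. These sizes give stable
Monte-Carlo behaviour for the properties tested while keeping the default
suite fast on a laptop.

## Limitations

- λ is identified only up to the assumption that knockout abolishes NMD
  completely; partial NMD inhibition biases λ downward.
- The ratio estimator $\mathrm{PSI}/(100-\mathrm{PSI})$ is convex, so at
  low junction depth the per-replicate ratios are biased upward; the
  geometric-mean aggregation mitigates but does not remove this at depths
  far below the default 500.
- τ on a collapsed panel depends on the brain-tissue set; published τ
  values for the reference gene are not desk-reproducible without the
  unpublished per-tissue values, so the package asserts ordering
  properties, not those numbers.
- The decay fit deliberately excludes a plateau term; chases with
  incomplete translational shutoff will show inflated half-lives.
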