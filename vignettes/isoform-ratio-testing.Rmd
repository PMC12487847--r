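---
title: "Isoform ratio testing for multiplexed proteomics: models and methods"
author: "ratioform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform ratio testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioform)
```

## The problem

Classic cardiac physiology has long read biology off the *ratio* of two
closely related proteins — myosin heavy chain beta over alpha (MYH7/MYH6),
fetal over adult troponin I — rather than either protein's level alone.
Two proteins that form a stoichiometric complex, repress each other, or
compete for a substrate pool are naturally described by their relative
usage, and a regulator that pushes one member up while pushing the other
down produces a large ratio change even when neither single protein passes
a differential-expression cutoff. `ratioform` implements this ratio-test
idea proteome-wide for MS2-multiplexed (TMT) proteomics: it estimates
absolute protein abundances per channel, restricts testing to
homology-defined isoform pairs (paralogs and splicing-derived isoforms),
and applies an empirical-Bayes moderated t-test to generalized-log
abundance ratios.

Restricting tests to within-group pairs is what makes the screen
tractable and interpretable: testing all pairs of 2,000 proteins would
mean roughly two million hypotheses, whereas gene families filtered at
50% or greater mean sequence identity yield a few hundred biologically
coupled pairs.

## From PSMs to absolute abundance

TMT reporter ions quantify *relative* channel intensities at MS2, while
the MS1 precursor intensity carries the *summed* amount of the peptide
across all pooled samples. The workflow combines the two:

1. **Apportionment.** Each PSM's MS1 intensity is split across channels
   proportionally to its reporter intensities, so the per-channel parts
   sum exactly to the MS1 value (`apportionChannels()`). A PSM with an
   all-zero reporter vector is unquantifiable and is excluded and
   counted, never silently zeroed.
2. **Aggregation.** Per protein and channel, the apportioned intensities
   of the protein's *unique* PSMs are summed. Peptides mapping to more
   than one accession are excluded: paralog pairs under test can be >90%
   identical, so shared peptides cannot be attributed. Summation at PSM
   level (rather than averaging at peptide level) lets high-intensity
   PSMs dominate naturally.
3. **iBAQ-style scaling.** The sum is divided by the protein's number of
   theoretically observable tryptic peptides (fully tryptic, zero missed
   cleavages, length 7–30, no cleavage of K/R before proline), making
   abundances comparable *across* proteins — the denominator corrects for
   the fact that longer proteins produce more peptides. These digestion
   constants are the usual observable window and are all configurable.
   An intensity-based (iBAQ-style) estimator was chosen over top-N
   averaging because it uses all unique PSMs and has a transparent
   linearity property: scaling every MS1 intensity by k scales every
   abundance by k.

A protein with no unique PSM in a sample is *missing*, never zero; the
distinction propagates through the whole pipeline, and a pair enters a
contrast only when quantified in every sample (complete-case default,
configurable).

## Variance stabilization

Absolute abundances span five or more orders of magnitude with
multiplicative error at the top and additive error near the noise floor.
The package calibrates samples and stabilizes variance in two transparent
steps (`glogNormalize()`):

* per-sample median scaling computed on proteins quantified in every
  sample, which aligns loadings;
* the generalized log transform
  $\mathrm{glog}_2(v) = \log_2\!\big((v + \sqrt{v^2 + c^2})/2\big)$,
  with the soft-zero constant $c$ set per sample to the 5th percentile of
  positive scaled intensities.

This preserves the intent of full VSN maximum-likelihood calibration in a
closed form whose properties are directly testable: the transform is
strictly monotone, finite at zero ($\log_2(c/2)$), and within 0.02 log2
units of $\log_2 v$ once $v \ge 100c$. Exact numerical equivalence to a
maximum-likelihood VSN fit is not claimed. Apportionment and aggregation
happen on the raw scale first; normalization comes last.

## Pairing rules

* **Paralogs.** An Ensembl BioMart-style homology table supplies gene
  pairs with bidirectional percent identities. Pairs are kept when the
  arithmetic mean of the two identities is at least 50% (inclusive at
  exactly 50) and both genes map to quantified proteins. Retained pairs
  form a graph whose connected components are the isoform groups; all
  within-group pairs are enumerated ($n(n-1)/2$ per group).
* **Spliceoforms.** Co-quantified UniProt accessions sharing a base
  accession (`P52480`, `P52480-2`, ...) are paired exhaustively. A group
  may contain both pair types; `pair_type` is per pair.
* **Orientation.** Within a pair, `accession_a` is the byte-order smaller
  accession, and reported log-fold-changes are for
  $\mathrm{glog}(a)-\mathrm{glog}(b)$. The field reports ratios in both
  orientations, so determinism matters more than direction; both
  accessions travel with every result row so signs can be flipped.
* **Ancestry.** A pair's family is "ancient" when its last common
  ancestor is Bilateria or a deeper clade (Opisthokonta, Metazoa, ...),
  "recent" otherwise, "unclassified" when missing. Both the
  opisthokonta-membership view and the family-origin view are expressible
  because the enrichment operation accepts any binary categorization.

## The moderated ratio test

For each pair the per-sample ratio statistic is the difference of glog
values. Differences cancel any per-sample constant — a global loading
shift, a batch intensity offset — which is the self-normalization
property that makes ratio tests robust to technical factors that move
both members together (verified exactly in the tests).

Each ratio row is fit by ordinary least squares against a design matrix
from a main-effects formula (e.g. `~ condition`, or
`~ treatment + age + block` with treatment coding, reference level =
first level observed). Residual variances $s_g^2$ with $d_g$ degrees of
freedom are shrunk toward a pooled prior by the standard empirical-Bayes
moment estimator: writing $z_g = \log s_g^2$, the mean and excess
variance of $z_g - \psi(d_g/2) + \log(d_g/2)$ identify the prior degrees
of freedom $d_0$ (by inverting the trigamma function with a Newton
iteration from the asymptotic start, tolerance 1e-8, at most 50 steps;
non-convergence falls back to $d_0=\infty$) and the prior variance
$s_0^2$. The posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and the moderated
$t_g = \hat\beta_g / (\tilde s_g u_g)$ is referred to a Student
distribution with $d_0 + d_g$ degrees of freedom (standard normal at
$d_0=\infty$). Setting $d_0=0$ recovers the ordinary row-wise t-test
exactly, a limit the test suite checks to 1e-10; the full pipeline is
also cross-checked against the reference empirical-Bayes implementation.
Robust prior estimation (outlier-tolerant $d_0$) is intentionally not
implemented; plain moment estimation keeps the estimator auditable.

Significance combines three criteria, each with a recorded reason code
when failed:

* Benjamini–Hochberg adjusted p below the FDR threshold — **0.01** by
  default. The strict 1% level (rather than the common 5%) partially
  compensates for the nonindependence introduced when one protein
  appears in several ratios; no dependence-adjusted procedure is used.
* absolute log-fold-change at or above **0.5** glog2 units;
* minor isoform fraction (MIF), the mean over complete samples of
  $\min(a,b)/(a+b)$ on the raw scale, at or above **0.05**, which removes
  pairs where one member is present only at trace levels. The mean pools
  both conditions by default (a per-condition minimum is available),
  matching the "average MIF" reading of the filter.

P-values are always two-sided; directional screens are done downstream
by sign filtering. Disease-reversal screens use a relaxed adjusted-p
threshold of **0.1** on the disease contrast, keep pairs whose disease
shift is codirectional with the fetal shift, and report the amplitude
ratio |disease logFC|/|fetal logFC| as the partial-reversal measure.
Multi-stage designs are handled as one model per stage window with its
own contrast; no time-course smoothing is attempted.

## The synthetic experiment

Because the deposited animal datasets are far beyond desk scale, every
statistical guarantee is exercised on a simulator whose defaults *are*
the study conditions of the package's benchmark:

* 1500 background proteins plus 200 two-member paralog groups (100 null,
  100 with a true glog2 ratio shift of 1.0), copy numbers log-uniform
  over 5 orders of magnitude;
* one 10-plex, 5 fetal + 5 postnatal samples; baseline member
  proportions drawn between 35% and 65% so minor-isoform fractions stay
  informative;
* synthetic tryptic sequences whose in-range peptides are exactly the
  emitted PSMs (Poisson mean 10 peptides per protein, KP motifs injected
  in 5% of proteins to exercise the proline rule);
* peptide-level lognormal noise at CV 0.2 on both the MS1 response and
  each reporter channel;
* co-isolation interference modeled as a constant pooled-background
  mixing fraction: each reporter channel measures
  $a_c + f\,\bar m_c$, the simplest model that reproduces TMT ratio
  compression toward 1:1 (benchmark default $f=0$; the compression curve
  is measured at 0/0.15/0.3);
* missingness applied at the protein-by-sample level after
  quantification (missing at random), matching the complete-case
  filter's assumptions; the benchmark default is 0.

Under these conditions the pipeline reaches sensitivity above 0.9 at the
1% FDR thresholds with observed FDR at or below 5% and mean logFC bias
within 0.05 — numbers recomputed from scratch by
`scripts/acceptance.R` and asserted by the test suite, not quoted from
anywhere. What the simulator deliberately does *not* model: spectra and
search-engine errors, retention-time structure, isotope impurity
matrices, peptide-level dropout correlated with intensity, and biological
replicate variance beyond measurement noise. Passing tests therefore
demonstrate the statistical machinery under its stated assumptions, not
the end-to-end behavior of a full raw-data workflow.

## Numerical choices and degenerate inputs

* Residual variance 0 (a constant row) gives an untestable/flagged row
  rather than an infinite t.
* Rows with residual df below 1, or whose missingness pattern makes the
  design rank-deficient, are flagged untestable.
* Fewer than 20 usable variances: moderation falls back to the
  unmoderated test with a warning.
* The exact 2x2 test defines the two-sided p by probability-mass
  ordering with the conventional (1 + 1e-7) relative tolerance on the
  observed table's probability, and reports the sample odds ratio;
  degenerate margins give p = 1 with the odds ratio flagged undefined.
* Pair identity (`"A|B"`) and orientation use byte-order (C-locale)
  comparison so outputs are reproducible across platforms and locales.
* All simulation and pipeline randomness requires an explicit seed.

## Scale of the bundled checks

The test suite and acceptance script run entirely on simulated data
sized for a laptop: the standard benchmark (1,900 proteins, ~19,000
PSMs), a 2,000-pair null calibration, a 40-pair compression curve at
three interference levels, exhaustive 2x2 enumeration up to table totals
of 40, and a 2,000-protein pair-enumeration check. These sizes were
chosen so each property is measured with comfortable statistical margin
while the whole suite completes in about a minute.

## Known limitations

* The absolute-abundance estimator is iBAQ-style by design choice; the
  original workflow's exact estimator may differ, and no claim of
  equivalence is made.
* Normalization is a two-step surrogate for full VSN calibration.
* Ratios sharing a protein are not independent; the only mitigation is
  the stricter 1% FDR, as in the underlying study design.
* Ratio compression from co-isolation is modeled and measured but not
  corrected; no deconvolution is attempted.
* Razor-peptide reassignment is not implemented; shared peptides are
  excluded.
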