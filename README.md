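# ratioform

Proteome-wide **protein isoform ratio testing** for MS2-multiplexed (TMT)
proteomics, in R.

Most proteomics analyses compare each protein's level between conditions.
But much of biology — the fetal-to-adult myosin switch (MYH7/MYH6), fetal
troponin I, GLUT1/GLUT4, PKM M1/M2 — lives in the *ratio* of two highly
homologous proteins: paralogs from ancient gene duplications, or
spliceoforms of one gene. A regulator that pushes one member up and the
other down produces a large ratio change even when neither protein alone
clears a differential-expression cutoff; conversely, a common shift (or a
technical batch effect) cancels in the ratio. `ratioform` makes this a
proteome-wide statistical screen, for researchers analyzing TMT (or
label-free) quantitative proteomics who want isoform *usage*, not just
expression.

## What it computes

1. **Absolute abundance from composite MS1–MS2 data.** Each PSM's MS1
   precursor intensity is apportioned across TMT channels proportionally
   to reporter-ion intensities; a protein's isoform-unique PSMs are
   summed per channel and divided by its theoretical tryptic peptide
   count (iBAQ-style; fully tryptic, no missed cleavages, length 7–30,
   KP/RP suppression). Missing is never zero.
2. **Variance stabilization.** Per-sample median scaling, then the
   generalized log,
   glog2(v) = log2((v + sqrt(v² + c²))/2),
   with c the 5th percentile of positive intensities per sample.
3. **Pairing.** Ensembl-style paralog homology records filtered at mean
   bidirectional identity ≥ 50%; connected components form isoform
   groups; all within-group pairs are enumerated. UniProt
   canonical/isoform accessions (`P52480` / `P52480-2`) give spliceoform
   pairs. Pairs carry identity, group and evolutionary-ancestry
   annotations.
4. **Moderated ratio test.** Row-wise linear models on glog ratio
   differences (R-style design formulas, e.g.
   `~ treatment + age + block`), empirical-Bayes variance shrinkage
   (posterior variance (d₀s₀² + d·s²)/(d₀ + d), moderated t on d₀ + d
   df), Benjamini–Hochberg FDR. Significance = adjusted p < 0.01 AND
   |logFC| ≥ 0.5 AND minor isoform fraction (MIF = mean min(a,b)/(a+b))
   ≥ 0.05, with reason codes for every exclusion.
5. **Downstream analyses.** Group proportion profiles with SEM of
   stacked proportions; proportion-shift fold changes; disease-reversal
   co-directionality screens (disease FDR ≤ 0.1); Fisher's exact
   enrichment of differential usage by evolutionary ancestry; PCA QC;
   single-protein DE with pair cross-tabulation.
6. **Synthetic benchmark.** A PSM-level simulator with known ground
   truth (copy numbers over 5 orders of magnitude, condition-specific
   isoform proportions, lognormal peptide noise, co-isolation ratio
   compression, missingness) so the whole pipeline is testable without
   external data.

## Worked example

Simulate the standard benchmark (1500 background proteins + 200
two-member paralog groups, 100 of them with a true 2-fold ratio shift,
5 + 5 samples, peptide CV 0.2), run the full pipeline, and compare with
the ground truth:

```r
library(ratioform)

sim <- simulateDataset(syntheticConfig(seed = 17))
pq  <- proteinAbsoluteQuant(sim$psms, sim$fasta_map,
                            samples = sim$design$sample,
                            colData = sim$design)
pq  <- glogNormalize(pq)
pq
#> ProteinQuant: 1900 proteins x 10 samples
#>   missing: 0 (0.0%)
#>   assays: abundance, glog

gm     <- geneMap(sim$fasta_map)
ret    <- filterParalogPairs(sim$homology, unique(gm[rownames(pq)]))
pairs  <- enumeratePairs(buildGroups(ret, split(names(gm), gm)))
pairs
#> IsoformPairs: 200 pairs (200 paralog, 0 spliceoform)
#>   groups: 200

X  <- designMatrix(sim$design, "~ condition")
tt <- ratioTest(pq, pairs, X)
head(tt$results[order(tt$results$adj_p),
                c("pair_id", "logFC", "t", "adj_p", "mif", "significant")], 3)
#>            pair_id     logFC         t        adj_p       mif significant
#> 10 PR00019|PR00020  1.069739  20.12078 3.815984e-10 0.4037230        TRUE
#> 4  PR00007|PR00008 -1.045719 -17.00665 9.078495e-10 0.3772876        TRUE
#> 13 PR00025|PR00026  1.068844  17.31720 9.078495e-10 0.3708306        TRUE

str(recoveryReport(tt$results, sim$truth))
#> List of 6
#>  $ n_true_shift: int 100
#>  $ n_called    : int 96
#>  $ bias        : num -0.024
#>  $ rmse        : num 0.192
#>  $ sensitivity : num 0.96
#>  $ observed_fdr: num 0
```

Reading the numbers: of 100 pairs simulated with a true 1.0 glog2-unit
usage shift, 96 are called at the strict thresholds (adjusted p < 0.01,
|logFC| ≥ 0.5, MIF ≥ 0.05), none of the 100 null pairs is called
(observed FDR 0), and the estimated log-fold-changes are essentially
unbiased (−0.024) — the small residual compression comes from the glog
soft-zero on the lowest-abundance pairs. The top pair's `logFC` of 1.07
is the fitted between-condition change of the glog2 ratio of the two
members; `mif` = 0.40 says the minor member carries 40% of the pair's
molecules, far above the 5% trace-level filter.

A staged, file-based interface with run manifests is available through
`runPipeline()` (stages `simulate`, `quantify`, `pair`, `test`,
`proportions`, `conservation`) and a thin CLI wrapper at
`inst/scripts/ratioform-cli.R`; thresholds and the model formula live in
a YAML config (`loadRunConfig()`).

## Documentation

The methods vignette (`vignettes/isoform-ratio-testing.Rmd`) describes
the model, assumptions, parameter defaults, simulator design and known
limitations; every exported function has roxygen documentation.
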