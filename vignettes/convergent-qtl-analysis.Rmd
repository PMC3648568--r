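---
title: "Convergent QTL–transcriptome analysis: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent QTL–transcriptome analysis: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlconverge)
```

## The problem

Mapping grain-yield-under-drought QTL in near-isogenic material is hard
twice over: the contrasted backcross inbred lines (BILs) are nearly
identical genetically (so marker polymorphism is scarce), and a QTL
interval projected onto the physical genome spans megabases containing
hundreds of genes. The convergent strategy implemented here attacks
both ends:

1. **Chip genotyping by hybridization.** Genomic DNA of a +QTL/−QTL
   BIL pair is hybridized to an expression array; probes whose
   intensity differs between lines (single-feature polymorphisms,
   SFPs) mark sequence divergence. Genome blocks where SFPs aggregate
   delimit the polymorphic regions worth saturating with markers.
2. **Marker-based QTL scans.** Mapping populations derived from the
   BILs are scanned by regression-based interval mapping with
   empirical permutation thresholds.
3. **Transcriptome meta-analysis.** Differentially expressed genes
   (DEGs) between +QTL and −QTL lines are located on the genome;
   blocks where DEGs aggregate, and Fisher-exact enrichment of DEGs
   inside QTL intervals and annotation categories, narrow the QTL to a
   candidate-gene list at the intersection of all three lines of
   evidence.
4. **Trial arithmetic.** Multi-environment trial tables summarise the
   realized yield advantage of QTL-introgressed lines over the
   recurrent parent.

Every stage is exercised end to end on synthetic data with planted
structure, so recall, calibration and power are measurable against a
known truth.

## The statistics

### Per-feature differential tests

Expression (per gene) and hybridization intensity (per probe) are
compared between the two lines of a BIL pair with a per-feature Welch
(unequal-variance) *t* test on the log2 scale. Following the
line-contrast design, the two water-stress levels (FTSW 0.5 and 0.2)
are pooled as replicates of the line by default; per-stress contrasts
are available through the `stress` argument. Decision rules are the
raw-threshold conventions of this literature: `p < 0.001` for
expression, `p < 0.05` for hybridization, with **no multiplicity
adjustment** at this stage.

The Welch test is a declared, oracle-checkable stand-in for the
original mixed-model array analysis, whose design terms (dye, array,
batch) are not part of the synthetic generative model. Two properties
are worth knowing: with 2×3 pooled replicates per group the
Satterthwaite degrees-of-freedom estimate makes the test mildly
conservative (measured size ≈ 0.045 at nominal 0.05 and ≈ 0.0005 at
nominal 0.001 under the null), and the test suite asserts validity
plus approximate calibration rather than exact nominal size.

### Sliding-window aggregation

Each chromosome is tiled with windows of `block_size_bp = 1000` kb
advanced by `step_bp = 500` kb (clipped at chromosome ends), features
are assigned to windows by their midpoint, and each window's hit count
is tested with a one-sided exact binomial upper tail

$$p_w = P\{X \ge k_w\}, \quad X \sim \mathrm{Bin}(n_w,\ \hat\pi),$$

where $n_w$ is the window's feature count, $k_w$ its hit count and
$\hat\pi$ the genome-wide hit fraction. A window is significant at
`alpha = 0.01` (raw; again no across-window adjustment, matching the
reporting convention). Significant windows that overlap or abut are
merged into *aggregation regions*; regions computed per tissue are
unioned when a per-pair "distinct regions" count is requested.

Two design points:

* **The null model is a choice.** The source method is cited without a
  formula; the binomial null with plug-in genome-wide rate is exact,
  fast and oracle-checkable. A permutation alternative (significance
  flags shuffled over feature positions, `method = "permutation"`) is
  provided as a sensitivity check; on planted fixtures the two agree.
* **Discreteness.** An exact binomial test on ~60-feature windows is
  conservative: its achievable rejection probability at
  `alpha = 0.05` is ≈ 0.03–0.04, not 0.05. The calibration experiment
  therefore compares the empirical rejection rate with the test's own
  expected rejection probability (the mean achievable tail mass below
  `alpha`), computed exactly per window — a band centred blindly on
  `alpha` would reject any faithful implementation of an exact
  discrete test.

### Chip-defined polymorphic regions

`chip_polymorphic_regions()` composes the window scan and region
merging on SFP calls, then adds a second stage: candidate regions
(raw per-window `alpha = 0.01`) are *selected* only if their best
window survives a genome-wide Bonferroni filter
(`min_p < region_alpha / n_windows`). With ~10³ windows genome-wide, a
raw 0.01 threshold alone admits a few false windows per genome; the
two-stage candidate→selected structure mirrors how chip-based region
definition is reported in practice (many candidates, few selected) and
cleanly separates planted blocks — whose windows carry overwhelming
hit excess — from the raw-threshold noise floor.

### Fisher-exact enrichment

All overlap questions (DEGs × QTL interval, gene set × annotation
category) go through one hypergeometric 2×2 test with fixed margins.
The default is one-sided "greater" — enrichment is the question being
asked — with a two-sided option; a zero margin yields `p = 1` and an
undefined (NaN) odds ratio; the odds ratio reported is the sample
estimate $ad/bc$. The gene universe defaults to the whole catalog
(the annotation-release analogue), with `universe = "tested_genes"`
as the alternative since the original choice is not recoverable.
A Benjamini–Hochberg column is emitted *alongside* the raw p-values
for the user's benefit but never gates the raw-threshold output.

### QTL scans

Scans use the Haley–Knott regression approximation: at pseudomarkers
the expected donor dose is computed from flanking markers under
Haldane's map function, and the phenotype is regressed on the expected
additive code. With BIL-level homozygosity the regression and mixture
likelihoods are nearly indistinguishable, and regression is
deterministic and verifiable against closed-form identities
($\mathrm{LOD} = \tfrac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$,
$\mathrm{LOD} = \tfrac{n}{2}\log_{10}(1 + F\,\mathrm{df}_1/\mathrm{df}_2)$,
$R^2 = 1 - \mathrm{RSS}_1/\mathrm{RSS}_0$), which the tests check to
1e-8.

* Additive effects are reported as the conventional half-difference of
  homozygote class means (donor minus recurrent, kg/ha). Trait tables
  in this literature sometimes phrase the effect "over the population
  mean"; that estimator is nonstandard and is not guessed at.
* Composite interval mapping forward-selects up to `n_cofactors`
  marker cofactors by RSS reduction, drops collinear candidates with a
  warning, and excludes cofactors within 10 cM of the test position.
  With zero cofactors it reduces exactly to the interval scan.
* The permutation threshold is the order statistic at index
  $\lceil (1-\alpha)(B+1) \rceil$ of $B$ permuted genome-wide max-LOD
  values, giving exceedance probability $(B+1-\mathrm{idx})/(B+1)$
  under exchangeability (0.00995 at $B = 200$, $\alpha = 0.01$) —
  measurably calibrated in the validation suite.

Numerical choices: $\mathrm{RSS}_1$ is floored at
$10^{-12}\,\mathrm{RSS}_0$ to cap the LOD in degenerate perfect fits;
peak ties break toward the smaller genomic coordinate; missing
genotypes are dropped pairwise in single-marker mode, imputed from the
nearest informative marker in interval mode, and mean-imputed in the
vectorised permutation pass; a zero-variance phenotype short-circuits
every position to LOD 0.

### Convergence and trial arithmetic

A candidate gene is a DEG (any tissue; the two BIL pairs' calls can be
pooled) whose position falls inside a named QTL interval, flagged for
overlap with the aggregation regions and carrying tissue provenance,
effect direction and annotation categories. The summary counts report
total-in-QTL and in-QTL∩region.

`yield_advantage()` is exact integer arithmetic on trial-table cells:
entry yield minus check yield per (site, regime), with min/max over
the requested scope. The packaged multi-site trial table prints a
per-site least significant difference (LSD); recomputing the
published range from the cells shows it corresponds to the advantages
*exceeding the site's LSD* (the plain minimum over all 21 cells is
271 kg/ha, and 519/723 also fall below the printed lower end of
528 kg/ha), so the `significant_only` flag implements that reading —
a line "shows" an advantage when the advantage is statistically
significant. The screening-trial range (194–1920 kg/ha) reproduces
with plain min/max.

## The synthetic study and its defaults

The generator defaults define one fixed study design; they are not
tuned per analysis.

| Parameter | Default | Why |
|---|---|---|
| genome | 12 chromosomes × 40 Mb | rice-scale genome, uniform lengths (only relative positions matter) |
| genes | ~40k uniform, log-normal lengths | annotation-release scale |
| planted regions | chr2 6.8–7.3, chr4 6.7–7.2, chr9 14.6–16.5, chr10 18.6–19.3 Mb | the four canonical drought-yield QTL intervals (`default_qtl_intervals()`) |
| expression noise | 0.5 sd, log2 | typical oligoarray replicate noise |
| planted DEG effect | 2.5 log2 units (~5.7-fold), random sign | "large effect" planting: per-gene detection power ≈ 0.99 at p < 0.001 with 3 replicates × 2 pooled stress levels |
| background DEG rate | 0.01; hotspots 10× | sparse background with clear planted aggregation |
| hybridization | noise 0.2 sd; block shift 5 × sd; 4 replicates/line | per-probe SFP power ≈ 0.99 at p < 0.05 |
| mapping population | n = 450, markers every 500 kb, 4 cM/Mb (Haldane) | population-scale n; order-of-magnitude rice map density |
| genotype model | donor/recurrent Markov chain, homozygote codes {0, 2}; donor frequency 0.5 in segregating QTL blocks, 1/16 elsewhere | BC4-derived expectation; residual heterozygosity collapsed to the minor homozygote class |
| planted QTL R² | 0.091, 0.112, 0.130, 0.170 | the reported per-locus phenotypic-variance scale (6–19%) |
| phenotype | mean 2000 kg/ha, residual sd 600 | stress-trial grain-yield scale |

**Exact R² calibration.** Requested QTL effects are calibrated against
the *realized sample moments*: the noise vector is residualised
against the planted-QTL marker genotypes and the coefficients are
solved from their sample correlation matrix, so each planted QTL's
marginal sample R² at its marker equals the requested value exactly.
Without this, the sampling noise of R² itself (sd ≈ 0.03 at n = 450)
would dominate any recovery tolerance; with it, deviations measured at
the scan peak isolate what the *method* adds (peak-selection
inflation, pseudomarker interpolation). The non-homogeneous genotype
chain preserves marginal donor frequencies exactly except for
probability clamping at segregating-block boundaries, where the
transition is compressed over one marker interval.

**What the generator does not emulate.** Normalization and background
artefacts, probe-level cross-hybridization, correlated co-expression
(noise is independent across genes), dye/array batch structure (hence
the Welch stand-in for the original mixed model), segregation
distortion, genotyping error, QTL×environment interaction and the
site structure of real multi-environment trials. Passing tests
therefore certify the *statistical machinery* — calibration, power,
recovery, exact arithmetic — under a clean generative model, not
performance on raw deposited array data; the published DEG counts,
region counts and per-table p-values require those deposited data and
are deliberately covered by schema tests only.

## Validation experiments and problem sizes

The validation suite (`R/calibration.R`, exercised by the tests and by
`scripts/acceptance.R`) runs at these scales, chosen to make the
Monte-Carlo error of each measured rate small relative to its
tolerance:

* window calibration: 200 null genomes (12 × 40 Mb, 30k genes, 5%
  rate), ~960 windows each; hotspot power: 200 redraws of a 10×
  hotspot over 40 consecutive genes;
* chip-region recovery: 50 simulated chip experiments at the default
  geometry, scored exactly (every planted block hit exactly once,
  nothing else selected);
* QTL recovery: 100 mapping populations (four planted QTL, n = 450),
  interval scan + 200-permutation threshold; threshold calibration:
  500 null populations (3 chromosomes × 11 markers, n = 200);
* DEG recall: 570 planted large-effect root DEGs in a 5k-gene catalog.

## Known limitations

* The aggregation null treats features as exchangeable given position;
  gene-density gradients enter only through per-window counts.
* The two-stage chip-region filter trades a little sensitivity for
  near-zero false regions; a planted block must produce window-level
  evidence strong enough to clear a genome-wide bound (trivially true
  at the default shift, not for marginal polymorphism).
* Single-population scans only; joint multi-population analysis is out
  of scope, though per-population scan outputs concatenate naturally.
* The interval-mode imputation of missing genotypes (nearest
  informative marker) is adequate at BIL-level homozygosity and low
  missingness, and is not a general hidden-Markov genotype
  reconstruction.
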