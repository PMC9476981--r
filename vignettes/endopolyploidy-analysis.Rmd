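---
title: "Gating DNA-content histograms and quantifying endopolyploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gating DNA-content histograms and quantifying endopolyploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endoflow)
```

## The measurement model

Flow cytometry of propidium-iodide-stained nuclei yields, per nucleus, a
fluorescence intensity proportional to its DNA content. In a somatic plant
tissue the intensities pile up in Gaussian peaks at the 2C position and its
successive doublings 4C, 8C, ..., because endoreplication doubles the genome
without division. `endoflow` models a measurement as

* a set of Gaussian peaks at positions $a \cdot 2^k$, $k = 0, 1, \dots$,
  with per-peak coefficient of variation (CV, instrument quality, typically
  1-5 %),
* a decaying sub-2C debris background,
* and a multinomial allocation of nuclei to the $k$ classes.

`fit_ploidy()` is the estimator for this model. It is deliberately
deterministic — every random quantity in the package lives in the
synthetic-data generator — and proceeds in four steps, each exposed as its
own function:

1. **Binning** (`build_histogram`): intensities are binned uniformly in
   log-intensity (the doubling series becomes equally spaced). The default
   is 512 bins: at typical sample sizes of 3000-5000 nuclei this keeps
   several counts per bin inside even a ~1 % class peak, which finer grids
   would dilute below Poisson noise, while position error from binning
   stays far below one percent. The range is padded by a quarter doubling
   on each side so a peak at the data extreme can decay to empty bins;
   without padding its prominence is truncated by the axis.
2. **Peak detection** (`detect_peaks`): local maxima of a 9-bin running
   mean are kept when their topographic prominence exceeds both 2 % of the
   tallest bin and a counting-noise floor of 3 Poisson standard deviations
   of the local smoothed count; shoulders not separated from a taller
   neighbour by a valley below half the smaller height are merged. Peak
   position is the count-weighted mean inside the full-width-at-half-maximum
   window; the CV is the within-window SD rescaled to the equivalent
   untruncated Gaussian SD (the window half-width is solved against the
   truncated-normal SD, so the reported CV matches the instrument's G0/G1
   convention).
3. **Doubling-series assignment** (`assign_doubling_series`): the anchor
   (2C) is the lowest peak whose doubling chain matches at least one other
   peak within a 10 % tolerance; if no chain matches, the tallest peak is
   the anchor. Chain consistency is preferred over height because the G0/G1
   class does not dominate everywhere — in roots and stems 4C can be the
   modal class — while a sub-2C debris peak never has doubling partners.
   The 10 % tolerance is a safe separator: with peak CVs capped at 5 % by
   QC, successive doublings are ~15 CVs apart. Unmatched peaks are flagged,
   never dropped.
4. **Gating** (`gate_events`): boundaries between adjacent assigned peaks
   sit at their geometric midpoint (symmetric under the doubling structure
   on the log axis); the outer boundaries sit half a doubling beyond the
   terminal peaks. Events outside all gates are reported as sub-2C debris
   or supra-gate aggregates and excluded from the nucleus total.

Where the original instrument software drew regions by operator convention,
the boundary placement here is a declared convention of this package, not a
reconstruction.

Quality control (`qc_check`) mirrors standard protocol rules: at least 5000
nuclei and all anchor-peak CVs at most 5 % for genome-size runs; at least
3000 nuclei for endopolyploidy screens. QC returns a report object so that
failing measurements can be excluded with a logged reason.

## Genome size

With an internal reference standard co-chopped into the sample (here the
tomato standard, 2C = 1.96 pg, configurable), the sample's 2C DNA amount is

$$2C_{\text{sample}} = 2C_{\text{standard}} \cdot
  \frac{\text{sample } G_0/G_1 \text{ peak mean}}
       {\text{standard } G_0/G_1 \text{ peak mean}},$$

with 1 pg = 978 Mbp and per-chromosome content $2C/2n$. Plants are measured
three times on different days; `aggregate_plant()` averages the runs and
flags a plant when the spread (range/mean) reaches 1.5 %, the conventional
between-day stability bound, implemented as a flag rather than an inference
because it is a protocol rule, not a hypothesis test. Species summaries use
the sample SD (n−1).

## Endopolyploidy parameters

With $n_k$ nuclei in class $2^k \cdot 2C$, $N = \sum n_k$, $f_k = n_k/N$:

| parameter | definition | meaning |
|---|---|---|
| EI | $\sum_k k f_k$ | mean endocycles per nucleus |
| MCV | $\sum_k 2^{k+1} f_k$ | mean C-value |
| E4P | $\sum_{k\ge1} 2^{k+1} n_k / \sum_{k\ge1} n_k$ | mean C-value of endopolyploid nuclei |
| ≥4C | $100 \sum_{k\ge1} f_k$ | percent of nuclei past the first endocycle |
| ECmax | $\max\{k : n_k > 0\}$ | deepest observed endocycle |
| meanDNA | $\mathrm{MCV} \cdot 2C_{pg}/2$ | tissue-specific mean DNA content (pg) |

E4P is undefined — reported as `NA`, never 0 — when no nucleus is at or
above 4C, which keeps downstream means honest. meanDNA uses the
species-level mean 2C rather than a per-plant value because genome sizes
are measured on different individuals than the endopolyploidy screens. A
tissue counts as endopolyploid when EI exceeds 0.1.

Replicate measurements of one individual and organ (several lateral roots
of one plant) are averaged at the parameter level, matching the study
convention; `pool_counts()` offers the count-pooling alternative, for which
EI, MCV and ≥4C obey an exact identity: the pooled index equals the
nucleus-weighted mean of per-replicate indices.

## The comparison layer

Between-group comparisons are gatekept: ANOVA with Tukey HSD only when
every group passes Shapiro-Wilk and the groups jointly pass Levene's test
(both at α = 0.05, Levene mean-centred by default with a median-centred
option); otherwise Kruskal-Wallis with Dunn's pairwise z tests under
Benjamini-Hochberg adjustment. Constant groups, where Shapiro-Wilk is
undefined, are treated as failing normality. Dunn's test is implemented in
the package (rank sums with tie correction) because no pre-installed
package provides it; ANOVA, Tukey, Kruskal-Wallis, Shapiro-Wilk, Levene and
BH all come from base R and `car`.

Compact letter displays are built from the maximal cliques of the
non-significance graph at α = 0.05. This makes letter soundness — two
groups share a letter exactly when their pair is not significantly
different — a structural property rather than an outcome of an
insert-and-absorb heuristic, and it is deterministic given the alphabetical
group order; with at most a handful of groups the exponential clique
enumeration is irrelevant.

Dispersion across species uses CV = 100·SD/mean over the per-species organ
means; ordination uses PCA on column-centred, unscaled matrices (all
columns share a unit), with individuals required to be complete across the
four non-leaf organs — leaves are excluded because they could rarely be
measured cleanly. Which individuals entered the original ordination (and
how replicates were handled) is not recorded in the source material, so
the published variance-explained figures are treated as soft references,
not targets; the package asserts instead the algebraic properties
(variance conservation, equivalence with a brute-force eigendecomposition).
Figure-style standardization (`standardize`) is the usual z-score with
sample SD.

## The synthetic generator

`simulate_study()` emulates the study design: 4 species × 4-5 organs ×
individuals, with per-individual class proportions drawn from a Dirichlet
centred on the published species × organ mean proportions. The Dirichlet
respects the simplex, keeps structurally absent classes at exactly zero,
and has one interpretable spread knob; its concentration default of 60
comes from matching the published between-individual SDs (e.g. 7.0/6.1/2.9
percentage points for the most-studied root cell) through
SD = √(p(1−p)/(c₀+1)). The Dirichlet implies weak negative correlation
between class proportions; per-class correlations were not published, so
this is an assumption, not a fit. Organ proportions of one individual are
drawn independently — real organs of one plant are likely correlated, so
between-organ covariance in synthetic data is understated.

Event-level simulation (`simulate_events`) draws multinomial class counts,
Gaussian intensities with SD = CV·position (CVs are quoted on the linear
scale), and sub-2C debris from a truncated exponential strictly below the
2C gate; aggregates above 64C are not modelled. The anchor default of 200
channels is cosmetic — gating is scale-invariant, which the suite asserts.
Genome-size samples (`simulate_gs_sample`) superpose the standard and
sample G0/G1 peaks and warn when the true ratio falls within 5 % of a
doubling of the standard, where the peaks would collide.

What passing tests show — and what they do not: the generator reproduces
the class-proportion structure, peak shapes and study bookkeeping, so the
suite demonstrates that the estimator chain recovers known truth under
realistic noise. It does not demonstrate robustness to what the generator
omits: S-phase continua between peaks, fluorescence spillover, staining
inhibition by secondary metabolites (the reason leaf samples failed in
practice), or drifting instrument gain.

## Numerical conventions and problem sizes

* All indices accept raw counts, proportions or percentages — every
  parameter is a ratio.
* Report tables round to 2 decimals (EI, MCV, E4P, meanDNA), integer Mbp,
  3 decimals for pg-per-chromosome.
* Ties in Spearman correlations use average ranks; correlation p-values
  are not computed (magnitudes are the object of interest).
* Degenerate inputs fail loudly: empty counts, zero SD in standardization,
  all-identical comparison groups, incomplete PCA matrices.
* The test suite works at n = 3000-5000 nuclei per measurement, 5
  individuals per species × organ cell for pipeline fixtures, 50-100 seeds
  for recovery properties and 1000 null replicates for the multiple-testing
  calibration — sizes chosen so the full suite completes in well under a
  minute while keeping Monte-Carlo error far below the asserted bounds.

Per-seed recovery assertions compare the gated result against the realized
composition of the drawn sample; template means are asserted on averages
over seeds, since at n = 5000 the sampling noise of EI itself (SD ≈ 0.015
for stem-like rows) exceeds what any gater could undo.

## Known limitations

* Partial endoreplication (peak ratios other than 2) and endosperm-type
  3C series are out of scope; the doubling assumption is structural.
* The sample/standard protocol assumes the standard's G0/G1 peak is
  cleanly separable; ratios within ~5 % of a doubling are rejected rather
  than deconvolved.
* No cell-cycle deconvolution: S-phase nuclei between 2C and 4C are gated
  to the nearer class.
* FCS container ingestion is not implemented; measurements enter as plain
  event tables or count tables.
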