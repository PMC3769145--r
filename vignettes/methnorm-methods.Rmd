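---
title: "Preprocessing 450K methylation arrays: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing 450K methylation arrays: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methnorm)
```

## The problem

The Infinium HumanMethylation450 BeadChip measures DNA methylation at
~485k CpG sites as a pair of fluorescence intensities per probe and
sample: methylated (M) and unmethylated (U), summarised as
$\beta = M/(M+U+\alpha)$ with $\alpha = 100$ stabilising the ratio at low
intensity.  Two chemistries coexist on the array.  Type I probes use two
beads read in a single colour channel; Type II probes use one bead and
two colours.  Because background fluorescence enters both M and U
additively, and the Type II assays collect background from two colour
channels, Type II betas are compressed toward 0.5 relative to Type I.
Two-colour readout also exposes Type II probes to dye bias.

The stance taken here is that background is not an error to be removed —
subtracting control-probe estimates only injects extra variance — but the
*difference* in background between the two probe types is worth
equalising, and systematic differences *between samples* (background
level, dye balance, overall intensity, methylation-reaction efficiency)
are what between-array normalization should remove, because they are
what limit sensitivity to the small group differences typical of complex
phenotypes.

## The method family

Every method takes a `MethylIntensitySet` (a `SummarizedExperiment` with
`methylated` and `unmethylated` assays, a probe manifest in `rowData`
and a sample sheet in `colData`) and returns a `BetaSet`.  Methods are
design points on two axes:

1. **Background equalisation** (`none` / per-sample / position-smoothed).
   Both M and U intensity distributions show a characteristic peak close
   to zero whose position differs between Type I and Type II probes.
   Per sample and channel we estimate a Gaussian-kernel density
   (Silverman's bandwidth, 512 grid points spanning [0, max intensity])
   for each probe type, locate the highest mode *below the channel's
   median intensity*, and add the Type II minus Type I peak difference to
   the Type I intensities, clipping negatives at zero.  Nothing is
   subtracted from Type II: the aim is equal backgrounds, not zero
   background.  Optionally the per-sample offsets are replaced by fitted
   values of a per-channel least-squares model `offset ~ chip row`
   (vertical Sentrix position), which is useful when the background
   shows a positional gradient — the smoothing avoids adding estimation
   noise to the offsets, while the gradient itself is left to the
   subsequent QN.
2. **Between-array quantile normalization.**  The engine forces each
   column of a features-by-samples matrix onto the common distribution
   formed by rank-wise means of the column-sorted matrix.  Modes: M and
   U normalized separately (`..ten`, `..sen`) or joined column-wise and
   normalized against each other (`..net`, `..nes`), which removes
   sample-varying dye bias at the cost of forcing M and U to a common
   distribution; assay types pooled (`..ten`, `..net`) or stratified
   (`..sen`, `..nes`); `betaqn` instead quantile-normalizes the raw
   betas; `raw` does nothing.

`dasen` — background equalisation followed by separate QN of the four
strata (M/U crossed with Type I/II) — is the reference point for "do the
simple, well-motivated thing on the intensity scale".

Numerical conventions: QN ties within a column receive the mean of the
target values at the tied ranks (the standard behaviour of the
rank-mean algorithm); a row group with a single feature is passed
through unchanged with a warning; $\alpha$ is applied after
normalization, when betas are computed from the normalized intensities;
`daten1` and `daten2` share their normalization axes and differ only in
the offset estimator (per-sample vs position-smoothed); the Type I
Red/Grn sub-channel is carried in the manifest but does not further
stratify QN.  QN is performed on the raw intensity scale.

## The three quality metrics

Real data carries no ground truth, so the metrics lean on probes whose
expected behaviour is known *a priori*; all three are standard-error-like
(lower = less technical variance = more sensitivity), and all are
computed separately for Type I and Type II probes.

* **DMRSE.**  Imprinted DMR probes are uniparentally methylated, so
  $\beta \approx 0.5$.  The default (and primary) form pools all iDMR
  entries: `sd(betas)/sqrt(n samples)`.  Because the sentence "standard
  deviation of the full set of DMR beta values" admits row-wise and
  column-wise readings too, both are available behind `mode = "row"` /
  `"col"`; the pooled form is the default.
* **GCOSE.**  Each SNP control probe is clustered with k-means, $k = 3$,
  Lloyd iterations from fixed centers (0.2, 0.5, 0.8) — fixed
  initialisation makes the metric deterministic without a seed, and the
  centers sit where diploid genotypes must fall.  Clusters are labelled
  BB/AB/AA by ascending center.  Within-cluster sums of squares and
  cluster sizes are summed across SNPs per label; each pooled SS is
  divided by its pooled size and by $\sqrt{n}$; GCOSE is the mean of the
  three.  A probe with fewer than three distinct values is clustered
  with reduced $k$ and contributes only to the groups it forms (mapped
  to labels by nearest canonical center).
* **Seabird.**  Welch t-tests per probe for male–female differences
  (pooled-variance Student form available as an option; zero-variance
  probes get $p = 1$ when means agree, $p = 0$ otherwise), then a
  rank-sum AUC of $-p$ predicting "probe is on chromosome X", with ties
  sharing average ranks; the metric is $1 - \mathrm{AUC}$.  Y-chromosome
  probes count among the negatives by default (an `excludeY` switch
  drops them).  Bonferroni-corrected significance counting is a
  reporting convenience only; the ROC consumes raw p-values as ranks.

## Cross-dataset ranking

Per dataset and assay type, methods are ranked (ascending) on DMRSE,
GCOSE (already collapsed from its three genotype groups by the mean) and
Seabird; the three metric ranks are averaged per method; those averages
are averaged across datasets; and the per-type pooled scores are ranked
once more, ties receiving mean ranks — hence fractional final scores
like 1.5.  The final table averages the Type I and Type II ranks.  Two
deliberate choices: the final ranking is applied to the pooled
mean-of-mean-ranks (not to pooled raw metric values, whose scales are
incommensurable), and datasets are weighted equally regardless of sample
size.  A metric that is missing for *every* dataset (Seabird on
single-sex data) is dropped from the ranking with a message; a partially
missing metric is an error rather than a silent reweighting.

## What the simulator emulates

`simulateDataset()` generates a complete synthetic array with ground
truth.  Per-probe true methylation: autosomal CpGs from a bimodal
mixture (45% low, Beta(1.5, 60); 45% high, Beta(60, 1.5); 10%
intermediate, Beta(5, 5)); iDMR probes at exactly 0.5; SNP probes at
{0, 0.5, 1} via Hardy–Weinberg draws at per-SNP allele frequencies
(default Uniform(0.2, 0.8)); X probes from an X-inactivation model in
which the male level is the active-X level (bimodal like autosomes) and
the female level averages the active X with a largely methylated
inactive X (Uniform(0.65, 0.95)), except for a 20% XCI-escape fraction
with no sex difference.  That last point matters: it makes sex
differences range from large to nil, so the Seabird ROC has something to
discriminate — if every X probe differed hugely, every method would
score a perfect AUC and the metric would be uninformative.

Per-sample scatter is Beta-distributed around the true level
(concentration 100, i.e. sd ≈ 0.05 at $\beta = 0.5$), keeping fractions
in [0, 1].  Intensities are then
$M = \theta T e_M + b_M$, $U = (1-\theta) T d e_U + b_U$ with:

| effect | default | why this magnitude |
|---|---|---|
| mean total intensity $T$ | 4000 au | typical scanner output scale |
| per-sample intensity scale | lognormal, sdlog 0.15 | array-to-array staining/scan differences |
| Type I / Type II background | 400 / 1000 au | Type II inflation, the source of the beta compression |
| per-cell background spread | lognormal, sdlog 0.2 | probe-level background heterogeneity |
| per-sample background level | lognormal, sdlog 0.3 | wash/staining efficiency varies per array |
| Type II dye bias $d$ | 1.15, per-sample sdlog 0.15 | two-colour imbalance varies between scans |
| per-cell channel noise $e_M, e_U$ | lognormal, sdlog 0.1, independent per channel | fluorescence noise hits the two signals independently — shared noise would cancel in the beta ratio |
| methylation-balance shift | logit shift, sd 0.15 per sample | bisulfite-conversion / extension efficiency moves a sample's whole M/U balance |
| chip-row gradient | 0 (off) | when enabled, added to the *Type II* background so the Type I/II offset varies with position (a common-mode gradient cancels in the offset by construction) |

The per-sample effects (background level, dye balance, methylation
balance, scale) are the systematic between-sample errors that
normalization exists to remove; without them, raw betas would already be
near-optimal and a comparison of preprocessing methods would be
meaningless.  Probe counts default to 20,000 autosomal + 237 iDMR + 65
SNP + 800 X (the X count a reduced-scale stand-in for the array's
11,232 X features) with 72% of probes Type II, and 20 samples on
6-row × 2-column chips.  Randomness is organised as fixed per-component
sub-seeds derived from one master seed, so any component can be
regenerated independently and every run is exactly reproducible.

What the simulator does **not** emulate: probe sequences and GC content,
spatial correlation beyond the row gradient, batch structure across
chips, cross-reactive or polymorphic probes, sample failures, saturation
nonlinearity, and tissue heterogeneity.  Passing tests therefore show
that the methods behave as designed under the modelled artifact
structure — not that the same ordering must hold for any real dataset,
especially heterogeneous ones where forcing identical distributions can
be counterproductive.

## Degenerate inputs and tolerances

Betas are guaranteed in [0, 1] whenever $\alpha > 0$; $M = U = 0$ yields
0, and $\alpha = 0$ with an all-zero cell is an explicit error.
`beta2m` rejects 0 and 1 (infinite M-values).  QN requires at least two
columns and finite values.  Offset estimation falls back to the global
density mode (with a warning) if no grid point lies below the median —
a pathological distribution — and refuses to smooth without chip
positions.  Negative intensities after equalisation are clipped to 0.
Equalisation followed by re-estimation returns offsets within one
density-grid step of zero, which is the estimator's resolution
(grid step = max intensity / 511).

## Problem sizes used by the test suite

Unit tests run on toy fixtures (a 6-probe set with every probe class)
and small simulations (~1.5k probes, 12 samples).  The end-to-end
comparison runs ten simulated datasets at the default scale (~21k
probes × 20 samples), evaluates all twelve methods on each, and checks
that `dasen` outranks `raw` and `betaqn` on the final average score and
beats `raw` on DMRSE for both probe types in at least nine of ten
replicates; `scripts/acceptance.R` repeats that study and writes the
measured quantities.  These sizes keep a full run in the low minutes on
one CPU while leaving the method ordering stable across seeds.

## Known limitations

The offset estimator's resolution is bounded by the density grid; very
small Type I/II differences disappear below one grid step.  The
k-means genotype clustering assumes three reachable clusters near
canonical positions and will mislabel exotic allele-frequency
configurations (all samples homozygous, for instance, collapse to one
cluster).  Seabird needs both sexes and both X and non-X probes.  The
ranking procedure treats metrics as exchangeable (equal weight) and
datasets as exchangeable; neither choice is forced by the mathematics,
both are the simplest defensible defaults.  Missing intensities are
rejected rather than imputed — the QN engine's contract assumes complete
matrices.
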