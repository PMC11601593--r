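---
title: "Models and methods behind xqtlgxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xqtlgxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xqtlgxe)
```

This vignette is the package's own account of the statistical models it
implements: the cytometry-based quantification of ubiquitin–proteasome
system (UPS) activity and its genotype-by-environment (GxE) tests, the
pooled-sequencing QTL scan, the rule-based classification of QTL-level
GxE, and the synthetic-data generator that drives calibration. It also
records the design decisions taken where more than one reasonable choice
existed, and what the simulation results do and do not establish about
real data.

## 1. UPS activity from tandem-fluorescent-timer events

A tandem fluorescent timer (TFT) is a GFP–RFP fusion appended to a
degron-bearing reporter. GFP matures quickly, RFP slowly, so the
RFP/GFP ratio of a cell falls as the reporter is turned over faster;
−log2(RFP/GFP) is proportional to the degradation rate and independent of
expression level. The per-event pipeline is:

1. **Forward-scatter gating** (`gate_fsc()`): keep events with FSC within
   ±10% of the sample median, a cell-size proxy that removes debris and
   aggregates. Samples with a bimodal FSC distribution (incompletely
   budded cells under nitrogen limitation) are first cut at the kernel
   density valley between the two dominant modes and restricted to the
   lower-FSC mode, then the median window is applied within that mode.
2. **Raw activity** (`compute_activity()`): activity = −log2(RFP/GFP).
   Events with a nonpositive channel value are dropped (and counted)
   rather than floored: the logarithm is undefined there and flooring
   would bias ratios.
3. **Time detrending** (`detrend_activity()`): instrument drift over the
   acquisition window is removed by taking residuals of a per-sample
   loess regression of raw activity on acquisition time. The loess span
   (0.75, degree 1) is a default, exposed in the call, because no
   canonical value exists for this detrending; the result is insensitive
   to the span for the slow drifts it corrects. Residuals are re-centred
   on the sample mean so samples keep their location. Samples with fewer
   than 50 events, or with constant acquisition time, are mean-centred
   only and flagged.
4. **Quality control** (`qc_gfp_exclusion()`): a reporter-by-environment
   group is excluded entirely when any of its replicates has a median GFP
   strictly below the negative control's median — one dim replicate makes
   the whole group's reporter signal untrustworthy.

### GxE tests

For one reporter, the baseline environment and one comparison
environment, `test_gxe()` fits

    activity ~ strain * environment + (1 | replicate)

on per-cell activity by maximum likelihood (lme4), and tests each term by
a likelihood-ratio comparison against the model without it (interaction
against the additive model; each main effect against the additive model
without it). Two decisions here were genuinely open:

* *Per-cell values or replicate summaries?* The model is fit on per-cell
  activity with a replicate random intercept. Cells within a culture are
  correlated; the random intercept absorbs that, and per-cell fitting
  keeps the event-level information.
* *Replicate coding.* A replicate label "r3" in the BY strain does not
  describe the same culture as "r3" in RM, so by default replicate
  intercepts are coded nested within strain (`strain.replicate`
  groups); a crossed coding is available for designs where replicate
  labels are true batches shared across strains. The synthetic generator
  draws one replicate effect per strain-by-replicate pair, shared across
  environments, matching the nested analysis model — that alignment is
  what makes the type-I-error calibration meaningful.

"Significant GxE" uses a Bonferroni threshold α/m where the family size m
is configuration, not a constant (for a 40-test family at α = 0.05 the
threshold is 0.00125). Environment effect sizes (`strain_env_deltas()`)
are deltas of replicate medians — the median over replicates of the
per-replicate median activity, comparison minus baseline — tested with a
two-tailed Welch t-test on the replicate medians (family m′, e.g.
0.05/80 = 0.000625). Welch is used wherever a two-sample t-test is
called for: it converges to Student's test under equal variances and is
safe otherwise.

## 2. Pooled-sequencing QTL scan

### Allele-frequency tracks

Pooled allele depths at biallelic BY/RM markers arrive as VCF (per-sample
AD) or TSV. The VCF REF allele is taken to be the BY allele by default —
the reference genome is essentially the BY background — and the
orientation is explicit configuration. Markers with raw RM frequency
below 0.1 or above 0.9 are excluded per sample (boundary values kept;
such markers are dominated by mapping artefacts or segregation
distortion); zero-depth markers, where frequency is undefined, are
dropped first and counted separately. Whether the filter should be
applied per pool or jointly across a pool pair is not determined by the
data model; per-sample filtering was chosen as the less destructive
option, since the scan joins the two tables on the shared markers anyway.

Smoothed frequency tracks use a degree-1 local regression with a tricube
kernel of *fixed genomic bandwidth* (40 kb window by default) rather than
a fixed fraction of markers: marker density varies along the genome while
the downstream matching radius (100 kb) is genomic, so the smoothing
scale should be genomic too. The smoother is linear in the input, hence
commutes exactly with the mirror transform f → 1−f; fitted values are
clipped to [0, 1]. The effect-size track is ΔAF = smoothed high-pool
frequency − smoothed low-pool frequency; positive ΔAF means the RM allele
is enriched among high-UPS-activity cells.

### The LOD statistic

At each 100-bp bin, marker counts within a tricube kernel of half-width
20 kb (about 9 cM at 2,200 bp/cM — the scale over which strong linkage
makes neighbouring markers near-copies of each other) are aggregated into
local counts (k, n) per pool. Two models are compared by likelihood
ratio: the pools share one allele frequency, or each pool has its own.
With binomial log-likelihoods ℓ and MLE frequencies p̂ the score in log10
units is

LOD(t) = [ℓ(k\*ₕ; n\*ₕ, p̂ₕ) + ℓ(k\*ₗ; n\*ₗ, p̂ₗ) − ℓ(k\*ₕ; n\*ₕ, p̂₀) − ℓ(k\*ₗ; n\*ₗ, p̂₀)] / ln 10.

The starred counts implement the **effective pool size cap**: reads are
not independent observations of the underlying segregant population once
read depth approaches the number of cells sorted into the pool, so local
counts are shrunk to n\* = n·N/(n+N) (counts rescaled proportionally),
which saturates the information at N as depth grows. N defaults to 1,000.
Two properties make this scan testable: with half-width 0 and the cap
disabled it equals the closed-form single-marker binomial
likelihood-ratio statistic at every marker, and it is symmetric under
pool swap.

**The cap must not exceed the number of sorted cells.** N's role is to
bound the information a pool carries about the segregant population; a
20,000-cell pool analysed with N = 1,000 is conservative, but a 100-cell
pool analysed with N = 1,000 is anti-conservative — the dominant noise is
then the sampling of 100 segregants, which is shared across linked
markers and not reduced by read depth, and the model would understate it
roughly 2.5-fold in variance, inflating LOD scores genome-wide. The
pipeline therefore sets `effective_pool_size = min(N, cells per pool)`
whenever the pool cell count is known (as it always is for simulated
experiments). This was derived from the variance budget of the statistic,
not fitted to any benchmark.

### Calling

QTLs are maximal contiguous runs of bins with LOD ≥ 4.5. Each run yields
one call: the peak is the bin of maximal LOD (leftmost on ties — the
data at these depths cannot resolve sub-peak structure below the 100-kb
matching radius anyway), and the support interval extends from the peak
in both directions until LOD falls more than 2 below the peak, clipped at
track ends. The effect size attached to a call is the ΔAF value at the
marker nearest the peak. Coordinates are 1-based inclusive in tables and
converted to 0-based half-open only in bedGraph output.

## 3. Replicate reconciliation and GxE classification

QTLs are called independently per biological replicate. Two replicate
calls describe the same locus when they lie on the same chromosome with
peaks within 100 kb and the same ΔAF sign; matched pairs are averaged
(peak, interval bounds, LOD, ΔAF) and flagged replicated. Matching is
greedy by peak distance with each QTL used at most once — the
within-100-kb matching rule by itself does not determine what happens
when several candidates fall inside the radius, and greedy nearest-first
matching is symmetric in replicate order and deterministic (ties broken
leftmost).

For a reporter and an environment pair, every replicated QTL is
classified:

* **presence/absence** — no peak within 100 kb in either replicate of the
  other environment. Requiring detection in *both* replicates of one side
  and absence in *both* replicates of the other focuses on strong cases
  and guards against power artefacts.
* **sign change** — a peak within 100 kb in at least one replicate of the
  other environment with opposite ΔAF sign. When the other environment
  also shows a same-sign peak within the radius the comparison is still a
  sign change but flagged ambiguous.
* **no GxE (full / partial)** — a same-sign match in both (full) or
  exactly one (partial) replicate of the other environment.

Pairs in which both sides are replicated would be found from either side;
they are counted once. Comparisons default to baseline-versus-other
pairs, mirroring the design in which every environment is contrasted with
the same reference medium; arbitrary environment pairs are supported.

Genome-wide summaries bin peaks into consecutive 100-kb half-open
intervals from position 0 of each chromosome — 128 bins for the default
sacCer3 genome — assigning each QTL by its averaged peak and each GxE
comparison by the peak of its replicated QTL. A sign-change pair has two
peaks; the bin of their mean is used, an arbitrary but declared
convention for the rare pair spanning a bin boundary. Direction bias
(does the RM allele raise activity more often than chance?) is an exact
two-sided binomial test against 0.5; the clustering of GxE in QTL-rich
regions is a tie-corrected Spearman correlation across bins containing at
least one QTL; comparison with a reference study flags each QTL present
when any reference replicate peaked within 100 kb and contrasts LOD and
|ΔAF| of present versus absent groups by Welch t-tests.

## 4. The synthetic-data generator

The generator emulates the study's data-generating process at desk
scale:

* **Genotypes.** Each haploid segregant chromosome starts from a fair
  coin and accumulates crossovers as a Poisson process at one Morgan per
  220,000 bp (2,200 bp/cM); alleles alternate at breakpoints. Crossover
  interference is ignored — the Poisson process is the simplest model
  consistent with the single map-density parameter, and at the ≥20-kb
  scales the scan resolves, interference is immaterial. Marker maps are
  uniformly spaced by default (~2,000 markers genome-wide, configurable
  up to the study's 18,871); real marker maps are irregular, which the
  fixed-bandwidth smoother is designed to tolerate.
* **Phenotypes.** Additive RM-allele effects per environment, in units of
  the Gaussian noise SD (1 by default) — no phenotype-scale model beyond
  that is warranted by the data the pipeline sees. A locus absent from an
  environment's effect table contributes 0 there (presence/absence GxE);
  opposite signs encode sign-change GxE.
  `tail_effect_for_delta_af()` inverts the selection model analytically:
  given a tail fraction and the number of equal-effect loci it returns
  the additive effect whose expected high-minus-low pool divergence is a
  requested ΔAF.
* **Pools.** Tail selection takes the floor(n·q) largest and smallest
  phenotypes (ties by original index), or a quantile band such as the
  3–5% area used when an outer tail cannot be re-collected. Sequencing
  draws Poisson depth per marker and binomial RM reads at probability
  f(1−ε) + (1−f)ε — a symmetric per-read allele flip (ε = 0.002 by
  default), adequate for biallelic SNP counts.
* **Fast conditional path.** For architectures with at most one planted
  locus per chromosome, `simulate_mapping_experiment()` draws the
  planted-locus alleles for the whole population, selects the tails on
  phenotype, and then simulates full marker genotypes *only for sorted
  cells*, conditional on their planted-locus alleles, by running the
  allele Markov chain outward from each locus (Haldane transition
  probabilities). This is exact, not approximate: the allele process
  along a chromosome is a stationary two-state Markov chain, and
  selection acts on the planted alleles plus independent noise, so the
  conditional law of all other markers is untouched by selection. The
  generic path materialises every genotype and handles arbitrary
  architectures.
* **Cytometry events.** True activity per event = strain-by-environment
  mean + replicate effect + drift(time) + Gaussian event noise; GFP is
  log-normal about an intensity scale, RFP = GFP·2^(−activity), FSC
  unimodal Gaussian or a two-component mixture. Replicate effects are
  drawn once per strain-by-replicate pair and shared across environments
  (a batch-like structure; see §1 on why this matches the analysis
  model). Seeds are explicit everywhere; the pipeline streams per-stage
  sub-seeds from one master seed so stages can be re-run in isolation,
  and all outputs are bit-reproducible under a fixed seed.

## 5. Simulation scales used by the test suite

The package's calibration claims are established on the following
problem sizes, chosen to exercise the study-scale mechanics while
remaining desk-computable:

* **False discovery rate.** 50 mapping experiments on the 16-chromosome
  genome with ~2,000 markers: 5,000 segregants, 2% tails (100-cell
  pools), ~100× depth, two planted loci of expected divergence 0.3 per
  run. With the cap at the sorted-cell count the scan is conservative at
  this pool size: calls are few but essentially never false (measured
  FDR ≤ 0.5%, usually 0). The occasional "false" call is in fact a
  linkage shoulder of a planted locus whose peak wandered beyond the
  100-kb radius.
* **Recovery.** 100 runs with one planted locus of expected divergence
  0.3, pools of 1,000 cells (10% tails of 10,000 segregants) so the
  sorted-cell count matches the default effective pool size — the regime
  the cap was designed for — and a ~5,000-marker map: peak-position
  accuracy is set by marker density, and at the ~2,000-marker density the
  positional wander (not power) is what fails a 30-kb localisation
  demand; 5,000 markers is the desk-scale step toward the study's
  18,871. The planted locus must be called within 30 kb in both
  simulated replicates.
* **Classifier.** 100 runs, three loci on three chromosomes (no-GxE,
  baseline-only, sign-flip), two environments × two replicates each,
  pools of 1,000; the planted category must be recovered at its locus.
* **Flow calibration.** 500 null experiments (no strain, environment or
  interaction effect; replicate SD 0.1, event SD 0.5, 8 replicates × 500
  events per sample) for the interaction test's type-I error at α = 0.05,
  and a planted 0.5-unit linear drift with event SD 0.1 for the
  detrending check.

What these simulations do **not** show: performance under real marker
maps (clustered, with gaps), depth heterogeneity and mapping bias along
the genome, segregation distortion, growth differences between sorted
pools, cytometer spillover (no compensation is attempted), or
magnitude-only GxE, which the classification deliberately does not search
for. The LOD values of this scan are also not expected to numerically
match other pooled-sequencing mapping programs, only to rank loci
similarly; thresholds were kept at the field-standard LOD ≥ 4.5 with
2-LOD intervals.

## 6. Numerical conventions and degenerate inputs

* Boundary conventions: the 0.1/0.9 frequency filter keeps boundary
  values; the 100-kb matching radius is inclusive; genomic bins are
  half-open [k·100kb, (k+1)·100kb); peak ties break leftmost; support
  intervals clip at track ends.
* LOD is clamped at 0 against floating-point underflow; bins with zero
  kernel weight in either pool score 0; the 0·log 0 = 0 convention is
  applied throughout the binomial likelihoods.
* Degenerate inputs fail loudly (empty pools, missing negative control,
  off-genome peaks, fewer than two replicates) or pass through flagged
  (sparse chromosomes unsmoothed, sub-50-event samples mean-centred,
  missing ΔAF near a peak).
* The one-QTL-per-suprathreshold-run rule means a deep LOD valley between
  two nearby loci yields two calls, but sub-threshold dips inside one
  locus's shoulder can also split a call; downstream reconciliation at
  the 100-kb radius absorbs these splits.
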