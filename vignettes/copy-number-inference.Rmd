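---
title: "Inferring tumor purity, ploidy and allele-specific copy number from low-coverage tumor/normal sequencing"
author: "PeriodicCN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number inference with PeriodicCN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A sequenced tumor sample is a mixture: a fraction $p$ (the *purity*) of
tumor cells whose genome carries somatic copy-number alterations (SCNAs),
diluted with normal cells that are diploid everywhere. From a matched
tumor/normal whole-genome pair, PeriodicCN estimates

* the tumor purity $p$,
* the tumor ploidy $\pi$ (length-weighted mean copy number of the tumor
  genome),
* the total copy number (TCN) of every genomic segment, with a
  clonal/subclonal label, and
* the major/minor allele copy numbers (MACN, mcn) of clonal segments.

It is designed for the regime where per-position evidence is weakest:
2--10X coverage and purity down to 0.1, where methods that genotype
individual sites run out of power. Everything works from two count tables
— per-bin read counts and allele counts at heterozygous germline SNVs
(HGSNVs) — so no BAM access is needed at analysis time.

# The model

## Tumor read enrichment and its lattice

The per-bin **Tumor Read Enrichment** is the double-normalized depth ratio

$$ \mathrm{TRE}_i \;=\; \frac{t_i / R_t}{n_i / R_n}, $$

with $t_i, n_i$ the tumor/normal counts of bin $i$ and $R_t, R_n$ the
genome totals. Library size cancels, the matched normal absorbs shared
biases (mappability, GC to first order), and the normal-count-weighted mean
TRE is exactly 1. In a sample of purity $p$, a clonal segment of copy
number $c$ has expectation

$$ E[\mathrm{TRE}] \;=\; \frac{p\,c + 2(1-p)}{p\,\pi + 2(1-p)}
   \;=\; 1 + \Delta\,(c - \pi), \qquad
   \Delta = \frac{p}{p\,\pi + 2(1-p)}. $$

Integer copy states therefore place segment TREs on an evenly spaced
*lattice* with spacing $\Delta$: the histogram of TRE values of a genome
with SCNAs is periodic, and the period determines purity once ploidy is
anchored. This is the core identifiability device: no individual bin needs
to be informative, only the comb structure of the histogram.

## Pipeline

1. **TRE and smoothing** (`computeTRE`, `smoothTRE`). Bins with normal
   count below `minNormalCount` (default 5) are masked. A Gaussian kernel
   (sd 3 bins, truncated at 4 sd) smooths the per-bin Poisson noise;
   smoothing reduces pointwise variance by $\sum_k w_k^2 \approx 0.094$
   but adds no information — a fact the segmenter must account for (below).
2. **Segmentation** (`segmentGenome`). A sparse-Bayesian-learning (SBL)
   changepoint model over the step basis — the published GADA algorithm —
   proposes breakpoints; backward elimination removes those whose
   mean-difference $t$ statistic falls below `tMin` (default 4), then
   segments shorter than `minSegBins` (default 10) are merged away.
3. **Period detection** (`treHistogram`, `treAutocorrelation`,
   `candidatePeriods`). The histogram of the segment-denoised TRE track is
   autocorrelated; local ACF maxima whose implied period lies inside the
   box allowed by purity $\in [0.05, 1]$ and ploidy $\in [1.2, 6]$ become
   ranked period candidates. Candidates near integer multiples of stronger
   candidates are kept but down-ranked as harmonics.
4. **Lattice mixture EM** (`emFit`, `candidateFits`, `selectModel`).
   Segment mean TREs are modelled as a Gaussian mixture over copy states
   $c = 0..8$ with means tied to the lattice, variances $\sigma^2/L_s$
   scaled by segment size, and a uniform outlier component. Each period
   candidate (and its sub-multiples) seeds EM runs from several ploidy
   anchors; the Bayesian Information Criterion picks the final model.
5. **Calls** (`callTCN`, `assignMACN`). Segments land on a continuous copy
   number $\hat c_s = \pi + (\bar{\mathrm{TRE}}_s - 1)/\Delta$; those
   within `clonalTol` (default 0.2) of an integer are clonal with that
   integer TCN, the rest are subclonal with $\hat c_s$ rounded to one
   decimal — a copy number averaged over tumor subclones. Clonal segments
   then receive an allele split from the LAR model below.

## Allele-specific copy number from LARs

At a heterozygous germline SNV with tumor allele counts $(t_a, t_b)$ and
normal counts $(n_a, n_b)$, the **log ratio of allelic-coverage ratios** is

$$ \mathrm{LAR} = \ln \frac{t_a / t_b}{n_a / n_b}. $$

For a clonal segment with allele split $(M, m)$, tumor reads carry the
major allele with probability
$f = (pM + 1 - p) / (p(M+m) + 2(1-p))$. Because the germline labels are
arbitrary, LARs follow an equal-weight two-component mixture at $\pm\mu$.

The subtle point is $\mu$. SNVs with a zero allele count have no finite
LAR and are excluded, so the observable tumor term is the expectation of
$\ln(X/(n-X))$ under a Binomial$(n, f)$ *truncated* to $1 \le X \le n-1$.
At depth 4--10 this truncation pulls the component mean far below the
naive logit $\ln(f/(1-f))$; ignoring it degrades allele-specific calls by
an order of magnitude at low coverage. `correctedLarMean` computes the
correction by exact enumeration over the segment's empirical depth
distribution (no parametric depth assumption), and the counterpart
truncated term of the normal sample (zero by symmetry at $f=1/2$) is
subtracted.

`fitMACN` scores every split $(M, m)$ with $M + m = \mathrm{TCN}$,
$M \ge m$, by a likelihood with three ingredients:

* component means **and** variances are the exact truncated-binomial
  moments at each SNV's own depth pair, with a single scale factor fitted
  per candidate. Pooling SNVs of different depths under one variance makes
  the pooled LAR distribution heavy-tailed, and a symmetric two-mode
  mixture then spuriously beats the true balanced model — depth
  stratification removes that degeneracy;
* each in-segment SNV contributes a Bernoulli term for whether it was
  zero-excluded, with probability computed from its own tumor *and* normal
  depths. This term is what identifies complete LOH in high-purity samples,
  where nearly every SNV is excluded ($f \to 1$);
* segments with fewer than `minSnvs` (default 20) informative SNVs get no
  allele call. SNVs need depth $\ge$ `minDepth` (default 4) on both sides.

MACN is only estimated for clonal segments: a subclonal region averages
different allele configurations across subclones and admits no single
integer split.

# Design choices and their reasons

**Why detect the period on the segment-denoised track.** The histogram of
per-bin smoothed TREs has peaks of width $\approx$ the smoothed per-bin
sd. At 2X coverage that width exceeds the lattice spacing for mid purity,
and the autocorrelation of the raw-bin histogram carries no periodicity at
all. Replacing each usable bin's value by its segment mean shrinks peak
widths by $\sqrt{L_s}$ and makes the comb resolvable at every coverage
studied; `treHistogram` itself is unchanged and can be applied to any TRE
track.

**Noise calibration on smoothed tracks.** Smoothing shrinks pointwise
noise but correlates neighbours; treating the smoothed sd as independent
per-bin noise makes every correlated wiggle a "significant" step. Both the
SBL likelihood and the elimination $t$ statistics therefore use the raw
per-bin sd, recovered from the smoothed-track MAD via the kernel's lag-1
autocorrelation and variance attenuation (both known exactly, since the
kernel is ours). For segment-scale contrasts this is the statistically
correct scale: the variance of a segment's mean is the same before and
after smoothing.

**Heteroscedastic elimination.** TRE is a ratio of Poisson counts, so its
variance grows with its level: relative to level 1 (where the global sd is
estimated), $\mathrm{Var} \propto m(1+m)/2$. With a constant-variance
statistic, high-copy regions are over-split by roughly $\sqrt{3}$, and the
resulting selection-biased fragments systematically mislead the lattice
fit. `backwardEliminate` applies the level factor when called by the
pipeline (`levelVar = TRUE`); the exported function defaults to the
classical homoscedastic statistic.

**SBL sparseness.** The hierarchical-prior parameter is `sblA = 0.2`. At
0.5 the stage-1 model is sparse enough to merge adjacent CNAs outright at
2X coverage (steps of three standard errors lost), which no downstream
stage can repair; 0.2 over-proposes mildly and leaves the pruning to the
$t$-based elimination, which is the division of labour the two-stage
design intends.

**Shift degeneracy and model selection.** The lattice model is invariant
under shifting every copy assignment by $\pm 1$ (purity and ploidy move
together) unless a copy-0 or copy-8 segment pins the ends. `selectModel`
therefore treats fits within 2 BIC units as tied and prefers, in order:
the fit whose *genome-mass-dominant* component is copy 2, the ploidy
closest to 2, the higher purity. The dominant-state rule encodes the
biological prior that the most common state of a tumor genome is the
ancestral diploid one; for genomes after a clean whole-genome duplication
it would mislead — but such genomes present no usable periodicity anyway.

**Outlier component and floors.** Off-lattice segment means exist for
legitimate reasons (subclonal regions, boundary smear). Without an outlier
component they are captured by whichever shifted lattice has a spare edge
component, corrupting model choice; with an unbounded one, EM can collapse
(outlier absorbs everything while $\sigma$ races to its floor on long
segments). Hence: uniform outlier with weight capped at 0.25, and a floor
of $2\times 10^{-3}$ TRE units on the standard error of any segment mean —
segment means carry systematic wobble (boundary contamination, residual
ratio bias of order $1/\lambda$) that no amount of length removes.

**EM parametrization.** The M step fits the lattice as intercept plus
slope by responsibility-weighted least squares, an exact M step, so the
log-likelihood is non-decreasing (asserted in the tests). Ploidy is
reported as the lattice point mapped to TRE 1, which coincides with the
weighted mean copy number because the weighted mean TRE is 1 by
construction.

**What BIC compares.** All candidate fits share one parameter count
($c_{\max}+1$ free mixture weights, intercept, spacing, noise sd), so BIC
differences are likelihood differences; the criterion's role is to stop
harmonic and sub-multiple lattices from overfitting, not to choose model
size.

# The simulator

`makeTruthProfile` draws 21 non-overlapping CNAs with copy numbers in
$\{0..8\}\setminus\{2\}$, lengths uniform within 5--135 Mb scaled to the
genome (0.5--13.5 Mb on the default 300 Mb three-chromosome layout),
rescaled so the affected fraction is $0.28 \pm 0.01$; each CNA gets a
consistent $(\mathrm{macn}, \mathrm{mcn})$ split. `simulatePair` then
emulates proportional mixing at the count level: normal bins are
Poisson with mean depth equal to the nominal coverage; tumor bins scale
that rate by $(p\,c + 2(1-p))/2$; 100,000 SNV loci (the full-genome
density of "over one million" HGSNVs, preserved on the scaled genome) get
binomial allele counts at the mixture fraction $f$, with the major allele
assigned to a random germline allele per locus. `twoSubcloneTruth` builds
a 0.6/0.4 two-subclone design whose six differing regions include one
engineered so the population-average TCN is exactly 4 ($0.6 \cdot 2 + 0.4
\cdot 7$) — a subclonal region that is legitimately called clonal.

What the simulator does *not* emulate: read-level sequencing error, GC and
mappability bias, alignment artifacts, germline CNVs in the normal, or
over-dispersion beyond Poisson. Shared tumor/normal biases cancel in TRE
by construction here, which flatters the method relative to real data;
passing benchmarks on these simulations demonstrates the statistical
machinery, not robustness to library artifacts. The simulation does
reproduce one bias of real count data faithfully: the ratio estimator's
$E[1/n]$ inflation, which is why purity estimates carry a small positive
bias at low coverage (about $+0.01$ at 5X for purity 0.5), of the same
size as reported by comparable tools.

# Problem sizes and determinism

The bundled benchmarks run on the 300 Mb scaled layout at 1 kb bins
(300,000 bins, 100,000 SNVs); one simulate-plus-infer cycle takes roughly
10--15 s on a single core, with the SBL stage in compiled code (O(active
set) per iteration via the tridiagonal structure of the step-basis Gram
inverse). All stochastic steps take explicit integer seeds and are
bit-reproducible; `runBenchmark` records per-cell failures rather than
aborting.

```{r example, eval = FALSE}
library(PeriodicCN)
lay   <- scaledGenomeLayout()
truth <- makeTruthProfile(lay, seed = 7)
sim   <- simulatePair(truth, coverage = 5, purity = 0.5, seed = 7)
res   <- runInference(sim$coverage, sim$snvs)
purity(res); ploidy(res)
evaluateCalls(truth, segmentCalls(res), lay, "tcn")$fullc
```

# Known limitations

* A genome with little or no copy-number alteration produces no periodic
  TRE pattern; the pipeline signals this (`noPeriodicity` / `noModel`
  conditions) rather than guessing.
* A perfectly clean whole-genome duplication is indistinguishable from a
  diploid genome in TRE and would be resolved toward the diploid
  interpretation.
* Allele-specific inference needs roughly 1X of tumor-derived coverage
  (coverage $\times$ purity); below that the package warns and calls
  degrade, mirroring the behaviour of the wider tool class.
* The normal is assumed diploid everywhere; germline CNVs will produce
  locally wrong calls.
* Subclone decomposition (how many subclones, at what fractions) is out of
  scope; subclonal regions are reported with averaged non-integer TCN.
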