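---
title: "Why cohort-normalized CNV calling misses a common deletion, and how continuous LRR association rescues it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Why cohort-normalized CNV calling misses a common deletion, and how continuous LRR association rescues it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A full-gene deletion with a homozygous-null frequency near 50% — the classic
example is the glutathione S-transferase mu 1 gene on 1p13.3 — is about the
easiest copy-number variant imaginable for a targeted assay, yet genome-wide
SNP-array callers can miss it entirely. The reason is not the hidden Markov
model but the normalization that feeds it. The Log R Ratio at a probe is

$$\mathrm{LRR} = \log_2\!\frac{R_\mathrm{obs}}{R_\mathrm{exp}},$$

where \(R_\mathrm{obs}\) is the sample's total two-channel intensity and
\(R_\mathrm{exp}\) is the intensity *expected for a two-copy sample*, read off
the probe's genotype clusters. When the clusters are fitted from the analysis
cohort itself and half of that cohort is homozygously deleted, the clusters sit
on the deleted samples: \(R_\mathrm{exp}\approx R_\mathrm{obs}\) for a null
individual and its LRR lands near 0 instead of near the 0-copy state mean
\(-3.53\). The caller, seeing diploid-looking signal, calls nothing. The
deletion is still recoverable from the *continuous* signal: disease can be
regressed on the per-probe LRR directly, or a latent-class mixture model can
genotype and test in one step.

This package rebuilds that whole comparison as a tested simulation study:
generator, normalization in both a cohort and a reference mode, PennCNV-style
sample QC, a 5-state Viterbi caller, and three association strategies.

## The synthetic cohort

`simulate_cohort()` draws a source population, assigns each sample a
locus-wide copy number \(c \in \{0,1,2\}\) with class probabilities
\((0.5296, 0.3810, 0.0894)\) — the empirical control frequencies for the
European-ancestry null polymorphism — simulates disease retrospectively, and
then fixes the margins at 773 cases and 759 controls, the hospital-based
design's sample sizes. Two disease models are available:
`trend` (per-copy log-odds, default \(\log 0.74\)) and `two_class`
(carrier-vs-null log-odds, default \(\log 0.66\)). Covariates (gender, age,
region, smoking) follow fixed fixture conventions with zero disease effect by
default; they exist so that the adjusted analyses exercise real design
matrices, not because the generator claims their distributions.

Noiseless channel intensities at a probe with full signal \(F\) are

$$X = F\left(\tfrac{c-b}{2} + \tfrac{f}{2}\right),\qquad
  Y = F\left(\tfrac{b}{2} + \tfrac{f}{2}\right),$$

with \(b\) the number of B alleles among the \(c\) carried copies and
\(f = 0.095\) the residual background fraction, chosen by solving
\(\log_2 f/(1+f) = -3.53\) so that a reference-normalized null sample sits
exactly at the caller's 0-copy state mean.

### The noise model

Noise enters through two components per sample-by-probe cell:

* a **shared multiplicative gain** \(2^{\varepsilon}\),
  \(\varepsilon \sim N(0, 0.10)\), applied to both channels — it moves total
  intensity but not the allelic angle, and is by construction the residual
  per-probe LRR noise (log2 units);
* an **antisymmetric split** \(\pm\delta\), \(\delta \sim N(0, 0.033F)\),
  moving signal between the channels — it moves the angle but not the total.

Negative channel values are truncated at zero. This structure is the minimal
one that reproduces, simultaneously, four facets of real array data at such a
locus: per-probe LRR standard deviations of order 0.1–0.3; a near-uniform BAF
for homozygously deleted samples (their residual background, of the same order
as the split noise, is allocated almost arbitrarily between the two dyes);
tight canonical BAF bands for diploid samples; and the compression phenomenon
itself. Independent additive noise on each channel cannot do this: any
per-channel noise large enough to spread a null sample's BAF across the unit
interval is, at the null sample's total signal of \(0.095F\), an LRR noise of
two to three log2 units — an order of magnitude above the printed per-probe
variability, and it floods the caller with spurious deletion evidence in
*both* normalization modes. The split sd 0.033 was fixed so that the
background-probe BAF drift stays comfortably inside the 0.002 QC threshold
(at 0.05 it straddles it); the gain sd 0.10 doubles as the residual probe
noise of the concordance fixture below.

## Normalization and the compression mechanism

`compute_polar()` maps channels to \(\theta = (2/\pi)\arctan(Y/X)\) and
\(R = X+Y\). `fit_cluster_model()` partitions samples at the fixed thresholds
\(\theta = 1/3, 2/3\) into AA/AB/BB candidates; each cluster's
\(\theta\)-center is the member median and its expected intensity
`r_expected` is the **windowed mode** of member \(R\): the center of the
densest blob (most neighbours within \(\pm 5\%\) of the cluster median), with
a plain median shortcut for tight unimodal clusters. The windowed mode is the
load-bearing choice. At this locus every \(\theta\)-bin holds two blobs of
*comparable mass* — deleted samples whose angle wandered there, at
\(R \approx 0.1F\), and genuine genotype clusters at \(R \approx 0.6F\) or
\(1.1F\) — so a median is a coin flip between them, seed by seed. The deleted
blob, however, is always far denser (tight multiplicative spread at low
intensity), and latching the densest blob is exactly the mechanism by which a
clustering-based normalization pipeline, confronted with a majority-deleted
locus, sets \(R_\mathrm{exp}\) from deleted samples.

`compute_lrr_baf()` interpolates `r_expected` linearly in \(\theta\) between
cluster centers (constant beyond the outermost), computes
\(\mathrm{LRR} = \log_2 R/R_\mathrm{exp}\) (floor \(-10\) for zero-intensity
cells, flagged), and maps \(\theta\) through the centers to canonical B-allele
fractions 0, 0.5, 1 (clipped). No special-casing is needed for deleted
samples: their noise-driven \(\theta\), pushed through the same
interpolation, *is* the near-uniform BAF.

On the default fixture this yields (stage-2 analysis table): cohort-mode mean
locus LRR of \(+0.03\) (null), \(+2.64\) (one copy), \(+3.53\) (two copies) —
every deleted class pulled to or above zero — versus reference-mode
\(-3.48 / -0.85 / +0.02\). Note the compression is one-sided: only classes
sharing clusters with the deleted majority are rescaled toward zero. The real
platform's proprietary 2-D clustering and affine rescaling compress the
carrier classes much further (printed class means \(-0.10 / 0.08 / 0.17\));
we make no attempt to replicate those internals, only the sign structure, the
ordering, and the zero-call consequence, which are what the comparison needs.
The printed class means are used directly, though, by the *summary-level*
concordance fixture (`simulate_lrr_fixture()`), which generates locus LRR at
exactly those three levels with residual per-probe sd 0.10.

## Sample QC

`qc_metrics()` implements the four PennCNV-style per-sample statistics with
the published exclusion thresholds: LRR sd over all probes (\(> 0.28\)
fails), median BAF over the heterozygous band \(\mathrm{BAF}\in(0.25,0.75)\)
(outside \([0.45, 0.55]\) fails — restricting to the band makes the statistic
track the heterozygote band center rather than the 0/1 atoms), BAF drift as
the mean squared distance to the nearest of \(\{0, \tfrac12, 1\}\)
(\(> 0.002\) fails), and a wave factor: the population sd of per-window
*median* LRR over non-overlapping 50-probe windows (outside \([-0.04, 0.04]\)
fails). The median window summary matters on a small panel: our locus is 5 of
2005 probes (versus 5 in a million on the real platform), and with window
means a carrier's genuinely elevated locus LRR masquerades as a genome-wide
wave and excludes almost every carrier — a statistic intended to catch waves
must not be driven by one real CNV. On the default fixture all samples pass
(stage-3 table), so the calling contrast is never an artifact of QC.

## The caller

`hmm_params()` defines a 5-state HMM (copy numbers 0–4) over position-ordered
probes. LRR emissions are Gaussian with means \((-3.53, -0.66, 0, 0.40,
0.68)\); the paper-facing means are fixed, while the sds \((1.0, 0.30, 0.18,
0.22, 0.24)\) are package defaults chosen so the state bands do not overlap at
the means (documented as tunable). BAF emissions are equal-weight mixtures of
truncated Gaussian bands (sd 0.04) at each state's canonical B-allele
fractions, uniform for the 0-copy state. Both emissions carry a 1% uniform
outlier component (the LRR one on \([-6, 6]\)); these mirror PennCNV's own
error terms and are not cosmetic. Without the LRR outlier term the 0-copy
state, having the widest sd, silently becomes the sink for *any* extreme
value — including the strongly positive carrier LRR under cohort
normalization — and the caller "finds" hundreds of deletions in samples whose
signal is two log units above diploid. Transitions are a fixed sticky prior
(stay 0.9996, off-diagonal mass split equally) and the initial distribution
favours diploid \((0.01, 0.02, 0.94, 0.02, 0.01)\); distance-dependent
transitions add nothing at a single locus. Viterbi decoding is exact dynamic
programming in log space, vectorized across samples, with ties broken toward
the diploid state and then toward higher copy number — a conservative,
deterministic convention. `extract_deletions()` reports maximal sub-diploid
runs of at least 3 probes; the 5-probe locus clears the floor.

Calling behaviour must be assessed with the locus embedded in flanking
diploid probes: on a bare 5-probe chromosome a sub-diploid path pays only the
initial prior (~94:1), not the two transition penalties (~\(10^8\)), and weak
BAF coincidences can flip single samples. All calling experiments therefore
keep at least 100 background probes around the locus; the replicate sweeps use
that size, and single runs use the full 2005-probe panel.

## Association

Three estimators, all sharing the same IRLS logistic core (`fit_logistic()`,
convergence at coefficient change \(<10^{-8}\), Wald intervals, fits with any
coefficient beyond \(\pm 15\) flagged as quasi-separated):

1. **Per-probe LRR regression** (`probe_lrr_tests()`): disease on the LRR at
   each of the five locus probes, adjusted for gender, continuous age,
   region, smoking. The odds ratio is per unit LRR, so its magnitude depends
   on the LRR scale of the normalization; the sign and the test are what
   transfer.
2. **Trend test** (`trend_test()`): disease on called copies as a linear
   per-copy term, same adjustment — the analysis one would run on a reliable
   targeted assay.
3. **Joint latent-class mixture** (`fit_joint_mixture()`): the five probes
   are summarized per sample (first principal component of the standardized
   probe matrix, sign-anchored to mean LRR; provisional classes from a 1-D
   K-component Gaussian fit to the score; a linear discriminant for those
   classes applied to the probe matrix), then a K-component Gaussian mixture
   with component-specific variances models the summary while disease follows
   a logistic model in which carrying any gene copy — membership in any
   component other than the lowest-mean, homozygous-null one — enters with
   one log-odds parameter, alongside the categorical covariates (age as
   quartile classes: the mixture model adjusts for qualitative variables
   only, an asymmetry kept deliberately). Null (shared mixing, covariate-only
   disease model) and alternative are both fitted by EM and compared by a
   1-df likelihood-ratio test.

EM numerics: component sds are floored at \(10^{-3}\) of the data sd to block
degenerate spikes; 30 starts (quantile-spread means, jittered) are run for 15
short iterations and the best is polished to tolerance \(10^{-8}\) (at most
500 iterations); the alternative model's start list always includes the null
solution with a zero association parameter, so its log-likelihood can never
fall below the null and the LRT is nonnegative by construction; components
are relabeled by ascending mean after every M-step; the weighted logistic
M-step takes a few warm-started IRLS steps (a generalized EM update — the
observed-data log-likelihood trace is checked to be non-decreasing).
K is fixed at 2 for the default locus (the real analysis clustered samples
into null vs non-null); BIC is reported so K can be compared when the locus
warrants it.

## What the simulation study shows, and at what sizes

The test suite and `scripts/acceptance.R` recompute everything from scratch.
Problem sizes are the package's own choices, balancing Monte Carlo error
against runtime: 20 replicate cohorts for the zero-call robustness sweep
(1532 samples, locus plus 100 flanking probes); 200 replicates for the trend
recovery study (mean estimate within \(\pm 0.02\) of the generating OR 0.74,
single runs within \(\pm 0.08\)); 100 replicates for the mixture recovery
study (mean within \(\pm 0.08\) of OR 0.66, LRT power at the 5% level of at
least 95%); 2000 phenotype replicates for the per-probe type-I error, which
must stay inside the 99% binomial band around 0.05; and exhaustive-enumeration
oracles for the Viterbi decoder (all paths on up-to-6-probe instances) plus
grid-search oracles for the logistic and mixture likelihoods.

## Limitations

The generator models one locus-wide deletion shared by all five probes — no
breakpoint variation, no linkage disequilibrium with flanking SNPs, no
multi-allelic states, no plate or GC-wave structure, and covariates carry no
confounding by default. The cohort-mode compression reproduces the mechanism
and its consequences, not the proprietary normalization's exact output scale;
per-unit-LRR odds ratios are therefore not numerically comparable to an
analysis of the real platform's LRR, while class frequencies, trend and
carrier odds ratios, and concordance are. Passing tests here show the
pipeline's statistics behave as designed under this generator; they cannot
certify behaviour under real-array artifacts the generator does not emulate.
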