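---
title: "Modelling V(D)J deletion depth signals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling V(D)J deletion depth signals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjlens)
```

## The signal

Every T or B cell carries a somatic deletion at its receptor locus: V(D)J
recombination joins one V segment to one J segment and excises everything in
between, on both alleles of the expressed locus. In bulk whole-genome
sequencing of a mixed cell population this leaves a dip in read depth across
TCRA, TCRB, TCRG and IGH that deepens towards the locus interior, because a
position between a given V and J is missing from every lymphocyte whose
rearrangement spans it. Class-switched B cells additionally delete IGH
constant genes upstream (in switch order) of their expressed isotype, on one
allele. The depth dip therefore encodes, quantitatively: the lymphocyte
fraction of the sample, the V and J segment usage of its repertoire, and (at
IGH) the isotype composition of its B cells. vdjlens recovers all three.

## Forward model

Let positions be mapped onto a *deletion axis* that runs V-region-first
(reverse loci such as IGH and TCRG are flipped at load time, so everything
downstream is orientation-free). For V usage $p$ and J usage $q$ (probability
vectors over segments), the probability that axis position $x$ is excised in
a rearranged cell is

$$F(x) = \Big(\sum_{v:\ \mathrm{end}(v) < x} p_v\Big)
         \Big(\sum_{j:\ \mathrm{start}(j) > x} q_j\Big),$$

a piecewise-constant curve that rises through the V region, equals 1 between
the last V and the first J, and falls through the J region. V-J independence
is assumed; exact pairing is not identifiable from marginal depth. With
tumour purity $\rho$ and local tumour copy number $n_t$ (germline $n_g = 2$),
the flank copy number is $C = \rho n_t + (1-\rho) n_g$ and the expected copy
number at $x$ for lymphocyte fraction $f$ (of **all** cells) is

$$\mathrm{CN}(x) = C - a\, f\, F(x), \qquad a = 2,$$

since both alleles are deleted per rearranged cell. Observed depth is
modelled as Poisson around $D \cdot \mathrm{CN}(x)/C$ times a smooth GC bias.
At IGH constant genes the V(D)J term is replaced by the class-switch term
$a_{cs} f_B S(g)$ with $a_{cs} = 1$ (one allele undergoes switching) and
survival $S(g) = \sum_{c:\,r(c) > r(g)} \pi_c$ for isotype mixture $\pi$ over
the eight switch classes (IgM/IgD share rank 0).

Fixing $a = 2$ for all loci means TCRB fractions under-read the true T cell
fraction where allelic exclusion leaves one allele unrearranged; this
behaviour is reported rather than corrected, and no per-locus allele count is
modelled.

## From coverage to a ratio profile

Per-base depth over each locus window (1-based inclusive coordinates
throughout) is averaged in 500 bp bins. 500 bp leaves at least two bins
between most neighbouring segment boundaries of the densest locus while
keeping per-bin Poisson noise workable at 5x; the paper-facing quantities are
pooled across bins, so results are insensitive to moderate changes in bin
size. A LOESS trend (span 0.75, weighted by bin footprint) of log2 depth on
GC is fitted on *baseline* bins — flanking windows that no rearrangement can
delete — and applied everywhere, clamped to GC in [0.25, 0.75]; a GC spread
below 0.05 degenerates to the identity with a warning. The log2 read-depth
ratio (RDR) is the corrected bin depth over the mean corrected baseline
depth. Zero-coverage bins receive a 0.5-read pseudo-count; bins within 250 bp
of a segment edge are down-weighted by 0.1 because their mixed copy-number
content straddles a step. Bin weights are proportional to the expected
undeleted read count, i.e. roughly inverse-variance for the transformed
signal.

## The two-stage isotonic estimator

Each bin's RDR is transformed to $d(x) = C(1 - 2^{\mathrm{RDR}})/a$, a
plug-in estimate of $f F(x)$. Bins are pooled between consecutive segment
boundaries on the deletion axis ($F$ is constant within each pool). The
pooled values are then projected onto the model's shape: non-decreasing
across the V region, a common plateau $m$ over the interior, non-increasing
across the J region, all within $[0, m]$. For fixed $m$ the solution is the
clipped weighted pool-adjacent-violators fit, so the profile objective in $m$
is convex and is minimised by one-dimensional search on $[0, \min(1, C/a)]$.
The plateau is the fraction estimate; V usage is read off the isotonic
increments at each V boundary (J usage from the decrements), renormalised to
the simplex with entries below $10^{-6}$ truncated. This construction is
convex and deterministic — no initialisation or tie-break sensitivity — and
on noiseless toy data it attains the global weighted least-squares optimum,
which the test suite certifies against an exhaustive grid search.

Fractions below $10^{-4}$ are reported as zero with a flag and uniform usage
vectors, since usage is undefined without signal. Uncertainty comes from a
bootstrap over bins resampled within pools (default 200 resamples, seed
1234); the percentile interval is widened, if necessary, to contain the point
estimate.

### Usage moderation

At realistic conditions (for example $f = 0.2$ at 30x with 40 V segments)
the raw isotonic increments carry substantial Poisson noise: each segment's
usage is a difference of two pool means. vdjlens therefore applies
empirical-Bayes moderation: the noise variance of each increment is
estimated from within-pool scatter, and the usage vector is shrunk towards
uniform by the estimated noise share of its between-segment variance —
exactly zero shrinkage on noiseless data, heavy shrinkage when the observed
spread is explained by noise. This is the same moderation philosophy used
throughout this field's differential-analysis packages, applied to a
simplex. Diversity statistics consequently tend towards their uniform
ceiling in low-information samples, a conservative direction for
between-sample comparisons.

## Class switching and germline CNVs

Class-switch breakpoints fall in switch regions just upstream of each
constant gene, so every position between two consecutive switch regions
shares the survival of the enclosed gene. Each of the eight switch ranks is
therefore estimated from its whole inter-switch interval — several-fold more
reads than the gene bodies alone. Conditional on the IGH fit's $f_B$, the
interval RDRs give plug-in survivals, fitted non-increasing along switch
order by weighted PAVA and clipped to $[0, 1]$; isotype proportions are the
decrements. Two safeguards apply. First, a detection threshold: the trailing
run of ranks whose fitted survival lies below two standard errors of its
interval estimate is called zero, so an unswitched sample does not acquire
phantom switching from noise (zeroing a suffix preserves monotonicity).
Second, if $f_B < 10^{-3}$ the steps are unidentifiable and the
decomposition is returned flagged undefined rather than as noise. IgE spans
the shortest interval and is always flagged low-confidence.

Germline IGH CNVs are common and would masquerade as class switching. From a
matched germline profile, each constant gene (and each V-segment block) is
assigned the integer copy number 0-4 minimising the distance between its
median RDR and $\log_2(\mathrm{CN}/2)$ (CN 0 is represented by
$\log_2(0.05/2)$ so deep deletions remain callable), with the margin to the
runner-up recorded. Non-diploid or low-margin regions are masked; bins in
masked gene bodies are excluded from the switch fit, and a rank left without
data inherits its upstream neighbour's survival, merging its mass into the
next class downstream — a local, conservative failure mode. Calls from
profiles whose baseline depth is below 10x (at integer reporting resolution)
carry a cohort-level low-confidence flag; the deletions themselves pull the
whole-profile mean below nominal depth, which is why the baseline, not the
profile mean, defines the scale.

## Diversity

Shannon diversity $-\sum_i p_i \ln p_i$ and the Jensen-Shannon divergence
$\tfrac12 D(P\|M) + \tfrac12 D(Q\|M)$, $M = (P+Q)/2$, are computed in nats
(natural log throughout, chosen once for consistency). Diversity uses the
full fitted usage vector; the strict $> 0.001$ threshold is used only for
binary segment-selection calls, and usage is not renormalised after
thresholding. Samples at or below 0.05 fitted fraction are gated: their
diversity is reported but flagged, since segment usage is poorly determined
without signal.

## The simulator

The simulator is the package's ground-truth instrument: it draws per-base
depth $\mathrm{Poisson}(D \cdot \mathrm{CN}(x)/C \cdot b(\mathrm{gc}))$ with
$\mathrm{CN}(x)$ composed from the same forward model the estimators invert
— V(D)J deletion, class-switch deletion, germline CNVs, purity mixture — over
a smooth synthetic GC landscape (a sinusoid spanning 0.38-0.62 with one
period per eighth of the locus) under a mild bias
$b(\mathrm{gc}) = e^{-(\mathrm{gc}-0.5)^2}$, roughly the few-percent scale of
PCR-free WGS. Defaults describe a germline blood sample at 30x, the typical
coverage of the cohorts this class of method targets; depth grids for
robustness studies span 0.1-60x via nested binomial thinning, which is
exactly nested in distribution. An optional negative-binomial knob exists
for overdispersion stress-tests. What the simulator does *not* emulate:
mappability artefacts, reference bias, fragment-length structure,
between-region GC curvature beyond the single smooth trend, and real
segment-level annotation error. Passing recovery tests therefore certify the
estimator against its stated stochastic model, not against every artefact of
real WGS; the exclusion-list hook and the masking machinery are the intended
escape hatches on real data.

The packaged segment annotation deserves the same honesty: locus windows are
the exact GRCh38 coordinates, but individual segment placements are
approximate, representative reconstructions of the locus architecture
(regularly spaced, correctly oriented, realistic counts: 40/20 V/J for TCRA,
30/13 for TCRB, 8/4 for TCRG, 40/6 plus nine constant genes for IGH). For
real data an IMGT-derived table should be supplied via `annotation_path`.

## Problem sizes and numerical choices

The validation suite simulates full-length loci (1.1-1.3 Mb) per sample: 100
TCRA samples at 30x thinned to 5x for fraction recovery, 50 IGH samples for
class-switch recovery, a 2-30x depth grid for CNV calling, and a purity 0.3/
0.6 by CN 1-4 grid for tumour adjustment — sizes chosen so the whole suite
completes in minutes on one core while keeping Monte-Carlo error well below
the tested tolerances. Plateau search tolerance is $10^{-10}$; simplex sums
are enforced to $10^{-8}$; ties in the CNV argmin resolve to the lower copy
number via stable ordering. Degenerate inputs (empty pools, all-zero bins,
zero baseline) produce typed errors or flagged outputs, never silent
results.

## Known limitations

Usage moderation trades a small bias towards uniform for a large variance
reduction; clonally dominated repertoires are slightly flattened. The
aggregate isotype errors at 30x are limited by the read count of the
shorter inter-switch intervals (IgG2/IgG4/IgE), not by the estimator.
TCRD is not quantified separately (nested within TCRA), IGK/IGL are out of
scope, and no allelic-exclusion correction is attempted. CRAM input is
supported only with a reference; exon-capture (WES) data is not a target of
this package.
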