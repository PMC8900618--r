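---
title: "Methods: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pluriscan)
```

`pluriscan` audits pluripotent stem-cell-line genomes from whole-genome
sequencing summaries: binned read depth, phased allele depths at
heterozygous sites, genotype matrices, annotated variant tables and array
probe intensities. This vignette records the statistical models behind each
module, the parameters that matter, and the design choices we made where
several constructions were defensible. Everything quantitative stated here
is computed by the package's own test suite or acceptance script on
synthetic data; nothing is quoted from external analyses.

## Read-depth CNV model

Coverage is summarized as samples × 100-kbp bins of normalized depth on a
copy-number scale (diploid = 2). For a sample $S$ and contiguous bin
interval $I$, the deviation score is

$$Z(S, I) = \frac{|\mathrm{coverage}(S,I) - \mathrm{median}(I)|}{\mathrm{MAD}(I)},$$

where the median and MAD are taken across samples over the interval means.
The MAD is used raw, without the 1.4826 normal-consistency factor, because
the 3/5 decision thresholds below are defined on that scale.

**Candidate search.** Reported calls must span at least 10 bins (1 Mbp),
reach interval $Z > 5$, and have sharp boundaries: the next bin outside each
end must lie more than halfway from the sample's in-interval coverage toward
that bin's cohort median. Candidates are generated as *maximal runs of
consecutive bins deviating in a constant direction with single-bin
$z > 2$*, required to contain at least one strong seed bin with single-bin
$z > 3$. We initially implemented the more literal "grow the interval while
its $Z$ does not decrease" search and found it unusable: with cohorts of
10–20 samples the interval MAD is so noisy that a 2-bin interval routinely
out-scores the full event and the ascent stalls almost immediately. A
CUSUM-objective ascent ($|\sum \mathrm{dev}|/\sqrt{L}$) recovers events but
cannot be matched exactly by an exhaustive all-intervals search, because the
exhaustive search's globally optimal noise intervals (driven by chance
near-zero MADs, which make $Z$ heavy-tailed at small cohort sizes) are not
reachable by local ascent. The run-based rule is purely local, so the
linear-time scan and a naive search over every contiguous interval provably
select the same candidates; the test suite verifies exact agreement, and the
null false-call behaviour is clean because ten consecutive same-direction
noise deviations at $z > 2$ essentially never occur. Calls of the same
sample and direction separated by at most one bin are merged — a
deterministic surrogate for the manual boundary curation a human analyst
would apply near centromeres and telomeres.

**Normalization.** Raw bin counts are divided by the sample's *median* bin
count, then by the across-sample bin median, and scaled to 2. The sample
median rather than the mean matters: a single 5-Mbp CN-3 event on a small
simulated genome shifts the sample mean by several MADs and contaminates
every other bin of that sample.

**Fixed versus mosaic.** A call with mean copy number $\hat c$ over $L$
bins is tested against the nearest integer copy state consistent with its
direction ($c_\mathrm{int} \ge 3$ for gains, $\le 1$ for losses) with a
normal approximation using the between-bin empirical standard error;
$P < 10^{-3}$ declares mosaicism. The cellular fraction is
$f = |\hat c - 2| / |c_\mathrm{int} - 2|$ from the mixture expectation
$E[\mathrm{CN}] = 2 + f\,(c_\mathrm{int} - 2)$, clipped to $(0, 1]$; the
single-copy-step assumption means multi-copy amplicons report $f$ clipped at
1. The same integer-divergence statistic applied genome-wide to event-free
samples is the calibration contract: under the simulator's Poisson model the
null flag rate at $P < 10^{-3}$ is far below 1% (the acceptance script
measures it on 20 cohorts of 243 samples × 25,000 bins).

## Allelic imbalance and CN-LOH

At phased heterozygous sites the B-allele frequency
$b = \mathrm{hap1}/(\mathrm{hap1}+\mathrm{hap2})$ has expectation 0.5 in
balanced regions. Mixture identities for an event at cell fraction $f$:
CN-LOH $\mathrm{BAF} = (1+f)/2$, single-copy duplication $(1+f)/(2+f)$,
single-copy deletion $1/(2-f)$; inverting these gives $f = 2d$,
$f = 4d/(1-2d)$ and $f = 4d/(1+2d)$ respectively, where
$d = |\bar b - 0.5|$. Sites are segmented per chromosome by recursive
binary splitting on the depth-weighted deviation; a split is accepted when
its two-sample normal statistic exceeds 4, roughly a Bonferroni bound for
the few thousand split positions scanned per chromosome. Segments are scored
with a binomial log10 likelihood ratio against $p = 0.5$ with the
alternative fixed at $0.5 \pm \hat d$, and reported at LOD > 20 and span
> 1 Mbp. Classification consults coverage over the segment: significantly
above 2 → duplication, below → deletion, otherwise CN-LOH; when the
BAF-implied and coverage-implied fractions disagree by more than 0.2 the
segment is flagged ambiguous rather than forced into a class. A CN-LOH
segment is *accepted* as culture-acquired only when mosaic ($f < 1$ — a
fixed run of homozygosity from inbreeding gives $d = 0.5$ exactly) and
extending to within one bin of a chromosome terminus, the geometry of a
single mitotic crossover.

## Relatedness and ancestry

Sites with MAF < 1% are excluded; LD pruning slides a 50-site window in
5-site steps removing the site with the largest variance inflation factor
until all VIF ≤ 2 (singular windows, e.g. duplicated sites, drop the most
correlated member). IBD fractions are estimated by the classic
method-of-moments equations relating observed identity-by-state counts to
expectations under IBD 0/1/2 given allele frequencies, clipped to the
simplex; $\hat\pi = \mathrm{IBD1}/2 + \mathrm{IBD2}$ and kinship
$= \hat\pi/2$. Pairs with $0.35 \le \hat\pi \le 0.70$ are directly related,
split into full siblings versus parent–child at IBD2 ≥ 0.10 (siblings expect
0.25, parent–child 0). Allele frequencies are estimated from the analyzed
cohort itself, which biases sibling $\hat\pi$ slightly downward at small
cohort sizes; in the 20-sibling-pair calibration the mean kinship still sits
comfortably inside the expected sibling band around 0.25. Ancestry fractions
come from a joint PCA of the standardized genotype relationship matrix with
a labelled reference panel, and a linear model from PC1–3 to the reference
fractions; predictions are clipped to [0, 1] and renormalized to sum to 1.
The simulated reference panels use a Balding–Nichols model at
$F_{ST} \approx 0.1$, which separates three continental-scale populations
cleanly in the first two PCs.

## Polygenic scores

Raw scores are $\sum \mathrm{dosage} \times \mathrm{weight}$ over markers
with source-study $p < 0.5$, dosages aligned to the effect allele and
missing dosages mean-imputed (the least informative single-value choice).
Scores are residualized on the first 12 principal components by OLS *fit on
the control cohort only*, then z-scored with the control residual mean and
$n-1$ SD, so controls have exactly zero mean and unit SD by construction.
Outliers are flagged at $|z| \ge 2$ (inclusive), and lines are ranked by
$\sum_\mathrm{traits} |z|$ ascending — the head of the ranking is the
"all-purpose" set closest to the population mean on every scored trait. The
PC count (12) is exposed as a knob; no LD clumping is applied before
scoring, matching the scoring convention the weights were built for.

## SNV prioritization cascade

Filters are applied in order, each to the survivors of the previous stage,
and missing annotations always *fail* a filter (conservative shortlists):

1. **HC-HQ**: site FILTER = PASS; at least one carrier genotype with
   DP ≥ 10, GQ ≥ 20 and within-sample alternate allele fraction ≥ 0.2; not
   in a low-complexity region or segmental duplication; population-reference
   status pass-or-missing.
2. **Consequence bins**: exact membership in the LoF / missense /
   synonymous term lists on canonical transcripts.
3. **Deleterious**: LoF or missense, ExAC AF < 0.001, CADD phred > 20
   (strict — the top 1% of the phred scale, since a phred cutoff $s$ marks
   the top $10^{-s/10}$), DANN > 0.99 (strict).
4. **Cancer**: COSMIC Tier-1 gene, catalog count ≥ 2, FATHMM-cancer
   positive.
5. **Fertility**: fertility-gene list, LOEUF ≤ 0.33 (*inclusive*), CGD
   autosomal-dominant.
6. **Disease**: autosomal, LOEUF < 0.33 (*strict*), CGD AD,
   FATHMM-XF > 0.75, DANN > 0.999, ExAC AF < 10⁻⁵.

The two LOEUF edge semantics differ deliberately between stages 5 and 6,
honouring each filter's own definition; both are overridable arguments. The
synthetic variant generator computes every record's truth flags by an
independent re-implementation of these thresholds (no shared code), and the
suite requires exact agreement — a genuine dual-route check on ~800-record
tables.

## Intensity rank-sum validation

For each CNV call with ≥ 2 assigned array probes, every sample's intensity
is ranked per probe (midranks on ties) and the carrier ranks pooled across
probes; the one-sided p-value (low for deletions, high for duplications)
is exact — by convolving per-probe discrete uniform rank distributions — for
a single carrier without ties, and a continuity-corrected normal
approximation otherwise (per-probe variance $n_c(N+1)(N-n_c)/12$). Under
the null the p-value is uniform, so the cohort false discovery rate is
estimated as $2 \times \mathrm{fraction}(p \ge 0.5)$, clipped to [0, 1];
true calls concentrate near 0 and contribute negligibly to the upper half.
The per-type length threshold search returns the smallest observed call
length whose retained calls meet a target FDR (default 3%), flagging
unattainable targets instead of silently relaxing them.

## Recurrence and reporting

The minimal shared region of a set of duplication intervals is the
maximum-depth segment from a boundary sweep; depth ties report every tied
segment. The breakpoint motif scan searches ±-flank windows for maximal
tandem runs (≥ 3 units by default) of the satellite unit GGAAT, treating all
cyclic rotations and their reverse complements as one pattern family, so the
hit count is invariant under reverse-complementing a window. Burden
regression is ordinary least squares of per-line variant counts on candidate
covariates (passage number, ancestry fractions, sex, provider), reported as
a `burden_reg` object with `tidy()`/`glance()` methods; count-model
alternatives (Poisson GLM) would be natural but OLS is the deliberate
default for a first-pass screen. The per-line report recounts every field
from the upstream tables (missing modules yield `NA`, never silent zeros),
and the selection policy maps findings to tiers: aneuploidy, fixed large
SVs, cancer- or disease-shortlist SNVs → avoid; mosaic large SVs (in
principle rescuable by sub-cloning), accepted CN-LOH, fertility SNVs, and
more than 3 outlier PRS traits → caution. The PRS-outlier count cutoff is
our default; no published count threshold exists.

## The simulator: what it does and does not emulate

The generators draw per-bin read counts as Poisson with expectation
`mean_depth × bin_size / read_length` scaled by the local copy-number
mixture (negative binomial with configurable dispersion is available for
over-dispersion); at the default 30× with 151-base reads this is ≈ 20,000
fragments per 100-kbp bin. Identical configurations (including the seed)
produce byte-identical outputs. The simulator deliberately does **not**
model GC waves, mappability variation, tagmentation bias, alignment
artifacts, phase-switch errors (phasing is emitted perfect), or linkage
disequilibrium except through an explicit block-copy mode used to exercise
the LD pruner. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean noise model, and calibration claims
(e.g. the < 1% null mosaicism flag rate) are statements about that model,
not about any particular sequencing platform; real data would need the
thresholds re-examined under its own dispersion.

## Problem sizes and numerical choices

The test suite runs cohorts of 5–243 samples over 200–25,000 bins, 1,500–
10,000 SNP sites, and variant tables of 400–800 records; the full suite
completes in roughly two minutes and the acceptance script (20 null cohorts
of 243 × 25,000 bins plus the 20-sibling-pair gene drop) in under one.
Degenerate inputs are handled explicitly: zero interval MAD flags the Z
score as infinite-degenerate rather than NaN; zero within-call variance
classifies as fixed; completely tied intensities give p = 0.5; constant
genotype sites are pruned before VIF computation; collinear PCs or
covariates are dropped with warnings. Coordinates are 0-based half-open in
all tables and BED output, with bin indices 1-based inclusive inside R.
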