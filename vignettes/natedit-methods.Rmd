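---
title: "Methods: differential A-to-I editing analysis and NAT-based prioritization"
author: "natedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential A-to-I editing analysis and NAT-based prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natedit)
```

# Scope and data model

`natedit` analyzes per-sample A-to-I RNA editing call tables from a
two-group (tumor vs adjacent tissue), two-subtype (ER+, TNBC) cohort
design. It deliberately starts *after* editing-site calling: its inputs
are BED-like call tables (one per sample), annotation tracks (Alu
repeats, natural antisense transcripts, SNPs), and a sample manifest that
is the single authority for group labels and sequencing depth. Raw reads,
alignment and the editing caller itself are out of scope.

In memory everything lives in Bioconductor containers: calls are a
width-1 `GRanges` inside an `EditingCallSet` (sample metadata on the
object), annotations are `GRanges` inside a kind-tagged `AnnotationSet`.
Coordinates follow the `GRanges` convention (1-based, closed). The file
formats keep their native conventions — BED and the call dialect are
0-based half-open, VCF is 1-based — and conversion happens exactly once,
at the read/write boundary, so a read–write round trip is the identity
and rendered reports match the 1-based positions a reader expects.

# The filter chain

Three per-sample stages, each monotone (output ⊆ input) and audited
(input = retained + excluded):

1. **Editing-type consistency.** A-to-I editing appears as A>G on the
   plus strand or T>C on the minus strand. The default rule retains
   exactly those two (base change, strand) pairs. The stricter reading is
   deliberate: an A>G call on the minus strand is not A-to-I on the
   transcript that produced it. A `lenient` flag accepts any A>G/T>C
   regardless of strand for callers with unreliable strand assignment.
2. **Alu retention.** Only calls inside annotated Alu elements are kept.
   The overlap is strand-agnostic: whether a single base lies inside a
   repeat does not depend on the repeat's annotated strand.
3. **SNP exclusion.** A call is removed when its position carries a known
   SNP whose allele pair is A>G or T>C — the pairs indistinguishable from
   editing in sequence data. A SNP of any other type at the position is
   not evidence against editing, so by default it does not trigger
   removal; `allelic = FALSE` switches to position-only matching for
   users who prefer the blunter rule. The stage reports the excluded
   fraction, the number a study would quote as its SNP-contamination
   estimate.

Filters run per sample, before any cohort aggregation, matching how
editing callers process runs individually.

# Editing burden

Per-sample burden is the number of distinct edited positions; since
deeper sequencing finds more sites, the comparable quantity is
**sites per million mapped reads** (raw × 10⁶ / mapped_reads, depth taken
from the manifest). This is the simplest depth proxy expressible in the
data model; anything finer (coverage-matched subsampling) would need the
alignments, which are out of scope. Both raw and normalized counts are
reported.

Groups are compared within a subtype — never pooled — by a two-sided
Mann–Whitney test written for this package:

* *U* from joint mid-ranks.
* **Exact p** when the data are tie-free and *n*₁+*n*₂ ≤ 16: the full
  null distribution of *U* is built by the q-binomial recurrence
  (partitions of *u* into ≤ *n*₁ parts each ≤ *n*₂), and
  p = min(1, 2·min(P(U ≤ u), P(U ≥ u))). The switch at 16 keeps the
  exact path where it costs microseconds.
* **Approximate p** otherwise: continuity-corrected normal
  approximation. For tie-free data an Edgeworth term is added using the
  exact excess kurtosis of the null *U* distribution,
  γ₂ = −6(m² + n² + mn + m + n) / (5mn(N+1)): the null distribution is
  platykurtic, and the plain normal curve misstates moderate-tail
  p-values by up to ~0.011 at 8+8, which the kurtosis term reduces to
  ~5×10⁻⁴. With ties, the tie-corrected variance is used and the
  Edgeworth term is dropped (its closed form assumes distinct ranks).

# Prioritizing candidate sites

Detection is **binary**: a site is "in" a sample if it appears in the
sample's filtered call file, with no further read-support threshold. The
prevalence of a site in a group is the fraction of samples detecting it.
The selection cascade per subtype:

1. Keep sites detected in **≥ 40 %** of either group (boundary
   inclusive).
2. Prevalence ratio *r* = prev_tumor / prev_adjacent. A zero detection
   count on either side is replaced by a Haldane-style half count
   0.5/*n* for that group before division. The guard is applied
   symmetrically (numerator and denominator) so that *r* is always
   positive, log₂ *r* is always finite, and swapping the group labels
   maps *r* to 1/*r* exactly.
3. Z-scores: *z* = (*v* − mean *v*) / sd *v* with the sample standard
   deviation (n − 1) and *v* = log₂ *r* by default. The log scale treats
   2-fold enrichment and 2-fold depletion symmetrically; raw ratios are
   right-skewed and make |*z*| one-sided. A `scale = "raw"` mode
   standardizes the ratios themselves for users who want the literal
   ratio-scale statistic; both modes are tested. Z-scores are computed
   per subtype over the post-40 %-filter record set (the set the cascade
   narrates), not over all sites. If all ratios are equal the sd is zero
   and every *z* is set to 0 with a warning.
4. Keep |*z*| **strictly** > 1.96 **and** positional overlap with a NAT
   interval. NAT overlap is strand-agnostic by default — a NAT is by
   construction antisense to the edited transcript — with a
   `strandAware` mode that additionally requires the NAT's strand to be
   opposite the call's. No multiple-testing correction is applied: the
   method is a fixed-threshold outlier screen, not an FDR procedure, and
   the report says so.
5. Candidates are ordered by |*z*| descending (ties by position), and
   two subtypes' lists intersect on (chrom, position), reported 1-based.

## When the Z-screen works — and when it cannot

Because the threshold is applied to a *self-standardized* set, the
screen's operating characteristics depend on how much of the set is
signal. With sparse contamination (the module suite uses 8 planted sites
among 2000, i.e. ≈ 3 % of the post-filter set) the planted sites are
recovered essentially completely. When differential sites make up on the
order of 10 % of the post-filter set, their own extreme ratios inflate
the sd they are standardized against, pushing moderate signal below
|z| = 1.96; in that regime (20 planted in a 1000-site cohort of 20 + 15
samples) measured sensitivity drops to ≈ 0.4–0.65 while the
false-discovery proportion stays low. This is an intrinsic property of
mean/sd standardization with a fixed cutoff, not an implementation
artifact; a robust location/scale (median/MAD) would resist the
inflation but is deliberately not the default, because the package
implements the plain Z-score screen as its method.

# The synthetic cohort generator

`simulateCohort` emulates the statistical structure the pipeline
consumes, not the biology upstream of it:

* **Sites** sit on a jittered ~500 bp grid of one pseudo-chromosome, so
  annotation intervals (Alu ±50 bp, NAT ±100 bp) can never spill onto a
  neighboring site and the truth table is exactly consistent with the
  emitted BED/VCF files.
* **Detection** is Bernoulli per (site, sample) with the group's
  prevalence: background sites draw one prevalence per site from
  Beta(2, 8) (mean 0.2, right-skewed — most sites rare, a minority
  common), shared between groups; planted sites use configured
  prevalences (defaults 0.8 tumor / 0.1 adjacent). Detection is binary
  because the prioritization statistic is presence/absence; read counts
  (negative-binomial coverage, Beta editing fractions, support ≥ 1) are
  generated only so parsers and filters see realistic rows.
* **Membership**: planted sites are always Alu-resident, SNP-free and
  NAT-overlapped — they model genuine NAT-associated editing candidates —
  while background sites are Alu with probability 0.85 (most human
  editing is Alu-borne), SNP decoys with probability 0.02, and
  NAT-overlapped with probability 0.30.
* **Depth**: mapped reads are log-normal (meanlog = log(4×10⁷),
  sdlog = 0.4 — tens of millions of reads with realistic spread). By
  default detection follows prevalence exactly; setting
  `burdenPerMillion` thins each sample's detection probabilities so its
  expected site count tracks depth, which makes depth-normalization
  behavior testable.
* **Seeding**: one master seed drives a named child stream per artifact
  (sites, depths, calls, decay), so adding a stream never shifts the
  others, and a fixed seed gives byte-identical output trees.

What the generator does **not** emulate: linkage between neighboring
sites, editing-fraction biology, hyper-editing clusters, sample-level
batch effects, or chromosome structure. Passing tests therefore show the
*statistics* behave as specified under the declared model — they do not
validate editing-caller accuracy on real alignments.

`simulateDecaySeries` encodes exp(−λt) (λ = ln 2 / t₁/₂) as target Ct
values over a fixed reference Ct, with multiplicative log-normal noise,
over the standard shutoff design {0, 0.5, 1, 2, 4, 6, 8} h, so
2^−ΔΔCt calibrated at t = 0 recovers the decay curve exactly at zero
noise.

# Kinetics

`ddct` implements 2^−ΔΔCt: technical replicate wells (identical
sample/condition/timepoint/gene/replicate keys) are averaged on the Ct
scale first; the `replicate` column denotes biological replicates, which
stay separate so downstream comparisons have real degrees of freedom.
ΔCt = Ct_target − Ct_reference per stratum; the calibrator stratum
(a condition, a timepoint, or both) is matched within the same sample
and replicate when possible. The double normalization used for
fractionation experiments (to a reference gene and to a total-cell
fraction) is the same computation with the total fraction as calibrator,
so no separate operation exists for it.

`fitDecay` regresses ln(expression) on time: λ = −slope floored at 0,
t₁/₂ = ln 2 / λ (infinite — "not reached" — for a flat series, with R²
undefined there). A closed-form log-linear fit is deterministic and
fully adequate for 7-point series; nonlinear least squares would add
iteration-dependence without precision at this design. Half-life
comparison (`compareDecay`) is a Welch t-test on replicate-level
half-life estimates, never on pooled curves, so its p-value has a
defensible unit of replication.

# Problem sizes and numerical checks

The test suite verifies, among others: exact Mann–Whitney p against full
rank-split enumeration for every tie-free input with *n*₁+*n*₂ ≤ 10, and
the approximation against the exact p on 8+8 suites; the filter chain
against an all-pairs overlap oracle on 100 random fixtures (up to 1000
calls × 200 intervals); an 8-site, 10+10-sample worked prioritization
cohort against hand arithmetic at 10⁻⁹; generator prevalence convergence
at 500 samples per group; burden-test power (2× shift, lognormal
sdlog = 0.4, 20 vs 15 samples, 100 replicates) and null p uniformity
(Kolmogorov–Smirnov); decay recovery for t₁/₂ ∈ {1, 2, 4, 8} h at 5 %
log-normal noise; and byte-identical reruns of the full pipeline under a
fixed seed. These sizes keep the default suite within a couple of
minutes on one CPU while leaving each check statistically meaningful.

# Known limitations

* Depth normalization is linear in mapped reads; saturation of site
  discovery at very high depth is not modeled.
* The prevalence statistic ignores editing *level*; a site edited at 2 %
  and 40 % in two samples counts identically. Fraction-based tests
  (e.g. beta-binomial) are intentionally out of scope.
* The fixed |z| > 1.96 cutoff controls nothing frequentist across sites;
  see the contamination discussion above.
* Chromosome names are compared verbatim between calls and annotations;
  harmonizing "chr" prefixes is the caller's responsibility, and silent
  renaming is deliberately avoided.
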