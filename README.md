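# natedit

Cohort-level analysis of A-to-I RNA editing in tumor / adjacent-tissue
RNA-seq studies, with prioritization of editing sites overlapped by
natural antisense transcripts (NATs).

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA;
sequencers read inosine as guanosine, so editing shows up as A>G calls
(T>C on the opposite strand). NATs — lncRNAs transcribed antisense to a
protein-coding gene — can form the RNA:RNA duplexes that ADAR requires,
which makes editing sites inside NAT-covered loci candidate read-outs of
sense/antisense regulation. Given per-sample editing-call tables from a
breast cancer cohort (tumor vs adjacent tissue, in ER+ and TNBC
subtypes), the package answers three questions:

1. **Are calls trustworthy?** A per-sample filter chain keeps
   A-to-I-consistent events (A>G on `+`, T>C on `-`), keeps events inside
   Alu repeats (where most human editing happens), and removes events
   coinciding with known A>G / T>C SNPs, with a per-stage audit of
   excluded fractions.
2. **Do tumors carry more editing?** Per-sample editing burden is the
   number of distinct edited sites, depth-normalized to sites per million
   mapped reads, and compared between groups with a Mann–Whitney test
   (exact by full enumeration of the null distribution of *U* for small
   tie-free samples; Edgeworth-corrected normal approximation otherwise).
3. **Which sites distinguish the groups?** For each site detected in
   ≥ 40 % of either group, the prevalence ratio
   *r* = prev(tumor) / prev(adjacent) is computed (zero counts replaced
   by a Haldane-style half count 0.5/*n*), ratios are standardized,
   *z* = (log₂*r* − mean) / sd, and sites with |*z*| > 1.96 that overlap
   a NAT are reported per subtype, plus the cross-subtype intersection.

A synthetic-cohort generator (`simulateCohort`) with planted
differential-prevalence sites and a ground-truth table makes the whole
pipeline testable without any downloads, and a kinetics layer covers the
wet-lab side: `2^-ΔΔCt` relative expression and first-order RNA
half-life estimation (*t*₁/₂ = ln 2 / λ from log-linear regression) for
actinomycin-D transcription-shutoff time courses.

## Worked example

```r
library(natedit)
cfg <- cohortSimConfig(nTumor = 20, nAdjacent = 15, nSites = 1000,
                       nPlanted = 20, seed = 42)
sim <- simulateCohort(cfg)
sim$cohort[[1]]
#> EditingCallSet 'T001' (ER+, tumor): 213 calls, 27,319,792 mapped reads

filt <- filterCohort(sim$cohort, sim$alu, sim$snps)
filt$report
#>          stage input_count retained_count excluded_count excluded_fraction
#> 1 editing_type        7265           7265              0        0.00000000
#> 2  alu_overlap        7265           6281            984        0.13544391
#> 3  snp_overlap        6281           6139            142        0.02260786

cmp <- compareBurden(burdenCounts(filt$cohort), "ER+")
#> Mann-Whitney U = 222, p = 0.0158 (medians 5.58 vs 4.12 per million)

prioritizeSites(filt$cohort, sim$nat, subtype = "ER+")
#> CandidateList (ER+): 14 candidate site(s) [prevalence >= 0.40, |Z| > 1.96, NAT-overlapped]
#>   chrom    pos prev_tumor prev_adjacent ratio        z
#> 1  chrS 121337       0.85             0  25.5 3.078104
#> ...
```

The filter report reads: every simulated call is A-to-I consistent, 13.5 %
fall outside Alu repeats and are dropped, and 2.3 % of the rest coincide
with an A>G/T>C SNP. The burden comparison says tumor samples carry more
edited sites per million mapped reads (U = 222 of a possible 300,
p ≈ 0.016). The candidate list holds NAT-overlapped sites whose
tumor/adjacent prevalence ratio is an outlier; `prev_adjacent = 0` rows
show the zero-guard at work (ratio 25.5 = 0.85 / (0.5/15)).

Decay kinetics:

```r
ct <- simulateDecaySeries(4, noiseSd = 0.05, nReplicates = 3, seed = 1)
decayFits(ct, "target", "reference")[[1]]
#> DecayFit target [ActD]: lambda=0.1728 /h, t1/2=4.01 h, R2=0.998 (n=7)
```

A full run (simulate → filter → burden → prioritize → intersect) with
TSV/JSON outputs:

```r
runPipeline(list(simulation = list(nTumor = 20, nAdjacent = 15,
                                   nSites = 1000, nPlanted = 20,
                                   subtypes = c("ER+", "TNBC"))),
            outDir = "run1", seed = 7)
```

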