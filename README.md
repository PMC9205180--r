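# f1ighv

Strain-specific germline IGHV inference from long-read VDJ-C repertoires of
F1 hybrid mice.

## The problem

Antibody repertoire analysis needs a complete germline IGHV reference for
the strain being studied, but for most inbred mouse strains no such
reference exists: reads from unreported alleles get forced onto the nearest
known gene and masquerade as hypermutated sequences. Inferring germline
genes from rearranged VDJ reads works, but in an inbred strain there is no
heterozygosity to phase the inferences, and rare inferred alleles are hard
to distinguish from PCR chimeras.

`f1ighv` implements the F1-hybrid strategy: cross two homozygous strains
(e.g. BALB/c × C57BL/6), sequence full-length VDJ-C amplicons (through the
constant-region CH3 exon) with a long-read platform, and use
constant-region strain SNPs to anchor every read to a parental chromosome.
With the IGHM CH1 SNP rs29176517 (`g` on the BALB/c chromosome, `a` on
C57BL/6) each read's `c_call` (`IgM*BALB` / `IgM*B6`) phases the V genes:

* **genotype**: an allele is present given ≥ 2 unique unmutated
  exact-match sequences; novel alleles are detected by the mutation-load
  intercept test (a germline polymorphism appears at a constant fraction
  y of sequences regardless of their mutation load m, so the intercept of
  the weighted regression of y on m over bins m = 1..10 is high, while
  hypermutation extrapolates to zero; candidates need intercept ≥ 0.125
  and ≥ 10 otherwise-unmutated supporting sequences);
* **haplotype**: per allele with nA/nB unique anchored sequences, the
  minor fraction q = min(nA,nB)/(nA+nB) is compared with kThreDel = 0.1,
  and single-chromosome calls require the log10 binomial likelihood ratio
  (leak ε = 0.01 vs p = 0.5) to reach 2;
* **chimerism**: prepared records whose V allele sits on one chromosome
  but whose own constant region reports the other;
* **curation**: 3'-end confirmation from the terminal-nucleotide reach
  distribution of unmutated reads, truncated-record extension, per-strain
  reference export, and reference-completeness evaluation via the
  read-mismatch histogram.

A synthetic F1 repertoire generator with complete ground truth (clonal read
duplication, SHM, exonuclease trims, PacBio-like homopolymer indels, PCR
template-switch chimeras) backs every stage with parameter-recovery tests.

## Worked example

```r
library(f1ighv)

cfg  <- sim_config(n_reads = 20000, seed = 42)   # F1 study conditions
haps <- build_parental_haplotypes(cfg)           # 2 x 100 V alleles, 4 shared
sim  <- simulate_f1(haps, cfg)                   # reads + full truth
refs <- combine_haplotype_references(haps)       # starting reference

res <- run_f1_pipeline(sim$reads, refs$v, refs$d, refs$j)

head(res$genotype, 4)
#>   allele      unmutated_support total_support frequency present
#> 1 b6IGHV096                 116           459    0.0313 TRUE
#> 2 balbIGHV093               104           473    0.0313 TRUE
#> 3 b6IGHV094                  92           424    0.0285 TRUE
#> 4 balbIGHV094                94           428    0.0278 TRUE
```

134 alleles are called present; `frequency` is the duplicate-weighted share
of assigned reads, and `unmutated_support` the number of unique unmutated
exact-match sequences behind the presence call. The haplotype table anchors
each allele to a chromosome:

```r
head(res$haplotype[order(-(res$haplotype$count_anchorA +
                           res$haplotype$count_anchorB)), ], 4)
#>   v_allele    count_anchorA count_anchorB assignment   deleted_on certainty
#> 1 b6IGHV096               0            20 anchorB_only BALB            5.93
#> 2 balbIGHV089            19             0 anchorA_only B6              5.64
#> 3 b6IGHV094               0            18 anchorB_only BALB            5.34
#> 4 balbIGHV096            18             0 anchorA_only B6              5.34

res$chimerism
#> $count 0; $n 542; $fraction 0
```

Each anchored allele here was seen only on its own chromosome (certainty is
the log10 likelihood ratio for deletion of the other chromosome), and none
of the 542 prepared sequences shows cross-strain V/C discordance after
filtering. Shared alleles accumulate counts on both anchors and are called
`both` once each side has enough unique sequences (at 50,000 reads the four
planted shared alleles reach ≈ 9 sequences per chromosome and are recovered
exactly).

The packaged transcriptions of the study's printed sequences are available
as fixtures:

```r
t1 <- table1_alleles()
pairwise_diff(t1$sequence[t1$name == "b6IGHV040"],
              t1$sequence[t1$name == "balbIGHV041"])
#>   position a     b     label
#> 1      100 c     t     C100T
```

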