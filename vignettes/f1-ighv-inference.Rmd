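---
title: "Inferring strain-specific IGHV reference sets from F1 VDJ-C repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring strain-specific IGHV reference sets from F1 VDJ-C repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f1ighv)
```

## The problem and the model

Germline IGHV genes of most inbred mouse strains are poorly documented, which
corrupts every downstream repertoire analysis: reads from an unreported
allele are forced onto the nearest known gene and appear "mutated". Germline
inference from rearranged VDJ sequences can recover the missing alleles, but
in an inbred strain there is no heterozygosity to phase the inferences and no
easy way to distinguish rare real alleles from PCR chimeras.

The strategy implemented here crosses two homozygous strains and sequences
full-length VDJ-C amplicons (through the constant-region CH3 exon) from the
F1 hybrid. Because VDJ recombination is chromosomal, every read's
constant region reports which parental chromosome it came from, provided the
two strains carry distinguishable constant-region alleles. Two anchor systems
are used:

* **IGHJ1**: the two strains carry IGHJ1 alleles differing at one SNP.
  Grouping reads by IGHJ1 allele and ranking their raw constant segments by
  frequency recovers each strain's constant-region exons de novo
  (`discover_c_alleles_by_j_anchor()`), including the IgG subclasses (top two
  sequences per anchor, because each strain expresses two CH3-primed IgG
  genes).
* **IGHM CH1 / IGHG2B**: a single IGHM CH1 SNP (rs29176517: `g` on the
  BALB/c chromosome, `a` on the C57BL/6 chromosome) and four IGHG2B SNPs
  type every read's chromosome directly. The IgM anchor is used for
  haplotyping because IgM-associated VDJ sequences are largely unmutated.

The inference chain is: annotate reads against a combined starting reference
(`annotate_reads()`); extract and indel-correct the constant segment, type
the SNPs and attach a `c_call` such as `IgM*BALB`
(`type_constant_regions()`); filter and collapse to unique VDJ sequences
(`filter_rearrangements()`, `collapse_unique()`); detect novel V alleles by
the mutation-load intercept test (`find_novel_alleles()`); call the
presence/absence genotype (`infer_genotype()`) and reassign reads to it
(`reassign_alleles()`); and finally assign every V allele to one or both
chromosomes (`infer_haplotype()`), estimate residual chimerism
(`estimate_chimerism()`), and curate gene ends and export per-strain
reference sets (`confirm_3prime_ends()`, `export_reference_set()`).

## Alignment model

Segment calls use local alignment with match +1, mismatch −2, gap −3,
seeded and banded for large V references (a k-mer index proposes
reference/diagonal candidates; only candidates are aligned). Two choices
matter scientifically:

* **Local, not end-to-end.** V genes are 3'-trimmed by exonuclease
  processing and reads may be 5'-truncated; an end-to-end (edit-distance)
  model would count those biological end losses as mismatches and destroy
  the "unmutated sequence" filters that genotyping and haplotyping depend
  on.
* **Anchored ends.** Both alignment ends must terminate in six consecutive
  matches. Without this, local alignments extend a few bases into the
  random junction whenever chance matches outscore a mismatch, inflating
  mismatch counts on ~10% of otherwise-clean reads. Six matches make such
  extensions rare (≈4⁻⁶ per junction offset) at the cost of occasionally
  shaving a genuine mutation in the last few bases of a segment — the same
  trade a production annotator makes.

Mismatch counts include substitutions and indels inside the aligned span;
unaligned overhangs are free. Ties (identical reference sequences) are
reported together, comma-separated in name order. `complete_vdj` requires
the V alignment to start at reference position ≤ 5. The identical contract
is implemented twice — the banded seeded C++ path used by the pipeline and a
plain full-matrix R implementation used as a test oracle — and the test
suite asserts their call sets coincide on random probes.

## Constant-region typing

The constant segment is everything one nucleotide past the final J-aligned
base. Long-read platforms concentrate errors in homopolymer runs, and an
uncorrected single-base indel upstream of a SNP shifts every downstream
position, so segments are globally aligned (affine gaps: open 4, extend 1,
mismatch 2; free tails) to the reference exon scaffold of their isotype;
read insertions are removed and deletions are filled with the reference base
but flagged low-confidence. A SNP read from a filled position is a no-call.
Correction is restricted to the exon prefix that contains the typed SNPs
(plus a 60 nt margin) — downstream exons carry no typing information.

A call is *highly confident* — and only then written into `c_call` — when
all required SNPs are called (one for IgM, all four for IgG2b), none is
deletion-filled, and alignment identity is ≥ 0.9. On simulated data the
corrected IgM call is ≈ 99.9% accurate versus ≈ 80% uncorrected, which is
the quantitative case for the correction stage.

## Haplotype model

Unique sequences entering haplotyping must be unmutated (zero V
mismatches), observed more than once (`duplicate_count > 1`), carry an
unambiguous anchor `c_call` (sequences seen with both anchors are dropped),
and have a single V call. For each allele with nA/nB unique sequences per
anchor, with minor fraction q = min/n:

* q ≥ `kThreDel` (0.1) **and** minor support ≥ 2 → present on both
  chromosomes;
* q < `kThreDel` and certainty ≥ 2 → single-chromosome, the minor anchor
  called deleted. Certainty is log10 of the binomial likelihood ratio of a
  single-chromosome model with leak ε = 0.01 (absorbing residual chimerism
  and typing error) against a both-chromosomes model with p = 0.5
  (symmetric prior; no usage weighting); each allele is scored
  independently;
* otherwise unknown.

The minor-support floor of 2 is a package design choice: with the bare
ratio rule, one stray chimeric sequence against nine genuine ones (1/10 =
0.1) would overturn a deletion call; requiring two independent unique
sequences mirrors the genotype's own support threshold. Genotyped alleles
with no surviving haplotype records are reported as unknown rather than
dropped.

Residual chimerism is estimated as the fraction of prepared records whose V
allele is single-chromosome but whose own `c_call` is the opposite anchor.

## Genotype and novel-allele model

An allele is *present* when at least two unique unmutated sequences match it
exactly; single-sequence alleles are listed as provisional, not called.
Novel alleles are found by the mutation-load intercept test: for each
reference allele with ≥ 50 assigned unique sequences, the fraction of
sequences carrying a specific substitution is regressed (weighted by bin
size) against total V mismatch count over bins 1–10. A germline polymorphism
rides at a constant fraction regardless of mutation load, so its fitted
intercept is high; hypermutation extrapolates to zero. Candidates need an
intercept ≥ 0.125 and ≥ 10 sequences carrying the substitution as their
only mismatch. When only one mismatch bin is populated the bin fraction
itself stands in for the intercept. Candidate alleles are deduplicated
against the reference by sequence.

## Gene-end curation

Exonuclease trimming means the terminal bases of a V gene are seen in only a
minority of reads, so reference 3' ends need independent confirmation. For
each allele, the fraction of unmutated assigned reads whose alignment
reaches each terminal position ("reach") decays smoothly for a correct end.
The end is *extended* while reads aligned through the current end show a
dominant (≥ 0.6) next nucleotide; terminal positions are *trimmed* while
they are reached by < 10% of reads and the reads stopping just short do not
support the reference base. Under geometric trimming with mean ≤ 3 the
true-next-base fraction at a short end is ≈ 0.68 while random junction bases
stay near 0.25–0.35, so 0.6 separates the two regimes; a correct end keeps
reach ≈ 25% at the final base, well above the 10% trim threshold. Verdicts
need ≥ 20 assigned sequences, otherwise "inconclusive".

## What the generator emulates

`simulate_f1()` draws reads from a clone pool rather than independently:
real long-read datasets contain a few reads per unique molecule (the study
regime is ≈ 2.3 reads per unique sequence), and without that multiplicity
the haplotype filter "read counts greater than 1" would retain nothing.
Defaults (all in `sim_config()`):

* two haplotypes of 100 V alleles in 12 gene families, 4 alleles shared;
  log-spaced usage giving F1-wide allele frequencies of ≈ 0.005%–3%, shared
  alleles near 1% (the reported regime for genes seen in both strains);
* IGHJ1 alleles one SNP apart; IGHM/IGHG2B exons differing at the strain
  SNPs (printed CH1 sequences; synthetic hinge/CH2/CH3 scaffolds where the
  study prints none);
* isotype mix 85% IgM / 15% IgG; IgM clones unmutated with probability 0.8,
  otherwise hypermutated at 0.005/base; IgG always at 0.02/base;
* geometric exonuclease trims (means: V3' 3, D ends 2, J5' 2), N inserts of
  0–6 random bases;
* sequencing errors: substitutions at 0.002/base plus a single-base
  insertion or deletion at each homopolymer run (length ≥ 2) with
  probability 0.01 — the long-read error signature the indel-correction
  stage exists for;
* PCR chimeras at 14% of reads: template switches between reads from
  opposite chromosomes at a homologous breakpoint drawn uniformly from
  30–90% of the V span. 5% of the chimeric mass is formed at the clone
  level (early-cycle products that get amplified); the rest are singletons.

A single integer seed determines everything; independent stages derive
sub-seeds deterministically.

**What it does not emulate.** Quality scores are constant (Q30 proxy);
error rates are uniform along the read rather than position-dependent;
clonal lineages (shared mutations between related clones) and light chains
are absent; V allele families are random mutants of random founders, so
inter-family similarity is lower than in the real locus. Consequently a
passing recovery suite demonstrates that the inference logic is correct
under the stated statistical assumptions, not that real-locus homology
cannot create harder cases. Two knock-on effects are worth knowing. First,
because chimera breakpoints sit inside V, a chimera's J and C segments come
from the same donor molecule, so the IGHJ1/C concordance on simulated data
stays near 1 and the 14% pre-filter chimerism is visible instead as V-vs-C
strain discordance (~9% observed: only late-breakpoint chimeras keep the
victim's V call). Second, a V-region mosaic of two random-family alleles
almost never equals any germline exactly, so virtually no chimera survives
the unmutated/duplicated/unambiguous filters: planted post-filter chimerism
and its estimate are both ≈ 0, which is the designed behaviour of the
filters, and `estimate_chimerism()`'s detection logic is therefore also
unit-tested on constructed tables with planted discordant records.

## Numerical and degenerate-input choices

* Geometric trims are resampled (never clamped) when they exceed the
  segment; J trims are capped to leave 20 nt of J.
* The k-mer seeder uses k = 13, every third read position, candidates
  within half the top vote count (cap 6, ties kept), band ±10 around the
  voted diagonal; reads with fewer than 3 seed hits get no V call. Reads
  whose V alignment stops early (chimeric mosaics) trigger a second, wider
  J search window.
* Deletion placement inside a homopolymer is degenerate; the corrector
  reports one of the cost-equivalent placements, which is why SNP no-calls
  key off the low-confidence flag, not the exact position.
* Empty inputs return empty tables; missing J calls make constant-segment
  extraction an error unless explicitly dropped; haplotype anchors default
  to the strains observed in `c_call`.

## Validation scale

The packaged validation drivers (`validate_recovery()`,
`validate_snp_typing()`, `validate_reference_eval()`) run the full chain on
generated data and score it against the planted truth, matching alleles by
sequence so detected novel candidates count under their derived names. The
acceptance suite runs ten recovery repertoires of 50,000 reads (the
full study-scale configuration, with a planted 1-SNP novel allele at 0.4%
and 20 decoy alleles in the reference), SNP typing on 4,000 reads, and the
reference-completeness experiment on 10,000 error-free reads; these sizes
keep each driver's runtime in the tens of seconds on a single core while
leaving the binomial standard errors of every scored quantity far inside
the asserted margins.

## Known limitations

* The IGHG2B SNP offsets other than the printed CH1 sequences are synthetic
  placements; real datasets need a strain SNP table with measured offsets
  (`strain_snps()` documents the `placement` column).
* Novel-allele detection covers single-substitution variants of known
  alleles (the dominant real-world case); multi-SNP novelties within one
  allele and D/J novelties are out of scope.
* The annotator is a minimal germline-guided caller: no frame analysis, no
  CDR1/2 delineation, no species models.
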