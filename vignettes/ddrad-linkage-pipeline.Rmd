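---
title: "From ddRADseq reads to CP linkage markers without a reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ddRADseq reads to CP linkage markers without a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

raddmap turns double-digest RAD sequencing of an outbred F1 family --
two heterozygous parents and their full-sib progeny, a "CP" population
in JoinMap terminology -- into mapping-ready SNP markers when no
reference genome exists. This vignette explains the model behind each
stage, the parameters that matter, what the built-in simulator does and
does not emulate, and the numerical choices that keep the pipeline
deterministic.

## The problem

ddRADseq anchors reads at restriction sites (an EcoRI/MseI-type double
digest, fragments size-selected to 300--500 bp) and sequences one
101 bp forward read per fragment end. In a CP family, a biallelic SNP
is informative for mapping when at least one parent is heterozygous:

* `lmxll` -- heterozygous in parent 1 only, progeny segregate 1:1;
* `nnxnp` -- heterozygous in parent 2 only, 1:1;
* `hkxhk` -- both parents heterozygous for the same two alleles, 1:2:1;
* `efxeg` / `abxcd` -- three- and four-allele configurations, 1:1:1:1,
  realizable only for multi-allelic (SSR-type) markers.

Without a reference genome, the locus catalog itself must be built from
the reads, and the dominant failure mode is *paralog collapse*: reads
from near-identical repeat copies stack onto one catalog sequence,
producing apparent markers whose "alleles" are really different genomic
loci. Those markers inflate maps -- under maximum-likelihood ordering a
single contaminated linkage group can stretch to ten times its
regression length. The premapping filter cascade exists to remove them
before mapping.

## De novo reference

### Digital normalization (DNR)

Reads are streamed in a canonical order (lexicographic by individual,
then read ID -- the stream order is part of the definition, so the
reference is reproducible) and a read is saved as a new putative allele
iff at least half of its distinct 15-mers are *novel*, i.e. absent from
every previously saved allele. Saving a read adds all its 15-mers to
the index. A 101 bp read has 87 15-mers, so the boundary sits at 44
novel 15-mers. Two consequences follow from 15-mer arithmetic:

* a read differing from a saved allele by one SNP creates at most 15
  novel 15-mers -- far below half -- so allelic variants of a locus
  collapse into one reference sequence (their SNP is recovered later by
  the pileup caller);
* repeat copies within a few substitutions of each other collapse the
  same way, which is what turns them into multi-SNP sequences the F1
  filter can recognise.

K-mers are counted as distinct forward-strand strings (only forward
reads exist in this protocol), and a k-mer occurring twice in a read
counts once.

### Support bounds

Every read is then assigned to its best putative allele by a lenient
matcher (below) and each allele's *support* -- parents and progeny
pooled -- is counted. Alleles with support of four or fewer are
error-read singletons; alleles with support above 500 are
very-high-copy sequences, dominated in practice by plastid DNA, whose
per-cell copy number is orders of magnitude above the nuclear loci.
Both bounds are exposed as parameters because they are *calibrated to a
coverage regime*: the printed defaults (4 and 500) correspond to the
published study's genome-wide support distribution. The rule that
transfers across designs is that the bounds must bracket the expected
pooled per-locus support D -- in deep simulated designs we use roughly
2% of D for the low bound and 4 x D for the high bound, which cleanly
separates error-derived near-duplicates (a few dozen reads at most)
from locus primaries (hundreds) and still removes the plastid-like
sequence by two orders of magnitude.

### Reference deduplication

When the first-saved read of a locus happens to carry two or more
sequencing errors, the locus's other haplotype can later clear the
novelty rule on the strength of those error positions, and the
reference ends up with two near-identical entries. Reads then split by
haplotype and the SNP never surfaces in either pileup. The pipeline
therefore collapses retained alleles lying within the matcher tolerance
of one another onto their highest-support representative (greedy, in
decreasing support order, deterministic tie-breaks). Diverged paralog
copies merge here too -- intentionally, since their divergence sites
must end up on one sequence for the F1 filter to see them.

### The lenient matcher

The internal stand-in for a permissive short-read aligner is seeded,
end-gap-free and substitution-only: candidate alleles share at least
one exact 15-mer with the read, the alignment offset is fixed at zero
(both reads and catalog sequences are restriction-anchored), and the
best hit is the candidate with the fewest mismatches if that count is
at most 8, ties to the lowest allele ID. Widely spaced mismatches (9+
substitutions spread every ~11 bp) can defeat the seeding; at the error
rates this protocol produces, that case is negligible. A SAM import is
provided for users who prefer a real aligner for this step.

### Center-star reference (CSR)

The alternative catalog construction clusters progeny reads on parental
alleles and emits, per cluster, the sequence minimizing the total
(multiplicity-weighted) Hamming distance to all cluster members, ties
to the lexicographically smallest sequence. Distances are Hamming over
the aligned overlap -- reads are equal-length and anchored, so no gaps
arise. On simulated families the CSR route recovers no more
double-heterozygous (hk x hk) loci than DNR, matching its role as the
less sensitive alternative.

## Genotyping

The minimal pileup caller genotypes every sample at every reference
position: missing below `min_depth` (default 5); heterozygous when the
second base reaches `het_min_fraction` (default 0.2) of the sample
depth; else homozygous for the majority base. A position is emitted as
a biallelic site when exactly two bases occur across the called
genotypes; three or more is counted and dropped as triallelic. The 0.2
fraction at a minimum depth of 5 is deliberately tolerant: at ~15x
progeny depth a true heterozygote fails the rule with probability well
under 1%, while a single error read can only masquerade as
heterozygosity at the very lowest callable depths. That trade-off is
visible in downsampling experiments, where spurious low-depth
heterozygote sites multiply -- another reason the missing-data and
chi-square screens follow. Genotypes can equally be imported from a VCF
produced by an external caller; positions are 1-based throughout, VCF
convention.

Parental genotype pairs are classified into the five CP configurations
and progeny are coded (`lm`/`ll`, `nn`/`np`, `hh`/`hk`/`kk`, ...), with
`--` for missing. Progeny genotypes impossible under the parental pair
are set missing and counted as Mendelian inconsistencies rather than
raising an error: one bad call should not kill a marker, and markers
with systematic problems are caught by the chi-square screen. Phase is
never inferred; mapping software handles phase.

## The premapping filter cascade

Applied in order, each with its count recorded in the cascade report:

1. **F1 -- multi-SNP sequences.** A marker survives iff its reference
   sequence carries exactly one called SNP. The per-sequence SNP count
   is fixed at call time: removing a site later in the cascade must not
   turn a two-SNP sequence into an apparently clean one (this also
   makes F1 and F2 commute). This is the paralog-collapse filter and
   by far the largest cut on real data (77% of calls in the reference
   study).
2. **F2 -- SNP position.** Positions 1--9, adjacent to the restriction
   site, are artifact-prone; markers survive iff position >= 10.
3. **F3 -- missing data.** Survive iff the missing fraction over the
   currently retained individuals is strictly below the threshold
   (published sweep 0--30%, final < 5%); a threshold of zero forbids
   any missing data.
4. **F4 -- segregation distortion.** Pearson chi-square of the
   non-missing code counts against the Mendelian ratio (1:1 on df 1,
   1:2:1 on df 2, 1:1:1:1 on df 3). Statistic mode retains markers
   strictly below the cutoff (published sweep 10--50, final 20);
   p-value mode retains markers with p >= alpha (0.025), applied per
   marker with no multiplicity correction, as published. Both modes
   are provided because the statistic cutoff does not translate to a
   single alpha across segregation types with different df.
5. **Individual exclusion.** Individuals with strictly more than 90%
   missing data across the current markers are removed.
6. **Similarity deduplication.** Pairs of markers that agree in at
   least 94.5% of their shared scored individuals are single-linkage
   clustered and one representative is kept per cluster -- the marker
   with the least missing data, ties by marker ID. Tightly linked
   neighbours are legitimately this similar, so this is a redundancy
   filter, not an error filter.

All boundaries are implemented exactly as printed -- "four or fewer"
removed, "> 500" removed, "< 20" retained, ">= 0.945" clustered,
"> 90%" excluded -- and boundary-tested.

## Linkage quality control

* **Independence LOD** between two markers is the G statistic of
  independence on their code contingency table over shared scored
  individuals, divided by 2 ln 10. It is phase-free, which is what
  makes it usable for grouping before phase is known. Zero cells
  contribute nothing; degenerate tables score 0. Grouping is
  single-linkage transitive closure at a threshold. The published
  thresholds (20 framework / 30 final) belong to a 217-individual
  family; the ceiling for perfectly associated 1:1 markers is about
  0.3 x n, so thresholds must be scaled to family size.
* **Two-point recombination fractions** are direct counts over
  unambiguous meioses for same-parent pairs (discordance for 1:1
  pairs; for hk x hk pairs only double homozygotes are unambiguous and
  the opposite-homozygote fraction f = r^2/(r^2+(1-r)^2) is inverted
  to r). Phase unknown means min(r, 1-r) is reported.
* **Kosambi distances**: d = 25 ln((1+2r)/(1-2r)) cM, with the exact
  inverse 0.5 tanh(d/50) available for simulation checks.
* **Map-inflation ratio** (maximum-likelihood over regression length)
  and **framework-order concordance** (1 minus the normalized count of
  pairwise inversions against the fixed framework order) are the two
  published criteria for choosing filter thresholds. Map ordering
  itself is out of scope -- orders are imported from mapping software
  or taken from simulation truth.
* **Summaries** report per-group locus counts, framework EST-SSR
  counts, lengths and spacing. Spacing is length/loci *truncated* (not
  rounded) to two decimals; truncation is the convention that
  reproduces all twelve printed values of the reference map's summary
  table, two of which disagree with rounding.

## The family simulator

Every stage above is testable against `sim_config()` /
`simulate_family()`, which generate a family with complete ground
truth. What it emulates, with defaults chosen as the study conditions:

* 12 chromosomes; loci placed uniformly on a cM axis; fragments
  300--500 bp; 101 bp restriction-anchored single-end reads;
* parents at 248 reads/locus, progeny at 15 (the published design:
  one lane for two parents, ~50 progeny per lane; the study also
  reports a realized progeny mean of 13x -- the simulator uses the
  design value 15);
* per-locus heterozygosity `het_rate` per parent, independent between
  parents; a doubly heterozygous locus shares the same site and
  alleles, so it segregates hk x hk. Segregating sites are placed
  inside the sequenced window -- elsewhere they would be invisible;
* Mendelian transmission with crossovers from a Poisson
  (no-interference) process on the cM axis -- the simplest process
  whose pairwise recombination fractions agree with standard map
  functions at small distances. (Its exact pairwise rf is the Haldane
  value; at 10 cM the Haldane/Kosambi difference is under 0.01 and
  inside the sampling noise of the checks that use it.)
* repeat families: near-identical multi-copy loci at distinct genomic
  positions. Divergence between copies is applied inside the read
  window as an exact per-copy substitution count
  (max(1, round(divergence x read length))) -- window divergence is
  the only divergence the data can see, and two or more window
  differences are exactly what makes a collapsed family an
  F1-removable multi-SNP sequence, while staying far below the
  novelty threshold that would split the copies into separate catalog
  entries;
* one plastid-like sequence emitted at `plastid_copy_factor` (default
  20) times the per-locus depth in every individual, transmitted
  uniparentally;
* per-base substitution errors at `error_rate` (default 0.005);
  constant high base qualities (trimming is out of scope);
* Poisson read counts per locus and individual, enabling closed-form
  depth checks.

Determinism: each stage reseeds from `seed`, `seed + 1`, `seed + 2`,
so identical configurations give byte-identical FASTQ output.

Not emulated, hence not demonstrated by passing tests: paired-end
reads, indels, PCR duplicates, quality-score error profiles, allele
dropout from restriction-site polymorphism, and real repeat-family
complexity (the simulator's families are clean substitutions at fixed
divergence). Genotyping accuracy on real data also depends on the
external caller when one is used.

## Problem sizes used in the checks

The package's test suite and acceptance script run the full pipeline on
a 500-locus, 50-progeny family at 248x/15x with 0.5% error (~650k
reads), a 150-locus, 30-progeny family for the downsampling comparison,
a 90-marker three-chromosome family for grouping, and 2000 simulated
Mendelian markers at n = 217 for the chi-square screen's type-I error
-- sizes at which the binomial/Poisson tolerances in the tests are
meaningful for the properties being checked.

## Worked example

```{r example}
library(raddmap)

cfg <- sim_config(n_loci = 60, n_progeny = 20, depth_parent = 40,
                  depth_progeny = 12, het_rate = 0.6,
                  repeat_families = list(list(copies = 3,
                                              divergence = 0.02)),
                  chrom_length_cM = 80, seed = 101)
fam <- simulate_family(cfg)

D <- 2 * cfg$depth_parent + cfg$n_progeny * cfg$depth_progeny
res <- run_pipeline(fam$reads,
                    dnr = dnr_params(min_support = ceiling(0.02 * D),
                                     max_support = 4 * D))
res$report
write_loc(res$markers, "family.loc", name = "sim_family")
```
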