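---
title: "Haplotype-based SNP detection: method and design notes"
author: "hapsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based SNP detection: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapsnp)
```

## The problem

Deep multi-read alignments — RNA-seq reads mapped to transcripts, or reads
placed by a *de novo* assembler — contain abundant single-nucleotide variation,
but most apparent variant columns are artifacts: sequencing miscalls,
homopolymer over/undercalls, untrimmed adaptor, or reads from paralogous gene
copies collapsed onto one contig. `hapsnp` detects *reliable* SNPs from such
alignments without a reference genome, in diploid and polyploid material, and
genotypes the samples in the alignment via their read groups. The output is
aimed at genotyping-by-sequencing and SNP-array design: marker sites with
flanking sequence, plus a per-contig paralogy heuristic.

## The three filters

Candidate sites pass three successive filters; a site's status moves forward
through `potential → high_confidence → reliable` or ends in a rejected state.

**Filter 1 — read support.** A column of the pileup is a *potential SNP* iff
at least two distinct alleles are each supported by at least
`min_allele_reads` reads (default 2). The threshold may instead be a fraction
of the reads covering the column (`threshold_mode = "fraction"`,
`ceiling(min_allele_fraction × coverage)`, never below one read), or the more
permissive of the two (`"both_or"`). A deletion relative to the contig (`-`)
may form an allele; such sites carry an `indel_flag`. `N` bases never count.

**Filter 2 — base quality.** Support is recomputed over *high-quality* bases
only; a site stays iff two alleles still meet the threshold. A base is high
quality iff:

* its Phred score is at least `phred_high_quality` (default 20, ≈1% call
  error). Bases without a score — reads lacking qualities entirely, and gap
  columns — are assumed high quality;
* it is not among the first `mask_5prime` / last `mask_3prime` bases of the
  read in sequencing orientation (reverse-strand reads are masked from their
  own ends). This suppresses false SNPs from incomplete adaptor trimming;
* when `mask_homopolymer` is on: it is not inside or immediately adjacent to
  a homopolymer run of `homopolymer_min_run` (default 3) or more identical
  bases *in the read's own sequence* — over/undercalls in homopolymeric
  tracts are the signature error of pyrosequencing-type platforms, and they
  land at run boundaries with high Phred scores, so the pattern mask is the
  only guard. A run truncated by the read's first or last base has unknown
  true length and is conservatively treated as homopolymeric: without this,
  reads that start or end *inside* a run evade the mask, and recurrent
  boundary overcalls were observed to leak through as false reliable SNPs.

Runs are detected on the read, not the consensus, because the error is a
read-level artifact. Homopolymer masking defaults to off; switch it on for
pyrosequencing-style data.

**Filter 3 — haplotype support.** Reads (mate pairs merged into one fragment;
mates disagreeing at a shared site give a missing value there) are clustered
over the high-confidence sites, and a site is *reliable* iff at least two of
its alleles each appear in a retained haplotype. Quality filtering runs
*before* haplotyping precisely so that haplotypes are built from
high-confidence sites only.

## The clustering rule

No optimization objective is imposed; clustering is greedy and deterministic:

1. Fragments are processed by (number of covered sites descending, fragment
   id ascending). Each fragment joins the first existing cluster it is
   compatible with — *at least one mutually covered site, and agreement at
   every mutually covered site* — otherwise it founds a new cluster.
2. Requiring an overlapping site is essential: fragments over disjoint SNP
   blocks are never linked, so a haplotype whose SNPs lie farther apart than
   the fragment span *fragments* into several clusters. This is a real
   phenomenon of the data, not an algorithmic accident, and it is corrected
   at the counting stage (below) rather than by speculative merging.
3. A conflict confined to cluster-vector entries attested by fewer than
   `min_haplotype_reads` member fragments does not veto a join: the attesting
   fragments are detached and reprocessed once at the end. One high-Phred
   miscall in the first fragment to reach a site would otherwise seed the
   cluster with a wrong allele and force every clean fragment behind it into
   a spurious cluster.
4. Clusters with fewer than `min_haplotype_reads` fragments (default 2) are
   discarded — a haplotype seen in one read is indistinguishable from a
   chimeric or error read — and their fragments are left unassigned.
5. A retained haplotype's allele at a site is the majority over its members,
   reported only where at least `min_haplotype_reads` members carry it; ties
   and weaker evidence give missing. For a conflict-free cluster this is the
   members' unanimous allele.
6. Retained haplotypes whose final vectors overlap compatibly are merged to a
   fixed point (founding order, deterministic). Clusters over disjoint site
   sets are never merged.

With `min_haplotype_reads = 1`, steps 3, 5 and 6 reduce to the plain greedy
rule: every entry is firm, vectors are unanimous, and post-hoc compatible
overlaps cannot arise. The test suite exploits this to compare the greedy
result against an exhaustive minimal partition of fragments into
conflict-free classes: every greedy cluster is internally compatible, the
cluster count never falls below the brute-force minimum, and the two agree
whenever the matrix has no missing cells.

Steps 3, 5 and 6 exist because measurement showed plain greedy clustering
failing this package's own recovery requirement: on the default diploid
scenario, single high-Phred miscalls at SNP columns seeded, blocked, or split
haplotype chains in ~8% of replicates, inflating the corrected haplotype
count. Each refinement targets one observed mechanism and leaves the
observable contract — haplotypes are groups of reads agreeing at SNP
positions — unchanged.

### Corrected haplotype count

The per-contig haplotype count is corrected for fragmentation by taking the
**maximum number of haplotypes carrying an allele at any single SNP
position**: fragmented pieces of one haplotype never co-occur at a site, so a
diploid contig with two unlinked SNP blocks shows four clusters but a
corrected count of two. Contigs whose corrected count exceeds
`expected_ploidy_haplotypes` (default 2, diploid) are flagged as possible
paralog mixtures on marker export. Discarded (low-support) haplotypes do not
contribute to per-site counts.

## Genotyping

At each reliable site, each sample's unmasked high-quality bases are counted
per allele. One allele at `min_allele_reads` or more gives a single-allele
call; two or more give a multi-allele call (`"A/G"`); covered-but-weak gives
`low_coverage`; no counted base gives `no_data`. The thresholds deliberately
reuse `min_allele_reads` — no new knob. Per-sample counts sum exactly to the
site's high-quality counts; this conservation is asserted in the tests.

## Input handling

SAM (plain text or BAM) is decoded via Rsamtools; ACE is parsed natively.
Internal coordinates are 0-based half-open (converted from SAM's 1-based
positions on read; reported 1-based again on output). CIGAR strings are
projected onto contig columns: insertions relative to the contig are dropped
(no variant calling inside insertions), deletions become `-` columns eligible
as alleles. Secondary and supplementary records are skipped, duplicates kept.
ACE pads (`*`) in reads become `-`; pad columns of the consensus are
insertions and are dropped entirely. When no reference is supplied the
consensus is the per-column majority (ties alphabetical, zero coverage `N`).
Sample labels come from SAM `RG` tags or from read names: by default the
prefix before the first `|`; a regular expression with a capture group
(e.g. `"\\|([^/]+)"`) selects any other name part. ACE files carry no
per-base qualities, so all their bases are treated as high quality — with
masking still applied — and SAM-vs-ACE result parity holds exactly under a
quality-blind configuration.

## The simulator

`sim_scenario()` / `simulate_alignment()` generate alignments with planted
haplotypes and a machine-readable truth table; they are the package's
validation surface. The default scenario models a diploid transcript
fragment: contig 600 bp; 10 SNPs evenly spaced (~55 bp, so 80 bp reads span
adjacent sites); two samples, each homozygous for one haplotype, sampled
50/50; 30× coverage; 1% substitution error. An injected error receives Phred
2 with probability `q_informative` (default 0.9) and otherwise keeps the high
score (40) — base callers flag most but not all miscalls; `q_informative = 0`
makes the quality filter blind, which the tests use to demonstrate filter 2's
effect. Homopolymer-associated errors are modelled as overcalls toward the
run base at run-adjacent positions, always at high Phred. Adaptor remnants
replace the 3' tail of reads at high Phred. Fragment ids are assigned in
start-position order (as in any coordinate-sorted alignment), with the sample
label as a name suffix.

Two generator properties matter for interpreting results:

* SNP sites are planted outside homopolymer context (the ±3 bp window around
  a site is rewritten to contain no two adjacent equal bases, and alternate
  alleles differ from both neighbours). With masking on, a variant inside or
  adjacent to a run is masked in every read *by design*; planted SNPs must
  therefore be recoverable sites. Consequently the tests say nothing about
  sensitivity for real variants in homopolymeric context — those are
  deliberately sacrificed by the masking filter.
* Errors are substitutions only. Indel genotyping is out of scope, so
  simulated indels would only exercise code paths the package does not claim.

`fragmentation_scenario()` plants two SNP blocks (sites 60/80 and 300/320 on
400 bp) farther apart than the 70 bp reads, error-free: the caller must
report four raw clusters and a corrected count of two; the paired variant
(300 bp insert) links the blocks and gives two raw clusters.

What the simulator does **not** emulate: cycle-dependent Illumina quality
decay, flowgram-resolved pyrosequencing errors, mapping bias, chimeric reads,
or non-uniform coverage along transcripts. Passing tests demonstrate the
filter logic under the stated error model, not performance on any particular
platform's full error spectrum.

## Numerical and degenerate-input choices

* Fraction thresholds round up and never drop below one read.
* "Fraction of total reads" means reads covering the column by default;
  `fraction_basis = "contig"` switches to the contig's read count.
* Consensus ties break alphabetically; zero-coverage columns are `N`.
* Zero high-confidence sites give an empty allele matrix, zero haplotypes and
  a corrected count of 0; empty alignments produce headers-only CSV files.
* Marker flanks truncate at contig edges and are never padded.
* All orderings (site, haplotype, read, CSV row) are fixed; identical input
  and configuration give byte-identical output files. The results manifest
  deliberately carries no timestamp.

A caveat found by the monotonicity tests: the *high-confidence* site count is
monotone in every threshold, but the *reliable* count is not guaranteed to be
— at the degenerate setting `min_allele_reads = 1`, every isolated
sequencing error becomes an allele-matrix column, and the noise-flooded
matrix can destroy haplotype backing for genuine sites; raising the threshold
back to 2 then increases the reliable count. From the two-read level upwards
monotonicity holds in all tested grids.

## Problem sizes used in validation

The replicate studies run 200 simulated contigs (600 bp, ~225 reads each)
through the full pipeline, the clustering oracle enumerates all partitions of
up to 8 fragments × 4 sites over 500 random matrices, and the scenario
round-trips cover the default, fragmentation and paired-fragmentation
geometries. These sizes give stable rate estimates (binomial SE ≈ 1.4% at
n = 200) while keeping the whole suite and the acceptance script to about a
minute each.

## Known limitations

* No statistical genotype likelihoods, ploidy dosage, or strand-bias tests.
* Indels are surfaced only as `-` alleles with a flag, never genotyped.
* No CRAM input, no realignment, no soft-clip rescue, no VCF output.
* The paralog flag is a count heuristic; sequence-similarity screening of
  exported markers (e.g. against the rest of the transcriptome) is left to
  external tools.
* Greedy clustering does not optimize any global objective; with very sparse
  matrices the haplotype count can exceed the minimal compatible partition.
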