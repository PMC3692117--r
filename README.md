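# hapsnp

Haplotype-based detection of reliable SNPs from multi-read alignments — no
reference genome required — with per-sample genotyping, fragmentation-corrected
haplotype counts, and marker export for assay design.

## Who this is for

Breeders and population geneticists working from RNA-seq or genomic reads
mapped to transcripts or *de novo* assembled contigs, in diploid or polyploid
material. Deep alignments are full of apparent variant columns that are really
sequencing miscalls, homopolymer over/undercalls, untrimmed adaptor, or
collapsed paralogs; `hapsnp` separates reliable SNPs from these artifacts and
produces the per-accession allele tables used in genotyping-by-sequencing and
the flanking-sequence records used to populate SNP arrays.

## The method

Candidate sites pass three successive filters:

1. **Read support** — a pileup column is a *potential* SNP iff ≥ 2 alleles
   each occur in at least `min_allele_reads` reads (default 2), or in a
   user-chosen fraction of the covering reads.
2. **Base quality** — support is recomputed over high-quality bases only
   (Phred ≥ 20 by default; bases without scores count as high quality).
   Optionally, bases in or adjacent to homopolymer runs (≥ 3 bp) and bases at
   the read 5'/3' ends are masked as low quality, targeting
   pyrosequencing-style overcalls and adaptor remnants. Survivors are
   *high-confidence* SNPs.
3. **Haplotype support** — read fragments (mate pairs merged) are clustered
   greedily and deterministically over the high-confidence sites: a fragment
   joins the first cluster it agrees with at every mutually covered site
   (≥ 1 shared site required), clusters below `min_haplotype_reads`
   fragments are discarded. A site is a *reliable* SNP iff ≥ 2 of its alleles
   are each carried by a retained haplotype.

Because SNPs farther apart than the fragment span cannot be linked, one true
haplotype may fragment into several clusters; the per-contig haplotype count
is therefore corrected by taking the **maximum number of haplotypes observed
at any single SNP position**. Contigs whose corrected count exceeds the
expected ploidy maximum (2 for diploids) are flagged as possible paralog
mixtures on marker export.

Inputs are SAM/BAM or ACE alignments; sample labels come from SAM read groups
(`RG`) or from read names. A bundled simulator (`sim_scenario()`,
`simulate_alignment()`) generates alignments with planted haplotypes, SNPs,
read groups and platform-style errors alongside a truth table, and is the
basis of the test suite. See the methods vignette
(`vignettes/haplotype-snp-calling.Rmd`) for the full model and design notes.

## Worked example

Simulate a diploid transcript (600 bp, 10 planted SNPs, two accessions each
homozygous for one haplotype, 30× coverage, 1% error), then call SNPs:

```r
library(hapsnp)

sc  <- sim_scenario(seed = 7, samples = list(`Col-0` = 1L, `Can-0` = 2L))
sim <- simulate_alignment(sc, dir = "demo")          # writes SAM, ACE, truth
res <- call_snps(sim$sam, filter_config(mask_homopolymer = TRUE))

res$contigs[c("n_reads", "n_potential_snps", "n_high_confidence_snps",
              "n_reliable_snps", "n_haplotypes", "corrected_haplotype_count")]
#>   n_reads n_potential_snps n_high_confidence_snps n_reliable_snps
#> 1     225               20                     10              10
#>   n_haplotypes corrected_haplotype_count
#> 1            2                         2
```

Twenty pileup columns had two alleles with two or more reads each; the
quality filter removed the ten error columns, and all ten planted SNPs
survived haplotype filtering. The two reconstructed haplotypes match the
planted ones, and the corrected haplotype count (2) matches diploid
expectation — no paralog flag:

```r
head(res$snps[c("position", "ref_allele", "alleles", "hq_allele_counts")], 3)
#>   position ref_allele alleles hq_allele_counts
#> 1       49          G     G/T         G=12;T=8
#> 2      105          G     G/T        G=21;T=14
#> 3      161          T     T/C        T=22;C=13

res$haplotypes[c("haplotype_id", "support", "alleles")]
#>   haplotype_id support    alleles
#> 1            1     115 GTCCGCTGCA
#> 2            2     109 TGTTCGGTTG

head(res$genotypes, 4)   # alleles per accession at each reliable SNP
#>   contig_id position sample allele_counts call
#> 1   contig1       49  Can-0           T=8    T
#> 2   contig1       49  Col-0          G=12    G
#> 3   contig1      105  Can-0          G=21    G
#> 4   contig1      105  Col-0          T=14    T

write_results(res, "demo_results")     # reloadable CSV file set
mk <- export_markers(res, flank_length = 25)
mk$context[1]
#> [1] "CGGCTCGATGCCGCTCTGTTAGCTA[G/T]CATAACTAGAGCTTATCGTCCCTGT"
```

The same run from the shell, using the installed `exec/hapsnp` script:

```sh
hapsnp simulate --out demo --seed 7
hapsnp call --in demo/sim.sam --out demo_results --mask-homopolymer
hapsnp view demo_results --min-snps 8 --max-snps 25
hapsnp export demo_results --out markers.csv --flank 60
```

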