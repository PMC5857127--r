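# readorigin

Exhaustive read accounting for RNA-seq: every read in a sample receives
exactly one origin category.

Standard RNA-seq analyses align reads to the host genome and transcriptome
and quietly discard the 10–20% that fail to map — yet those unmapped reads
carry signal: densely A-to-I-edited transcripts, repeat elements missing
from the assembly, circRNA back-splices, gene fusions and trans-splicing,
recombined B/T-cell receptors, and microbial RNA.  `readorigin` implements
the read origin protocol for transcriptomics researchers and method
developers who want the whole sample explained, and a fully labelled
synthetic benchmark to prove the machinery correct at desk scale.

## The method in brief

Stage 0 maps all reads to the host transcriptome + genome at a strict
primary edit budget (≤ 2 edits) and profiles the mapped ones into genomic
(junction/CDS/UTR/intron/…), repeat (class/family), and immune-locus
categories.  Unmapped reads then pass through seven *sequential* filters,
each consuming its matches:

1. quality control — quality < 30 in ≥ 75% of bases, low-complexity
   (dinucleotide entropy < 1 bit or homopolymer run ≥ 60%), and rDNA
   matches;
2. lost human reads — sensitive realignment at ≤ 10% of read length;
3. hyper-edited reads — transform A→G in reads and references, realign,
   recover, and keep dense clusters where A-to-G mismatches exceed 5% of
   the read length (strictly);
4. lost repeats — sensitive alignment to repeat consensus sequences;
5. non-co-linear reads — split alignment classified as fusion (different
   chromosomes), circRNA (head-to-tail within one gene) or trans-splicing
   (distant co-linear), aggregated into events supported by > 1 read;
6. V(D)J recombination — reads spanning a V 3' end and a J 5' start of
   one locus (≥ 20 bp each, ≤ 10% mismatches);
7. microbial reads — best-hit assignment with lowest-common-ancestor
   resolution of ties; the total is the microbial load.

The sequential order is the point: compartments share homology, and
classifying conservatively (host before microbe) prevents
cross-assignment.  `order_experiment()` quantifies exactly that.

Repertoire/community summaries: richness, Shannon index
(−Σ p·log2 p, bits), Sørensen–Dice dissimilarity (1 − 2J/(A+B)), and
seeded subsampling to the smallest sample.

## Worked example

```r
library(readorigin)

cfg    <- sim_config(seed = 1, n_reads = c(
  transcriptomic = 600, "repeat" = 100, rdna = 40, low_quality = 40,
  low_complexity = 30, lost_human = 40, hyper_edited = 60,
  ncl_circ = 30, ncl_fusion = 30, ncl_trans = 30, immune_vj = 60,
  microbial = 90, immune_locus = 20, mitochondrial = 20))
bundle <- build_references(cfg)
sim    <- simulate_reads(bundle, cfg)
result <- rop_run(sim$reads, bundle, rop_config(sample_id = "demo"))
result
#> <rop_profile> demo - 1190 reads
#>   mapped_genomic            611   51.34%
#>   mapped_repeat              49    4.12%
#>   mapped_immune_locus        20    1.68%
#>   low_quality                40    3.36%
#>   low_complexity             23    1.93%
#>   rdna                       40    3.36%
#>   lost_human                 50    4.20%
#>   hyper_edited               60    5.04%
#>   lost_repeat                50    4.20%
#>   ncl                        90    7.56%
#>   immune_vj                  60    5.04%
#>   microbial                  90    7.56%
#>   unaccounted                 7    0.59%
```

Reading the numbers: 680 reads (57.1%) map outright — 611 to genes and
intergenic space, 49 into annotated repeat copies, 20 wholly inside
germline V segments.  The seven steps then explain all but 7 of the 510
unmapped reads: the 40 planted low-quality and 40 rDNA reads are removed
at QC, the 40 reads with four extra substitutions (plus mapped-class reads
that picked up ≥ 3 sequencing errors) come back as `lost_human`, all 60
densely edited reads are recovered as `hyper_edited`, the host-absent
repeat family accounts for `lost_repeat`, the 90 NCL reads classify into
their three subtypes, and every V(D)J and microbial read lands in its
category.  The 7 unaccounted reads (0.59%) are dinucleotide-repeat reads
whose sequencing errors lifted them just above the low-complexity entropy
threshold — the understood residue of this mixture.

Results are tidyverse-native throughout:

```r
glance(result)          # one-row run summary
#> # A tibble: 1 × 9
#>   sample_id total_reads mapped pct_mapped unaccounted pct_unaccounted ...
#> 1 demo             1190    680       57.1           7           0.588

tidy(result)            # one row per read: category, step, evidence
autoplot(result)        # category bar chart

head(result$ncl_events, 2)
#> # A tibble: 2 × 9
#>   subtype chrom_a pos_a chrom_b pos_b gene_a gene_b support reported
#> 1 circRNA chr1     1800 chr1     1000 g01    g01         20 TRUE
#> 2 circRNA chr2    10799 chr2     9999 g09    g09         10 TRUE

ev <- result$vj_events  # repertoire diversity over VJ combinations
alpha_diversity(dplyr::transmute(ev, sample_id = "demo",
                                 event = paste(v_gene, j_gene)))
#> # A tibble: 1 × 3
#>   sample_id richness shannon
#> 1 demo            40    5.19
```

A thin command-line front end covers the two end-to-end entry points:

```sh
Rscript inst/scripts/rop.R simulate --seed 1 --out sim_dir
Rscript inst/scripts/rop.R run --reads sim_dir/reads.fastq \
        --bundle sim_dir --out report_dir
```

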