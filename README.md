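# chiralseq

Chiral spike-in controls ("sequins") for DNA sequencing assays.

## The problem

Reference standards for sequencing must behave like the sample they
accompany (*commutability*) yet remain distinguishable from it, so they can
be separated and used as internal truth. These demands usually conflict: a
standard identical to human DNA cannot be told apart from it; a scrambled
one no longer behaves like it.

A chiral control resolves the conflict. A DNA sequence written 5'→3' is
generally not superimposable on the same bases in reverse order: `ATGCATGC`
and its mirror `CGTACGTA` form a chiral pair (the mirror is *not* the
reverse complement, `GCATGCAT` — nothing is complemented). Reversal
preserves every order-insensitive property — composition, GC, repeat
structure, k-mer entropy — but destroys directional sequence identity, the
one property aligners key on. A synthetic mirrored copy of a genomic region
can therefore be spiked into a sample, sequenced with it, and cleanly
partitioned afterwards by aligning to a combined index of the genome and
its mirrored build (`hg38`-style contigs plus `<contig>_rev` twins).

`chiralseq` implements the full method:

* **mirror transforms** — sequences, whole genomes, intervals, primer
  pairs, alignments (CIGAR-reversing coordinate transform) and pileup
  profiles, each an exact involution;
* **sequin design** — 1.8 kb mirrored molecules carrying SNV/indel
  alleles; germline genotype mixtures (het = ref+alt at equal mass,
  hom = alt alone); somatic VAF dilution ladders (level *i* at VAF
  2^−(i−1), 100% → 0.1% over 11 levels); stable/unstable microsatellite
  mixtures; in-silico-verified mirrored primer pairs;
* **read operations** — namespace partitioning with cross-alignment
  accounting, quality-preserving read flipping, direct mirrored-coordinate
  alignment transform, seeded pair-coherent downsampling with nested
  fractions;
* **profiles and commutability** — per-base depth/mismatch/insertion/
  deletion pileups, windowed concordance (R², Pearson, Spearman),
  feature-aggregated error rates, breadth at depth, insert sizes;
* **variant evaluation** — truth labeling against the manifest after
  left-normalization, sensitivity, observed-vs-expected VAF regression
  (1.5–100% range), and score-threshold optimization that excludes all
  sequin false positives while maximizing retained true positives
  (verified optimal against exhaustive search);
* **MSI calling** — spanning-read repeat-length histograms (CIGAR walk,
  4 bp aligned overhang) with an internal resolution check: if the assay
  cannot separate the stable from the unstable sequin mixture, the sample
  verdict is `insufficient_resolution` rather than a false negative;
* **simulation** — seeded genomes with planted repeats, paired-end and
  long reads with context-dependent error models (`error_free`,
  `pcr_free`, `standard`, `nanopore_like`; indel rate scaled by
  mirror-invariant repeat-run length), truth alignments included.

See the vignette (`vignettes/chiral-sequin-controls.Rmd`) for the model,
parameter defaults and design rationale.

## Worked example

Design a germline sequin mixture, sequence it in silico alongside a human
sample, and evaluate the assay against the manifest:

```r
library(chiralseq)

mirror_sequence("ATGCATGC")
#> [1] "CGTACGTA"

g <- simulate_genome(data.frame(name = "chr1", length = 16000, gc = 0.45),
                     seed = 7)
pos <- seq(1800, by = 1800, length.out = 6)
ref <- substring(g$genome[["chr1"]], pos + 1, pos + 1)
alt <- vapply(ref, function(r) setdiff(c("A","C","G","T"), r)[1], "")
variants <- data.frame(contig = "chr1", pos0 = pos, ref = ref, alt = alt,
                       genotype = rep(c("het", "hom"), 3))

manifest <- design_genotype_mixture(g$genome, variants, region_length = 1200)
manifest
#> mixture manifest 'germline': 9 molecules, 6 expected variants

mir    <- build_mirrored_genome(g$genome)
human  <- simulate_reads(mir$combined["chr1"], c(chr1 = 1), coverage = 45,
                         seed = 8, prefix = "hs")
sequin <- simulate_sequin_reads(manifest, mir$contig_table, coverage = 1500,
                                seed = 9)

report <- run_germline_eval(rbind(human, sequin), g$genome,
                            mir$contig_table, manifest, seed = 1)
str(report$stages$evaluation[c("expected", "detected", "sensitivity")])
#> List of 3
#>  $ expected   : int 6
#>  $ detected   : int 6
#>  $ sensitivity: num 1
str(report$stages$downsample)
#> List of 3
#>  $ fraction  : num 0.183
#>  $ human_cov : num 45.7
#>  $ chiral_cov: num 250
```

The nine molecules are the three het sites (wild-type + variant molecule
each) plus the three hom sites (variant molecule only). The chiral reads
arrived at ~250× and were downsampled to the human sample's ~46× before
calling; every planted variant was recovered. The classic summary numbers
print as expected:

```r
sensitivity(85, 87)$value          # detection sensitivity, 2 decimals
#> [1] 0.98
cross_alignment_percent(133, 732e6) # misassigned reads, percent, 3 s.f.
#> [1] 1.82e-05
100 * ladder_vaf(5)                 # VAF at dilution-ladder level 5
#> [1] 6.25
```

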