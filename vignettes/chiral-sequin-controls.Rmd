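---
title: "Chiral sequin controls: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chiral sequin controls: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralseq)
```

## The chiral control model

A DNA sequence read 5'→3' is generally not superimposable on the same bases
written in reverse order: `ATGCATGC` and its mirror `CGTACGTA` form a
*chiral pair*. The mirror is **not** the reverse complement (`GCATGCAT`) —
nothing is complemented, only the order reverses. Because reversal is a
bijection on positions, a sequence and its mirror share every
order-insensitive property: mono-nucleotide composition, GC content, the
homopolymer run-length spectrum, and the k-mer entropy (each k-mer of the
mirror is a reversed k-mer of the original). They differ exactly in the
property that matters to an aligner — directional sequence identity — so a
synthetic mirrored copy of a genomic region ("sequin") can be spiked into a
sample, sequenced alongside it, and unambiguously separated afterwards by
aligning to a combined index that contains both the genome and its mirrored
build (`<contig>_rev` contigs). The separated sequin reads then serve as an
internal truth set for the assay: their coverage biases, error profiles,
variant calls and repeat-length distributions report what the assay does to
a sequence of exactly that composition and context.

`chiralseq` implements this whole loop: design (mirror transforms, sequin
molecules, mixtures), data processing (partition, flip, coordinate
transform, downsampling), measurement (pileup profiles, concordance,
variant labeling, threshold optimization, MSI calling) and a seeded read
simulator that generates the data the tests and examples run on.

## Coordinate algebra

All internal coordinates are 0-based half-open; 1-based conventions appear
only at SAM/VCF file boundaries. On a contig of length $L$, position $p$
maps to $L-1-p$ and interval $[s,e)$ to $[L-e,\,L-s)$; the map is a
width-preserving involution (`map_interval()`, exhaustively checked for all
$L \le 50$). An alignment at position $p$ with reference span $w$ transforms
to $L-p-w$ on the twin contig with its CIGAR operation order reversed and
its stored bases mirrored (`transform_alignments()`). This direct transform
replaces re-alignment of flipped reads in the bundled workflows: external
aligners are not a dependency, and on simulated truth alignments the
transform is exact rather than approximate. `flip_reads()` is still
provided for the re-alignment route in production settings.

One subtlety is insertion attribution. Pileup insertion counts are anchored
to the left flanking base of their junction. Junctions map to junctions
under mirroring, but the *left* flank of a junction becomes the *right*
flank after reversal, so the mirrored insertion array is the reversal
shifted by one position. `mirror_profile()` encodes exactly this, which is
why `pileup(transform_alignments(a))` equals `mirror_profile(pileup(a))`
bit-exactly — an equality the test suite asserts on randomized alignment
sets including soft clips, insertions and deletions.

## Sequin design

* **Molecules.** A sequin molecule is the mirror of a (by default) 1.8 kb
  genomic region, optionally edited first with SNV/insertion/deletion
  alleles (`build_molecule()`); editing and mirroring commute with variant
  projection (`project_variant()`), a property tested on randomized indels.
* **Genotype mixtures.** Heterozygous variants are represented by a
  reference and a variant molecule at equal mass (expected VAF 0.5),
  homozygous variants by the variant molecule alone (VAF 1.0).
* **The VAF ladder.** Somatic mixtures place variants on a geometric
  ladder, level $i$ at VAF $2^{-(i-1)}$. Eleven levels span 100% down to
  $2^{-10} \approx 0.098\%$, which prints as 0.1%; level 5 is 6.25%.
  Default placement bounds are 7–9 variants per level. A matched "normal"
  manifest carries only the wild-type molecule of every site.
* **MSI sequins.** For a microsatellite locus (unit × copies) the stable
  control is the wild-type sequin alone; the unstable control adds a
  mutant differing by one repeat unit, at a default 0.5 mass fraction. The
  mixing ratio is not dictated by the biology and is exposed as a
  parameter.
* **Primers.** The pair amplifying $[s,e)$ of a template maps to the pair
  amplifying $[L-e, L-s)$ of the mirrored template by *complementing* each
  primer (no reversal) and swapping the forward/reverse roles. This is the
  unique recipe consistent with the geometry, and `mirror_primer_pair()`
  refuses to return a design that its in-silico PCR check
  (`insilico_pcr()`) cannot verify on both templates. A plain per-primer
  "mirror the string" reading would not prime the mirrored interval.

## The read simulator and its error models

`simulate_reads()` draws fragments per molecule proportional to mass
fraction (per-template expected depth = `coverage × abundance`), with
truncated-normal fragment lengths (default 300 ± 30), uniform starts, both
orientations equiprobable, and fixed 100 nt reads. Errors are injected per
reference position: a flat mismatch rate and an indel rate scaled by
repeat context,

$$r_{\text{indel}}(p) = \min\!\big(r_0 \, (1 + \sigma \,(\ell(p)-1)),\; 0.3\big)$$

where $\ell(p)$ is the length of the longest simple tandem run (units
1–3 nt) covering $p$ (`repeat_context()`), $r_0$ the base indel rate and
$\sigma$ the slippage coefficient. Because maximal run spans mirror
exactly, $\ell$ is mirror-invariant and error injection is
mirror-symmetric *by construction* — the structural assumption behind
treating a mirrored control as commutable with its template, here made
explicit and testable. Truth alignments carry the injected errors in their
CIGARs, so profiling tests need no aligner.

Preset rates (per base): `error_free` (0/0/0); `pcr_free` mismatch
$10^{-3}$, indel $4\times10^{-4}$, $\sigma = 0.15$; `standard` mismatch
$10^{-3}$, indel $4\times10^{-3}$, $\sigma = 0.9$; `nanopore_like`
mismatch 0.02, indel 0.03, $\sigma = 0.5$. The two library-preparation
presets were fixed once from what they must represent: at a 25 nt
homopolymer the standard (PCR-amplified) preset yields ≈ 0.09 indels per
base — nearly every spanning read carries slippage, the regime in which
repeat-length distributions smear into uninformativeness — while the
PCR-free preset yields ≈ 0.002, leaving ~95% of spanning reads exact.
Deletions and insertions are equally likely (`del_frac = 0.5`); the cap of
0.3 per base keeps degenerate contexts finite.

What the simulator does *not* emulate: quality-score structure (all bases
Q40), GC-dependent amplification bias, optical duplicates, chimeras, and
unit-length (rather than single-base) slippage at multi-nucleotide
repeats. Passing tests therefore demonstrate the correctness and internal
consistency of the algorithms under the stated error structure, not
performance on any particular instrument's artifacts.

## Commutability metrics

`pileup()` tallies per-position depth (reads spanning, deletions
included), mismatches, anchored insertions and deletions, above a
configurable MapQ floor (a floor of 11 reproduces the usual "MapQ > 10"
unique-alignment filter). Concordance between two profiles is the squared
Pearson correlation of (optionally) 40 bp sliding-window means — window
step defaults to half the window — with mirrored pairing reversing the
second profile's axis first; Spearman's rho is reported alongside.
Feature-aggregated error rates divide the error count over a feature
class's positional footprint by the total depth there, so classes are
comparable regardless of footprint size; classes without coverage are
absent rather than zero.

The mirror benchmark (`make_mirror_benchmark()`) builds 8 region pairs of
1.8 kb with planted homopolymers and dinucleotide repeats, sequences all
16 templates at 200× under the standard preset, and feeds the profile
pipeline. At these sizes the paired fwd/rev windowed indel-error profiles
reach $R^2 \approx 0.86$–0.91 while unpaired regions sit near 0 — the
desk-scale, property-based analog of the published concordance
experiments, whose exact values depend on archived sequencing data and are
not reproducible from code alone. Problem sizes (8 × 1.8 kb × 200×;
~58,000 reads) were chosen as the smallest panel at which window-level
Poisson noise is clearly subordinate to the planted rate structure.

## Variant evaluation and threshold optimization

Calls inside sequin footprints are decidable by construction: after
left-normalization against the reference (`normalize_variant()`, so
alternate indel anchorings match), a call is TP iff its
(contig, position, ref, alt) appears in the manifest, otherwise FP; calls
outside any footprint are an error rather than silently unlabeled.
`optimize_thresholds()` searches minimum-value score thresholds (AND
semantics over any number of named scores, ties pass) over the grid of
−∞, observed values and +∞ per dimension, keeping only rules that retain
zero sequin FPs and maximizing retained TPs, then retained sample
candidates, then choosing the lexicographically smallest thresholds — a
deterministic optimum verified against exhaustive search on randomized
instances. When only the all-rejecting rule is feasible it is returned
flagged (`all_rejected`). Whether SNVs and indels should be thresholded
jointly or separately is left to the caller: the optimizer is generic in
its score columns, so passing per-class subsets gives per-class rules.

VAF accuracy is summarized by simple regression of observed on expected
VAF within 1.5–100% — below that floor, binomial sampling noise at
typical depths dominates the signal, so those levels are excluded from
the fit rather than allowed to leverage it.

## MSI calling and the resolution check

Repeat length per spanning read is measured by a CIGAR walk across the
locus (reference width + insertions strictly inside − deletions
overlapping), requiring ≥ 4 aligned bases of overhang on both sides;
soft-clipped bases do not count. This is deterministic and
alignment-consistent, at the cost of mis-attributing indels that an
aligner places at the locus edge — a documented limitation of any
CIGAR-based length extraction.

The decision rule is necessarily explicit where visual gel comparison is
not: a distribution pair is *separated* when their near-modal offset sets
are disjoint or the unstable mixture's frequency at ±1 unit reaches
`tau = 0.3`. The near-modal set takes every offset within 75% of the peak
frequency: a 50:50 wild-type/mutant mixture has an exact expected tie
between offsets 0 and −1 unit, and the smear under slippage is slightly
asymmetric (the shorter mutant run slips less), so a strict argmax — or
too tight a band — lets sampling noise fabricate or destroy a "modal
shift". With the 0.75 band the verdicts are stable across independent
simulation seeds. The internal control logic runs first: if the stable
and unstable sequin mixtures are not separated under the same metric, the
sample verdict is `insufficient_resolution` — the assay cannot support
any MSI claim — which is exactly what the standard-prep error regime
produces, while the PCR-free regime resolves the unstable control and the
sample. Both `tau` and the band are exposed parameters and are echoed in
reports.

## Determinism and numerical choices

Every stochastic component takes an integer seed; simulator draws follow a
documented order (template by template, fragments before errors), so equal
seeds give byte-identical FASTA/SAM/JSON outputs. Downsampling uses a
seeded hash of the read name rather than an RNG stream: retention is
order-independent, automatically pair-coherent, and monotone — the reads
kept at fraction $f_2 < f_1$ are a subset of those kept at $f_1$, which
makes incremental depth series internally consistent. The hash is a small
LCG-scrambled polynomial over the id bytes computed in exact double
arithmetic (modulus $2^{25}$), identical across platforms. Manifest
fractions must sum to 1 within $10^{-9}$; expected VAFs are recomputed
from fractions, never stored independently. Ties in the threshold grid
pass (≥ semantics) to match the convention that a dashed cutoff line
retains points on it.

## Known limitations

* The exact-match read assigner used in tests is an oracle for simulated
  unique-sequence reads, not an aligner; production partitioning assumes
  an upstream aligner against the combined index.
* `simulate_sequin_reads()` lifts molecule-local truth alignments onto the
  mirrored genome only for length-preserving (wild-type/SNV) molecules;
  indel sequins are simulated and measured in molecule coordinates (as in
  the MSI assay) rather than lifted.
* The naive pileup caller is SNV-only test plumbing; real call sets
  (e.g. from haplotype or somatic callers) are consumed as VCF-derived
  data frames.
* Single-base slippage is a simplification for multi-nucleotide repeat
  units; MSI simulations therefore use mononucleotide loci, which are
  also the most error-prone in practice.
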