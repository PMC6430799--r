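#' chiralseq: chiral spike-in controls for DNA sequencing assays
#'
#' A chiral pair is a DNA sequence and its copy arranged in reverse
#' nucleotide order (no complementation). The two are generally
#' non-superimposable, yet share nucleotide composition, GC content, repeat
#' structure and k-mer entropy. This package designs such mirrored spike-in
#' controls ("sequins"), processes sequencing data containing them, and uses
#' them as internal truth for variant-calling and microsatellite-instability
#' evaluation.
#'
#' @section Module overview:
#' * Mirror transforms and sequence properties: [mirror_sequence()],
#'   [build_mirrored_genome()], [map_interval()], [kmer_entropy()],
#'   [find_simple_repeats()], [gc_windows()].
#' * Sequin design: [extract_region()], [build_molecule()],
#'   [design_genotype_mixture()], [design_vaf_ladder()],
#'   [design_msi_sequins()], [mirror_primer_pair()], [insilico_pcr()].
#' * Read/alignment operations: [partition_alignments()], [flip_reads()],
#'   [transform_alignments()], [downsample_alignments()].
#' * Profiles and commutability: [pileup()], [concordance()],
#'   [error_rates_by_feature()], [breadth_at_depth()].
#' * Variant evaluation: [label_calls()], [optimize_thresholds()],
#'   [vaf_regression()], [sensitivity_vs_depth()].
#' * Microsatellite instability: [collect_spanning_reads()],
#'   [length_histogram()], [msi_call()].
#' * Simulation: [simulate_genome()], [simulate_reads()],
#'   [make_mirror_benchmark()].
#'
#' @name chiralseq-package
#' @keywords internal
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

## complement lookup used by primer mirroring and read flipping; N -> N
COMPLEMENT_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Validate a DNA sequence over the alphabet {A,C,G,T,N}
#'
#' @param x character vector of sequences (upper case).
#' @param what label used in error messages.
#' @return `x` invisibly; errors report the first invalid character and its
#'   1-based position within the offending element.
#' @export
check_dna <- function(x, what = "sequence") {
  if (!is.character(x)) stop(what, " must be a character vector")
  bad <- regexpr("[^ACGTN]", x)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1L]
    stop(sprintf("invalid character '%s' at position %d of %s '%s'",
                 substr(x[i], bad[i], bad[i]), bad[i], what,
                 if (is.null(names(x))) as.character(i) else names(x)[i]))
  }
  invisible(x)
}

#' Mirror a DNA sequence (reverse nucleotide order, no complementation)
#'
#' The chiral partner of a sequence is the same bases written in reverse
#' order. This is *not* the reverse complement: the mirror of `ATGCATGC` is
#' `CGTACGTA`, whereas its reverse complement is `GCATGCAT`. Mirroring is an
#' involution and preserves composition, GC content, k-mer entropy and the
#' homopolymer length spectrum.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N). Names are kept.
#' @return character vector of mirrored sequences.
#' @examples
#' mirror_sequence("ATGCATGC")  # "CGTACGTA"
#' @export
mirror_sequence <- function(x) {
  check_dna(x)
  out <- vapply(x, function(s) {
    if (nchar(s) == 0L) return(s)
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1L), USE.NAMES = FALSE)
  names(out) <- names(x)
  out
}

#' Complement a DNA sequence without reversing it
#'
#' Used by [mirror_primer_pair()]: the primer pair for a mirrored template is
#' the complement (not reverse complement) of the original pair with the
#' forward/reverse roles swapped.
#'
#' @param x character vector of DNA sequences.
#' @return complemented sequences, same orientation.
#' @export
dna_complement <- function(x) {
  check_dna(x)
  chartr("ACGTN", "TGCAN", x)
}

#' Reverse complement
#' @param x character vector of DNA sequences.
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(x) {
  mirror_sequence(dna_complement(x))
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  ## keep only the first word of the header, as aligners do
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @param width line width (default 60).
#' @return `path` invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  check_dna(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("sequences must be named for FASTA output")
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

## random DNA with given GC fraction; draws length(n) bases with the
## package-wide RNG stream (callers set the seed)
random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
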