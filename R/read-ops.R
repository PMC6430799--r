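#' Partition alignments between human (fwd) and chiral (rev) namespaces
#'
#' Every record is assigned to exactly one bucket by its contig's namespace
#' in the combined-index contig table; unmapped records (`rname == "*"`) form
#' a third bucket. When a truth `origin` column is present (simulated data),
#' the per-origin misassignment fraction is reported: an origin template
#' living in one namespace whose read aligned to the other.
#'
#' @param aln alignment record data.frame.
#' @param contig_table combined-index contig table
#'   ([build_mirrored_genome()]).
#' @return list with `human`, `chiral`, `unmapped` (data.frames), `counts`
#'   (named vector) and, when truth is available, `cross_alignment`
#'   (data.frame per origin namespace with misassigned counts and
#'   fractions).
#' @export
partition_alignments <- function(aln, contig_table) {
  mapped <- aln$rname != "*"
  unknown <- setdiff(unique(aln$rname[mapped]), contig_table$name)
  if (length(unknown))
    stop("unknown contig: ", paste(unknown, collapse = ", "))
  ns <- contig_table$namespace[match(aln$rname, contig_table$name)]
  ns[!mapped] <- "unmapped"
  out <- list(human = aln[ns == "fwd", , drop = FALSE],
              chiral = aln[ns == "rev", , drop = FALSE],
              unmapped = aln[ns == "unmapped", , drop = FALSE])
  out$counts <- c(human = nrow(out$human), chiral = nrow(out$chiral),
                  unmapped = nrow(out$unmapped))
  stopifnot(sum(out$counts) == nrow(aln))
  if (!is.null(aln$origin) && nrow(aln)) {
    true_ns <- contig_table$namespace[match(aln$origin, contig_table$name)]
    ok <- !is.na(true_ns) & ns != "unmapped"
    ca <- lapply(c(fwd = "fwd", rev = "rev"), function(o) {
      sel <- ok & true_ns == o
      n <- sum(sel)
      cross <- sum(sel & ns != o)
      data.frame(origin = o, n = n, cross = cross,
                 fraction = if (n) cross / n else NA_real_)
    })
    out$cross_alignment <- do.call(rbind, ca)
    rownames(out$cross_alignment) <- NULL
  }
  out
}

#' Cross-alignment rate as a percentage, at 3 significant figures
#'
#' For example 133 misassigned reads among 732 million is 1.82e-5 %.
#'
#' @param n_cross number of misassigned reads.
#' @param n_total total reads of that origin.
#' @return percentage (numeric), rounded to 3 significant figures.
#' @export
cross_alignment_percent <- function(n_cross, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  signif(100 * n_cross / n_total, 3L)
}

#' Reverse chiral-derived reads for re-alignment to the forward genome
#'
#' Chiral reads become forward-genome reads by reversing the base order
#' while keeping each base's own quality (qualities reverse together with
#' the bases); nothing is complemented. Input records stored on the reverse
#' strand of an alignment are first restored to as-sequenced orientation
#' (reverse complement of `seq`, reversed `qual`). Read ids and mate labels
#' are unchanged so pairing is preserved.
#'
#' @param reads alignment records or a read data.frame with columns `qname`,
#'   `mate`, `seq`, `qual` (and optionally `strand`; missing means `"+"`).
#' @return data.frame with columns `qname`, `mate`, `seq`, `qual` holding
#'   the flipped reads.
#' @export
flip_reads <- function(reads) {
  seq <- reads$seq
  qual <- reads$qual
  if (!is.null(reads$strand)) {
    neg <- reads$strand == "-"
    seq[neg] <- reverse_complement(seq[neg])
    qual[neg] <- vapply(qual[neg], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1L), USE.NAMES = FALSE)
  }
  data.frame(
    qname = reads$qname,
    mate = if (is.null(reads$mate)) 0L else reads$mate,
    seq = mirror_sequence(seq),
    qual = vapply(qual, function(q)
      if (nchar(q)) intToUtf8(rev(utf8ToInt(q))) else q,
      character(1L), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Transform alignments onto the mirrored twin contig
#'
#' Direct coordinate alternative to flipping and re-aligning: a record at
#' `pos0` with reference span `w` on a contig of length `L` maps to
#' `L - pos0 - w` on the twin, with the CIGAR operation order reversed
#' (soft/hard clips swap ends) and strand preserved. Mate coordinates are
#' transformed consistently by pairing records on `qname` within the input;
#' `tlen` changes sign. Alignment-specific optional tags are not carried.
#'
#' @param aln alignment record data.frame.
#' @param contig_table combined-index contig table.
#' @return transformed alignment record data.frame.
#' @export
transform_alignments <- function(aln, contig_table) {
  if (!nrow(aln)) return(aln)
  info <- contig_info(contig_table, aln$rname)
  span <- cigar_ref_span(aln$cigar)
  if (any(aln$pos0 + span > info$length))
    stop("alignment span overruns its contig")
  out <- aln
  out$rname <- info$partner
  out$pos0 <- info$length - (aln$pos0 + span)
  out$cigar <- reverse_cigar(aln$cigar)
  out$tlen <- -aln$tlen
  ## the stored bases must mirror with the coordinates (reverse, no
  ## complement) so M operations still compare against the twin reference;
  ## each base keeps its own quality
  has_seq <- nchar(aln$seq) > 0L
  out$seq[has_seq] <- mirror_sequence(aln$seq[has_seq])
  out$qual[has_seq] <- vapply(aln$qual[has_seq], function(q)
    if (nchar(q)) intToUtf8(rev(utf8ToInt(q))) else q,
    character(1L), USE.NAMES = FALSE)
  ## mate fields via the partner record when present
  if (any(aln$mate %in% c(1L, 2L))) {
    key <- paste(aln$qname, aln$mate)
    mate_key <- paste(aln$qname, ifelse(aln$mate == 1L, 2L, 1L))
    j <- match(mate_key, key)
    has <- !is.na(j)
    out$mrnm[has] <- out$rname[j[has]]
    out$mpos0[has] <- out$pos0[j[has]]
  }
  out
}

#' Deterministic per-read retention hash
#'
#' Maps a read id and seed to a uniform value in \\[0, 1). Used by
#' [downsample_alignments()]: hashing the id (not the mate) makes retention
#' pair-coherent and order-independent, and thresholding one shared hash
#' makes nested fractions strictly monotone (the records kept at a smaller
#' fraction are a subset of those kept at a larger one).
#'
#' @param id character vector of read ids.
#' @param seed integer seed.
#' @return numeric vector in \\[0, 1).
#' @export
retention_hash <- function(id, seed = 1L) {
  M <- 33554432  # 2^25: keeps all integer arithmetic exact in doubles
  h <- vapply(id, function(s) {
    v <- utf8ToInt(s)
    x <- (as.double(seed) %% M + 15485863) %% M
    for (c in v) x <- (x * 131 + c) %% M
    ## two LCG scramble rounds decorrelate near-identical ids
    x <- (x * 69069 + 1) %% M
    x <- (x * 69069 + 12345) %% M
    x
  }, numeric(1L), USE.NAMES = FALSE)
  h / M
}

#' Downsample alignments to a target fraction or coverage
#'
#' Each read (both mates jointly) is retained when its seeded
#' [retention_hash()] falls below the fraction. Provide either `fraction`
#' directly, or a `target_mean_cov`/`current_mean_cov` pair from which the
#' fraction is derived. Fraction 1 is the identity; fractions form nested
#' subsets under a fixed seed, supporting incremental downsampling series.
#'
#' @param aln alignment record data.frame.
#' @param fraction retention probability in (0, 1].
#' @param target_mean_cov,current_mean_cov alternative way to give the
#'   fraction as `target_mean_cov / current_mean_cov`.
#' @param seed integer seed.
#' @return the retained records.
#' @export
downsample_alignments <- function(aln, fraction = NULL,
                                  target_mean_cov = NULL,
                                  current_mean_cov = NULL, seed = 1L) {
  if (is.null(fraction)) {
    if (is.null(target_mean_cov) || is.null(current_mean_cov))
      stop("give either fraction or target/current coverage")
    fraction <- target_mean_cov / current_mean_cov
  }
  if (fraction > 1) stop("fraction must be <= 1")
  if (fraction <= 0) stop("fraction must be positive")
  if (fraction == 1) return(aln)
  keep <- retention_hash(aln$qname, seed) < fraction
  aln[keep, , drop = FALSE]
}

#' Assign reads to contigs by exact sequence match
#'
#' Internal truth oracle standing in for an external aligner in tests: a
#' read is assigned to every contig containing it (or its reverse
#' complement) as an exact substring. With unique-sequence simulated reads
#' this reproduces the aligner-partition experiment without an aligner.
#'
#' @param seqs character vector of read sequences (equal lengths).
#' @param genome named character vector of contigs (e.g. a combined
#'   fwd+rev index).
#' @return data.frame with columns `read` (index), `contig`; multi-mapping
#'   reads appear once per hit, unassigned reads not at all.
#' @export
assign_reads_exact <- function(seqs, genome) {
  check_dna(seqs)
  subject <- Biostrings::DNAStringSet(genome)
  hits <- list()
  for (strand_seq in list(seqs, reverse_complement(seqs))) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(strand_seq))
    for (ci in seq_along(subject)) {
      cnt <- Biostrings::countPDict(pd, subject[[ci]])
      idx <- which(cnt > 0L)
      if (length(idx))
        hits[[length(hits) + 1L]] <- data.frame(
          read = idx, contig = names(genome)[ci],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(read = integer(), contig = character()))
  out <- unique(do.call(rbind, hits))
  out[order(out$read), , drop = FALSE]
}
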