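#' Construct an alignment record table
#'
#' The package's canonical in-memory alignment representation is a plain
#' data.frame with one row per alignment record and 0-based leftmost
#' positions (`pos0`); SAM's 1-based convention is applied only at file
#' boundaries. Columns: `qname`, `mate` (1/2, or 0 for unpaired), `rname`,
#' `pos0`, `mapq`, `cigar`, `strand` (`"+"`/`"-"`), `seq`, `qual`, `mrnm`,
#' `mpos0`, `tlen`, and optionally `origin` (truth template for simulated
#' reads).
#'
#' @param qname,mate,rname,pos0,mapq,cigar,strand,seq,qual vectors (recycled
#'   to the longest length).
#' @param mrnm,mpos0,tlen,origin optional mate/truth columns.
#' @return data.frame of alignment records.
#' @export
alignment_records <- function(qname, mate = 0L, rname, pos0, mapq = 60L,
                              cigar, strand = "+", seq = "", qual = "",
                              mrnm = NA_character_, mpos0 = NA_integer_,
                              tlen = 0L, origin = NULL) {
  d <- data.frame(qname = qname, mate = as.integer(mate), rname = rname,
                  pos0 = as.integer(pos0), mapq = as.integer(mapq),
                  cigar = cigar, strand = strand, seq = seq, qual = qual,
                  mrnm = mrnm, mpos0 = as.integer(mpos0),
                  tlen = as.integer(tlen), stringsAsFactors = FALSE)
  if (!is.null(origin)) d$origin <- origin
  bad <- nchar(d$seq) > 0L & nchar(d$qual) > 0L &
    nchar(d$seq) != nchar(d$qual)
  if (any(bad)) stop("seq and qual lengths differ for read ",
                     d$qname[bad][1L])
  d
}

#' Reference span of CIGAR strings
#'
#' Number of reference bases consumed (M/D/N/=/X operations).
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector.
#' @export
cigar_ref_span <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

## exploded CIGAR ops/lengths; returns list(ops = list, lens = list)
cigar_explode <- function(cigar) {
  list(ops = GenomicAlignments::explodeCigarOps(cigar),
       lens = GenomicAlignments::explodeCigarOpLengths(cigar))
}

#' Reverse the operation order of CIGAR strings
#'
#' Used when transforming an alignment onto the mirrored contig: operation
#' types are unchanged but their order reverses (soft/hard clips swap ends).
#'
#' @param cigar character vector of CIGAR strings.
#' @return character vector.
#' @export
reverse_cigar <- function(cigar) {
  ex <- cigar_explode(cigar)
  vapply(seq_along(cigar), function(i)
    paste0(rev(ex$lens[[i]]), rev(ex$ops[[i]]), collapse = ""),
    character(1L))
}

#' Write alignment records to SAM
#'
#' @param aln alignment record data.frame ([alignment_records()]).
#' @param path output SAM path.
#' @param contig_lengths named integer vector for `@SQ` header lines.
#' @return `path` invisibly.
#' @export
write_sam <- function(aln, path, contig_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- integer(nrow(aln))
  paired <- aln$mate %in% c(1L, 2L)
  flag <- flag + ifelse(paired, 1L, 0L) +
    ifelse(aln$mate == 1L, 64L, 0L) + ifelse(aln$mate == 2L, 128L, 0L) +
    ifelse(aln$strand == "-", 16L, 0L) + ifelse(aln$rname == "*", 4L, 0L)
  rnext <- ifelse(is.na(aln$mrnm), "*",
                  ifelse(aln$mrnm == aln$rname, "=", aln$mrnm))
  pnext <- ifelse(is.na(aln$mpos0), 0L, aln$mpos0 + 1L)
  seqf <- ifelse(nchar(aln$seq) > 0L, aln$seq, "*")
  qualf <- ifelse(nchar(aln$qual) > 0L, aln$qual, "*")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  aln$qname, flag, aln$rname, aln$pos0 + 1L, aln$mapq,
                  aln$cigar, rnext, pnext, aln$tlen, seqf, qualf)
  if (!is.null(aln$origin))
    body <- paste0(body, "\tXO:Z:", aln$origin)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment record table
#'
#' Minimal text SAM reader for the package's own record set: mandatory
#' fields plus the `XO:Z` truth-origin tag when present.
#'
#' @param path SAM path (plain text).
#' @return alignment record data.frame.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln))
    return(alignment_records(character(0L), integer(0L), character(0L),
                             integer(0L), integer(0L), character(0L),
                             character(0L), character(0L), character(0L)))
  parts <- strsplit(ln, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, `[[`, character(1L), i)
  flag <- as.integer(get(2L))
  mate <- ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                 ifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L))
  rnext <- get(7L)
  rname <- get(3L)
  origin <- vapply(parts, function(p) {
    tag <- p[startsWith(p, "XO:Z:")]
    if (length(tag)) substring(tag[1L], 6L) else NA_character_
  }, character(1L))
  d <- alignment_records(
    qname = get(1L), mate = mate, rname = rname,
    pos0 = as.integer(get(4L)) - 1L, mapq = as.integer(get(5L)),
    cigar = get(6L),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq = ifelse(get(10L) == "*", "", get(10L)),
    qual = ifelse(get(11L) == "*", "", get(11L)),
    mrnm = ifelse(rnext == "*", NA_character_,
                  ifelse(rnext == "=", rname, rnext)),
    mpos0 = ifelse(rnext == "*", NA_integer_,
                   as.integer(get(8L)) - 1L),
    tlen = as.integer(get(9L)))
  if (!all(is.na(origin))) d$origin <- origin
  d
}

#' Write reads to FASTQ (Phred+33, 4-line records)
#'
#' Paired records (`mate` 1 and 2) are written to `path1`/`path2` in
#' synchronized order; unpaired or orphaned records go to `singles`. An
#' orphaned mate (partner missing) triggers a warning.
#'
#' @param reads data.frame with columns `qname`, `mate`, `seq`, `qual`.
#' @param path1 FASTQ path for mate-1 (and unpaired when `path2` is NULL).
#' @param path2 FASTQ path for mate-2 reads, or `NULL`.
#' @param singles path for orphaned mates (default: `path1` with a
#'   `.singles` suffix).
#' @return invisible list of written paths.
#' @export
write_fastq <- function(reads, path1, path2 = NULL,
                        singles = paste0(path1, ".singles")) {
  fq <- function(d, suffix = "") {
    if (!nrow(d)) return(character(0L))
    as.vector(rbind(paste0("@", d$qname, suffix), d$seq, "+", d$qual))
  }
  if (is.null(path2)) {
    writeLines(fq(reads), path1)
    return(invisible(list(path1 = path1)))
  }
  r1 <- reads[reads$mate == 1L, , drop = FALSE]
  r2 <- reads[reads$mate == 2L, , drop = FALSE]
  common <- intersect(r1$qname, r2$qname)
  o1 <- r1[match(common, r1$qname), , drop = FALSE]
  o2 <- r2[match(common, r2$qname), , drop = FALSE]
  orphans <- rbind(r1[!r1$qname %in% common, , drop = FALSE],
                   r2[!r2$qname %in% common, , drop = FALSE],
                   reads[reads$mate == 0L, , drop = FALSE])
  writeLines(fq(o1, "/1"), path1)
  writeLines(fq(o2, "/2"), path2)
  out <- list(path1 = path1, path2 = path2)
  if (nrow(orphans)) {
    warning(nrow(orphans), " orphaned/unpaired reads written to ", singles)
    writeLines(fq(orphans), singles)
    out$singles <- singles
  }
  invisible(out)
}

#' Read a FASTQ file (Phred+33 plain text)
#'
#' @param path FASTQ path.
#' @return data.frame with columns `qname`, `seq`, `qual` (mate suffixes
#'   `/1`, `/2` are split into a `mate` column).
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ: ", path)
  ids <- sub("^@", "", ln[seq(1L, length(ln), by = 4L)])
  ids <- sub("\\s.*$", "", ids)
  mate <- ifelse(grepl("/1$", ids), 1L, ifelse(grepl("/2$", ids), 2L, 0L))
  data.frame(qname = sub("/[12]$", "", ids), mate = mate,
             seq = ln[seq(2L, length(ln), by = 4L)],
             qual = ln[seq(4L, length(ln), by = 4L)],
             stringsAsFactors = FALSE)
}
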