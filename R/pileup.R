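#' Per-base coverage and error profile from alignments
#'
#' Walks CIGARs against the reference to tally, at every reference position
#' of the region: `depth` (reads whose aligned footprint spans the position,
#' including deleted bases), `mismatch`, `insertion` (events anchored at the
#' left flanking base of their junction) and `deletion`. Records below
#' `mapq_floor` are excluded (a floor of 11 reproduces the usual
#' "MapQ > 10" uniquely-aligned filter).
#'
#' @param aln alignment record data.frame.
#' @param genome named character vector of contig sequences.
#' @param contig contig to profile.
#' @param start,end region, 0-based half-open (default: whole contig).
#' @param mapq_floor minimum mapping quality (default 0).
#' @param bases also tally a 5 x width A/C/G/T/N count matrix of aligned
#'   read bases (used by the naive caller).
#' @return object of class `pileup_profile`: list with `contig`, `start`,
#'   `end`, `contig_length`, `mapq_floor`, integer arrays `depth`,
#'   `mismatch`, `insertion`, `deletion` (length `end - start`) and
#'   optionally `base_counts`.
#' @export
pileup <- function(aln, genome, contig, start = 0L, end = NULL,
                   mapq_floor = 0L, bases = FALSE) {
  if (!contig %in% names(genome)) stop("region off contig: ", contig)
  ref <- genome[[contig]]
  L <- nchar(ref)
  if (is.null(end)) end <- L
  if (start < 0L || end > L || end < start) stop("region off contig")
  a <- aln[aln$rname == contig & aln$mapq >= mapq_floor, , drop = FALSE]
  depth_inc <- integer(L + 1L)
  mm <- integer(L); ins <- integer(L); del <- integer(L)
  bc <- if (bases) matrix(0L, nrow = 5L, ncol = L,
                          dimnames = list(DNA_ALPHABET, NULL)) else NULL
  refraw <- charToRaw(ref)
  alpha_raw <- charToRaw(paste(DNA_ALPHABET, collapse = ""))
  if (nrow(a)) {
    span <- cigar_ref_span(a$cigar)
    if (any(a$pos0 + span > L)) stop("alignment span overruns contig")
    simple <- grepl("^[0-9]+M$", a$cigar) & nchar(a$seq) == span
    s <- a[simple, , drop = FALSE]
    if (nrow(s)) {
      starts <- s$pos0
      lens <- nchar(s$seq)
      inc <- tabulate(starts + 1L, L)
      dec <- tabulate(starts + lens + 1L, L)
      bigread <- paste(s$seq, collapse = "")
      bigref <- paste(substring(ref, starts + 1L, starts + lens),
                      collapse = "")
      rd <- charToRaw(bigread)
      rr <- charToRaw(bigref)
      offsets <- cumsum(c(0L, lens))
      ne <- which(rd != rr)
      if (length(ne)) {
        idx <- findInterval(ne - 0.5, offsets)
        gpos0 <- starts[idx] + (ne - offsets[idx] - 1L)
        mm <- mm + tabulate(gpos0 + 1L, L)
      }
      if (bases) {
        gp0 <- rep(starts, lens) + (sequence(lens) - 1L)
        code <- match(rd, alpha_raw)
        bc <- bc + matrix(tabulate((gp0) * 5L + code, nbins = 5L * L),
                          nrow = 5L)
      }
      depth_simple <- cumsum(inc - dec)
    } else depth_simple <- integer(L)
    ## general path: any CIGAR with I/D/S/N/X/= operations
    g <- a[!simple, , drop = FALSE]
    if (nrow(g)) {
      ex <- cigar_explode(g$cigar)
      for (i in seq_len(nrow(g))) {
        ops <- ex$ops[[i]]; lens_i <- ex$lens[[i]]
        rp <- g$pos0[i]          # 0-based ref cursor
        qp <- 0L                 # 0-based query cursor
        qraw <- if (nchar(g$seq[i])) charToRaw(g$seq[i]) else raw(0L)
        for (k in seq_along(ops)) {
          op <- ops[k]; len <- lens_i[k]
          if (op %in% c("M", "=", "X")) {
            depth_inc[rp + 1L] <- depth_inc[rp + 1L] + 1L
            depth_inc[rp + len + 1L] <- depth_inc[rp + len + 1L] - 1L
            if (length(qraw)) {
              qs <- qraw[(qp + 1L):(qp + len)]
              rs <- refraw[(rp + 1L):(rp + len)]
              bad <- which(qs != rs)
              if (length(bad)) {
                pos <- rp + bad
                mm[pos] <- mm[pos] + 1L
              }
              if (bases) {
                code <- match(qs, alpha_raw)
                bc[cbind(code, rp + seq_len(len))] <-
                  bc[cbind(code, rp + seq_len(len))] + 1L
              }
            }
            rp <- rp + len; qp <- qp + len
          } else if (op == "I") {
            if (rp > 0L) ins[rp] <- ins[rp] + 1L  # anchor: left base rp-1
            qp <- qp + len
          } else if (op == "D") {
            depth_inc[rp + 1L] <- depth_inc[rp + 1L] + 1L
            depth_inc[rp + len + 1L] <- depth_inc[rp + len + 1L] - 1L
            del[(rp + 1L):(rp + len)] <- del[(rp + 1L):(rp + len)] + 1L
            rp <- rp + len
          } else if (op == "N") {
            rp <- rp + len
          } else if (op %in% c("S", "H", "P")) {
            if (op == "S") qp <- qp + len
          } else stop("unsupported CIGAR op: ", op)
        }
      }
      depth <- depth_simple + cumsum(depth_inc[seq_len(L)])
    } else depth <- depth_simple + cumsum(depth_inc[seq_len(L)])
  } else depth <- integer(L)
  w <- seq.int(start + 1L, length.out = end - start)
  structure(list(contig = contig, start = as.integer(start),
                 end = as.integer(end), contig_length = L,
                 mapq_floor = mapq_floor,
                 depth = depth[w], mismatch = mm[w], insertion = ins[w],
                 deletion = del[w],
                 base_counts = if (bases) bc[, w, drop = FALSE] else NULL),
            class = "pileup_profile")
}

#' @export
print.pileup_profile <- function(x, ...) {
  cat(sprintf(
    "pileup profile %s:[%d,%d) mean depth %.1f; mm/ins/del %d/%d/%d%s\n",
    x$contig, x$start, x$end, mean(x$depth), sum(x$mismatch),
    sum(x$insertion), sum(x$deletion),
    if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Mirror a pileup profile into the twin contig's coordinates
#'
#' Depth, mismatch and deletion arrays simply reverse. Insertion counts are
#' anchored to the left base of their junction, and junctions map to
#' junctions under mirroring, so the insertion array reverses with a
#' one-position shift. With this definition the pileup of
#' [transform_alignments()] output equals the mirrored pileup of the input
#' bit-exactly.
#'
#' @param p a `pileup_profile`.
#' @param contig name to give the mirrored profile (default: unchanged).
#' @return a `pileup_profile` in mirrored coordinates.
#' @export
mirror_profile <- function(p, contig = p$contig) {
  w <- p$end - p$start
  ins <- if (w >= 2L) c(p$insertion[(w - 1L):1L], 0L) else p$insertion
  structure(list(contig = contig,
                 start = p$contig_length - p$end,
                 end = p$contig_length - p$start,
                 contig_length = p$contig_length,
                 mapq_floor = p$mapq_floor,
                 depth = rev(p$depth), mismatch = rev(p$mismatch),
                 insertion = ins, deletion = rev(p$deletion),
                 base_counts = if (is.null(p$base_counts)) NULL
                               else p$base_counts[, w:1L, drop = FALSE]),
            class = "pileup_profile")
}

#' Normalize a coverage profile by its mean depth
#'
#' @param p a `pileup_profile`.
#' @param mode `"mean"` (divide depth by its mean; the normalized profile
#'   has mean exactly 1) or `"none"`.
#' @return the profile with a numeric, normalized `depth` array.
#' @export
normalize_profile <- function(p, mode = c("mean", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(p)
  m <- mean(p$depth)
  if (m == 0) stop("cannot normalize a zero-mean profile")
  p$depth <- p$depth / m
  p$normalized <- TRUE
  p
}

#' Per-position error-rate vector from a profile
#'
#' @param p a `pileup_profile`.
#' @param type `"indel"` (insertions + deletions), `"mismatch"` or `"any"`.
#' @return numeric vector of per-position rates (count / depth; `NaN` where
#'   depth is 0).
#' @export
error_rate_profile <- function(p, type = c("indel", "mismatch", "any")) {
  type <- match.arg(type)
  cnt <- switch(type,
                indel = p$insertion + p$deletion,
                mismatch = p$mismatch,
                any = p$insertion + p$deletion + p$mismatch)
  cnt / p$depth
}

#' Fraction of positions reaching a depth threshold
#'
#' @param p a `pileup_profile`.
#' @param k depth threshold (default 30).
#' @return fraction of region positions with depth >= k.
#' @export
breadth_at_depth <- function(p, k = 30L) {
  if (k < 0L) stop("k must be >= 0")
  mean(p$depth >= k)
}

#' Insert-size distribution of paired alignments
#'
#' Outer distance (fragment length) per properly stored pair: from the
#' leftmost start to the rightmost aligned end of the two mates.
#'
#' @param aln alignment record data.frame with both mates present.
#' @return list with `sizes` (per-pair outer distances), `histogram`
#'   (table), `mean`, `median`, `sd`, `n_pairs`.
#' @export
insert_size_distribution <- function(aln) {
  p1 <- aln[aln$mate == 1L, , drop = FALSE]
  p2 <- aln[aln$mate == 2L, , drop = FALSE]
  common <- intersect(p1$qname, p2$qname)
  if (!length(common)) stop("no complete read pairs in input")
  a <- p1[match(common, p1$qname), , drop = FALSE]
  b <- p2[match(common, p2$qname), , drop = FALSE]
  ea <- a$pos0 + cigar_ref_span(a$cigar)
  eb <- b$pos0 + cigar_ref_span(b$cigar)
  sizes <- pmax(ea, eb) - pmin(a$pos0, b$pos0)
  list(sizes = sizes, histogram = table(sizes), mean = mean(sizes),
       median = stats::median(sizes), sd = stats::sd(sizes),
       n_pairs = length(sizes))
}
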