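#' Allele specification table
#'
#' Alleles to apply to a forward-space region are given as a data.frame with
#' columns `kind` (`"SNV"`, `"INS"`, `"DEL"`), `offset` (0-based position
#' within the region), `ref` and `alt`. Conventions: an SNV has one-base
#' `ref`/`alt`; a DEL deletes `ref` (non-empty) starting at `offset`
#' (`alt = ""`); an INS inserts `alt` (non-empty) immediately after the base
#' at `offset` (`ref = ""`).
#'
#' @param kind,offset,ref,alt vectors defining the alleles.
#' @return validated data.frame.
#' @export
allele_spec <- function(kind, offset, ref = "", alt = "") {
  d <- data.frame(kind = kind, offset = as.integer(offset), ref = ref,
                  alt = alt, stringsAsFactors = FALSE)
  ok <- d$kind %in% c("SNV", "INS", "DEL")
  if (!all(ok)) stop("unknown allele kind: ", d$kind[!ok][1L])
  bad <- (d$kind == "SNV" & (nchar(d$ref) != 1L | nchar(d$alt) != 1L)) |
         (d$kind == "INS" & nchar(d$alt) == 0L) |
         (d$kind == "DEL" & nchar(d$ref) == 0L)
  if (any(bad)) stop("malformed allele at row ", which(bad)[1L])
  d
}

## allele reference footprint [start, end) within the region; INS occupies
## the junction after `offset` and is modeled as a zero-width footprint at
## offset + 1 for overlap checking
allele_footprint <- function(alleles) {
  start <- ifelse(alleles$kind == "INS", alleles$offset + 1L, alleles$offset)
  end <- ifelse(alleles$kind == "DEL", alleles$offset + nchar(alleles$ref),
         ifelse(alleles$kind == "SNV", alleles$offset + 1L, start))
  data.frame(start = start, end = end)
}

#' Apply alleles to a forward-space region sequence
#'
#' Alleles are applied left to right with cumulative coordinate shifting for
#' indels. Overlapping alleles are rejected; `ref` mismatches are rejected
#' naming the offset.
#'
#' @param seq the region sequence (forward space).
#' @param alleles data.frame from [allele_spec()]; may have zero rows.
#' @return the edited sequence.
#' @export
apply_alleles <- function(seq, alleles) {
  check_dna(seq)
  if (is.null(alleles) || nrow(alleles) == 0L) return(seq)
  n <- nchar(seq)
  if (any(alleles$offset < 0L | alleles$offset >= n))
    stop("allele offset outside region")
  o <- order(alleles$offset)
  alleles <- alleles[o, , drop = FALSE]
  fp <- allele_footprint(alleles)
  if (nrow(fp) > 1L) {
    prev_end <- cummax(fp$end)[-nrow(fp)]
    same_ins <- duplicated(paste(alleles$kind, alleles$offset))
    if (any(fp$start[-1L] < prev_end) || any(same_ins))
      stop("overlapping alleles are not supported")
  }
  ## verify refs before editing
  for (i in seq_len(nrow(alleles))) {
    a <- alleles[i, ]
    if (a$kind != "INS") {
      seen <- substr(seq, a$offset + 1L, a$offset + nchar(a$ref))
      if (seen != a$ref)
        stop(sprintf("ref mismatch at offset %d: expected '%s', found '%s'",
                     a$offset, a$ref, seen))
    }
  }
  ## assemble: untouched segments interleaved with allele replacements
  pieces <- character(0L)
  cursor <- 0L
  for (i in seq_len(nrow(alleles))) {
    a <- alleles[i, ]
    if (a$kind == "INS") {
      pieces <- c(pieces, substr(seq, cursor + 1L, a$offset + 1L), a$alt)
      cursor <- a$offset + 1L
    } else {
      pieces <- c(pieces, substr(seq, cursor + 1L, a$offset), a$alt)
      cursor <- a$offset + nchar(a$ref)
    }
  }
  pieces <- c(pieces, substr(seq, cursor + 1L, n))
  paste(pieces, collapse = "")
}

#' Extract a fixed-length region centered on an anchor
#'
#' The region of `length` nt is centered on the anchor midpoint (ties toward
#' the lower coordinate). Regions that would extend past either contig end
#' are an error: no silent clamping.
#'
#' @param genome named character vector of forward-space contigs.
#' @param contig contig name.
#' @param anchor_start,anchor_end anchor interval, 0-based half-open.
#' @param length region length in nt (default 1800, the standard sequin
#'   molecule size).
#' @return list with `contig`, `start`, `end` (0-based half-open) and `seq`.
#' @export
extract_region <- function(genome, contig, anchor_start, anchor_end,
                           length = 1800L) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  L <- nchar(genome[[contig]])
  if (anchor_start < 0L || anchor_end < anchor_start || anchor_end > L)
    stop("anchor out of bounds")
  mid <- (anchor_start + anchor_end) %/% 2L
  start <- mid - length %/% 2L
  end <- start + length
  if (start < 0L || end > L)
    stop(sprintf("region [%d,%d) exceeds contig bounds [0,%d)", start, end, L))
  list(contig = contig, start = as.integer(start), end = as.integer(end),
       seq = substr(genome[[contig]], start + 1L, end))
}

#' Build a chiral sequin molecule from a region and alleles
#'
#' Alleles are applied to the forward subsequence, and the edited sequence is
#' mirrored (reversed, no complementation) to give the synthetic molecule.
#'
#' @param region region list from [extract_region()] (or any list with
#'   `contig`, `start`, `end`, `seq`).
#' @param alleles data.frame from [allele_spec()], or `NULL` for a wild-type
#'   molecule.
#' @param id molecule identifier.
#' @return object of class `sequin_molecule`: list with `id`, `source`
#'   (contig/start/end), `alleles`, `role` (`"wildtype"`/`"variant"`),
#'   `fwd_bases` (edited forward sequence) and `bases` (chiral sequence).
#' @export
build_molecule <- function(region, alleles = NULL, id) {
  fwd <- apply_alleles(region$seq, alleles)
  structure(list(
    id = id,
    source = list(contig = region$contig, start = region$start,
                  end = region$end),
    alleles = alleles,
    role = if (is.null(alleles) || nrow(alleles) == 0L) "wildtype"
           else "variant",
    fwd_bases = fwd,
    bases = mirror_sequence(fwd)
  ), class = "sequin_molecule")
}

#' @export
print.sequin_molecule <- function(x, ...) {
  cat(sprintf("sequin molecule '%s' (%s), %d nt, source %s:[%d,%d)\n",
              x$id, x$role, nchar(x$bases), x$source$contig,
              x$source$start, x$source$end))
  invisible(x)
}

#' Normalize a variant record (minimal, left-aligned, anchored)
#'
#' Standard VCF-style normalization against a reference sequence: trim the
#' shared suffix/prefix, left-shift indels as far as the reference allows,
#' and keep at least one base in each allele (indels carry the left flanking
#' anchor base).
#'
#' @param ref_seq the reference contig sequence.
#' @param pos0 0-based variant position.
#' @param ref,alt allele strings (non-empty).
#' @return list with `pos0`, `ref`, `alt`.
#' @export
normalize_variant <- function(ref_seq, pos0, ref, alt) {
  if (nchar(ref) == 0L || nchar(alt) == 0L)
    stop("ref and alt must be non-empty (anchored representation)")
  if (substr(ref_seq, pos0 + 1L, pos0 + nchar(ref)) != ref)
    stop("ref allele does not match the reference at pos ", pos0)
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0L && la > 0L &&
        substr(ref, lr, lr) == substr(alt, la, la) &&
        !(lr == 1L && la == 1L)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos0 == 0L) {  # cannot extend left; re-anchor on the right
          base <- substr(ref_seq, pos0 + nchar(ref) + 1L,
                         pos0 + nchar(ref) + 1L)
          ref <- paste0(ref, base); alt <- paste0(alt, base)
          break
        }
        base <- substr(ref_seq, pos0, pos0)
        ref <- paste0(base, ref); alt <- paste0(base, alt)
        pos0 <- pos0 - 1L
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos0 <- pos0 + 1L
  }
  list(pos0 = as.integer(pos0), ref = ref, alt = alt)
}

#' Project a variant between mirrored coordinate systems
#'
#' A variant that replaces `ref` with `alt` at rev-space position `p`
#' corresponds, in forward space, to replacing the reversed `ref` with the
#' reversed `alt` at position `L - p - nchar(ref)` (no complementation). The
#' projected record is then left-normalized against the forward reference.
#' The same function projects fwd -> rev by passing the roles swapped.
#'
#' @param from_seq sequence of the contig the record is on.
#' @param to_seq sequence of the mirrored twin contig (used for validation
#'   and normalization).
#' @param pos0 0-based position of the record on `from_seq`.
#' @param ref,alt allele strings (non-empty, anchored or not).
#' @return list with `pos0`, `ref`, `alt` in the twin's coordinates,
#'   normalized.
#' @export
project_variant <- function(from_seq, to_seq, pos0, ref, alt) {
  L <- nchar(from_seq)
  if (nchar(to_seq) != L) stop("mirrored contigs must have equal length")
  if (substr(from_seq, pos0 + 1L, pos0 + nchar(ref)) != ref)
    stop("ref allele does not match the source contig at pos ", pos0)
  new_pos <- L - pos0 - nchar(ref)
  out <- normalize_variant(to_seq, new_pos, mirror_sequence(ref),
                           mirror_sequence(alt))
  if (substr(to_seq, out$pos0 + 1L, out$pos0 + nchar(out$ref)) != out$ref)
    stop("projected ref mismatch: inconsistent mirrored genome build")
  out
}
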