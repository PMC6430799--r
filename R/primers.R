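#' In-silico PCR: predict amplicons for a primer pair on a template
#'
#' A product is reported wherever the forward primer matches the template
#' exactly and the reverse complement of the reverse primer matches at or
#' downstream of it, with total product length at most `max_product`.
#'
#' @param template template sequence (single strand, 5'->3').
#' @param forward,reverse primer sequences (5'->3'; the reverse primer is
#'   given in its own 5'->3' orientation, as ordered from a vendor).
#' @param max_product maximum product length in nt.
#' @return data.frame of product intervals `start`, `end` (0-based,
#'   half-open, on the template); zero rows when there is no product.
#' @examples
#' insilico_pcr("ATCCAGGCCGTA", "ATCC", "TACG", 50)  # one product [0, 12)
#' @export
insilico_pcr <- function(template, forward, reverse, max_product) {
  check_dna(c(template, forward, reverse))
  if (nchar(forward) == 0L || nchar(reverse) == 0L)
    stop("primers must be non-empty")
  find_all <- function(pat) {
    m <- gregexpr(pat, template, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0L) else as.integer(m) - 1L
  }
  f_starts <- find_all(forward)
  rc <- reverse_complement(reverse)
  r_starts <- find_all(rc)
  out <- data.frame(start = integer(), end = integer())
  for (sf in f_starts) {
    for (sr in r_starts) {
      end <- sr + nchar(rc)
      if (sr >= sf && end - sf <= max_product)
        out <- rbind(out, data.frame(start = sf, end = end))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Mirror a primer pair onto the chiral partner template
#'
#' The pair amplifying `[s, e)` of a forward template maps to the pair
#' amplifying the mirrored interval `[L - e, L - s)` of the mirrored
#' template. Because mirroring reverses base order without complementation,
#' the mirrored pair is the *complement* (not reverse complement) of the
#' original primers with the forward/reverse roles swapped; this is the
#' unique recipe for which in-silico PCR on the mirrored template yields the
#' mirrored amplicon. Both designs are verified by [insilico_pcr()] before
#' returning.
#'
#' @param template forward template sequence.
#' @param forward,reverse the original primer pair (5'->3').
#' @param amplicon_start,amplicon_end the amplicon the pair is stated to
#'   produce (0-based half-open on `template`).
#' @param max_product maximum product length passed to the in-silico check
#'   (default: the stated amplicon width).
#' @return list with `forward`, `reverse` (primers for the mirrored
#'   template) and `amplicon` (`start`, `end` on the mirrored template).
#' @export
mirror_primer_pair <- function(template, forward, reverse,
                               amplicon_start, amplicon_end,
                               max_product = amplicon_end - amplicon_start) {
  prods <- insilico_pcr(template, forward, reverse, max_product)
  hit <- any(prods$start == amplicon_start & prods$end == amplicon_end)
  if (!hit)
    stop(sprintf("primer pair does not amplify the stated amplicon [%d,%d)",
                 amplicon_start, amplicon_end))
  L <- nchar(template)
  mf <- dna_complement(reverse)
  mr <- dna_complement(forward)
  m_start <- L - amplicon_end
  m_end <- L - amplicon_start
  mt <- mirror_sequence(template)
  mprods <- insilico_pcr(mt, mf, mr, max_product)
  if (!any(mprods$start == m_start & mprods$end == m_end))
    stop("internal error: mirrored pair failed in-silico verification")
  list(forward = mf, reverse = mr,
       amplicon = data.frame(start = m_start, end = m_end))
}
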