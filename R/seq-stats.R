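#' Shannon entropy of the k-mer distribution of a sequence
#'
#' Entropy (log base 2) of the empirical distribution of overlapping k-mers.
#' Because the k-mers of a mirrored sequence are the reversed k-mers of the
#' original (a bijection of the multiset), entropy is conserved under
#' mirroring.
#'
#' @param s a single DNA sequence.
#' @param k k-mer size (>= 1, <= nchar(s)).
#' @return entropy in bits.
#' @examples
#' kmer_entropy("ACGT", 1)  # 2 bits
#' @export
kmer_entropy <- function(s, k) {
  check_dna(s)
  if (length(s) != 1L) stop("s must be a single sequence")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  n <- nchar(s)
  if (n < k) stop("sequence shorter than k")
  kmers <- substring(s, 1:(n - k + 1L), k:n)
  p <- table(kmers) / (n - k + 1L)
  -sum(p * log2(p))
}

#' Mono-nucleotide composition
#'
#' @param s a single DNA sequence.
#' @return named integer vector of A/C/G/T/N counts.
#' @export
base_composition <- function(s) {
  check_dna(s)
  cnt <- table(factor(strsplit(s, "")[[1L]], levels = DNA_ALPHABET))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' GC fraction of a sequence
#'
#' N bases are excluded from the denominator.
#'
#' @param s a single DNA sequence.
#' @return fraction in \\[0, 1\\]; `NaN` if the sequence has no A/C/G/T base.
#' @export
gc_content <- function(s) {
  cnt <- base_composition(s)
  acgt <- sum(cnt[c("A", "C", "G", "T")])
  (cnt[["C"]] + cnt[["G"]]) / acgt
}

#' Sliding-window GC fraction
#'
#' @param s a single DNA sequence.
#' @param window window width in nt (1..nchar(s)).
#' @param step step between window starts (default: `window`, i.e. tiling).
#' @return data.frame with columns `start` (0-based), `end` and `gc`. N bases
#'   are excluded from the denominator; an all-N window yields `NaN`.
#' @export
gc_windows <- function(s, window, step = window) {
  check_dna(s)
  window <- as.integer(window); step <- as.integer(step)
  n <- nchar(s)
  if (window < 1L) stop("window must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  if (window > n) stop("window larger than sequence")
  ch <- strsplit(s, "")[[1L]]
  cgc <- cumsum(ch == "G" | ch == "C")
  cn <- cumsum(ch == "N")
  starts <- seq.int(0L, n - window, by = step)
  ends <- starts + window
  gcc <- cgc[ends] - c(0L, cgc)[starts + 1L]
  nn <- cn[ends] - c(0L, cn)[starts + 1L]
  data.frame(start = starts, end = ends, gc = gcc / (window - nn))
}

## minimal period check: TRUE if `unit` cannot be written as a repetition of
## a shorter unit
is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        unit == strrep(substr(unit, 1L, d), u %/% d)) return(FALSE)
  }
  TRUE
}

## lexicographically smallest rotation of a repeat unit
canonical_rotation <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(unit)
  rot <- vapply(seq_len(u), function(i)
    paste0(substr(unit, i, u), substr(unit, 1L, i - 1L)), character(1L))
  min(rot)
}

#' Find maximal simple tandem repeats
#'
#' Detects maximal tandem runs of units of 1..`max_unit` nt. For each run the
#' reported `interval` (`start`, `end`) is trimmed to whole copies, so that
#' `copies * nchar(unit) == total_len == end - start`; `full_start`/`full_end`
#' give the untrimmed maximal span including any partial trailing copy (the
#' full span, unlike the trimmed one, mirrors exactly under sequence
#' mirroring). Units are reported as they appear at the run start;
#' `canonical_unit` is the lexicographically smallest rotation. When a run is
#' explicable by several unit sizes the smallest (primitive) unit is kept,
#' and runs nested inside a reported run are suppressed. Runs never span N.
#'
#' @param s a single DNA sequence.
#' @param min_total_len minimum trimmed run length in nt.
#' @param max_unit maximum unit size (default 6).
#' @return data.frame with columns `start`, `end`, `unit`, `copies`,
#'   `total_len`, `full_start`, `full_end`, `canonical_unit` (0-based
#'   half-open coordinates), ordered by `start`.
#' @examples
#' find_simple_repeats("GGAAAAAGG", 5)   # one run: unit A, 5 copies
#' @export
find_simple_repeats <- function(s, min_total_len, max_unit = 6L) {
  check_dna(s)
  if (min_total_len < 1L || max_unit < 1L) stop("parameters must be positive")
  n <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      unit = character(), copies = integer(),
                      total_len = integer(), full_start = integer(),
                      full_end = integer(), canonical_unit = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  ch <- strsplit(s, "")[[1L]]
  cand <- list()
  for (u in seq_len(min(max_unit, n - 1L))) {
    a <- ch[seq_len(n - u)]
    b <- ch[(u + 1L):n]
    eq <- a == b & a != "N"
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in which(r$values)) {
      m <- r$lengths[j]            # match-chain length
      if (m < u) next              # fewer than 2 full copies
      i <- pos[j]                  # 1-based start of the run
      run_len <- m + u
      copies <- run_len %/% u
      total_len <- copies * u
      if (total_len < min_total_len) next
      unit <- substr(s, i, i + u - 1L)
      if (!is_primitive_unit(unit)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + total_len, unit = unit,
        copies = copies, total_len = total_len,
        full_start = i - 1L, full_end = i - 1L + run_len,
        canonical_unit = canonical_rotation(unit),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  ## prefer smaller units, then longer spans; drop runs nested in a kept run
  ord <- order(nchar(cand$unit), -(cand$full_end - cand$full_start),
               cand$full_start)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    nested <- FALSE
    for (j in which(keep)) {
      if (cand$full_start[j] <= cand$full_start[i] &&
          cand$full_end[j] >= cand$full_end[i]) { nested <- TRUE; break }
    }
    keep[i] <- !nested
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start, nchar(out$unit)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homopolymer length spectrum
#'
#' Run-length spectrum of single-base runs; conserved under mirroring.
#'
#' @param s a single DNA sequence.
#' @param min_len minimum run length to report (default 1).
#' @return data.frame with columns `base`, `length`, `count`, sorted.
#' @export
homopolymer_spectrum <- function(s, min_len = 1L) {
  check_dna(s)
  if (nchar(s) == 0L)
    return(data.frame(base = character(), length = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  r <- rle(strsplit(s, "")[[1L]])
  d <- data.frame(base = r$values, length = r$lengths,
                  stringsAsFactors = FALSE)
  d <- d[d$length >= min_len, , drop = FALSE]
  agg <- stats::aggregate(list(count = rep(1L, nrow(d))),
                          by = d[c("base", "length")], FUN = sum)
  agg <- agg[order(agg$base, agg$length), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-position repeat-run context length
#'
#' For every position, the length in nt of the longest simple tandem run
#' (units of 1..`max_unit` nt, full maximal span) covering it; positions in
#' no run get 1. This is the context variable used by the read simulator's
#' slippage error model; it is mirror-invariant because maximal run spans
#' mirror exactly.
#'
#' @param s a single DNA sequence.
#' @param max_unit maximum repeat unit size considered (default 3).
#' @param min_total_len minimum run length to count as context (default 4).
#' @return integer vector of length `nchar(s)`.
#' @export
repeat_context <- function(s, max_unit = 3L, min_total_len = 4L) {
  n <- nchar(s)
  ctx <- rep(1L, n)
  rep_df <- find_simple_repeats(s, min_total_len = min_total_len,
                                max_unit = max_unit)
  if (nrow(rep_df)) {
    for (i in seq_len(nrow(rep_df))) {
      span <- (rep_df$full_start[i] + 1L):rep_df$full_end[i]
      len <- rep_df$full_end[i] - rep_df$full_start[i]
      ctx[span] <- pmax(ctx[span], len)
    }
  }
  ctx
}
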