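#' Label variant calls against a sequin truth set
#'
#' Because every base of a synthetic chiral standard is known, any call
#' inside the sequin footprint is decidable: TP when `(contig, pos0, ref,
#' alt)` matches an expected variant exactly (after normalization),
#' otherwise FP. Calls outside the stated footprints are an error — they
#' cannot be adjudicated by the controls.
#'
#' @param calls data.frame with columns `contig`, `pos0`, `ref`, `alt` (plus
#'   any score/VAF columns, carried through).
#' @param truth data.frame of expected variants with the same key columns
#'   (e.g. `manifest$expected_variants`).
#' @param genome optional named contig sequences; when given, both calls and
#'   truth are normalized ([normalize_variant()]) before matching, so
#'   alternate indel representations match.
#' @param footprints optional data.frame `contig`, `start`, `end` of sequin
#'   regions; calls outside any footprint raise an error.
#' @return `calls` with a `label` column (`"TP"`/`"FP"`).
#' @export
label_calls <- function(calls, truth, genome = NULL, footprints = NULL) {
  norm <- function(d) {
    if (is.null(genome) || !nrow(d)) return(d)
    for (i in seq_len(nrow(d))) {
      nv <- normalize_variant(genome[[d$contig[i]]], d$pos0[i], d$ref[i],
                              d$alt[i])
      d$pos0[i] <- nv$pos0; d$ref[i] <- nv$ref; d$alt[i] <- nv$alt
    }
    d
  }
  calls <- norm(calls)
  truth_n <- norm(truth)
  if (!is.null(footprints) && nrow(calls)) {
    inside <- vapply(seq_len(nrow(calls)), function(i)
      any(footprints$contig == calls$contig[i] &
          footprints$start <= calls$pos0[i] &
          footprints$end > calls$pos0[i]), logical(1L))
    if (!all(inside))
      stop("call outside sequin footprint at ",
           calls$contig[!inside][1L], ":", calls$pos0[!inside][1L])
  }
  key <- function(d) paste(d$contig, d$pos0, d$ref, d$alt)
  calls$label <- ifelse(key(calls) %in% key(truth_n), "TP", "FP")
  calls
}

#' Detection sensitivity
#'
#' @param detected number of expected variants detected.
#' @param expected number of variants expected.
#' @return list with `detected`, `expected`, `exact` (the fraction) and
#'   `value` (rounded to 2 decimals, the conventional reporting precision:
#'   85 of 87 gives 0.98).
#' @export
sensitivity <- function(detected, expected) {
  if (expected <= 0) stop("expected count must be positive")
  if (detected > expected) stop("detected cannot exceed expected")
  exact <- detected / expected
  list(detected = detected, expected = expected, exact = exact,
       value = round(exact, 2L))
}

#' Linear regression of observed against expected VAF
#'
#' Quantification accuracy over a dilution ladder is summarized by
#' regressing observed on expected VAF within a stated range (default
#' 1.5-100%, below which sampling noise dominates at typical depths).
#'
#' @param observed,expected numeric VAF vectors (fractions).
#' @param range length-2 range of expected VAFs included in the fit.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
vaf_regression <- function(observed, expected, range = c(0.015, 1)) {
  keep <- expected >= range[1L] & expected <= range[2L]
  if (sum(keep) < 3L) stop("fewer than 3 points in the VAF range")
  x <- expected[keep]; y <- observed[keep]
  if (stats::var(x) == 0) stop("expected VAFs are constant in the range")
  slope <- stats::cov(x, y) / stats::var(x)
  list(slope = slope,
       intercept = mean(y) - slope * mean(x),
       r_squared = stats::cor(x, y)^2,
       n = length(x))
}

#' Optimize score thresholds to exclude all sequin false positives
#'
#' Searches minimum-value thresholds over the named scores (a call passes
#' only if *every* score is >= its threshold; ties pass). Candidate
#' thresholds per score are -Inf, each observed value, and +Inf. Among rules
#' admitting zero sequin FPs the optimizer maximizes retained sequin TPs,
#' then retained sample candidates, then picks the lexicographically
#' smallest thresholds — a deterministic optimum. When no feasible rule
#' retains any TP the all-rejecting rule is returned with
#' `all_rejected = TRUE`.
#'
#' @param labeled labeled sequin calls ([label_calls()]) containing the
#'   score columns.
#' @param scores character vector of score column names (the search grid is
#'   exponential in the number of scores; two is typical).
#' @param sample_calls optional data.frame of sample variant candidates with
#'   the same score columns, used for the secondary objective and reported
#'   filtering.
#' @return object of class `threshold_rule`: list with `thresholds` (named
#'   numeric), `n_tp_retained`, `n_fp_retained` (always 0), `n_tp`, `n_fp`,
#'   `n_sample_retained`, `n_sample`, `all_rejected`.
#' @export
optimize_thresholds <- function(labeled, scores, sample_calls = NULL) {
  for (s in scores) {
    if (is.null(labeled[[s]]) || anyNA(labeled[[s]]))
      stop("missing score: ", s)
  }
  tp <- as.matrix(labeled[labeled$label == "TP", scores, drop = FALSE])
  fp <- as.matrix(labeled[labeled$label == "FP", scores, drop = FALSE])
  sm <- if (!is.null(sample_calls))
    as.matrix(sample_calls[, scores, drop = FALSE]) else
    matrix(numeric(0L), ncol = length(scores))
  cand <- lapply(scores, function(s)
    c(-Inf, sort(unique(labeled[[s]])), Inf))
  grid <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
  pass_count <- function(m, thr) {
    if (!nrow(m)) return(0L)
    sum(rowSums(sweep(m, 2L, thr, `>=`)) == ncol(m))
  }
  n_tp <- integer(nrow(grid)); n_fp <- integer(nrow(grid))
  n_sm <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    thr <- grid[i, ]
    n_fp[i] <- pass_count(fp, thr)
    if (n_fp[i] == 0L) {
      n_tp[i] <- pass_count(tp, thr)
      n_sm[i] <- pass_count(sm, thr)
    } else n_tp[i] <- -1L
  }
  feas <- n_fp == 0L
  best_tp <- max(n_tp[feas])
  sel <- feas & n_tp == best_tp
  best_sm <- max(n_sm[sel])
  sel <- sel & n_sm == best_sm
  ord <- do.call(order, as.data.frame(grid[sel, , drop = FALSE]))
  thr <- grid[which(sel)[ord[1L]], ]
  names(thr) <- scores
  structure(list(thresholds = thr,
                 n_tp_retained = best_tp, n_fp_retained = 0L,
                 n_tp = nrow(tp), n_fp = nrow(fp),
                 n_sample_retained = best_sm,
                 n_sample = nrow(sm),
                 all_rejected = (nrow(tp) > 0L && best_tp == 0L)),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat("threshold rule:",
      paste(names(x$thresholds), ">=", signif(x$thresholds, 4L),
            collapse = " AND "), "\n")
  cat(sprintf("  sequin: %d/%d TP retained, %d/%d FP retained%s\n",
              x$n_tp_retained, x$n_tp, x$n_fp_retained, x$n_fp,
              if (x$all_rejected) " [no feasible rule retains any TP]"
              else ""))
  invisible(x)
}

#' Apply a threshold rule to calls
#'
#' @param rule a `threshold_rule`.
#' @param calls data.frame containing the rule's score columns.
#' @return `calls` with a logical `pass` column (AND semantics, ties pass).
#' @export
apply_thresholds <- function(rule, calls) {
  thr <- rule$thresholds
  m <- as.matrix(calls[, names(thr), drop = FALSE])
  calls$pass <- rowSums(sweep(m, 2L, thr, `>=`)) == length(thr)
  calls
}

#' Naive pileup SNV caller (test plumbing)
#'
#' Minimal caller standing in for production callers in simulations: an SNV
#' is emitted where the most frequent non-reference base reaches
#' `min_alt_fraction` of the aligned bases at a position with at least
#' `min_depth` aligned bases.
#'
#' @param p a `pileup_profile` computed with `bases = TRUE`.
#' @param genome named contig sequences.
#' @param min_depth minimum aligned-base depth (default 10).
#' @param min_alt_fraction minimum alt fraction (default 0.2).
#' @return data.frame with `contig`, `pos0`, `ref`, `alt`, `vaf`, `depth`,
#'   `genotype` (`"het"` below 0.75 VAF, else `"hom"`).
#' @export
naive_pileup_caller <- function(p, genome, min_depth = 10L,
                                min_alt_fraction = 0.2) {
  if (is.null(p$base_counts)) stop("pileup must be computed with bases=TRUE")
  bc <- p$base_counts[c("A", "C", "G", "T"), , drop = FALSE]
  tot <- colSums(bc)
  refseq <- substr(genome[[p$contig]], p$start + 1L, p$end)
  refch <- strsplit(refseq, "")[[1L]]
  ri <- match(refch, c("A", "C", "G", "T"))
  out <- list()
  for (j in which(tot >= min_depth & !is.na(ri))) {
    alt_counts <- bc[, j]
    alt_counts[ri[j]] <- 0L
    ai <- which.max(alt_counts)
    vaf <- alt_counts[ai] / tot[j]
    if (vaf >= min_alt_fraction) {
      out[[length(out) + 1L]] <- data.frame(
        contig = p$contig, pos0 = p$start + j - 1L, ref = refch[j],
        alt = c("A", "C", "G", "T")[ai], vaf = vaf, depth = tot[j],
        genotype = if (vaf >= 0.75) "hom" else "het",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(), pos0 = integer(),
                      ref = character(), alt = character(), vaf = numeric(),
                      depth = integer(), genotype = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Sensitivity as a function of downsampled depth
#'
#' Re-evaluates variant detection after downsampling the alignments to a
#' series of fractions (nested subsets under one seed), calling with the
#' naive pileup caller and labeling against the truth set.
#'
#' @param aln alignment record data.frame.
#' @param genome named contig sequences.
#' @param truth expected-variant data.frame (`contig`, `pos0`, `ref`,
#'   `alt`).
#' @param fractions descending vector of retention fractions in (0, 1].
#' @param seed downsampling seed.
#' @param min_depth,min_alt_fraction caller parameters.
#' @return data.frame with columns `fraction`, `detected`, `expected`,
#'   `sensitivity`.
#' @export
sensitivity_vs_depth <- function(aln, genome, truth, fractions, seed = 1L,
                                 min_depth = 10L, min_alt_fraction = 0.2) {
  if (is.unsorted(rev(fractions), strictly = FALSE))
    stop("fractions must be descending")
  contigs <- unique(truth$contig)
  key <- paste(truth$contig, truth$pos0, truth$ref, truth$alt)
  rows <- lapply(fractions, function(f) {
    sub <- downsample_alignments(aln, fraction = f, seed = seed)
    calls <- do.call(rbind, lapply(contigs, function(ct) {
      p <- pileup(sub, genome, ct, bases = TRUE)
      naive_pileup_caller(p, genome, min_depth, min_alt_fraction)
    }))
    det <- if (is.null(calls) || !nrow(calls)) 0L else
      sum(key %in% paste(calls$contig, calls$pos0, calls$ref, calls$alt))
    data.frame(fraction = f, detected = det, expected = nrow(truth),
               sensitivity = det / nrow(truth))
  })
  do.call(rbind, rows)
}
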