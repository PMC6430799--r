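#' Mean over sliding windows
#'
#' @param v numeric vector.
#' @param window window width (positions).
#' @param step step between window starts (default `window / 2`, rounded
#'   down, minimum 1).
#' @param na.rm drop NA/NaN positions within a window.
#' @return numeric vector of window means.
#' @export
window_means <- function(v, window, step = max(1L, window %/% 2L),
                         na.rm = TRUE) {
  n <- length(v)
  if (window < 1L || window > n) stop("bad window")
  starts <- seq.int(1L, n - window + 1L, by = step)
  vapply(starts, function(s) mean(v[s:(s + window - 1L)], na.rm = na.rm),
         numeric(1L))
}

#' Concordance between two per-base profiles
#'
#' Measures how similarly an assay treats a sequence and a partner sequence:
#' profiles are optionally averaged in sliding windows (whole-profile
#' comparison with `window = NULL`), then compared by squared Pearson
#' correlation (R^2), Pearson and Spearman. With `pairing = "mirrored"` the
#' second profile's position axis is reversed first, so a chiral pair's
#' profiles line up base-for-base.
#'
#' @param x,y numeric vectors of equal length (e.g. depth arrays or
#'   [error_rate_profile()] output), or `pileup_profile` objects (their
#'   depth is used).
#' @param pairing `"mirrored"`, `"replicate"` or `"unpaired"` (recorded in
#'   the result; `"mirrored"` also reverses `y`).
#' @param window sliding-window width in bp (default 40), or `NULL` for
#'   per-base comparison.
#' @param step window step (default `window / 2`).
#' @return object of class `concordance_result`: list with `r_squared`,
#'   `pearson`, `spearman`, `n_points`, `pairing`, `window`, and the
#'   windowed vectors `wx`, `wy`.
#' @export
concordance <- function(x, y, pairing = c("mirrored", "replicate",
                                          "unpaired"),
                        window = 40L, step = NULL) {
  pairing <- match.arg(pairing)
  if (inherits(x, "pileup_profile")) x <- x$depth
  if (inherits(y, "pileup_profile")) y <- y$depth
  if (length(x) != length(y)) stop("profile length mismatch")
  if (pairing == "mirrored") y <- rev(y)
  if (!is.null(window)) {
    if (is.null(step)) step <- max(1L, window %/% 2L)
    wx <- window_means(x, window, step)
    wy <- window_means(y, window, step)
  } else {
    wx <- x; wy <- y
  }
  ok <- is.finite(wx) & is.finite(wy)
  wx <- wx[ok]; wy <- wy[ok]
  if (length(wx) < 3L) stop("fewer than 3 comparable points")
  pe <- stats::cor(wx, wy)
  sp <- stats::cor(wx, wy, method = "spearman")
  structure(list(r_squared = pe^2, pearson = pe, spearman = sp,
                 n_points = length(wx), pairing = pairing,
                 window = window, wx = wx, wy = wy),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance (%s, window %s): R^2 = %.3f, rho = %.3f, n = %d\n",
              x$pairing, ifelse(is.null(x$window), "none", x$window),
              x$r_squared, x$spearman, x$n_points))
  invisible(x)
}

#' Pooled concordance across several profile pairs
#'
#' Windows each pair, concatenates the windowed points and computes one
#' overall correlation — the whole-panel analog of per-pair concordance.
#'
#' @param pairs list of `list(x = , y = )` numeric profile pairs.
#' @param pairing,window,step as in [concordance()].
#' @return a `concordance_result` over the pooled points.
#' @export
pooled_concordance <- function(pairs, pairing = "mirrored", window = 40L,
                               step = NULL) {
  parts <- lapply(pairs, function(p)
    concordance(p$x, p$y, pairing = pairing, window = window, step = step))
  wx <- unlist(lapply(parts, `[[`, "wx"))
  wy <- unlist(lapply(parts, `[[`, "wy"))
  pe <- stats::cor(wx, wy)
  structure(list(r_squared = pe^2, pearson = pe,
                 spearman = stats::cor(wx, wy, method = "spearman"),
                 n_points = length(wx), pairing = pairing, window = window,
                 wx = wx, wy = wy),
            class = "concordance_result")
}

#' Error rates aggregated over feature classes
#'
#' For each feature class (e.g. repeat-length bin or GC bin) the error rate
#' is the total error count over the class's positional footprint divided by
#' the total depth there — a per-base-observation rate in \\[0, 1\\],
#' normalized to the class's footprint size. Classes with no positions or no
#' coverage are absent from the result (not reported as zero).
#'
#' @param p a `pileup_profile`.
#' @param features data.frame with columns `class`, `start`, `end`
#'   (0-based half-open, within the profiled region).
#' @param type error type as in [error_rate_profile()].
#' @return data.frame with columns `class`, `n_positions`, `errors`,
#'   `depth`, `rate`.
#' @export
error_rates_by_feature <- function(p, features, type = "indel") {
  if (any(features$start < p$start | features$end > p$end))
    stop("feature outside profiled region")
  cnt <- switch(type,
                indel = p$insertion + p$deletion,
                mismatch = p$mismatch,
                any = p$insertion + p$deletion + p$mismatch)
  rows <- lapply(split(features, features$class), function(f) {
    idx <- unique(unlist(mapply(function(s, e)
      if (e > s) (s - p$start + 1L):(e - p$start) else integer(0L),
      f$start, f$end, SIMPLIFY = FALSE)))
    if (!length(idx)) return(NULL)
    d <- sum(p$depth[idx])
    if (d == 0) return(NULL)
    data.frame(class = f$class[1L], n_positions = length(idx),
               errors = sum(cnt[idx]), depth = d,
               rate = sum(cnt[idx]) / d, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(class = character(), n_positions = integer(),
                      errors = integer(), depth = integer(),
                      rate = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
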