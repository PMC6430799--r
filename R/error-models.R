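#' Sequencing error models for the read simulator
#'
#' An error model has a flat per-base mismatch rate, a per-base indel rate,
#' and a repeat-slippage coefficient that scales the indel rate with the
#' length of the repeat run containing a position:
#' `indel_rate(pos) = min(indel * (1 + slip * (run_len - 1)), max_rate)`,
#' where `run_len` is the [repeat_context()] value (mirror-invariant, so
#' error injection is mirror-symmetric by construction). Presets:
#'
#' * `error_free` — no errors.
#' * `pcr_free` — low-indel preparation: mismatch 1e-3, indel 4e-4,
#'   slip 0.15. At a 25 nt homopolymer the per-base indel rate is ~1.8e-3,
#'   leaving ~95% of spanning reads indel-free across the run.
#' * `standard` — PCR-amplified preparation: mismatch 1e-3, indel 4e-3,
#'   slip 0.9. At a 25 nt homopolymer the per-base indel rate is ~0.090, so
#'   nearly every spanning read carries slippage indels — the regime in
#'   which repeat-length distributions smear.
#' * `nanopore_like` — indel-dominated long reads: mismatch 0.02,
#'   indel 0.03, slip 0.5.
#'
#' @param preset preset name, or `"custom"` with explicit rates.
#' @param mismatch,indel,slip,del_frac,max_rate custom parameters
#'   (`del_frac` is the deletion share of indel events; `max_rate` caps the
#'   position-wise indel rate).
#' @return object of class `error_model`.
#' @export
error_model <- function(preset = c("error_free", "pcr_free", "standard",
                                   "nanopore_like", "custom"),
                        mismatch = 0, indel = 0, slip = 0, del_frac = 0.5,
                        max_rate = 0.3) {
  preset <- match.arg(preset)
  p <- switch(preset,
    error_free = list(mismatch = 0, indel = 0, slip = 0),
    pcr_free = list(mismatch = 1e-3, indel = 4e-4, slip = 0.15),
    standard = list(mismatch = 1e-3, indel = 4e-3, slip = 0.9),
    nanopore_like = list(mismatch = 0.02, indel = 0.03, slip = 0.5),
    custom = list(mismatch = mismatch, indel = indel, slip = slip))
  stopifnot(p$mismatch >= 0, p$mismatch <= 1, p$indel >= 0, p$indel <= 1,
            p$slip >= 0, del_frac >= 0, del_frac <= 1)
  structure(c(p, list(del_frac = del_frac, max_rate = max_rate,
                      name = preset)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "error model '%s': mismatch %.2g, indel %.2g, slippage %.2g/nt\n",
    x$name, x$mismatch, x$indel, x$slip))
  invisible(x)
}

#' Position-wise indel rate of a template under an error model
#'
#' @param seq template sequence.
#' @param model an `error_model`.
#' @return numeric vector of per-base indel rates, length `nchar(seq)`.
#' @export
indel_rate_profile <- function(seq, model) {
  if (model$indel == 0) return(rep(0, nchar(seq)))
  ctx <- repeat_context(seq)
  pmin(model$indel * (1 + model$slip * (ctx - 1)), model$max_rate)
}
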