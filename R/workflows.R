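#' Simulate a full MSI assay and measure the locus length distribution
#'
#' Sequences a sequin MSI mixture ([design_msi_sequins()]) with the given
#' error model and measures the repeat-length distribution from spanning
#' reads. Each molecule is measured at its own locus interval (its CIGARs
#' are relative to its own sequence) and observations are pooled on the
#' assay reference length, so a one-unit mutant contributes at offset -unit
#' even with error-free reads.
#'
#' @param design result of [design_msi_sequins()].
#' @param model an [error_model()].
#' @param coverage per-mixture pool coverage (default 1500).
#' @param read_len read length (default 120).
#' @param min_overhang spanning-read overhang (default 4).
#' @param seed integer seed.
#' @return a `length_distribution` for the mixture.
#' @export
simulate_msi_assay <- function(design, model, coverage = 1500,
                               read_len = 120L, min_overhang = 4L,
                               seed = 1L) {
  manifest <- design$manifest
  mols <- design$molecules[manifest$entries$molecule_id]
  templates <- vapply(mols, `[[`, character(1L), "bases")
  ab <- stats::setNames(manifest$entries$fraction, names(templates))
  aln <- simulate_reads(templates, ab, coverage = coverage,
                        read_len = read_len, model = model, seed = seed,
                        prefix = "msi")
  ref_len <- design$locus_spec$end - design$locus_spec$start
  obs <- integer(0L)
  for (id in names(mols)) {
    loc <- mols[[id]]$locus
    sp <- collect_spanning_reads(aln[aln$rname == id, , drop = FALSE], id,
                                 loc$start, loc$end, min_overhang)
    if (!nrow(sp)) next
    lens <- vapply(seq_len(nrow(sp)), function(i)
      repeat_length_from_read(sp$pos0[i], sp$cigar[i], loc$start, loc$end),
      integer(1L))
    obs <- c(obs, lens)
  }
  length_histogram(obs, ref_len)
}

#' Germline sequin evaluation workflow
#'
#' End-to-end evaluation of a germline sequin mixture against its manifest:
#' partition the combined alignments by namespace, transform the chiral
#' records onto the forward genome, downsample them to the human sample's
#' mean footprint coverage, call SNVs with the naive pileup caller over the
#' sequin footprints, label the calls against the manifest, and summarize
#' sensitivity and VAF accuracy.
#'
#' @param aln combined alignment record data.frame (human + chiral).
#' @param genome named forward-space contig sequences.
#' @param contig_table combined-index contig table.
#' @param manifest germline `mixture_manifest` with `expected_variants` and
#'   molecule source intervals.
#' @param seed downsampling seed.
#' @param min_depth,min_alt_fraction caller parameters.
#' @param vaf_range range for [vaf_regression()] (default 1.5-100%).
#' @return object of class `run_report` (a list; see [write_run_report()]).
#' @export
run_germline_eval <- function(aln, genome, contig_table, manifest,
                              seed = 1L, min_depth = 10L,
                              min_alt_fraction = 0.2,
                              vaf_range = c(0.015, 1)) {
  part <- partition_alignments(aln, contig_table)
  chiral_fwd <- transform_alignments(part$chiral, contig_table)
  footprints <- unique(do.call(rbind, lapply(manifest$molecules, function(m)
    data.frame(contig = m$source$contig, start = m$source$start,
               end = m$source$end, stringsAsFactors = FALSE))))
  mean_cov <- function(a) {
    tot <- 0; npos <- 0L
    for (i in seq_len(nrow(footprints))) {
      p <- pileup(a, genome, footprints$contig[i], footprints$start[i],
                  footprints$end[i])
      tot <- tot + sum(p$depth); npos <- npos + (p$end - p$start)
    }
    tot / npos
  }
  cov_h <- mean_cov(part$human)
  cov_c <- mean_cov(chiral_fwd)
  frac <- if (cov_c > 0) min(1, cov_h / cov_c) else 1
  chiral_ds <- downsample_alignments(chiral_fwd, fraction = frac,
                                     seed = seed)
  calls <- list()
  for (i in seq_len(nrow(footprints))) {
    p <- pileup(chiral_ds, genome, footprints$contig[i],
                footprints$start[i], footprints$end[i], bases = TRUE)
    calls[[i]] <- naive_pileup_caller(p, genome, min_depth,
                                      min_alt_fraction)
  }
  calls <- do.call(rbind, calls)
  truth <- manifest$expected_variants
  labeled <- label_calls(calls, truth, genome = genome,
                         footprints = footprints)
  key <- function(d) paste(d$contig, d$pos0, d$ref, d$alt)
  detected <- sum(key(truth) %in% key(labeled[labeled$label == "TP", ,
                                              drop = FALSE]))
  sn <- sensitivity(detected, nrow(truth))
  tp <- labeled[labeled$label == "TP", , drop = FALSE]
  exp_vaf <- truth$expected_vaf[match(key(tp), key(truth))]
  reg <- tryCatch(vaf_regression(tp$vaf, exp_vaf, range = vaf_range),
                  error = function(e) NULL)
  structure(list(
    tool = "chiralseq",
    version = as.character(utils::packageVersion("chiralseq")),
    workflow = "germline_eval",
    seed = seed,
    config = list(min_depth = min_depth,
                  min_alt_fraction = min_alt_fraction,
                  vaf_range = vaf_range),
    stages = list(
      partition = list(counts = as.list(part$counts),
                       cross_alignment = if (is.null(part$cross_alignment))
                         NULL else part$cross_alignment),
      downsample = list(fraction = frac, human_cov = cov_h,
                        chiral_cov = cov_c),
      evaluation = list(expected = sn$expected, detected = sn$detected,
                        sensitivity = sn$value,
                        sensitivity_exact = sn$exact,
                        n_tp = sum(labeled$label == "TP"),
                        n_fp = sum(labeled$label == "FP"),
                        vaf_regression = reg)),
    labeled_calls = labeled),
    class = "run_report")
}

#' Somatic sequin evaluation workflow
#'
#' Optimizes score thresholds on labeled sequin calls (zero FPs retained,
#' maximum TPs, then maximum retained sample candidates) and applies the
#' rule to the sample candidates.
#'
#' @param sequin_calls data.frame of sequin variant candidates with score
#'   columns, either pre-labeled (`label` column) or labeled here against
#'   `truth`.
#' @param sample_calls data.frame of sample candidates with the same score
#'   columns.
#' @param scores character vector of score column names (e.g.
#'   `c("QSS", "SomaticEVS")`).
#' @param truth optional expected-variant data.frame for labeling.
#' @param genome,footprints passed to [label_calls()] when labeling.
#' @param seed recorded in the report.
#' @return a `run_report` with the rule, retained/excluded accounting and
#'   the filtered sample calls.
#' @export
run_somatic_eval <- function(sequin_calls, sample_calls, scores,
                             truth = NULL, genome = NULL, footprints = NULL,
                             seed = 1L) {
  if (is.null(sequin_calls$label)) {
    if (is.null(truth)) stop("either pre-labeled sequin calls or truth")
    sequin_calls <- label_calls(sequin_calls, truth, genome, footprints)
  }
  rule <- optimize_thresholds(sequin_calls, scores,
                              sample_calls = sample_calls)
  seq_f <- apply_thresholds(rule, sequin_calls)
  fp_after <- sum(seq_f$pass & seq_f$label == "FP")
  stopifnot(fp_after == 0L)
  sample_f <- apply_thresholds(rule, sample_calls)
  structure(list(
    tool = "chiralseq",
    version = as.character(utils::packageVersion("chiralseq")),
    workflow = "somatic_eval",
    seed = seed,
    config = list(scores = scores),
    stages = list(
      optimize = list(thresholds = as.list(rule$thresholds),
                      n_tp = rule$n_tp, n_fp = rule$n_fp,
                      n_tp_retained = rule$n_tp_retained,
                      n_fp_retained = fp_after,
                      all_rejected = rule$all_rejected),
      filter = list(n_sample = nrow(sample_calls),
                    n_sample_retained = sum(sample_f$pass))),
    rule = rule,
    sample_calls = sample_f),
    class = "run_report")
}

#' Write a run report to JSON
#'
#' Reports are pure functions of (inputs, config, seed): no timestamps, so
#' two runs with the same inputs produce byte-identical files.
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @return `path` invisibly.
#' @export
write_run_report <- function(report, path) {
  keep <- report[setdiff(names(report),
                         c("labeled_calls", "rule", "sample_calls"))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", dataframe = "rows")
  invisible(path)
}

#' Validate a run report against the shipped schema
#'
#' Checks the required fields and types of the report JSON schema at
#' `system.file("schema", "run_report.schema.json", package = "chiralseq")`.
#'
#' @param report a `run_report` or a list parsed from report JSON.
#' @return `TRUE` (invisibly); errors describe the first violation.
#' @export
validate_run_report <- function(report) {
  req <- c("tool", "version", "workflow", "seed", "config", "stages")
  miss <- setdiff(req, names(report))
  if (length(miss)) stop("report missing fields: ",
                         paste(miss, collapse = ", "))
  if (!identical(report$tool, "chiralseq")) stop("unexpected tool field")
  if (!report$workflow %in% c("germline_eval", "somatic_eval"))
    stop("unknown workflow: ", report$workflow)
  if (!is.numeric(report$seed)) stop("seed must be numeric")
  if (!is.list(report$stages) || !length(report$stages))
    stop("stages must be a non-empty list")
  invisible(TRUE)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("chiralseq %s report (seed %d)\n", x$workflow, x$seed))
  utils::str(x$stages, max.level = 2L, give.attr = FALSE)
  invisible(x)
}
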