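#' Simulate a genome with planted features
#'
#' Contigs are drawn base-by-base at the requested GC fraction, then planted
#' features (homopolymers, STRs, microsatellites) overwrite the draw at
#' stated positions. Fully reproducible from the seed.
#'
#' @param contigs data.frame with columns `name`, `length`, `gc`.
#' @param features optional data.frame with columns `contig`, `start`
#'   (0-based), `unit`, `copies`; features must not overlap.
#' @param seed integer seed.
#' @return list with `genome` (named character vector) and `truth`
#'   (features with `start`, `end` filled in; the truth BED content).
#' @export
simulate_genome <- function(contigs, features = NULL, seed = 1L) {
  set.seed(seed)
  genome <- stats::setNames(vector("character", nrow(contigs)),
                            contigs$name)
  for (i in seq_len(nrow(contigs)))
    genome[[contigs$name[i]]] <- random_dna(contigs$length[i], contigs$gc[i])
  truth <- data.frame(contig = character(), start = integer(),
                      end = integer(), unit = character(),
                      copies = integer(), stringsAsFactors = FALSE)
  if (!is.null(features) && nrow(features)) {
    features$end <- features$start + nchar(features$unit) * features$copies
    o <- order(features$contig, features$start)
    features <- features[o, , drop = FALSE]
    for (ct in unique(features$contig)) {
      f <- features[features$contig == ct, , drop = FALSE]
      if (nrow(f) > 1L && any(f$start[-1L] < f$end[-nrow(f)]))
        stop("overlapping features on ", ct)
      if (any(f$end > nchar(genome[[ct]])))
        stop("feature beyond contig end on ", ct)
      for (i in seq_len(nrow(f))) {
        ins <- strrep(f$unit[i], f$copies[i])
        substr(genome[[ct]], f$start[i] + 1L, f$end[i]) <- ins
      }
    }
    truth <- features[c("contig", "start", "end", "unit", "copies")]
    rownames(truth) <- NULL
  }
  list(genome = genome, truth = truth)
}

## core error-injection + record assembly for one template.
## starts: 0-based left edges of aligned windows; read_lens: bases to emit.
## Returns an alignment_records data.frame (no mate fields filled).
sim_reads_from_windows <- function(template, tname, starts, read_lens,
                                   strand, model, qname, mate = 0L) {
  n <- length(starts)
  if (!n) return(NULL)
  L <- nchar(template)
  idr <- indel_rate_profile(template, model)
  tch <- strsplit(template, "")[[1L]]
  acgt <- c("A", "C", "G", "T")
  tcode <- match(tch, acgt)
  slack <- pmax(10L, ceiling(read_lens * model$max_rate))
  win <- pmin(read_lens + slack, L - starts)
  out_seq <- character(n); out_cigar <- character(n)
  out_pos <- integer(n)
  total <- sum(win)
  ## one uniform draw per window position decides indel events; a second
  ## stream decides mismatches on emitted template bases
  u_indel <- stats::runif(total)
  u_mm <- stats::runif(total)
  u_pick <- stats::runif(total)  # base choice for ins/mismatch
  off <- cumsum(c(0L, win))
  for (r in seq_len(n)) {
    s <- starts[r]; w <- win[r]; R <- read_lens[r]
    pos_idx <- (s + 1L):(s + w)
    ui <- u_indel[(off[r] + 1L):(off[r] + w)]
    rate <- idr[pos_idx]
    if (model$indel == 0 && model$mismatch == 0) {
      out_seq[r] <- substr(template, s + 1L, s + min(R, w))
      out_cigar[r] <- paste0(min(R, w), "M")
      out_pos[r] <- s
      next
    }
    is_del <- ui < rate * model$del_frac
    is_ins <- !is_del & ui < rate
    um <- u_mm[(off[r] + 1L):(off[r] + w)]
    is_mm <- !is_del & um < model$mismatch
    if (!any(is_del | is_ins | is_mm)) {
      out_seq[r] <- substr(template, s + 1L, s + min(R, w))
      out_cigar[r] <- paste0(min(R, w), "M")
      out_pos[r] <- s
      next
    }
    up <- u_pick[(off[r] + 1L):(off[r] + w)]
    base_op <- ifelse(is_del, "D", "M")
    reps <- 1L + as.integer(is_ins & !is_del)
    idx <- rep(seq_len(w), reps)
    ops <- base_op[idx]
    ops[duplicated(idx)] <- "I"
    emits <- as.integer(ops != "D")
    cum <- cumsum(emits)
    last <- match(R, cum)
    if (is.na(last)) last <- length(ops)
    ops <- ops[seq_len(last)]
    oidx <- idx[seq_len(last)]
    lead <- match(FALSE, ops == "D", nomatch = length(ops) + 1L) - 1L
    if (lead > 0L) {
      ops <- ops[-seq_len(lead)]
      oidx <- oidx[-seq_len(lead)]
    }
    ## emitted bases
    emit <- ops != "D"
    src <- oidx[emit] + s            # 1-based template positions
    bases <- tch[src]
    eops <- ops[emit]
    ## mismatches replace the template base by one of the other three
    mm_here <- eops == "M" & is_mm[oidx[emit]]
    if (any(mm_here)) {
      shift <- 1L + floor(up[oidx[emit][mm_here]] * 3) %% 3L
      bases[mm_here] <- acgt[((tcode[src[mm_here]] - 1L + shift) %% 4L) + 1L]
    }
    ## inserted bases are uniform random
    ins_here <- eops == "I"
    if (any(ins_here))
      bases[ins_here] <- acgt[1L + floor(up[oidx[emit][ins_here]] * 4) %% 4L]
    r_rle <- rle(ops)
    out_cigar[r] <- paste0(r_rle$lengths, r_rle$values, collapse = "")
    out_seq[r] <- paste(bases, collapse = "")
    out_pos[r] <- s + lead
  }
  alignment_records(
    qname = qname, mate = mate, rname = tname, pos0 = out_pos,
    mapq = 60L, cigar = out_cigar, strand = strand, seq = out_seq,
    qual = strrep("I", nchar(out_seq)), origin = tname)
}

#' Simulate paired-end reads from template molecules with truth alignments
#'
#' Fragments are drawn per template in proportion to `abundance`; the
#' expected depth of template `i` is `coverage * abundance[i]` (so a 50:50
#' heterozygous molecule pair at coverage 1000 yields ~1000x combined at the
#' shared locus). Fragment lengths are truncated-normal, start positions
#' uniform, and both fragment orientations equiprobable. Sequencing errors
#' are injected per the model, with the indel probability scaled by the
#' repeat-run length at each position; the records returned are the truth
#' alignments (exact origin, coordinates and injected-error CIGARs), with
#' minus-strand records stored reference-forward as in SAM.
#'
#' @param templates named character vector of template sequences.
#' @param abundances named numeric mass fractions (must sum to 1).
#' @param coverage pool coverage scale (see above).
#' @param read_len read length (default 100).
#' @param frag_mean,frag_sd fragment length distribution (default 300/30).
#' @param model an [error_model()].
#' @param seed integer seed; draws are made template by template in input
#'   order, so output is fully reproducible.
#' @param prefix read-name prefix.
#' @return alignment record data.frame (both mates, `origin` = template).
#' @export
simulate_reads <- function(templates, abundances, coverage, read_len = 100L,
                           frag_mean = 300L, frag_sd = 30L,
                           model = error_model("error_free"), seed = 1L,
                           prefix = "sim") {
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  if (!all(names(templates) %in% names(abundances) |
           names(abundances) %in% names(templates)))
    stop("abundance names must match template names")
  set.seed(seed)
  parts <- list()
  for (tn in names(templates)) {
    a <- abundances[[tn]]
    if (is.null(a) || a == 0) next
    tmpl <- templates[[tn]]
    L <- nchar(tmpl)
    if (read_len > L) stop("read length exceeds template ", tn)
    n_frag <- round(coverage * a * L / (2 * read_len))
    if (n_frag < 1L) next
    flen <- pmin(pmax(round(stats::rnorm(n_frag, frag_mean, frag_sd)),
                      read_len), L)
    fstart <- floor(stats::runif(n_frag, 0, L - flen + 1))
    first_left <- stats::runif(n_frag) < 0.5  # mate1 on the left end?
    qn <- sprintf("%s_%s_%06d", prefix, tn, seq_len(n_frag))
    left <- sim_reads_from_windows(
      tmpl, tn, as.integer(fstart), rep(read_len, n_frag), "+", model,
      qname = qn, mate = ifelse(first_left, 1L, 2L))
    right_start <- as.integer(pmax(fstart, fstart + flen - read_len))
    right <- sim_reads_from_windows(
      tmpl, tn, right_start, rep(read_len, n_frag), "-", model,
      qname = qn, mate = ifelse(first_left, 2L, 1L))
    ## mate fields
    left$mrnm <- tn; right$mrnm <- tn
    left$mpos0 <- right$pos0; right$mpos0 <- left$pos0
    outer <- pmax(right$pos0 + cigar_ref_span(right$cigar),
                  left$pos0 + cigar_ref_span(left$cigar)) -
             pmin(left$pos0, right$pos0)
    left$tlen <- as.integer(outer); right$tlen <- -as.integer(outer)
    parts[[length(parts) + 1L]] <- rbind(left, right)
  }
  if (!length(parts)) stop("no reads simulated; increase coverage")
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Simulate single-end long reads (indel-dominated error preset)
#'
#' @param templates,abundances,coverage as in [simulate_reads()].
#' @param len_mean,len_sd read length distribution (truncated normal,
#'   minimum 200 nt, capped at template length).
#' @param model error model (default `nanopore_like`).
#' @param seed integer seed.
#' @param prefix read-name prefix.
#' @return alignment record data.frame (unpaired truth alignments).
#' @export
simulate_long_reads <- function(templates, abundances, coverage,
                                len_mean = 1000L, len_sd = 300L,
                                model = error_model("nanopore_like"),
                                seed = 1L, prefix = "lr") {
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  set.seed(seed)
  parts <- list()
  for (tn in names(templates)) {
    a <- abundances[[tn]]
    if (is.null(a) || a == 0) next
    tmpl <- templates[[tn]]
    L <- nchar(tmpl)
    n <- round(coverage * a * L / len_mean)
    if (n < 1L) next
    rl <- pmin(pmax(round(stats::rnorm(n, len_mean, len_sd)), 200L), L)
    st <- floor(stats::runif(n, 0, L - rl + 1))
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
    parts[[length(parts) + 1L]] <- sim_reads_from_windows(
      tmpl, tn, as.integer(st), as.integer(rl), strand, model,
      qname = sprintf("%s_%s_%06d", prefix, tn, seq_len(n)), mate = 0L)
  }
  if (!length(parts)) stop("no reads simulated; increase coverage")
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Build the chiral mirror benchmark: paired regions, reads and truth
#'
#' Emulates the standard commutability experiment: `n_pairs` synthetic
#' regions with planted repeat features, each mirrored, all 2n templates
#' mixed at equal abundance and sequenced to `coverage` per template with a
#' mirror-symmetric context error model. Returns everything the profile
#' pipeline needs, with truth alignments in place of an external aligner.
#'
#' @param n_pairs number of fwd/rev pairs (default 8).
#' @param length region length (default 1800 nt).
#' @param coverage per-template depth (default 200).
#' @param model an [error_model()] (default `"standard"`).
#' @param seed integer seed.
#' @param read_len,frag_mean,frag_sd read simulation parameters.
#' @param n_features planted repeat runs per region (default 6).
#' @return list with `genome` (combined fwd+rev contigs), `contig_table`,
#'   `aln` (truth alignments), `features` (planted repeats on fwd contigs)
#'   and `pairs` (fwd/rev contig name pairs).
#' @export
make_mirror_benchmark <- function(n_pairs = 8L, length = 1800L,
                                  coverage = 200, model =
                                    error_model("standard"), seed = 1L,
                                  read_len = 100L, frag_mean = 300L,
                                  frag_sd = 30L, n_features = 6L) {
  set.seed(seed)
  fwd <- character(n_pairs)
  names(fwd) <- sprintf("mb%02d", seq_len(n_pairs))
  feats <- list()
  for (i in seq_len(n_pairs)) {
    s <- random_dna(length, gc = 0.45)
    placed <- data.frame(start = integer(), end = integer())
    for (k in seq_len(n_features)) {
      if (stats::runif(1) < 0.5) {
        unit <- sample(c("A", "C", "G", "T"), 1L)
        copies <- sample(8:16, 1L)
      } else {
        unit <- paste0(sample(c("A", "C", "G", "T"), 2L), collapse = "")
        copies <- sample(5:8, 1L)
      }
      w <- nchar(unit) * copies
      for (try in 1:50) {
        st <- sample.int(length - w - 40L, 1L) + 20L
        if (!any(st < placed$end + 10L & st + w > placed$start - 10L)) {
          substr(s, st + 1L, st + w) <- strrep(unit, copies)
          placed <- rbind(placed, data.frame(start = st, end = st + w))
          feats[[base::length(feats) + 1L]] <- data.frame(
            contig = names(fwd)[i], start = st, end = st + w, unit = unit,
            copies = copies, stringsAsFactors = FALSE)
          break
        }
      }
    }
    fwd[i] <- s
  }
  mir <- build_mirrored_genome(fwd)
  templates <- mir$combined
  ab <- stats::setNames(rep(1 / base::length(templates),
                            base::length(templates)), names(templates))
  aln <- simulate_reads(templates, ab,
                        coverage = coverage * base::length(templates),
                        read_len = read_len, frag_mean = frag_mean,
                        frag_sd = frag_sd, model = model,
                        seed = seed + 1L, prefix = "mb")
  list(genome = mir$combined, contig_table = mir$contig_table, aln = aln,
       features = do.call(rbind, feats),
       pairs = data.frame(fwd = names(fwd), rev = paste0(names(fwd), "_rev"),
                          stringsAsFactors = FALSE))
}

#' Simulate sequencing of a sequin mixture onto the mirrored genome
#'
#' Reads are simulated from each molecule of the manifest at its mass
#' fraction and their truth alignments lifted into the coordinates of the
#' mirrored genome contig the molecule derives from (a molecule mirrored
#' from forward region `[a, b)` of a contig of length `L` occupies
#' `[L - b, L - a)` of the mirrored twin). Only length-preserving molecules
#' (wild-type or SNV) can be lifted; indel-carrying molecules are an error.
#'
#' @param manifest a `mixture_manifest` with molecule sequences.
#' @param contig_table combined-index contig table.
#' @param coverage pool coverage (per-molecule depth = coverage * fraction).
#' @param read_len,frag_mean,frag_sd,model,seed,prefix as in
#'   [simulate_reads()].
#' @return alignment record data.frame on the mirrored contigs, with
#'   `origin` set to the mirrored contig name.
#' @export
simulate_sequin_reads <- function(manifest, contig_table, coverage,
                                  read_len = 100L, frag_mean = 300L,
                                  frag_sd = 30L,
                                  model = error_model("error_free"),
                                  seed = 1L, prefix = "sq") {
  mols <- manifest$molecules[manifest$entries$molecule_id]
  templates <- vapply(mols, `[[`, character(1L), "bases")
  widths <- vapply(mols, function(m) m$source$end - m$source$start,
                   numeric(1L))
  if (any(nchar(templates) != widths))
    stop("only length-preserving molecules can be lifted onto the genome")
  ab <- stats::setNames(manifest$entries$fraction, names(templates))
  aln <- simulate_reads(templates, ab, coverage = coverage,
                        read_len = read_len, frag_mean = frag_mean,
                        frag_sd = frag_sd, model = model, seed = seed,
                        prefix = prefix)
  for (id in names(mols)) {
    src <- mols[[id]]$source
    info <- contig_info(contig_table, src$contig)
    offset <- info$length - src$end
    sel <- aln$rname == id
    aln$pos0[sel] <- aln$pos0[sel] + offset
    aln$mpos0[sel] <- aln$mpos0[sel] + offset
    aln$rname[sel] <- info$partner
    aln$mrnm[sel] <- info$partner
    aln$origin[sel] <- info$partner
  }
  aln
}
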