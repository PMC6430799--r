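# shared fixture builders; all randomness is seeded by the calling test

# independent string-reverse oracle (never uses mirror_sequence)
oracle_reverse <- function(s) {
  vapply(s, function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = ""),
         character(1L), USE.NAMES = FALSE)
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random alignment set on one contig: mixtures of M/I/D/S operations with
# no leading/trailing I; sequences drawn at random (mismatches arise
# naturally against the reference)
random_alignment_set <- function(L, n_reads) {
  recs <- lapply(seq_len(n_reads), function(i) {
    ops <- c()
    lens <- c()
    if (runif(1) < 0.3) { ops <- "S"; lens <- sample(1:5, 1) }
    ops <- c(ops, "M"); lens <- c(lens, sample(8:20, 1))
    for (k in seq_len(sample(0:3, 1))) {
      ops <- c(ops, sample(c("I", "D"), 1)); lens <- c(lens, sample(1:3, 1))
      ops <- c(ops, "M"); lens <- c(lens, sample(5:15, 1))
    }
    if (runif(1) < 0.3) { ops <- c(ops, "S"); lens <- c(lens, sample(1:5, 1)) }
    span <- sum(lens[ops %in% c("M", "D")])
    qlen <- sum(lens[ops %in% c("M", "I", "S")])
    if (span >= L) return(NULL)
    pos <- sample.int(L - span, 1) - 1L
    alignment_records(
      qname = sprintf("rr%04d", i), rname = "ctg", pos0 = pos,
      cigar = paste0(lens, ops, collapse = ""),
      seq = rand_dna(qlen), qual = strrep("I", qlen))
  })
  do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
}

# genome + SNV variant table spaced along one contig
make_variant_fixture <- function(n_variants, contig_len = 20000L,
                                 spacing = 2000L, genotype = NULL,
                                 seed = 1L) {
  set.seed(seed)
  g <- simulate_genome(data.frame(name = "chr1", length = contig_len,
                                  gc = 0.45), seed = seed)
  pos <- seq(spacing, by = spacing, length.out = n_variants)
  stopifnot(max(pos) + spacing <= contig_len)
  ref <- substring(g$genome[["chr1"]], pos + 1L, pos + 1L)
  alt <- vapply(ref, function(r) setdiff(c("A", "C", "G", "T"), r)[1L], "")
  if (is.null(genotype))
    genotype <- rep(c("het", "hom"), length.out = n_variants)
  list(genome = g$genome,
       variants = data.frame(contig = "chr1", pos0 = pos, ref = ref,
                             alt = alt, genotype = genotype,
                             stringsAsFactors = FALSE))
}

# brute-force threshold optimizer used as oracle: enumerates the same
# candidate grid definition independently of the package implementation
oracle_optimize <- function(tp, fp, scores) {
  cand <- lapply(scores, function(s) c(-Inf, sort(unique(c(tp[[s]],
                                                           fp[[s]]))), Inf))
  grid <- expand.grid(cand)
  best <- -1L
  for (i in seq_len(nrow(grid))) {
    thr <- as.numeric(grid[i, ])
    fp_pass <- if (nrow(fp)) sum(apply(fp[scores], 1L, function(v)
      all(v >= thr))) else 0L
    if (fp_pass > 0L) next
    tp_pass <- if (nrow(tp)) sum(apply(tp[scores], 1L, function(v)
      all(v >= thr))) else 0L
    if (tp_pass > best) best <- tp_pass
  }
  best
}
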