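test_that("pileup tallies depth, mismatches and indels per position", {
  set.seed(401)
  genome <- c(ctg = rand_dna(60))
  mir <- build_mirrored_genome(genome)
  read10 <- substr(genome[["ctg"]], 1, 10)
  a <- alignment_records("r1", 0L, "ctg", 0L, cigar = "10M", seq = read10,
                        qual = strrep("I", 10))
  p <- pileup(a, genome, "ctg")
  expect_equal(p$depth[1:10], rep(1L, 10))
  expect_equal(p$depth[11:60], rep(0L, 50))
  expect_equal(sum(p$mismatch) + sum(p$insertion) + sum(p$deletion), 0L)

  # one mismatch at read offset 3 (position 3, 0-based)
  rd <- read10
  orig <- substr(rd, 4, 4)
  substr(rd, 4, 4) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  p2 <- pileup(alignment_records("r2", 0L, "ctg", 0L, cigar = "10M",
                                 seq = rd, qual = strrep("I", 10)),
               genome, "ctg")
  expect_equal(which(p2$mismatch == 1L), 4L)   # 1-based array index
  expect_equal(sum(p2$mismatch), 1L)

  # deletion spans count in depth and deletion arrays; insertion anchors
  # at the preceding reference base
  seq_id <- paste0(substr(genome[["ctg"]], 1, 5),
                   substr(genome[["ctg"]], 8, 12))
  p3 <- pileup(alignment_records("r3", 0L, "ctg", 0L, cigar = "5M2D5M",
                                 seq = seq_id, qual = strrep("I", 10)),
               genome, "ctg")
  expect_equal(p3$deletion[6:7], c(1L, 1L))
  expect_equal(p3$depth[1:12], rep(1L, 12))
  seq_ins <- paste0(substr(genome[["ctg"]], 1, 5), "A",
                    substr(genome[["ctg"]], 6, 10))
  p4 <- pileup(alignment_records("r4", 0L, "ctg", 0L, cigar = "5M1I5M",
                                 seq = seq_ins, qual = strrep("I", 11)),
               genome, "ctg")
  expect_equal(which(p4$insertion == 1L), 5L)  # anchor = base 4 (0-based)

  # mapq floor excludes records
  lowq <- alignment_records("r5", 0L, "ctg", 0L, mapq = 5L, cigar = "10M",
                            seq = read10, qual = strrep("I", 10))
  expect_equal(sum(pileup(lowq, genome, "ctg", mapq_floor = 11)$depth), 0L)
  expect_error(pileup(a, genome, "nope"), "off contig")
  expect_error(pileup(a, genome, "ctg", start = 0, end = 100),
               "off contig")
})

test_that("profile normalization scales to unit mean and mirrors cleanly", {
  p <- structure(list(contig = "c", start = 0L, end = 5L,
                      contig_length = 5L, mapq_floor = 0L,
                      depth = rep(40L, 5), mismatch = integer(5),
                      insertion = integer(5), deletion = integer(5),
                      base_counts = NULL), class = "pileup_profile")
  n <- normalize_profile(p)
  expect_equal(n$depth, rep(1, 5))
  set.seed(402)
  p$depth <- sample(10:80, 5)
  expect_equal(mean(normalize_profile(p)$depth), 1)
  # normalization commutes with mirroring
  expect_equal(normalize_profile(mirror_profile(p))$depth,
               mirror_profile(normalize_profile(p))$depth)
  p$depth <- rep(0L, 5)
  expect_error(normalize_profile(p), "zero-mean")
})

test_that("concordance is 1 for identical/mirrored pairs, ~0 for unpaired", {
  set.seed(403)
  x <- runif(1800, 10, 100)
  cc <- concordance(x, x, pairing = "replicate")
  expect_equal(cc$r_squared, 1)
  expect_equal(cc$spearman, 1)
  # a mirrored pair: y is the reversal of x
  cm <- concordance(x, rev(x), pairing = "mirrored")
  expect_equal(cm$r_squared, 1)
  # independent random profiles decorrelate (per-base comparison; windowed
  # means of featureless noise leave too few effective points)
  cu <- concordance(x, runif(1800, 10, 100), pairing = "unpaired",
                    window = NULL)
  expect_lt(cu$r_squared, 0.05)
  expect_error(concordance(x, x[-1]), "length mismatch")
  # whole-sequence comparison (no windowing)
  expect_equal(concordance(x, x, "replicate", window = NULL)$n_points, 1800L)
})

test_that("feature-aggregated error rates localize and mirror", {
  set.seed(404)
  L <- 200L
  genome <- c(ctg = rand_dna(L))
  p <- structure(list(contig = "ctg", start = 0L, end = L,
                      contig_length = L, mapq_floor = 0L,
                      depth = rep(50L, L), mismatch = integer(L),
                      insertion = integer(L), deletion = integer(L),
                      base_counts = NULL), class = "pileup_profile")
  # all errors inside one class
  p$deletion[41:60] <- 3L
  feats <- data.frame(class = c("repeat", "repeat", "flank"),
                      start = c(40L, 100L, 150L), end = c(60L, 120L, 170L))
  agg <- error_rates_by_feature(p, feats)
  expect_equal(agg$rate[agg$class == "repeat"], 60 / (40 * 50))
  expect_equal(agg$rate[agg$class == "flank"], 0)
  # empty class is absent, not zero
  feats2 <- rbind(feats, data.frame(class = "void", start = 10L, end = 10L))
  expect_false("void" %in% error_rates_by_feature(p, feats2)$class)
  # mirrored profile with mirrored features gives the identical aggregate
  mf <- feats
  mf$start <- L - feats$end
  mf$end <- L - feats$start
  agg_m <- error_rates_by_feature(mirror_profile(p), mf)
  expect_equal(agg_m, agg)
  expect_error(error_rates_by_feature(p, data.frame(class = "x", start = -1L,
                                                    end = 5L)), "outside")
})

test_that("error rates increase with repeat run length under slippage", {
  set.seed(405)
  base <- rand_dna(400)
  tmpl <- c(t1 = paste0(substr(base, 1, 100), strrep("A", 5),
                        substr(base, 101, 250), strrep("A", 15),
                        substr(base, 251, 400)))
  model <- error_model("standard")
  aln <- simulate_reads(tmpl, c(t1 = 1), coverage = 400, read_len = 80,
                        frag_mean = 160, frag_sd = 10, model = model,
                        seed = 406)
  p <- pileup(aln, tmpl, "t1")
  feats <- data.frame(class = c("run5", "run15"),
                      start = c(100L, 255L), end = c(105L, 270L))
  agg <- error_rates_by_feature(p, feats, type = "indel")
  expect_gt(agg$rate[agg$class == "run15"], agg$rate[agg$class == "run5"])
})

test_that("breadth at depth counts threshold positions", {
  p <- structure(list(contig = "c", start = 0L, end = 3L,
                      contig_length = 3L, mapq_floor = 0L,
                      depth = c(40L, 10L, 35L), mismatch = integer(3),
                      insertion = integer(3), deletion = integer(3),
                      base_counts = NULL), class = "pileup_profile")
  expect_equal(breadth_at_depth(p, 30), 2 / 3)
  expect_equal(breadth_at_depth(p, 0), 1)
  expect_equal(breadth_at_depth(mirror_profile(p), 30), 2 / 3)
  expect_error(breadth_at_depth(p, -1), ">= 0")
})

test_that("insert sizes survive flipping and transforming", {
  set.seed(407)
  genome <- c(ctg = rand_dna(800))
  mir <- build_mirrored_genome(genome)
  aln <- simulate_reads(genome, c(ctg = 1), coverage = 30, read_len = 60,
                        frag_mean = 300, frag_sd = 0, seed = 408)
  isd <- insert_size_distribution(aln)
  expect_true(all(isd$sizes == 300L))
  expect_equal(isd$mean, 300)
  # transformed pairs keep identical insert sizes (mirror preserves width)
  tr <- transform_alignments(aln, mir$contig_table)
  expect_equal(sort(insert_size_distribution(tr)$sizes), sort(isd$sizes))
  expect_error(insert_size_distribution(aln[aln$mate == 1L, ]),
               "no complete read pairs")
})
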