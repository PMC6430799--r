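test_that("region extraction centers on the anchor and never clamps", {
  set.seed(201)
  genome <- c(c1 = rand_dna(5000))
  r <- extract_region(genome, "c1", 2500, 2501, 1800)
  expect_equal(c(r$start, r$end), c(1600L, 3400L))
  # positionwise slice oracle
  expect_identical(strsplit(r$seq, "")[[1]],
                   strsplit(genome[["c1"]], "")[[1]][1601:3400])
  # no silent clamping: an anchor too close to the contig start errors
  expect_error(extract_region(genome, "c1", 800, 801, 1800), "exceeds")
  expect_error(extract_region(genome, "c1", 4500, 4501, 1800), "exceeds")
  expect_error(extract_region(genome, "nope", 10, 11, 100), "unknown")
})

test_that("molecule building applies alleles then mirrors", {
  set.seed(202)
  genome <- c(c1 = rand_dna(3000))
  region <- extract_region(genome, "c1", 1500, 1501, 400)
  n <- 400L
  # wild-type: bases are the mirror of the region
  wt <- build_molecule(region, NULL, "wt")
  expect_identical(wt$bases, mirror_sequence(region$seq))
  expect_equal(wt$role, "wildtype")

  # SNV at fwd offset i lands at chiral offset n-1-i, same letter
  i <- 137L
  ref <- substr(region$seq, i + 1L, i + 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snv <- build_molecule(region, allele_spec("SNV", i, ref, alt), "snv")
  expect_equal(substr(snv$bases, n - i, n - i), alt)
  # apply-then-mirror equals mirror-then-project oracle everywhere else
  expect_identical(mirror_sequence(snv$bases),
                   apply_alleles(region$seq,
                                 allele_spec("SNV", i, ref, alt)))

  # insertion of GAT after fwd offset i shows up reversed at the mirrored
  # junction
  ins <- build_molecule(region, allele_spec("INS", i, "", "GAT"), "ins")
  j <- nchar(ins$bases) - i - 1L   # first inserted base in chiral coords
  expect_equal(substr(ins$bases, j - 2L, j), "TAG")

  expect_error(build_molecule(region, allele_spec("SNV", i, alt, ref), "x"),
               "mismatch")
  expect_error(
    apply_alleles(region$seq,
                  allele_spec(c("DEL", "SNV"), c(10L, 11L),
                              c(substr(region$seq, 11, 14),
                                substr(region$seq, 12, 12)),
                              c("", "A"))),
    "overlapping")
})

test_that("variant projection commutes with sequence editing", {
  expect_equal(
    project_variant(strrep("A", 10), strrep("A", 10), 2, "A", "G")$pos0, 7)
  set.seed(203)
  for (i in 1:100) {
    fwd <- rand_dna(80)
    rev_ <- mirror_sequence(fwd)
    L <- 80L
    kind <- sample(c("SNV", "INS", "DEL"), 1)
    p <- sample(5:70, 1)
    if (kind == "SNV") {
      ref <- substr(rev_, p + 1, p + 1)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    } else if (kind == "DEL") {
      w <- sample(2:4, 1)
      ref <- substr(rev_, p + 1, p + w)
      alt <- substr(ref, 1, 1)
    } else {
      ref <- substr(rev_, p + 1, p + 1)
      alt <- paste0(ref, rand_dna(sample(1:3, 1)))
    }
    pr <- project_variant(rev_, fwd, p, ref, alt)
    # commutation: apply projected to fwd, mirror, equals apply original
    # to rev
    apply_rec <- function(s, pos0, r, a)
      paste0(substr(s, 1, pos0), a, substr(s, pos0 + nchar(r) + 1, nchar(s)))
    expect_identical(mirror_sequence(apply_rec(fwd, pr$pos0, pr$ref, pr$alt)),
                     apply_rec(rev_, p, ref, alt),
                     info = paste(kind, p, ref, alt))
    # projecting back returns an equivalent normalized record
    back <- project_variant(fwd, rev_, pr$pos0, pr$ref, pr$alt)
    norm <- normalize_variant(rev_, p, ref, alt)
    expect_identical(back, norm)
  }
  expect_error(project_variant("ACGT", "TGCA", 1, "G", "T"),
               "does not match")
})

test_that("genotype mixtures follow het/hom representation rules", {
  fx <- make_variant_fixture(2, genotype = c("het", "hom"), seed = 204)
  man <- design_genotype_mixture(fx$genome, fx$variants,
                                 region_length = 1000)
  expect_s3_class(man, "mixture_manifest")
  # het: ref+alt molecules at equal fraction; hom: alt alone
  expect_equal(nrow(man$entries), 3L)
  het <- man$entries[grepl("_001_", man$entries$molecule_id), ]
  expect_equal(het$fraction, c(0.25, 0.25))
  expect_equal(sum(man$entries$fraction), 1)
  expect_equal(man$expected_variants$expected_vaf, c(0.5, 1))

  # 29 hom + 58 het variants yield 145 molecules
  fx2 <- make_variant_fixture(87, contig_len = 180000L,
                              genotype = rep(c("hom", "het"), c(29, 58)),
                              seed = 205)
  man2 <- design_genotype_mixture(fx2$genome, fx2$variants,
                                  region_length = 1500)
  expect_equal(nrow(man2$entries), 29L + 2L * 58L)
  expect_equal(sum(man2$entries$fraction), 1)
  # expected VAFs are derivable from entry fractions: per variant,
  # alt fraction over total fraction at the site
  frac <- stats::setNames(man2$entries$fraction, man2$entries$molecule_id)
  for (i in seq_len(87)) {
    var_id <- sprintf("gt_%03d_var", i)
    wt_id <- sprintf("gt_%03d_wt", i)
    tot <- frac[var_id] + ifelse(wt_id %in% names(frac), frac[wt_id], 0)
    expect_equal(unname(frac[var_id] / tot),
                 man2$expected_variants$expected_vaf[i])
  }
  dup <- fx$variants[c(1, 1), ]
  expect_error(design_genotype_mixture(fx$genome, dup), "duplicate")
})

test_that("the VAF ladder halves per level within placement bounds", {
  expect_equal(ladder_vaf(1), 1)
  expect_equal(100 * ladder_vaf(5), 6.25)
  expect_equal(round(100 * ladder_vaf(11), 1), 0.1)
  expect_true(all(diff(ladder_vaf(1:11)) < 0))
  expect_equal(ladder_vaf(2:11) / ladder_vaf(1:10), rep(0.5, 10))

  fx <- make_variant_fixture(94, contig_len = 200000L, seed = 206)
  lad <- design_vaf_ladder(fx$genome, fx$variants, levels = 11,
                           per_level = c(7, 9), region_length = 1500)
  sizes <- table(lad$assignment$level)
  expect_equal(length(sizes), 11L)
  expect_true(all(sizes >= 7 & sizes <= 9))
  expect_equal(sum(sizes), 94)
  expect_equal(sum(lad$tumor$entries$fraction), 1)
  expect_equal(sum(lad$normal$entries$fraction), 1)
  # the normal mixture holds only wild-type molecules
  expect_true(all(grepl("_wt$", lad$normal$entries$molecule_id)))
  # expected VAF of each variant is derivable from tumor fractions
  frac <- stats::setNames(lad$tumor$entries$fraction,
                          lad$tumor$entries$molecule_id)
  ev <- lad$tumor$expected_variants
  for (i in seq_len(nrow(ev))) {
    var_id <- sprintf("som_%03d_var", i)
    wt_id <- sprintf("som_%03d_wt", i)
    tot <- frac[var_id] + ifelse(wt_id %in% names(frac), frac[wt_id], 0)
    expect_equal(unname(frac[var_id] / tot), ev$expected_vaf[i])
  }
  expect_error(design_vaf_ladder(fx$genome, fx$variants[1:20, ]),
               "feasible count range")
})

test_that("manifest tables and expected-variant VCF round trip losslessly", {
  fx <- make_variant_fixture(10, contig_len = 40000L, spacing = 3000L,
                             seed = 207)
  lad <- design_vaf_ladder(fx$genome, fx$variants, levels = 2,
                           per_level = c(5, 5), region_length = 1000)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_manifest(lad$tumor, tsv)
  write_expected_vcf(lad$tumor, vcf,
                     contig_lengths = c(chr1 = nchar(fx$genome[["chr1"]])))
  ev <- read_expected_vcf(vcf)
  back <- read_manifest(tsv, expected_variants = ev)
  expect_equal(back$label, "tumor")
  expect_equal(back$entries$molecule_id, lad$tumor$entries$molecule_id)
  expect_equal(back$entries$fraction, lad$tumor$entries$fraction)
  want <- lad$tumor$expected_variants
  expect_equal(ev$contig, want$contig)
  expect_equal(ev$pos0, want$pos0)
  expect_equal(ev$ref, want$ref)
  expect_equal(ev$alt, want$alt)
  expect_equal(ev$expected_vaf, want$expected_vaf)
  expect_equal(ev$level, want$level)
})

test_that("MSI sequins represent stable and unstable loci", {
  set.seed(208)
  g <- simulate_genome(data.frame(name = "chr5", length = 3000, gc = 0.45),
                       features = data.frame(contig = "chr5", start = 1490,
                                             unit = "A", copies = 25),
                       seed = 208)
  st <- design_msi_sequins(g$genome, "chr5", 1490, 1515, "A", "stable",
                           region_length = 600)
  expect_equal(nrow(st$manifest$entries), 1L)
  expect_equal(st$manifest$entries$fraction, 1)
  un <- design_msi_sequins(g$genome, "chr5", 1490, 1515, "A", "unstable",
                           region_length = 600)
  wt <- un$molecules$msi_wt
  mut <- un$molecules$msi_mut
  expect_equal(substr(wt$bases, wt$locus$start + 1, wt$locus$end),
               strrep("A", 25))
  expect_equal(substr(mut$bases, mut$locus$start + 1, mut$locus$end),
               strrep("A", 24))
  # expected length-distribution mass from manifest arithmetic
  mass <- stats::setNames(un$manifest$entries$fraction,
                          un$manifest$entries$molecule_id)
  expect_equal(unname(mass[c("msi_wt", "msi_mut")]), c(0.5, 0.5))
  expect_error(design_msi_sequins(g$genome, "chr5", 1490, 1515, "AG",
                                  "stable"), "whole number")
  expect_error(design_msi_sequins(g$genome, "chr5", 1480, 1504, "A",
                                  "stable"), "does not equal")
  expect_error(design_msi_sequins(g$genome, "chr5", 1490, 1491, "A",
                                  "stable"), "at least 2")
})

test_that("in-silico PCR finds exact products", {
  p <- insilico_pcr("ATCCAGGCCGTA", "ATCC", "TACG", 50)
  expect_equal(nrow(p), 1L)
  expect_equal(c(p$start, p$end), c(0L, 12L))
  expect_equal(nrow(insilico_pcr("ATCCAGGCCGTA", "GGGG", "TACG", 50)), 0L)
  # tandem-duplicated template yields two forward sites, so >= 2 products
  tandem <- strrep("ATCCAGGCCGTA", 2)
  expect_gte(nrow(insilico_pcr(tandem, "ATCC", "TACG", 50)), 2L)
})

test_that("primer mirroring is the complement-and-role-swap recipe", {
  mp <- mirror_primer_pair("ATGCCGGACCTA", "ATGC", "TAGG", 0, 12)
  expect_equal(mp$forward, "ATCC")
  expect_equal(mp$reverse, "TACG")
  expect_equal(c(mp$amplicon$start, mp$amplicon$end), c(0L, 12L))
  # mirroring twice returns the original pair
  back <- mirror_primer_pair(mirror_sequence("ATGCCGGACCTA"),
                             mp$forward, mp$reverse, 0, 12)
  expect_equal(back$forward, "ATGC")
  expect_equal(back$reverse, "TAGG")
  expect_error(mirror_primer_pair("ATGCCGGACCTA", "ATGC", "AAAA", 0, 12),
               "does not amplify")

  # 100 random designs: mirrored amplicon width equals the original
  set.seed(209)
  for (i in 1:100) {
    tmpl <- rand_dna(200)
    s <- sample(0:100, 1)
    w <- sample(60:90, 1)
    pf <- substr(tmpl, s + 1, s + 20)
    pr <- reverse_complement(substr(tmpl, s + w - 19, s + w))
    res <- tryCatch(mirror_primer_pair(tmpl, pf, pr, s, s + w),
                    error = function(e) NULL)
    if (is.null(res)) next   # rare off-target duplicate match
    expect_equal(res$amplicon$end - res$amplicon$start, w)
  }
})
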