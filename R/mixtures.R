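#' Expected VAF of a dilution-ladder level
#'
#' Level 1 is 100%; each further step halves the frequency:
#' `vaf = 2^-(index - 1)`. Level 5 is 6.25%; level 11 is 2^-10, which rounds
#' to 0.1%.
#'
#' @param index level index (>= 1).
#' @return expected VAF as a fraction.
#' @export
ladder_vaf <- function(index) {
  index <- as.integer(index)
  if (any(index < 1L)) stop("ladder index must be >= 1")
  2^-(index - 1)
}

#' Construct a mixture manifest
#'
#' A manifest lists the synthetic molecules of a mixture with their mass
#' fractions, and the variants the mixture is expected to present with their
#' expected VAFs (derivable from the fractions).
#'
#' @param label one of `"germline"`, `"tumor"`, `"normal"`, `"msi_stable"`,
#'   `"msi_unstable"`.
#' @param entries data.frame with columns `molecule_id`, `fraction`.
#' @param expected_variants data.frame with columns `contig`, `pos0`, `ref`,
#'   `alt`, `expected_vaf`, `genotype` (and optionally `level`), or `NULL`.
#' @param molecules named list of `sequin_molecule` objects (optional but
#'   required for simulation).
#' @return object of class `mixture_manifest`.
#' @export
mixture_manifest <- function(label, entries, expected_variants = NULL,
                             molecules = list()) {
  label <- match.arg(label, c("germline", "tumor", "normal", "msi_stable",
                              "msi_unstable"))
  if (anyDuplicated(entries$molecule_id)) stop("duplicate molecule id")
  if (any(entries$fraction < 0)) stop("negative mass fraction")
  if (abs(sum(entries$fraction) - 1) > 1e-9)
    stop("mass fractions must sum to 1")
  if (length(molecules)) {
    miss <- setdiff(entries$molecule_id, names(molecules))
    if (length(miss)) stop("molecule sequence missing for: ",
                           paste(miss, collapse = ", "))
  }
  structure(list(label = label, entries = entries,
                 expected_variants = expected_variants,
                 molecules = molecules),
            class = "mixture_manifest")
}

#' @export
print.mixture_manifest <- function(x, ...) {
  cat(sprintf("mixture manifest '%s': %d molecules, %s expected variants\n",
              x$label, nrow(x$entries),
              if (is.null(x$expected_variants)) "no"
              else nrow(x$expected_variants)))
  invisible(x)
}

## classify an anchored VCF-style (pos0, ref, alt) record and convert it to
## the region-local allele representation used by apply_alleles()
vcf_record_to_allele <- function(pos0, ref, alt, region_start) {
  off <- pos0 - region_start
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    allele_spec("SNV", off, ref, alt)
  } else if (nchar(ref) > nchar(alt) && substr(ref, 1L, nchar(alt)) == alt) {
    allele_spec("DEL", off + nchar(alt), substr(ref, nchar(alt) + 1L,
                nchar(ref)), "")
  } else if (nchar(alt) > nchar(ref) && substr(alt, 1L, nchar(ref)) == ref) {
    allele_spec("INS", off + nchar(ref) - 1L, "",
                substr(alt, nchar(ref) + 1L, nchar(alt)))
  } else stop("complex allele not supported: ", ref, ">", alt)
}

## shared molecule construction: one region per variant, wild-type and
## variant molecules
build_variant_molecules <- function(genome, variants, region_length,
                                    id_prefix) {
  if (anyDuplicated(variants[c("contig", "pos0")]))
    stop("duplicate variant loci within one molecule set")
  mols <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    region <- extract_region(genome, v$contig, v$pos0, v$pos0 + 1L,
                             length = region_length)
    al <- vcf_record_to_allele(v$pos0, v$ref, v$alt, region$start)
    wt_id <- sprintf("%s_%03d_wt", id_prefix, i)
    var_id <- sprintf("%s_%03d_var", id_prefix, i)
    mols[[wt_id]] <- build_molecule(region, NULL, wt_id)
    mols[[var_id]] <- build_molecule(region, al, var_id)
  }
  mols
}

#' Design a germline genotype mixture
#'
#' Heterozygous variants are represented by paired reference/variant
#' molecules at equal abundance (expected VAF 0.5); homozygous variants by
#' the variant molecule alone (expected VAF 1.0). For example 29 homozygous
#' plus 58 heterozygous variants yield 29 + 2*58 = 145 molecules.
#'
#' @param genome named character vector of forward-space contigs.
#' @param variants data.frame with columns `contig`, `pos0` (0-based), `ref`,
#'   `alt` (anchored VCF-style alleles) and `genotype`
#'   (`"het"`/`"hom"`).
#' @param region_length sequin region length (default 1800 nt).
#' @param id_prefix molecule id prefix.
#' @return a `mixture_manifest` with label `"germline"`.
#' @export
design_genotype_mixture <- function(genome, variants, region_length = 1800L,
                                    id_prefix = "gt") {
  stopifnot(all(variants$genotype %in% c("het", "hom")))
  mols <- build_variant_molecules(genome, variants, region_length, id_prefix)
  n <- nrow(variants)
  rows <- list()
  for (i in seq_len(n)) {
    wt_id <- sprintf("%s_%03d_wt", id_prefix, i)
    var_id <- sprintf("%s_%03d_var", id_prefix, i)
    if (variants$genotype[i] == "het") {
      rows[[i]] <- data.frame(molecule_id = c(wt_id, var_id),
                              fraction = c(0.5, 0.5) / n)
    } else {
      rows[[i]] <- data.frame(molecule_id = var_id, fraction = 1 / n)
    }
  }
  entries <- do.call(rbind, rows)
  keep <- unique(entries$molecule_id)
  ev <- data.frame(contig = variants$contig, pos0 = variants$pos0,
                   ref = variants$ref, alt = variants$alt,
                   expected_vaf = ifelse(variants$genotype == "het", 0.5, 1),
                   genotype = variants$genotype, stringsAsFactors = FALSE)
  mixture_manifest("germline", entries, ev, mols[keep])
}

## level sizes for the ladder: as even as possible within [min, max]
ladder_level_sizes <- function(n, levels, per_level) {
  lo <- per_level[1L]; hi <- per_level[2L]
  if (n < levels * lo || n > levels * hi)
    stop(sprintf("cannot place %d variants on %d levels with %d-%d each; feasible count range is [%d, %d]",
                 n, levels, lo, hi, levels * lo, levels * hi))
  base <- n %/% levels
  sizes <- rep(base, levels)
  rem <- n - base * levels
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes
}

#' Design a staggered VAF dilution ladder ("tumor") and its matched "normal"
#'
#' Variants are placed on a geometric ladder where level `i` has expected VAF
#' `2^-(i-1)` (100% down to ~0.1% over 11 levels), assigned round-robin
#' subject to per-level size bounds. Each variant contributes a variant
#' molecule at `vaf/n` mass fraction and, below 100% VAF, a wild-type
#' molecule making up the rest of its `1/n` share. The matched normal
#' mixture contains only the wild-type molecule for every site.
#'
#' @param genome named character vector of forward-space contigs.
#' @param variants data.frame as in [design_genotype_mixture()] (the
#'   `genotype` column is not required).
#' @param levels number of ladder levels (default 11).
#' @param per_level allowed variants per level, length-2 integer (default
#'   7..9).
#' @param region_length sequin region length (default 1800 nt).
#' @param id_prefix molecule id prefix.
#' @return list with `mixture_manifest` components `tumor` and `normal`, and
#'   `assignment` (data.frame variant index -> level).
#' @export
design_vaf_ladder <- function(genome, variants, levels = 11L,
                              per_level = c(7L, 9L), region_length = 1800L,
                              id_prefix = "som") {
  n <- nrow(variants)
  sizes <- ladder_level_sizes(n, levels, per_level)
  ## round-robin with per-level capacity
  lev <- integer(n)
  fill <- integer(levels)
  l <- 1L
  for (i in seq_len(n)) {
    while (fill[l] >= sizes[l]) l <- l %% levels + 1L
    lev[i] <- l
    fill[l] <- fill[l] + 1L
    l <- l %% levels + 1L
  }
  mols <- build_variant_molecules(genome, variants, region_length, id_prefix)
  vafs <- ladder_vaf(lev)
  rows <- list(); nrows <- list()
  for (i in seq_len(n)) {
    wt_id <- sprintf("%s_%03d_wt", id_prefix, i)
    var_id <- sprintf("%s_%03d_var", id_prefix, i)
    r <- data.frame(molecule_id = var_id, fraction = vafs[i] / n)
    if (vafs[i] < 1)
      r <- rbind(r, data.frame(molecule_id = wt_id,
                               fraction = (1 - vafs[i]) / n))
    rows[[i]] <- r
    nrows[[i]] <- data.frame(molecule_id = wt_id, fraction = 1 / n)
  }
  tumor_entries <- do.call(rbind, rows)
  normal_entries <- do.call(rbind, nrows)
  ev <- data.frame(contig = variants$contig, pos0 = variants$pos0,
                   ref = variants$ref, alt = variants$alt,
                   expected_vaf = vafs, genotype = "somatic", level = lev,
                   stringsAsFactors = FALSE)
  tumor <- mixture_manifest("tumor", tumor_entries, ev,
                            mols[unique(tumor_entries$molecule_id)])
  normal <- mixture_manifest("normal", normal_entries, NULL,
                             mols[unique(normal_entries$molecule_id)])
  list(tumor = tumor, normal = normal,
       assignment = data.frame(variant = seq_len(n), level = lev,
                               expected_vaf = vafs))
}

#' Design microsatellite-instability sequins
#'
#' For a microsatellite locus (reference sequence = `unit` repeated
#' `ref_copies` times) the wild-type sequin alone represents a stable
#' microsatellite; the unstable mixture combines the wild-type with a mutant
#' differing by the insertion or deletion of a single repeat unit.
#'
#' @param genome named character vector of forward-space contigs.
#' @param contig contig carrying the locus.
#' @param locus_start,locus_end locus interval, 0-based half-open; the
#'   reference there must be an exact whole-copy repeat of `unit`.
#' @param unit repeat unit (1-6 nt).
#' @param mode `"stable"` or `"unstable"`.
#' @param mutant `"deletion"` (default) or `"insertion"`: the single-unit
#'   change carried by the mutant molecule.
#' @param mutant_fraction mass fraction of the mutant in the unstable
#'   mixture (default 0.5; the mixing ratio is a design parameter).
#' @param region_length sequin region length (default 1800 nt).
#' @param id_prefix molecule id prefix.
#' @return list with `molecules` (list of `sequin_molecule`, each annotated
#'   with a `locus` element giving the repeat interval in the molecule's own
#'   chiral coordinates and its `ref_len` versus the assay reference),
#'   `manifest` (a `mixture_manifest`) and `locus_spec`.
#' @export
design_msi_sequins <- function(genome, contig, locus_start, locus_end, unit,
                               mode = c("stable", "unstable"),
                               mutant = c("deletion", "insertion"),
                               mutant_fraction = 0.5, region_length = 1800L,
                               id_prefix = "msi") {
  mode <- match.arg(mode)
  mutant <- match.arg(mutant)
  u <- nchar(unit)
  width <- locus_end - locus_start
  if (width %% u != 0L) stop("locus width is not a whole number of units")
  ref_copies <- width %/% u
  if (ref_copies < 2L) stop("locus must hold at least 2 repeat copies")
  locus_seq <- substr(genome[[contig]], locus_start + 1L, locus_end)
  if (locus_seq != strrep(unit, ref_copies))
    stop("reference at locus does not equal unit^ref_copies")
  region <- extract_region(genome, contig, locus_start, locus_end,
                           length = region_length)
  loff <- locus_start - region$start   # locus start within region
  wt_id <- paste0(id_prefix, "_wt")
  mut_id <- paste0(id_prefix, "_mut")
  wt <- build_molecule(region, NULL, wt_id)
  ## locus interval within the chiral molecule: mirror the region-local
  ## interval with the molecule's own length
  add_locus <- function(mol, fwd_start, fwd_end) {
    n <- nchar(mol$bases)
    m <- map_interval(fwd_start, fwd_end, n)
    mol$locus <- list(start = m$start, end = m$end, unit = unit,
                      ref_len = width)
    mol
  }
  wt <- add_locus(wt, loff, loff + width)
  molecules <- list()
  molecules[[wt_id]] <- wt
  if (mode == "stable") {
    manifest <- mixture_manifest(
      "msi_stable",
      data.frame(molecule_id = wt_id, fraction = 1),
      molecules = molecules)
  } else {
    if (mutant == "deletion") {
      al <- allele_spec("DEL", loff + width - u, unit, "")
      mut <- build_molecule(region, al, mut_id)
      mut <- add_locus(mut, loff, loff + width - u)
    } else {
      al <- allele_spec("INS", loff + width - 1L, "", unit)
      mut <- build_molecule(region, al, mut_id)
      mut <- add_locus(mut, loff, loff + width + u)
    }
    molecules[[mut_id]] <- mut
    manifest <- mixture_manifest(
      "msi_unstable",
      data.frame(molecule_id = c(wt_id, mut_id),
                 fraction = c(1 - mutant_fraction, mutant_fraction)),
      molecules = molecules)
  }
  list(molecules = molecules, manifest = manifest,
       locus_spec = list(contig = contig, start = locus_start,
                         end = locus_end, unit = unit,
                         ref_copies = ref_copies))
}

#' Write / read a mixture manifest abundance table (TSV)
#'
#' Columns: `molecule_id`, `fraction`, `label`. The round trip is lossless
#' for the abundance table; molecule sequences travel in FASTA and expected
#' variants in VCF ([write_expected_vcf()]).
#'
#' @param manifest a `mixture_manifest`.
#' @param path file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns a `mixture_manifest` (without molecule sequences).
#' @export
write_manifest <- function(manifest, path) {
  d <- manifest$entries
  d$label <- manifest$label
  utils::write.table(format(d, digits = 17), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param expected_variants optional data.frame to attach (e.g. read back
#'   with [read_expected_vcf()]).
#' @export
read_manifest <- function(path, expected_variants = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "numeric", "character"))
  mixture_manifest(d$label[1L],
                   data.frame(molecule_id = trimws(d$molecule_id),
                              fraction = d$fraction),
                   expected_variants = expected_variants)
}

#' Write expected variants to VCF (forward coordinates)
#'
#' INFO fields: `VAF` (expected VAF), `GT` (genotype class) and, when
#' present, `LEVEL` (ladder level).
#'
#' @param manifest a `mixture_manifest` with `expected_variants`.
#' @param path output VCF path.
#' @param contig_lengths optional named lengths for `##contig` headers.
#' @return `path` invisibly.
#' @export
write_expected_vcf <- function(manifest, path, contig_lengths = NULL) {
  ev <- manifest$expected_variants
  if (is.null(ev)) stop("manifest has no expected variants")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=chiralseq",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Expected variant allele frequency\">",
           "##INFO=<ID=GT,Number=1,Type=String,Description=\"Genotype class\">",
           "##INFO=<ID=LEVEL,Number=1,Type=Integer,Description=\"Dilution ladder level\">")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("VAF=%.10g;GT=%s", ev$expected_vaf, ev$genotype)
  if (!is.null(ev$level)) info <- paste0(info, ";LEVEL=", ev$level)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  ev$contig, ev$pos0 + 1L, ev$ref, ev$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an expected-variant VCF back into a data.frame
#'
#' @param path VCF path (plain text).
#' @return data.frame with columns `contig`, `pos0`, `ref`, `alt`,
#'   `expected_vaf`, `genotype` and `level` (NA when absent).
#' @export
read_expected_vcf <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln))
    return(data.frame(contig = character(), pos0 = integer(),
                      ref = character(), alt = character(),
                      expected_vaf = numeric(), genotype = character(),
                      level = integer(), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    if (!length(m)) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  info <- f[, 8L]
  vaf <- suppressWarnings(as.numeric(vapply(info, function(x)
    info_get(x, "VAF"), character(1L))))
  gt <- vapply(info, function(x) info_get(x, "GT"), character(1L))
  lv <- suppressWarnings(as.integer(vapply(info, function(x)
    info_get(x, "LEVEL"), character(1L))))
  data.frame(contig = f[, 1L], pos0 = as.integer(f[, 2L]) - 1L,
             ref = f[, 4L], alt = f[, 5L], expected_vaf = vaf,
             genotype = unname(gt), level = lv, stringsAsFactors = FALSE)
}
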