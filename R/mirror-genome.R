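#' Build a mirrored (chiral) copy of a genome and a combined index
#'
#' For every contig `x` a twin `x<suffix>` is added whose bases are the bases
#' of `x` in reverse order (no complementation). Reads derived from chiral
#' molecules align to the mirrored contigs of a combined index, so human and
#' spike-in reads can be partitioned by contig namespace alone.
#'
#' @param genome named character vector of contig sequences (forward space).
#' @param suffix suffix appended to forward contig names to form mirrored
#'   contig names (default `"_rev"`).
#' @return list with components
#'   * `combined`: named character vector holding forward contigs followed by
#'     their mirrored twins;
#'   * `contig_table`: data.frame with columns `name`, `length`, `namespace`
#'     (`"fwd"`/`"rev"`) and `partner` (the twin contig's name).
#' @examples
#' build_mirrored_genome(c(chrT = "ACGT"))$combined
#' @export
build_mirrored_genome <- function(genome, suffix = "_rev") {
  check_dna(genome, "genome contig")
  nm <- names(genome)
  if (is.null(nm) || anyDuplicated(nm)) stop("contig names must be unique")
  if (!nzchar(suffix)) stop("suffix must be non-empty")
  rev_nm <- paste0(nm, suffix)
  clash <- intersect(rev_nm, nm)
  if (length(clash))
    stop("mirrored contig name collides with an input contig: ",
         paste(clash, collapse = ", "))
  rev_seq <- mirror_sequence(genome)
  names(rev_seq) <- rev_nm
  combined <- c(genome, rev_seq)
  contig_table <- data.frame(
    name = c(nm, rev_nm),
    length = nchar(combined),
    namespace = rep(c("fwd", "rev"), each = length(nm)),
    partner = c(rev_nm, nm),
    stringsAsFactors = FALSE
  )
  rownames(contig_table) <- NULL
  list(combined = combined, contig_table = contig_table)
}

#' Write / read the combined-index contig table
#'
#' Plain TSV with columns `name`, `length`, `namespace`, `partner`.
#'
#' @param contig_table data.frame as produced by [build_mirrored_genome()].
#' @param path file path.
#' @return `write_contig_table()` returns `path` invisibly;
#'   `read_contig_table()` returns the data.frame.
#' @export
write_contig_table <- function(contig_table, path) {
  utils::write.table(contig_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contig_table
#' @export
read_contig_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "integer", "character",
                                   "character"))
}

## internal: look up contig length / partner, with a clear error
contig_info <- function(contig_table, contig) {
  i <- match(contig, contig_table$name)
  if (anyNA(i)) stop("unknown contig: ",
                     paste(unique(contig[is.na(i)]), collapse = ", "))
  contig_table[i, , drop = FALSE]
}

#' Map an interval between mirrored coordinate systems
#'
#' A half-open 0-based interval `[s, e)` on a contig of length `L` maps to
#' `[L - e, L - s)` on its mirrored twin. The map is a width-preserving
#' involution.
#'
#' @param start,end integer vectors, 0-based half-open.
#' @param L contig length(s).
#' @return data.frame with columns `start`, `end` in the twin's coordinates.
#' @examples
#' map_interval(0, 4, 12)  # [8, 12)
#' @export
map_interval <- function(start, end, L) {
  if (any(start < 0 | end < start | end > L))
    stop("interval out of bounds: need 0 <= start <= end <= L")
  data.frame(start = L - end, end = L - start)
}

#' Map a single reference position between mirrored coordinates
#'
#' Position `p` (0-based) maps to `L - 1 - p`.
#'
#' @param p 0-based position(s).
#' @param L contig length(s).
#' @return mapped position(s).
#' @export
map_position <- function(p, L) {
  if (any(p < 0 | p >= L)) stop("position out of bounds")
  L - 1L - p
}

#' Mirror a table of intervals using the combined-index contig table
#'
#' @param iv data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open).
#' @param contig_table contig table from [build_mirrored_genome()].
#' @return data.frame with `contig` replaced by the twin contig and
#'   coordinates mapped into its space.
#' @export
mirror_intervals <- function(iv, contig_table) {
  info <- contig_info(contig_table, iv$contig)
  m <- map_interval(iv$start, iv$end, info$length)
  out <- iv
  out$contig <- info$partner
  out$start <- m$start
  out$end <- m$end
  out
}
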