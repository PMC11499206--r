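#' Genomic intervals
#'
#' All locus and gene positions in the package are 1-based inclusive
#' intervals on a named sequence with an explicit strand, mirroring the
#' coordinate convention of public locus tables ("complement" = REV).
#' `genomic_interval()` builds a one-row tibble; most package functions
#' carry intervals as plain `seq_id`/`start`/`end`/`strand` columns.
#'
#' @param seq_id sequence (chromosome/contig) identifier.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"FWD"` or `"REV"`.
#'
#' @return A tibble with columns `seq_id`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr14", 86452632, 87593842, "REV")
#' @export
genomic_interval <- function(seq_id, start, end, strand = "FWD") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 1)) abort("interval start must be >= 1")
  if (any(end < start)) abort("interval end must be >= start")
  if (!all(strand %in% c("FWD", "REV"))) abort("strand must be FWD or REV")
  tibble(seq_id = as.character(seq_id), start = start, end = end,
         strand = strand)
}

#' Interval length (bp)
#'
#' Length of a 1-based inclusive interval: `end - start + 1`. Reproduces the
#' published "Sequence length (bp)" of a locus from its printed positions.
#'
#' @param start,end 1-based inclusive positions (vectorised), or `start` may
#'   be a tibble with `start`/`end` columns.
#' @return Numeric vector of lengths.
#' @examples
#' interval_length(86452632, 87593842)  # 1141211
#' @export
interval_length <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  end - start + 1
}

# Map a chromosome-frame position into the locus frame (1 = 5' end of the
# locus) given the locus interval and orientation, and back.
locus_pos_from_chrom <- function(pos, locus_start, locus_end, orientation) {
  if (orientation == "FWD") pos - locus_start + 1 else locus_end - pos + 1
}

chrom_pos_from_locus <- function(pos, locus_start, locus_end, orientation) {
  if (orientation == "FWD") locus_start + pos - 1 else locus_end - pos + 1
}

# Convert a locus-frame interval (start <= end in locus coordinates) to a
# chromosome-frame interval; REV loci flip ends.
chrom_interval_from_locus <- function(start, end, locus_start, locus_end,
                                      orientation) {
  a <- chrom_pos_from_locus(start, locus_start, locus_end, orientation)
  b <- chrom_pos_from_locus(end, locus_start, locus_end, orientation)
  list(start = pmin(a, b), end = pmax(a, b))
}

revcomp_chr <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}
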