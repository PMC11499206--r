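#' Recombination signal sequence (RSS) model
#'
#' V, D and J genes are flanked by conserved recombination signals: a 7-mer
#' (consensus `CACAGTG`) and a 9-mer (consensus `ACAAAAACC`) separated by a
#' spacer of nominally 12 or 23 bp. [score_rss()] scores candidate motifs by
#' weighted consensus mismatches: the first three heptamer positions (the
#' `CAC` critical for recombination) weigh double, the nonamer uniformly,
#' and a spacer one base off nominal costs a flat 0.1 penalty:
#'
#' `score = 1 - (hept_mm/2 + nona_mm/2) - 0.1 * |spacer - nominal|`
#'
#' where `hept_mm` is the weight fraction of mismatched heptamer positions
#' (weights 2,2,2,1,1,1,1) and `nona_mm` the fraction of mismatched nonamer
#' positions. The score is 1 exactly when heptamer, nonamer and spacer are
#' all canonical, and is clamped at 0.
#'
#' Motifs on the 5' side of a gene (D 5' RSS, J RSS) lie on the reverse
#' strand of the reading direction; their genomic window is
#' reverse-complemented before scoring so that the one consensus applies to
#' both sides.
#'
#' @name rss
NULL

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"
RSS_HEPT_WEIGHTS <- c(2, 2, 2, 1, 1, 1, 1)

rss_consensus_score <- function(heptamer, spacer_length, nonamer, nominal) {
  h <- strsplit(heptamer, "")[[1]]
  n <- strsplit(nonamer, "")[[1]]
  if (length(h) != 7 || length(n) != 9) return(0)
  hc <- strsplit(RSS_HEPTAMER, "")[[1]]
  nc <- strsplit(RSS_NONAMER, "")[[1]]
  hept_mm <- sum(RSS_HEPT_WEIGHTS * (h != hc)) / sum(RSS_HEPT_WEIGHTS)
  nona_mm <- sum(n != nc) / 9
  spacer_pen <- 0.1 * abs(spacer_length - nominal)
  max(0, 1 - (hept_mm + nona_mm) / 2 - spacer_pen)
}

#' Score the best RSS motif near an anchor position
#'
#' Searches heptamer start offsets within +/- 10 bp of `anchor` and spacer
#' lengths within one base of the nominal class, on the appropriate strand
#' for `side`, and returns the best-scoring motif.
#'
#' For `side = "three_prime"` the motif reads heptamer-spacer-nonamer
#' forward from `anchor` (the expected heptamer start, usually one past the
#' gene end). For `side = "five_prime"` `anchor` is the expected heptamer
#' *end* (usually one before the gene start) and the motif is read on the
#' reverse complement.
#'
#' @param locus_seq locus nucleotide sequence (character or DNAString), 5'
#'   to 3' in the reading orientation of the gene.
#' @param anchor expected heptamer start (3' side) or end (5' side).
#' @param side `"five_prime"` or `"three_prime"` of the gene.
#' @param expected_class nominal spacer class, `12` or `23`.
#' @param config see [igloci_config()]; `rss_accept` sets the acceptance
#'   threshold reported in `accepted`.
#' @return A one-row tibble: `heptamer`, `spacer_length`, `nonamer`, `side`,
#'   `class`, `score`, `start`, `end` (motif envelope, given orientation),
#'   `accepted`. Score 0 with `accepted = FALSE` when no window fits in the
#'   sequence.
#' @export
score_rss <- function(locus_seq, anchor, side = c("three_prime", "five_prime"),
                      expected_class = 23, config = igloci_config()) {
  side <- match.arg(side)
  seq_chr <- as.character(locus_seq)
  L <- base::nchar(seq_chr)
  stopifnot(expected_class %in% c(12, 23))
  best <- NULL
  for (off in -10:10) {
    for (spacer in expected_class + (-1:1)) {
      tot <- 7 + spacer + 9
      if (side == "three_prime") {
        s <- anchor + off
        e <- s + tot - 1
        if (s < 1 || e > L) next
        win <- substr(seq_chr, s, e)
      } else {
        e <- anchor + off
        s <- e - tot + 1
        if (s < 1 || e > L) next
        win <- revcomp_chr(substr(seq_chr, s, e))
      }
      hept <- substr(win, 1, 7)
      nona <- substr(win, 7 + spacer + 1, tot)
      if (grepl("N", hept) || grepl("N", nona)) next
      sc <- rss_consensus_score(hept, spacer, nona, expected_class)
      cand <- list(heptamer = hept, spacer = spacer, nonamer = nona,
                   score = sc, start = s, end = e, off = off)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && abs(off) < abs(best$off))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(tibble(heptamer = NA_character_, spacer_length = NA_integer_,
                  nonamer = NA_character_, side = side,
                  class = as.integer(expected_class), score = 0,
                  start = NA_real_, end = NA_real_, accepted = FALSE))
  }
  tibble(heptamer = best$heptamer, spacer_length = as.integer(best$spacer),
         nonamer = best$nonamer, side = side,
         class = as.integer(expected_class), score = best$score,
         start = best$start, end = best$end,
         accepted = best$score >= config$rss_accept)
}

# canonical RSS construction helpers (used by the synthetic generator)
rss_canonical <- function(class, spacer_seq = NULL) {
  spacer_len <- as.integer(class)
  if (is.null(spacer_seq)) {
    spacer_seq <- paste(rep(c("T", "G"), length.out = spacer_len), collapse = "")
  }
  stopifnot(base::nchar(spacer_seq) == spacer_len)
  paste0(RSS_HEPTAMER, spacer_seq, RSS_NONAMER)
}
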