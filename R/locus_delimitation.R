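#' Localize an IG locus on an assembly
#'
#' Scans every assembly sequence for similarity to the locus's reference
#' gene set on both strands, and returns the envelope of the densest
#' cluster of accepted hits (identity >= the configured threshold, merged
#' when separated by less than the cluster gap). Locus orientation is the
#' majority strand of the hits weighted by aligned length. A second
#' cluster within 10% of the best cluster's weight is an ambiguity error;
#' no acceptable hit raises a "locus not found" condition (class
#' `igloci_locus_not_found`).
#'
#' @param assembly a named [Biostrings::DNAStringSet] ([read_assembly()]).
#' @param refs the reference set, filtered internally to `locus`.
#' @param locus locus id (`"IGH"`, `"IGK"`, `"IGL"`).
#' @param config see [igloci_config()].
#' @return A list of class `ig_locus_region`: `locus`, `seq_id`, `start`,
#'   `end` (chromosome envelope of hits), `orientation` (`"FWD"`/`"REV"`),
#'   `n_hits`, `weight`.
#' @export
localize_locus <- function(assembly, refs, locus, config = igloci_config()) {
  lrefs <- refs[refs$locus == locus, ]
  if (!nrow(lrefs)) abort(paste0("no reference alleles for locus ", locus))
  clusters <- list()
  reps <- representative_refs(lrefs)
  for (sid in names(assembly)) {
    seq_chr <- toupper(as.character(assembly[[sid]]))
    L <- base::nchar(seq_chr)
    frames <- list(sense = seq_chr, antisense = revcomp_chr(seq_chr))
    cands <- scan_seed_candidates(frames, reps)
    if (!nrow(cands)) next
    # seed windows in chromosome-forward coordinates
    hits <- cands |>
      mutate(start = ifelse(.data$strand == "sense", .data$win_s,
                            L - .data$win_e + 1),
             end = ifelse(.data$strand == "sense", .data$win_e,
                          L - .data$win_s + 1)) |>
      arrange(.data$start)
    grp <- cumsum(c(1, diff(hits$start) > config$cluster_gap))
    for (g in unique(grp)) {
      h <- hits[grp == g, ]
      w <- sum(h$seed_n)
      # a real locus carries dense seed support; isolated spurious matches
      # (a short D region at the mismatch ceiling) never reach this weight
      if (w < 5) next
      fwd_w <- sum(h$seed_n[h$strand == "sense"])
      rev_w <- sum(h$seed_n[h$strand == "antisense"])
      clusters[[length(clusters) + 1L]] <- list(
        seq_id = sid, start = min(h$start), end = max(h$end), weight = w,
        n_hits = nrow(h),
        orientation = if (fwd_w >= rev_w) "FWD" else "REV")
    }
  }
  if (!length(clusters)) {
    abort(paste0("locus not found: no ", locus, " reference hit in assembly"),
          class = "igloci_locus_not_found")
  }
  weights <- map_dbl(clusters, "weight")
  ord <- order(-weights)
  if (length(clusters) > 1 && weights[ord[2]] >= 0.9 * weights[ord[1]]) {
    c1 <- clusters[[ord[1]]]; c2 <- clusters[[ord[2]]]
    abort(sprintf(
      "ambiguous locus localization for %s: %s:%d-%d (weight %.0f) vs %s:%d-%d (weight %.0f)",
      locus, c1$seq_id, c1$start, c1$end, c1$weight,
      c2$seq_id, c2$start, c2$end, c2$weight),
      class = "igloci_locus_ambiguous")
  }
  best <- clusters[[ord[1]]]
  structure(list(locus = locus, seq_id = best$seq_id, start = best$start,
                 end = best$end, orientation = best$orientation,
                 n_hits = best$n_hits, weight = best$weight),
            class = "ig_locus_region")
}

#' Find locus borne genes flanking a localized region
#'
#' Searches each borne probe within the configured window outside the gene
#' envelope, on the side it belongs to in locus orientation. A probe is
#' found when it aligns at or above the identity threshold; a borne falling
#' inside the gene envelope is reported as absent with a warning.
#'
#' @param assembly named DNAStringSet.
#' @param region an `ig_locus_region` from [localize_locus()].
#' @param bornes tibble of [borne_definition()] rows for the locus.
#' @param config see [igloci_config()].
#' @return A named list (`five_prime`, `three_prime`) of borne hits
#'   (`start`, `end`, `identity`, chromosome coordinates); missing sides
#'   are absent from the list.
#' @export
find_bornes <- function(assembly, region, bornes, config = igloci_config()) {
  out <- list()
  if (is.null(bornes) || !nrow(bornes)) return(out)
  chr <- as.character(assembly[[region$seq_id]])
  L <- base::nchar(chr)
  for (i in seq_len(nrow(bornes))) {
    side <- bornes$side[i]
    # chromosome side: locus 5' is at low coordinates iff orientation FWD
    low_side <- (side == "five_prime") == (region$orientation == "FWD")
    if (low_side) {
      ws <- max(1L, region$start - config$borne_window)
      we <- region$start - 1L
    } else {
      ws <- region$end + 1L
      we <- min(L, region$end + config$borne_window)
    }
    if (we < ws) next
    win <- substr(chr, ws, we)
    probe <- bornes$probe_sequence[i]
    hit <- best_probe_hit(probe, win)
    if (is.null(hit)) next
    if (hit$identity < config$identity || hit$coverage < 0.5) next
    out[[side]] <- list(start = ws + hit$start - 1L, end = ws + hit$end - 1L,
                        identity = hit$identity,
                        gene_symbol = bornes$gene_symbol[i])
  }
  # a borne inside the envelope would have been clipped by the window; also
  # guard against probes matching the envelope itself
  for (side in names(out)) {
    b <- out[[side]]
    if (b$start <= region$end && b$end >= region$start) {
      warn(paste0("borne ", b$gene_symbol, " found inside the gene envelope; treated as absent"))
      out[[side]] <- NULL
    }
  }
  out
}

# seeded best local hit of a probe (either strand) in a window
best_probe_hit <- function(probe, window_chr) {
  best <- NULL
  for (p in c(probe, revcomp_chr(probe))) {
    est <- seed_region_hits(p, DNAString(window_chr))
    for (cl in cluster_positions(est, 1000L)) {
      s <- max(1L, min(cl) - 100L)
      e <- min(base::nchar(window_chr), max(cl) + base::nchar(p) + 100L)
      pr <- project_region(p, substr(window_chr, s, e), s - 1L)
      if (is.null(pr)) next
      if (is.null(best) || pr$identity * pr$coverage > best$identity * best$coverage) {
        best <- pr
      }
    }
  }
  best
}

#' Delimit a locus around its terminal genes
#'
#' IGH: 10,000 bp 5' of the first gene to 11,000 bp 3' of the last gene.
#' IGK/IGL, each side independently: when a borne gene lies within
#' 10,000 bp of the terminal gene, the boundary is the first base proximal
#' to the borne (the borne stays outside the locus); otherwise the fixed
#' 10,000 bp flank applies. Boundaries are clamped to the sequence.
#'
#' @param region an `ig_locus_region` (supplies orientation and locus id).
#' @param bornes borne hits from [find_bornes()] (may be empty).
#' @param first_gene,last_gene chromosome intervals (tibbles with
#'   `start`/`end`) of the 5'-most and 3'-most genes in locus order.
#' @param seq_length length of the chromosome sequence (for clamping).
#' @param config see [igloci_config()].
#' @return A list: `start`, `end` (chromosome interval), `rule_5`,
#'   `rule_3` (`"borne"` or `"fixed_flank"`).
#' @export
delimit_locus <- function(region, bornes, first_gene, last_gene, seq_length,
                          config = igloci_config()) {
  o <- region$orientation
  fg5 <- if (o == "FWD") first_gene$start else first_gene$end
  lg3 <- if (o == "FWD") last_gene$end else last_gene$start
  # locus-order sanity: first gene must be 5' of last gene
  if ((o == "FWD" && first_gene$start > last_gene$end) ||
      (o == "REV" && first_gene$end < last_gene$start)) {
    abort("first_gene lies 3' of last_gene in locus order")
  }
  flank3 <- if (region$locus == "IGH") config$flank_3_igh else config$flank
  side_boundary <- function(side, gene_edge, flank) {
    borne <- bornes[[side]]
    outward <- (side == "five_prime") == (o == "FWD")  # TRUE: decreasing coords
    if (!is.null(borne) && region$locus != "IGH") {
      prox_edge <- if (outward) borne$end else borne$start
      dist <- abs(gene_edge - prox_edge) - 1
      if (dist <= config$flank) {
        b <- if (outward) prox_edge + 1 else prox_edge - 1
        return(list(pos = b, rule = "borne"))
      }
    }
    b <- if (outward) gene_edge - flank else gene_edge + flank
    list(pos = b, rule = "fixed_flank")
  }
  b5 <- side_boundary("five_prime", fg5, config$flank_5)
  b3 <- side_boundary("three_prime", lg3, flank3)
  start <- max(1, min(b5$pos, b3$pos))
  end <- min(seq_length, max(b5$pos, b3$pos))
  list(start = start, end = end, rule_5 = b5$rule, rule_3 = b3$rule)
}

#' Extract a locus sequence in 5' to 3' locus orientation
#'
#' @param assembly named DNAStringSet.
#' @param seq_id,start,end chromosome interval (1-based inclusive).
#' @param orientation `"FWD"` or `"REV"`; REV loci are returned
#'   reverse-complemented.
#' @return The locus nucleotide sequence as a character string of length
#'   `end - start + 1`.
#' @export
extract_locus_sequence <- function(assembly, seq_id, start, end,
                                   orientation = "FWD") {
  if (!seq_id %in% names(assembly)) abort(paste0("no sequence ", seq_id))
  L <- base::nchar(as.character(assembly[[seq_id]]))
  if (start < 1 || end > L || end < start) {
    abort(sprintf("interval %d-%d out of bounds for %s (length %d)",
                  start, end, seq_id, L))
  }
  s <- substr(as.character(assembly[[seq_id]]), start, end)
  if (orientation == "REV") revcomp_chr(s) else s
}
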