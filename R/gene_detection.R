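#' @include rss.R
NULL

# Alignment scoring used for all nucleotide local alignments (BLAST-like).
align_local <- function(pattern_chr, subject_chr) {
  pairwiseAlignment(DNAString(pattern_chr), DNAString(subject_chr),
                    type = "local",
                    substitutionMatrix =
                      Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
                    gapOpening = 5, gapExtension = 2)
}

align_global <- function(pattern_chr, subject_chr) {
  pairwiseAlignment(DNAString(pattern_chr), DNAString(subject_chr),
                    type = "global",
                    substitutionMatrix =
                      Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
                    gapOpening = 5, gapExtension = 2)
}

# Project one reference region into a subject window. The pattern
# (reference region) is aligned globally, the window locally
# ("global-local"), so the projected boundaries are exact even when the
# target carries internal indels or terminal substitutions (a plain local
# alignment would clip them). Gap costs are kept low so an internal indel
# is taken as a gap rather than sliding the boundary into flanking
# sequence. Identity is measured over aligned columns only (PID2) so an
# indel does not dilute it; coverage is the fraction of reference bases
# with an aligned target base.
project_region <- function(region_chr, window_chr, window_offset = 0L) {
  if (base::nchar(window_chr) < base::nchar(region_chr)) return(NULL)
  aln <- pairwiseAlignment(DNAString(region_chr), DNAString(window_chr),
                           type = "global-local",
                           substitutionMatrix =
                             Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
                           gapOpening = 10, gapExtension = 0.5)
  sr <- aln@subject@range
  rl <- base::nchar(region_chr)
  unaligned_ref <- sum(width(Biostrings::insertion(aln)[[1]]))
  list(start = window_offset + start(sr), end = window_offset + end(sr),
       identity = Biostrings::pid(aln, type = "PID2") / 100,
       coverage = (rl - unaligned_ref) / rl,
       aligned_len = rl - unaligned_ref,
       score = Biostrings::score(aln))
}

seed_starts <- function(len, k, step) {
  if (len < k) return(integer(0))
  unique(c(seq(1L, len - k + 1L, by = step), len - k + 1L))
}

SEED_K <- 14L

# Hash index of all k-mer positions of a subject sequence, for O(1) exact
# seed lookup.
build_kmer_index <- function(subject_chr, k = SEED_K) {
  L <- base::nchar(subject_chr)
  if (L < k) return(new.env(parent = emptyenv()))
  kmers <- substring(subject_chr, 1:(L - k + 1L), k:L)
  env <- new.env(parent = emptyenv(), size = length(kmers))
  pos_by_kmer <- split(seq_along(kmers), kmers)
  list2env(pos_by_kmer, envir = env)
  env
}

# Exact k-mer seed matching of one reference region against a subject;
# returns estimated region start positions in the subject. Short regions
# (D) fall back to a full-pattern mismatch scan.
seed_region_hits <- function(region_chr, subject_dna, index = NULL,
                             k = SEED_K, step = 12L, short_mm_frac = 0.25) {
  len <- base::nchar(region_chr)
  if (len < 40) {
    hits <- matchPattern(DNAString(region_chr), subject_dna,
                         max.mismatch = floor(short_mm_frac * len))
    return(start(hits))
  }
  est <- integer(0)
  for (p in seed_starts(len, k, step)) {
    seed <- substr(region_chr, p, p + k - 1L)
    if (grepl("N", seed)) next
    if (!is.null(index)) {
      m <- index[[seed]]
      if (!is.null(m)) est <- c(est, m - (p - 1L))
    } else {
      m <- matchPattern(DNAString(seed), subject_dna)
      if (length(m)) est <- c(est, start(m) - (p - 1L))
    }
  }
  sort(est)
}

cluster_positions <- function(pos, gap) {
  if (!length(pos)) return(list())
  pos <- sort(pos)
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i) pos[(brk[i] + 1L):brk[i + 1L]])
}

# representative allele per gene (lowest allele number)
representative_refs <- function(refs) {
  refs |> group_by(.data$gene_name) |> slice_min(.data$allele, n = 1) |> ungroup()
}

#' Scan a locus sequence for candidate V/D/J/C genes
#'
#' Seeded similarity search of every reference region (V: leader and V
#' exon; D/J: the region; C: each exon) on both strands. Exact k-mer seeds
#' locate candidate windows; each region is then locally aligned into its
#' window and the projections are kept when overall identity and coverage
#' pass the configured thresholds. Overlapping hits to the same reference
#' gene are merged keeping the best identity.
#'
#' @param locus_seq locus nucleotide sequence (character or DNAString),
#'   5' to 3' in locus orientation.
#' @param refs an `ig_reference_set` (see [read_reference_set()]).
#' @param config see [igloci_config()].
#' @return A tibble of raw hits: `gene_name`, `gene_type`, `strand`
#'   (`sense`/`antisense`), `start`/`end` (sense locus coordinates),
#'   `frame_start`/`frame_end` (coordinates on the strand the hit was found
#'   on), `identity`, `coverage`, `regions` (list-column of per-region
#'   projections in frame coordinates).
#' @export
scan_candidates <- function(locus_seq, refs, config = igloci_config()) {
  seq_chr <- toupper(as.character(locus_seq))
  L <- base::nchar(seq_chr)
  frames <- list(sense = seq_chr, antisense = revcomp_chr(seq_chr))
  reps <- representative_refs(refs)
  cands <- scan_seed_candidates(frames, reps)
  # Competing references at one genomic location: only the best-identity
  # hit survives overlap resolution, and seed support tracks identity, so
  # align only the few best-supported candidates per location.
  if (nrow(cands)) {
    cands <- cands |>
      group_by(.data$strand, .data$gene_type) |>
      group_modify(function(d, k) {
        d <- arrange(d, .data$win_s)
        d$.grp <- cumsum(c(1, diff(d$win_s) > 500))
        d |>
          group_by(.data$.grp) |>
          slice_max(.data$seed_n, n = 4L, with_ties = FALSE) |>
          ungroup() |>
          select(-".grp")
      }) |>
      ungroup()
  }
  out <- list()
  for (ci in seq_len(nrow(cands))) {
    strand <- cands$strand[ci]
    i <- cands$ref_i[ci]
    tp <- cands$gene_type[ci]
    fchr <- frames[[strand]]
    regions <- reps$regions[[i]]
    win_s <- cands$win_s[ci]
    win <- substr(fchr, win_s, cands$win_e[ci])
    projs <- list()
    for (j in seq_along(regions)) {
      p <- project_region(regions[[j]], win, win_s - 1L)
      if (!is.null(p) && p$identity >= config$identity &&
          p$coverage >= 0.5 && p$score > 0) {
        projs[[names(regions)[j]]] <- p
      }
    }
    if (!length(projs)) next
    tot_ref <- sum(base::nchar(regions))
    aligned <- sum(map_dbl(projs, "aligned_len"))
    identity <- sum(map_dbl(projs, ~ .x$identity * .x$aligned_len)) / aligned
    coverage <- aligned / tot_ref
    if (identity < config$identity || coverage < config$coverage) next
    fs <- min(map_dbl(projs, "start")); fe <- max(map_dbl(projs, "end"))
    reg_tbl <- tibble(label = names(projs),
                      start = map_dbl(projs, "start"),
                      end = map_dbl(projs, "end"),
                      identity = map_dbl(projs, "identity"),
                      coverage = map_dbl(projs, "coverage"))
    sense_iv <- if (strand == "sense") c(fs, fe) else c(L - fe + 1, L - fs + 1)
    out[[length(out) + 1L]] <- tibble(
      gene_name = reps$gene_name[i], gene_type = tp, strand = strand,
      start = sense_iv[1], end = sense_iv[2],
      frame_start = fs, frame_end = fe,
      identity = identity, coverage = coverage,
      regions = list(reg_tbl))
  }
  if (!length(out)) {
    return(tibble(gene_name = character(), gene_type = character(),
                  strand = character(), start = double(), end = double(),
                  frame_start = double(), frame_end = double(),
                  identity = double(), coverage = double(), regions = list()))
  }
  hits <- bind_rows(out)
  # merge overlapping hits to the same reference gene: best identity wins
  hits <- hits |>
    arrange(.data$gene_name, .data$start) |>
    group_by(.data$gene_name) |>
    group_modify(~ merge_same_gene_hits(.x)) |>
    ungroup() |>
    arrange(.data$start)
  hits
}

# Seed phase of the scan: exact k-mer (or short-pattern mismatch) matching
# of every reference region on both strands, clustered into candidate
# windows per reference gene.
scan_seed_candidates <- function(frames, reps) {
  cands <- list()
  for (strand in names(frames)) {
    fchr <- frames[[strand]]
    fdna <- DNAString(fchr)
    fidx <- build_kmer_index(fchr)
    L <- base::nchar(fchr)
    for (i in seq_len(nrow(reps))) {
      regions <- reps$regions[[i]]
      tp <- reps$gene_type[i]
      # how far apart seed estimates may sit and still mean one gene copy:
      # bounded by the intron span for multi-exon genes; tight for the
      # single-region D/J so tandem copies do not merge into one window
      cluster_gap <- c(V = 500L, D = 100L, J = 100L, C = 2000L)[[tp]]
      est <- integer(0)
      reg_off <- cumsum(c(0L, base::nchar(regions)))[seq_along(regions)]
      for (j in seq_along(regions)) {
        h <- seed_region_hits(regions[[j]], fdna, fidx)
        # normalise to an approximate gene start so regions co-cluster
        if (length(h)) est <- c(est, h - reg_off[j])
      }
      for (cl in cluster_positions(est, cluster_gap)) {
        win_s <- max(1L, min(cl) - 200L)
        span <- sum(base::nchar(regions)) + cluster_gap
        win_e <- min(L, max(cl) + span + 200L)
        cands[[length(cands) + 1L]] <- tibble(
          ref_i = i, gene_type = tp, strand = strand, win_s = win_s,
          win_e = win_e, seed_n = length(cl))
      }
    }
  }
  if (!length(cands)) {
    return(tibble(ref_i = integer(), gene_type = character(),
                  strand = character(), win_s = double(), win_e = double(),
                  seed_n = integer()))
  }
  bind_rows(cands)
}

merge_same_gene_hits <- function(h) {
  if (nrow(h) <= 1) return(h)
  keep <- rep(TRUE, nrow(h))
  ord <- order(-h$identity * h$coverage)
  taken <- list()
  for (i in ord) {
    ok <- TRUE
    for (iv in taken) {
      if (h$start[i] <= iv[2] && h$end[i] >= iv[1]) { ok <- FALSE; break }
    }
    if (ok) taken[[length(taken) + 1L]] <- c(h$start[i], h$end[i]) else keep[i] <- FALSE
  }
  h[keep, , drop = FALSE]
}

# Among overlapping hits of the same gene type keep the best
# identity * coverage; ties by longer span then 5'-most start.
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits |>
    mutate(.qual = .data$identity * .data$coverage,
           .len = .data$end - .data$start + 1) |>
    arrange(desc(.data$.qual), desc(.data$.len), .data$start)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (hits$gene_type[i] == hits$gene_type[j] &&
          hits$start[i] <= hits$end[j] && hits$end[i] >= hits$start[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  hits |> filter(keep) |> select(-".qual", -".len") |> arrange(.data$start)
}

splice_donor_ok <- function(seq_chr, pos) {
  substr(seq_chr, pos, pos + 1L) == "GT"
}

splice_acceptor_ok <- function(seq_chr, pos) {
  substr(seq_chr, pos - 1L, pos) == "AG"
}

frame_seq <- function(locus_seq, strand) {
  s <- toupper(as.character(locus_seq))
  if (strand == "antisense") revcomp_chr(s) else s
}

empty_call <- function() {
  tibble(gene_type = character(), strand = character(), start = double(),
         end = double(), exons = list(), rss = list(), best_hit = character(),
         identity = double(), coverage = double(), reasons = list(),
         core_seq = character(), coding_seq = character(),
         hinge_count = integer())
}

new_call <- function(gene_type, strand, exons, rss, best_hit, identity,
                     coverage, reasons, core_seq, coding_seq = NA_character_,
                     hinge_count = NA_integer_) {
  tibble(gene_type = gene_type, strand = strand,
         start = min(exons$start), end = max(exons$end),
         exons = list(exons), rss = list(rss), best_hit = best_hit,
         identity = identity, coverage = coverage,
         reasons = list(unique(reasons)), core_seq = core_seq,
         coding_seq = coding_seq, hinge_count = hinge_count)
}

empty_rss_tbl <- function() {
  tibble(heptamer = character(), spacer_length = integer(),
         nonamer = character(), side = character(), class = integer(),
         score = double(), start = double(), end = double(),
         accepted = logical())
}

#' Delimit a candidate V gene
#'
#' Projects leader (`L-PART1`) and V exon boundaries from the hit, checks
#' the canonical `GT..AG` intron dinucleotides and scores the 3' RSS
#' (12-spacer class for IGK V genes, 23 otherwise). Splice or RSS failures
#' become `DEFECTIVE_SPLICE` / `DEFECTIVE_RSS` reason codes; an
#' unprojectable leader yields `TRUNCATED`. A hit with overall coverage
#' below 30% is dropped (returns `NULL`).
#'
#' @param locus_seq locus sequence, 5' to 3' locus orientation.
#' @param hit one row of [scan_candidates()] output.
#' @param locus locus id (`IGH`, `IGK`, `IGL`), sets the RSS spacer class.
#' @param config see [igloci_config()].
#' @return A one-row gene-call tibble (frame coordinates), or `NULL`.
#' @export
delimit_v_gene <- function(locus_seq, hit, locus = "IGH",
                           config = igloci_config()) {
  if (hit$coverage < 0.30) return(NULL)
  fchr <- frame_seq(locus_seq, hit$strand)
  reg <- hit$regions[[1]]
  reasons <- character(0)
  if (!"V-EXON" %in% reg$label) return(NULL)
  vx <- reg[reg$label == "V-EXON", ]
  exons <- tibble(label = "V-EXON", start = vx$start, end = vx$end)
  if ("L-PART1" %in% reg$label) {
    lp <- reg[reg$label == "L-PART1", ]
    exons <- bind_rows(tibble(label = "L-PART1", start = lp$start, end = lp$end),
                       exons)
    if (!(splice_donor_ok(fchr, lp$end + 1) && splice_acceptor_ok(fchr, vx$start - 1))) {
      reasons <- c(reasons, "DEFECTIVE_SPLICE")
    }
  } else {
    reasons <- c(reasons, "TRUNCATED")
  }
  cls <- if (locus == "IGK") 12 else 23
  rss <- score_rss(fchr, anchor = vx$end + 1, side = "three_prime",
                   expected_class = cls, config = config)
  if (!isTRUE(rss$accepted)) {
    reasons <- c(reasons, "DEFECTIVE_RSS")
    rss <- empty_rss_tbl()
  }
  exons$sequence <- substr(rep(fchr, nrow(exons)), exons$start, exons$end)
  core <- exons$sequence[exons$label == "V-EXON"]
  coding <- paste(exons$sequence, collapse = "")
  new_call("V", hit$strand, exons, rss, hit$gene_name, hit$identity,
           hit$coverage, reasons, core, coding)
}

#' Delimit a candidate D gene
#'
#' The D region is flanked by a 12-class RSS on each side; both are scored
#' within 10 bp of the alignment ends. A candidate with neither RSS
#' acceptable is dropped (decoy); one missing RSS yields `DEFECTIVE_RSS`.
#'
#' @inheritParams delimit_v_gene
#' @return A one-row gene-call tibble, or `NULL` when dropped.
#' @export
delimit_d_gene <- function(locus_seq, hit, locus = "IGH",
                           config = igloci_config()) {
  fchr <- frame_seq(locus_seq, hit$strand)
  reg <- hit$regions[[1]][1, ]
  rss5 <- score_rss(fchr, anchor = reg$start - 1, side = "five_prime",
                    expected_class = 12, config = config)
  rss3 <- score_rss(fchr, anchor = reg$end + 1, side = "three_prime",
                    expected_class = 12, config = config)
  if (!isTRUE(rss5$accepted) && !isTRUE(rss3$accepted)) return(NULL)
  reasons <- character(0)
  rss <- bind_rows(rss5[isTRUE(rss5$accepted), ], rss3[isTRUE(rss3$accepted), ])
  if (!isTRUE(rss5$accepted) || !isTRUE(rss3$accepted)) {
    reasons <- c(reasons, "DEFECTIVE_RSS")
  }
  exons <- tibble(label = "D-REGION", start = reg$start, end = reg$end,
                  sequence = substr(fchr, reg$start, reg$end))
  new_call("D", hit$strand, exons, rss, hit$gene_name, hit$identity,
           hit$coverage, reasons, exons$sequence)
}

#' Delimit a candidate J gene
#'
#' The J region carries a 5' 23-class RSS, a terminal `GT` splice donor
#' after the region, and a frame-consistent FR4 motif (`W/F-G-X-G`); a
#' missing motif yields `NO_CANONICAL_MOTIF`.
#'
#' @inheritParams delimit_v_gene
#' @return A one-row gene-call tibble, or `NULL` when dropped.
#' @export
delimit_j_gene <- function(locus_seq, hit, locus = "IGH",
                           config = igloci_config()) {
  fchr <- frame_seq(locus_seq, hit$strand)
  reg <- hit$regions[[1]][1, ]
  reasons <- character(0)
  rss5 <- score_rss(fchr, anchor = reg$start - 1, side = "five_prime",
                    expected_class = 23, config = config)
  rss <- rss5[isTRUE(rss5$accepted), ]
  if (!isTRUE(rss5$accepted)) reasons <- c(reasons, "DEFECTIVE_RSS")
  if (!splice_donor_ok(fchr, reg$end + 1)) reasons <- c(reasons, "DEFECTIVE_SPLICE")
  jseq <- substr(fchr, reg$start, reg$end)
  if (!has_fr4_motif(jseq)) reasons <- c(reasons, "NO_CANONICAL_MOTIF")
  exons <- tibble(label = "J-REGION", start = reg$start, end = reg$end,
                  sequence = jseq)
  new_call("J", hit$strand, exons, rss, hit$gene_name, hit$identity,
           hit$coverage, reasons, jseq)
}

# FR4 motif W/F-G-X-G in any reading frame of the J region
has_fr4_motif <- function(jseq) {
  n <- base::nchar(jseq)
  for (f in 0:2) {
    aa <- safe_translate(substr(jseq, 1 + f, n - (n - f) %% 3))
    if (grepl("[WF]G.G", aa)) return(TRUE)
  }
  FALSE
}

safe_translate <- function(nt) {
  if (base::nchar(nt) < 3) return("")
  nt <- substr(nt, 1, base::nchar(nt) - base::nchar(nt) %% 3)
  as.character(translate(DNAString(nt), if.fuzzy.codon = "X"))
}

#' Delimit a candidate C gene
#'
#' One exon per aligned reference exon (CH domains, hinge exons `H1..Hn`,
#' secreted/membrane exons). Internal exons are checked for `AG` acceptor /
#' `GT` donor dinucleotides; exons aligned out of reference order flag the
#' call `REARRANGED`; reference exons without an aligned counterpart yield
#' `MISSING_EXON`.
#'
#' @inheritParams delimit_v_gene
#' @param ref the reference allele row whose exons define the expected
#'   structure (from the reference set; matched by `hit$gene_name`).
#' @return A one-row gene-call tibble, or `NULL`.
#' @export
delimit_c_gene <- function(locus_seq, hit, ref, locus = "IGH",
                           config = igloci_config()) {
  fchr <- frame_seq(locus_seq, hit$strand)
  reg <- hit$regions[[1]]
  ref_labels <- names(ref$regions[[1]])
  reasons <- character(0)
  missing <- setdiff(ref_labels, reg$label)
  if (length(missing)) reasons <- c(reasons, "MISSING_EXON")
  # order found exons by reference label order; check genomic order agrees
  reg <- reg[order(match(reg$label, ref_labels)), ]
  if (is.unsorted(reg$start, strictly = TRUE)) {
    reasons <- c(reasons, "REARRANGED")
    reg <- reg[order(reg$start), ]
  }
  n <- nrow(reg)
  if (n == 0) return(NULL)
  for (k in seq_len(n)) {
    ok <- TRUE
    if (k > 1 && !splice_acceptor_ok(fchr, reg$start[k] - 1)) ok <- FALSE
    if (k < n && !splice_donor_ok(fchr, reg$end[k] + 1)) ok <- FALSE
    if (!ok) reasons <- c(reasons, "DEFECTIVE_SPLICE")
  }
  exons <- tibble(label = reg$label, start = reg$start, end = reg$end,
                  sequence = substr(rep(fchr, n), reg$start, reg$end))
  core <- paste(exons$sequence, collapse = "")
  call <- new_call("C", hit$strand, exons, empty_rss_tbl(), hit$gene_name,
                   hit$identity, hit$coverage, reasons, core, core,
                   hinge_count = sum(grepl("^H[0-9]+$", exons$label)))
  call
}

#' Count hinge exons of a C gene call
#'
#' @param call a one-row C gene call.
#' @return Integer number of exons labelled `H1..Hn`.
#' @export
count_hinge_exons <- function(call) {
  if (!identical(call$gene_type[1], "C")) abort("count_hinge_exons: not a C gene call")
  sum(grepl("^H[0-9]+$", call$exons[[1]]$label))
}

#' Detect hinge-exon indels of a C gene call against a reference allele
#'
#' For each hinge exon, the net insertion/deletion length relative to the
#' reference hinge and whether it shifts the reading frame
#' (`length %% 3 != 0`). A 15-bp hinge deletion is in-frame; a 2-bp
#' deletion is a frameshift.
#'
#' @param call a one-row C gene call with hinge exon(s).
#' @param ref the reference allele row to compare against.
#' @return A tibble `exon_label`, `indel_length`, `frameshift`, one row per
#'   hinge exon with a net indel (empty when hinges are length-identical).
#' @export
detect_hinge_indels <- function(call, ref) {
  if (!identical(call$gene_type[1], "C")) abort("detect_hinge_indels: not a C gene call")
  exons <- call$exons[[1]]
  hx <- exons[grepl("^H[0-9]+$", exons$label), ]
  regions <- ref$regions[[1]]
  out <- list()
  for (i in seq_len(nrow(hx))) {
    lab <- hx$label[i]
    if (!lab %in% names(regions)) next
    d <- base::nchar(hx$sequence[i]) - base::nchar(regions[[lab]])
    if (d != 0) {
      out[[length(out) + 1L]] <- tibble(exon_label = lab, indel_length = d,
                                        frameshift = (d %% 3) != 0)
    }
  }
  if (!length(out)) {
    return(tibble(exon_label = character(), indel_length = integer(),
                  frameshift = logical()))
  }
  bind_rows(out)
}

#' Find assembly gaps (N runs) in a sequence
#'
#' @param locus_seq nucleotide sequence.
#' @param gap_min minimum run length reported (default 100 bp, separating
#'   assembly gaps from isolated ambiguity codes).
#' @return A tibble `start`, `end`, `length` of maximal N runs.
#' @export
find_gaps <- function(locus_seq, gap_min = 100L) {
  s <- toupper(as.character(locus_seq))
  m <- gregexpr(sprintf("N{%d,}", as.integer(gap_min)), s)[[1]]
  if (m[1] == -1) return(tibble(start = double(), end = double(), length = double()))
  len <- attr(m, "match.length")
  tibble(start = as.numeric(m), end = as.numeric(m) + len - 1, length = as.numeric(len))
}

# Delimit every hit of a scan, dispatching on gene type. Returns gene calls
# in frame coordinates plus sense-frame envelope columns.
delimit_hits <- function(locus_seq, hits, refs, locus, config = igloci_config()) {
  hits <- resolve_overlaps(hits)
  L <- base::nchar(as.character(locus_seq))
  reps <- representative_refs(refs)
  calls <- list()
  for (i in seq_len(nrow(hits))) {
    hit <- hits[i, ]
    call <- switch(hit$gene_type,
      V = delimit_v_gene(locus_seq, hit, locus, config),
      D = delimit_d_gene(locus_seq, hit, locus, config),
      J = delimit_j_gene(locus_seq, hit, locus, config),
      C = delimit_c_gene(locus_seq, hit,
                         reps[reps$gene_name == hit$gene_name, ], locus, config))
    if (is.null(call)) next
    call$sense_start <- if (call$strand == "sense") call$start else L - call$end + 1
    call$sense_end <- if (call$strand == "sense") call$end else L - call$start + 1
    calls[[length(calls) + 1L]] <- call
  }
  if (!length(calls)) {
    out <- empty_call()
    out$sense_start <- double(0); out$sense_end <- double(0)
    return(out)
  }
  bind_rows(calls) |> arrange(.data$sense_start)
}
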