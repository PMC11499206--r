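REASON_CODES <- c("STOP_CODON", "FRAMESHIFT", "DEFECTIVE_SPLICE",
                  "DEFECTIVE_RSS", "TRUNCATED", "REPEAT_INSERTION",
                  "NO_CANONICAL_MOTIF", "NO_INIT_CODON", "REARRANGED",
                  "MISSING_EXON")
PSEUDO_REASONS <- c("STOP_CODON", "FRAMESHIFT", "TRUNCATED",
                    "REPEAT_INSERTION", "REARRANGED", "MISSING_EXON",
                    "NO_INIT_CODON")
ORF_REASONS <- c("DEFECTIVE_SPLICE", "DEFECTIVE_RSS", "NO_CANONICAL_MOTIF")

#' Functionality state from a set of reason codes
#'
#' Total, deterministic mapping of defect reason codes to the IMGT
#' three-state functionality: any coding-destroying code (stop codon,
#' frameshift, truncation, large repeat insertion, exon rearrangement or
#' loss, missing initiation codon) makes a pseudogene; an intact frame with
#' only regulatory/recombination defects (splice, RSS, FR4 motif) is an
#' ORF; no reasons means functional.
#'
#' @param reasons character vector of reason codes (may be empty).
#' @return `"functional"`, `"ORF"` or `"pseudogene"`.
#' @export
functionality_state <- function(reasons) {
  reasons <- unique(reasons)
  bad <- setdiff(reasons, REASON_CODES)
  if (length(bad)) abort(paste0("unknown reason code: ", bad[1]))
  if (any(reasons %in% PSEUDO_REASONS)) return("pseudogene")
  if (length(reasons)) return("ORF")
  "functional"
}

#' Assign functionality to a delimited gene call
#'
#' Combines the detection-stage reason codes (splice, RSS, motif,
#' truncation, exon order) with coding-level checks against the best-hit
#' reference allele: internal stop codons in the projected frame,
#' indel-induced frameshifts (net indel not a multiple of 3), insertions of
#' 100 bp or more inside the gene body (`REPEAT_INSERTION`), and for V
#' genes a missing `ATG` initiation codon.
#'
#' @param call a one-row gene-call tibble (see `delimit_*` functions).
#' @param refs the reference set; the best-hit allele supplies the
#'   comparison sequence.
#' @return The call with `reasons` completed and columns `functionality`
#'   (state) added.
#' @export
assign_functionality <- function(call, refs) {
  reasons <- call$reasons[[1]]
  tp <- call$gene_type[1]
  ref <- best_hit_ref(call, refs)
  if (tp %in% c("V", "C") && !is.null(ref)) {
    ref_coding <- paste(ref$regions[[1]][coding_labels(ref)], collapse = "")
    has_leader <- "L-PART1" %in% call$exons[[1]]$label
    reasons <- c(reasons, coding_reasons(call$coding_seq[1], ref_coding,
                                         check_init = (tp == "V" && has_leader)))
  }
  reasons <- unique(reasons)
  call$reasons <- list(reasons)
  call$functionality <- functionality_state(reasons)
  call
}

coding_labels <- function(ref) {
  labs <- names(ref$regions[[1]])
  labs[labs %in% c("L-PART1", "V-EXON") | grepl("^CH|^H[0-9]+$|^M", labs)]
}

best_hit_ref <- function(call, refs) {
  r <- refs[refs$gene_name == call$best_hit[1], ]
  if (!nrow(r)) return(NULL)
  r[which.min(r$allele), ]
}

# Coding-level defect codes from a call coding sequence vs its reference.
coding_reasons <- function(coding, ref_coding, check_init = FALSE) {
  reasons <- character(0)
  if (is.na(coding) || !base::nchar(coding)) return(reasons)
  if (check_init && substr(coding, 1, 3) != "ATG") {
    reasons <- c(reasons, "NO_INIT_CODON")
  }
  aln <- align_global(coding, ref_coding)
  ins <- Biostrings::insertion(aln)[[1]]  # extra bases in the call
  del <- Biostrings::deletion(aln)[[1]]   # bases missing from the call
  if (length(ins) && max(width(ins)) >= 100) {
    reasons <- c(reasons, "REPEAT_INSERTION")
  }
  net <- sum(width(ins)) - sum(width(del))
  if (net %% 3 != 0) reasons <- c(reasons, "FRAMESHIFT")
  aa <- safe_translate(coding)
  body <- substr(aa, 1, base::nchar(aa) - 1)  # terminal codon may be a stop
  if (grepl("\\*", body)) reasons <- c(reasons, "STOP_CODON")
  reasons
}

#' Project IMGT-style unique numbering from a reference onto a V call
#'
#' Globally aligns the amino-acid translation of the call's V exon to the
#' numbered reference translation and transfers reference positions through
#' the alignment columns. Insertions relative to the reference are reported
#' as sub-positions (`"27.1"` etc.). Conserved-position sanity (23 C, 41 W,
#' 104 C where those positions exist in the reference map) is reported in
#' the `conserved_ok` attribute.
#'
#' @param call a one-row V gene call.
#' @param ref_numbering integer vector: IMGT position of each amino acid of
#'   the reference V translation.
#' @param ref_aa the reference amino-acid sequence (same length as
#'   `ref_numbering`).
#' @return A tibble `position` (character), `aa`; errors when alignment
#'   identity is below 40%.
#' @export
project_unique_numbering <- function(call, ref_numbering, ref_aa) {
  stopifnot(identical(call$gene_type[1], "V"))
  aa <- sub("\\*$", "", safe_translate(call$core_seq[1]))
  aln <- pairwiseAlignment(AAString(aa), AAString(ref_aa), type = "global",
                           substitutionMatrix = "BLOSUM62",
                           gapOpening = 10, gapExtension = 1)
  if (!isTRUE(Biostrings::pid(aln) >= 40)) {
    abort("numbering refused: alignment identity below 40%",
          class = "igloci_numbering_refused")
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  pos <- character(0); res <- character(0)
  ref_i <- 0L; sub_k <- 0L
  for (col in seq_along(pat)) {
    if (sub[col] != "-") { ref_i <- ref_i + 1L; sub_k <- 0L }
    if (pat[col] == "-") next
    if (sub[col] == "-") {
      sub_k <- sub_k + 1L
      pos <- c(pos, paste0(ref_numbering[max(ref_i, 1L)], ".", sub_k))
    } else {
      pos <- c(pos, as.character(ref_numbering[ref_i]))
    }
    res <- c(res, pat[col])
  }
  out <- tibble(position = pos, aa = res)
  conserved <- c(`23` = "C", `41` = "W", `104` = "C")
  have <- intersect(names(conserved), as.character(ref_numbering))
  ok <- all(map_lgl(have, function(p) {
    any(out$position == p & out$aa == conserved[[p]])
  }))
  attr(out, "conserved_ok") <- ok
  out
}

#' Assign a V gene to a subgroup or clan
#'
#' The call takes the subgroup of the reference allele with the highest
#' nucleotide identity when that identity is at least the subgroup
#' threshold (default 75%); below it, the clan of the best clan-level
#' representative (parenthesised subgroup labels, e.g. `IGHV(III)`); below
#' 50%, `"unclassified"`. Ties break by reference name lexicographic order.
#'
#' @param call a one-row V gene call.
#' @param refs the reference set.
#' @param config see [igloci_config()].
#' @return The subgroup or clan label, or `"unclassified"`.
#' @export
assign_subgroup <- function(call, refs, config = igloci_config()) {
  vr <- refs[refs$gene_type == "V", ]
  if (!nrow(vr)) return("unclassified")
  ids <- map_dbl(seq_len(nrow(vr)), function(i) {
    ref_core <- vr$regions[[i]][["V-EXON"]]
    aln <- align_global(call$core_seq[1], ref_core)
    Biostrings::pid(aln) / 100
  })
  ord <- order(-ids, vr$gene_name)
  best <- ord[1]
  if (ids[best] >= config$subgroup) return(vr$subgroup[best])
  if (ids[best] < config$unclassified_below) return("unclassified")
  is_clan <- grepl("\\(", vr$subgroup)
  if (!any(is_clan)) return("unclassified")
  clan_ord <- ord[is_clan[ord]]
  vr$subgroup[clan_ord[1]]
}

#' Match a gene call to known alleles
#'
#' Allele identity is decided over the core regions only (V exon; D/J
#' region; C exons). An exact nucleotide match to a known allele returns
#' its number; otherwise the call is a new allele, numbered after the
#' maximum existing number, with the substitution/indel list against the
#' nearest known allele (ties to the lower allele number).
#'
#' @param call a one-row gene call with `core_seq`.
#' @param known_alleles reference rows for the assigned gene (same
#'   `gene_name`), with `allele` numbers and `regions`.
#' @return A list: `allele` (integer or `"new"`), `new_number` (the number
#'   a new allele takes), `nearest` (allele number compared against),
#'   `differences` (tibble `position`, `ref`, `alt`, `type`).
#' @export
match_allele <- function(call, known_alleles) {
  cores <- map_chr(seq_len(nrow(known_alleles)), function(i) {
    allele_core(known_alleles$regions[[i]], known_alleles$gene_type[i])
  })
  hit <- which(cores == call$core_seq[1])
  if (length(hit)) {
    a <- min(known_alleles$allele[hit])
    return(list(allele = a, new_number = NA_integer_, nearest = a,
                differences = empty_diffs()))
  }
  d <- map_int(cores, ~ edit_distance(call$core_seq[1], .x))
  ord <- order(d, known_alleles$allele)
  nearest <- ord[1]
  list(allele = "new",
       new_number = max(known_alleles$allele) + 1L,
       nearest = known_alleles$allele[nearest],
       differences = diff_list(call$core_seq[1], cores[nearest]))
}

edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

empty_diffs <- function() {
  tibble(position = integer(), ref = character(), alt = character(),
         type = character())
}

# Substitution/indel list vs a reference core, positions on the reference.
diff_list <- function(call_core, ref_core) {
  aln <- align_global(call_core, ref_core)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- list()
  ref_i <- 0L
  for (col in seq_along(pat)) {
    if (sub[col] != "-") ref_i <- ref_i + 1L
    if (sub[col] == "-") {
      out[[length(out) + 1L]] <- tibble(position = ref_i, ref = "-",
                                        alt = pat[col], type = "ins")
    } else if (pat[col] == "-") {
      out[[length(out) + 1L]] <- tibble(position = ref_i, ref = sub[col],
                                        alt = "-", type = "del")
    } else if (pat[col] != sub[col]) {
      out[[length(out) + 1L]] <- tibble(position = ref_i, ref = sub[col],
                                        alt = pat[col], type = "sub")
    }
  }
  if (!length(out)) return(empty_diffs())
  bind_rows(out)
}

# core-region sequence of a reference allele
allele_core <- function(regions, gene_type) {
  switch(gene_type,
         V = regions[["V-EXON"]],
         D = regions[["D-REGION"]],
         J = regions[["J-REGION"]],
         C = paste(regions[grepl("^CH|^H[0-9]+$|^M", names(regions))],
                   collapse = ""))
}

#' Star confidence of an allele
#'
#' One to three stars for an allele identified in one, two, or more
#' distinct genomic sequences.
#'
#' @param observations number of distinct genomic sequences containing the
#'   allele (>= 1).
#' @return Integer star count, capped at 3.
#' @export
assign_stars <- function(observations) {
  if (any(observations < 1)) abort("observations must be >= 1")
  pmin(as.integer(observations), 3L)
}
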