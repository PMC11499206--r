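#' Orthology-based gene naming
#'
#' Genes are named after their reference (human) counterparts when their
#' best hits form a chain consistent with the reference gene order along
#' the locus; the chain is the longest order-consistent subsequence of
#' best-hit reference ranks (ties resolved toward higher summed identity,
#' then 5'-most genes). Genes off the chain are handled afterwards as
#' duplicated blocs or inserted genes.
#'
#' @param genes gene-call tibble ordered 5' to 3' in locus orientation,
#'   with `best_hit` and `identity` columns.
#' @param ref_order character vector of reference gene names in reference
#'   locus order (5' to 3').
#' @return A tibble `index`, `base_name` (NA when unset), `provenance`
#'   (`"ortholog"` or NA), `synteny_support`.
#' @export
assign_ortholog_names <- function(genes, ref_order) {
  n <- nrow(genes)
  out <- tibble(index = seq_len(n), base_name = NA_character_,
                provenance = NA_character_, synteny_support = FALSE)
  if (n == 0) return(out)
  ranks <- match(genes$best_hit, ref_order)
  chain <- lis_chain(ranks, genes$identity)
  out$base_name[chain] <- genes$best_hit[chain]
  out$provenance[chain] <- "ortholog"
  out$synteny_support[chain] <- TRUE
  out
}

# Longest strictly increasing subsequence of ranks (NA ranks excluded);
# among maximal chains prefers the highest total identity, then the
# lexicographically earliest index set. O(n^2) dynamic programme.
lis_chain <- function(ranks, identity = rep(0, length(ranks))) {
  n <- length(ranks)
  if (!n) return(integer(0))
  len <- rep(0L, n); wt <- rep(-Inf, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (is.na(ranks[i])) next
    len[i] <- 1L; wt[i] <- identity[i]; prev[i] <- NA_integer_
    for (j in seq_len(i - 1L)) {
      if (is.na(ranks[j]) || ranks[j] >= ranks[i]) next
      cand_len <- len[j] + 1L
      cand_wt <- wt[j] + identity[i]
      if (cand_len > len[i] || (cand_len == len[i] && cand_wt > wt[i])) {
        len[i] <- cand_len; wt[i] <- cand_wt; prev[i] <- j
      }
    }
  }
  if (all(len == 0L)) return(integer(0))
  best <- which(len == max(len))
  best <- best[order(-wt[best], best)][1]
  chain <- integer(0)
  i <- best
  while (!is.na(i)) { chain <- c(i, chain); i <- prev[i] }
  chain
}

#' Detect duplicated gene blocs
#'
#' A maximal run of unnamed genes whose per-gene identity to an
#' equal-length run of named genes (order-preserved, same gene types) has a
#' mean of at least the bloc threshold (default 99.5%) is a duplicated
#' bloc; each member takes its counterpart's name plus a `"D"` suffix.
#' Single-gene duplications are permitted. Identity is measured over gene
#' core sequences.
#'
#' @param genes gene-call tibble ordered in locus orientation, with
#'   `gene_type` and `core_seq`.
#' @param assignments output of [assign_ortholog_names()].
#' @param config see [igloci_config()].
#' @return A tibble `index`, `name`, `initial_name`, `mean_identity`, one
#'   row per duplicated gene; empty when no bloc qualifies.
#' @export
detect_duplicated_blocs <- function(genes, assignments,
                                    config = igloci_config()) {
  unset <- which(is.na(assignments$base_name))
  named <- which(!is.na(assignments$base_name))
  empty <- tibble(index = integer(), name = character(),
                  initial_name = character(), mean_identity = double())
  if (!length(unset) || !length(named)) return(empty)
  runs <- split(unset, cumsum(c(1L, diff(unset) != 1L)))
  out <- list()
  for (run in runs) {
    L <- length(run)
    run_types <- genes$gene_type[run]
    # candidate initial runs: equal-length windows of named genes with the
    # same gene-type sequence
    cands <- list()
    for (s in seq_len(max(0L, length(named) - L + 1L))) {
      win <- named[s:(s + L - 1L)]
      if (!all(diff(win) == 1L) && L > 1L) next  # contiguous named run
      if (!identical(genes$gene_type[win], run_types)) next
      ids <- map_dbl(seq_len(L), function(k) {
        aln <- align_global(genes$core_seq[run[k]], genes$core_seq[win[k]])
        Biostrings::pid(aln) / 100
      })
      if (mean(ids) >= config$bloc_identity) {
        cands[[length(cands) + 1L]] <- list(win = win, mean_identity = mean(ids))
      }
    }
    if (length(cands) > 1L) {
      labs <- map_chr(cands, ~ paste(assignments$base_name[.x$win], collapse = ","))
      abort(paste0("duplicated bloc matches two initial blocs at >= ",
                   config$bloc_identity * 100, "% identity: [",
                   labs[1], "] and [", labs[2], "]"),
            class = "igloci_bloc_ambiguity")
    }
    if (length(cands) == 1L) {
      win <- cands[[1]]$win
      out[[length(out) + 1L]] <- tibble(
        index = run,
        name = paste0(assignments$base_name[win], "D"),
        initial_name = assignments$base_name[win],
        mean_identity = cands[[1]]$mean_identity)
    }
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Name the remaining inserted genes
#'
#' Completes the assignment after orthologs and duplicated blocs:
#' \itemize{
#' \item an unset V gene between named neighbours takes the 3' neighbour's
#'   name plus a `-k` sub-position, `k` incrementing 3' to 5';
#' \item an unset D gene takes the 5' neighbour's name plus `-k`,
#'   incrementing 5' to 3';
#' \item unset J/C genes take the nearest named same-type 5' neighbour's
#'   name plus letters `A`, `B`, ... incrementing 5' to 3';
#' \item genes 5' of all named genes get new top-level position numbers by
#'   incrementing the locus-extreme position number.
#' }
#' Sub-position numbering continues after any sub-position already present
#' among named genes, preserving uniqueness.
#'
#' @param genes gene-call tibble ordered 5' to 3' in locus orientation.
#' @param assignments assignment tibble after [assign_ortholog_names()] and
#'   [detect_duplicated_blocs()] results have been applied (see
#'   [apply_bloc_names()]).
#' @param subgroups optional character vector of per-gene subgroup labels,
#'   used to name genes 5' of all named genes.
#' @return The completed assignment tibble; every gene has a `base_name`.
#' @export
assign_inserted_names <- function(genes, assignments, subgroups = NULL) {
  n <- nrow(genes)
  if (!n) return(assignments)
  if (all(is.na(assignments$base_name))) {
    abort("cannot name inserted genes: no named anchor in the locus")
  }
  a <- assignments
  named_idx <- function() which(!is.na(a$base_name))
  # --- genes 5' of the 5'-most named gene: new top-level positions -------
  first_named <- min(named_idx())
  if (first_named > 1L) {
    ext <- max_top_position(a$base_name)
    pos <- ext$pos
    for (i in (first_named - 1L):1L) {
      if (!is.na(a$base_name[i])) next
      pos <- pos + 1L
      sub <- if (!is.null(subgroups) && !is.na(subgroups[i]) &&
                 nzchar(subgroups[i])) subgroups[i] else ext$subgroup
      a$base_name[i] <- paste0(sub, "-", pos)
      a$provenance[i] <- "inserted"
    }
  }
  # --- V genes between named anchors: sub-positions on the 3' anchor ----
  unset <- which(is.na(a$base_name) & genes$gene_type == "V")
  for (run in split_runs(unset)) {
    after <- run[length(run)] + 1L
    anchors_3p <- which(!is.na(a$base_name))
    anchors_3p <- anchors_3p[anchors_3p >= after]
    if (!length(anchors_3p)) next
    anchor <- min(anchors_3p)
    base <- a$base_name[anchor]
    k <- max_sub_position(a$base_name, base)
    for (i in rev(run)) {   # walk 3' -> 5'
      k <- k + 1L
      a$base_name[i] <- paste0(base, "-", k)
      a$provenance[i] <- "inserted"
    }
  }
  # --- D genes: sub-positions on the 5' anchor, incrementing 5' -> 3' ----
  unset <- which(is.na(a$base_name) & genes$gene_type == "D")
  for (run in split_runs(unset)) {
    before <- run[1] - 1L
    anchors_5p <- which(!is.na(a$base_name))
    anchors_5p <- anchors_5p[anchors_5p <= before]
    if (!length(anchors_5p)) next
    anchor <- max(anchors_5p)
    base <- a$base_name[anchor]
    k <- max_sub_position(a$base_name, base)
    for (i in run) {        # walk 5' -> 3'
      k <- k + 1L
      a$base_name[i] <- paste0(base, "-", k)
      a$provenance[i] <- "inserted"
    }
  }
  # --- J/C genes: letter suffix on nearest named same-type 5' neighbour --
  unset <- which(is.na(a$base_name) & genes$gene_type %in% c("J", "C"))
  for (i in unset) {
    sib <- which(!is.na(a$base_name) & genes$gene_type == genes$gene_type[i])
    sib <- sib[sib < i]
    if (!length(sib)) next
    base <- a$base_name[max(sib)]
    suf <- next_letter_suffix(a$base_name, base)
    a$base_name[i] <- paste0(base, suf)
    a$provenance[i] <- "inserted"
  }
  if (anyNA(a$base_name)) {
    abort(paste0("naming incomplete: no usable anchor for gene(s) ",
                 paste(which(is.na(a$base_name)), collapse = ", ")))
  }
  if (anyDuplicated(a$base_name)) {
    abort(paste0("duplicate gene name assigned: ",
                 a$base_name[duplicated(a$base_name)][1]))
  }
  a
}

split_runs <- function(idx) {
  if (!length(idx)) return(list())
  unname(split(idx, cumsum(c(1L, diff(idx) != 1L))))
}

# highest existing sub-position k among names "<base>-k"
max_sub_position <- function(names, base) {
  pat <- paste0("^", escape_regex(base), "-([0-9]+)$")
  hits <- stats::na.omit(as.integer(sub(pat, "\\1", names[grepl(pat, names)])))
  if (!length(hits)) 0L else max(hits)
}

# next unused letter suffix A, B, ... (then AA, AB, ...) for "<base><letter>"
next_letter_suffix <- function(names, base) {
  pat <- paste0("^", escape_regex(base), "([A-Z]+)$")
  used <- sub(pat, "\\1", names[grepl(pat, names)])
  k <- if (!length(used)) 0L else max(map_int(used, letters_to_int))
  int_to_letters(k + 1L)
}

letters_to_int <- function(s) {
  chars <- strsplit(s, "")[[1]]
  sum((match(chars, LETTERS)) * 26^(rev(seq_along(chars)) - 1L))
}

int_to_letters <- function(k) {
  out <- character(0)
  while (k > 0L) {
    r <- (k - 1L) %% 26L
    out <- c(LETTERS[r + 1L], out)
    k <- (k - 1L) %/% 26L
  }
  paste(out, collapse = "")
}

# extreme (largest) top-level position number among named genes, with the
# subgroup prefix of the gene carrying it
max_top_position <- function(names) {
  nm <- names[!is.na(names)]
  m <- str_match(nm, "^([A-Z0-9()]+)-([0-9]+)")
  keep <- !is.na(m[, 3])
  if (!any(keep)) abort("no positional gene names to extend from")
  pos <- as.integer(m[keep, 3])
  i <- which.max(pos)
  list(pos = max(pos), subgroup = m[keep, 2][i])
}

escape_regex <- function(x) {
  gsub("([.\\\\|()^${}*+?]|\\[|\\])", "\\\\\\1", x)
}

#' Apply duplicated-bloc names onto an assignment table
#'
#' @param assignments assignment tibble from [assign_ortholog_names()].
#' @param blocs output of [detect_duplicated_blocs()].
#' @return The assignment tibble with bloc members named (provenance
#'   `"duplicated"`).
#' @export
apply_bloc_names <- function(assignments, blocs) {
  if (nrow(blocs)) {
    assignments$base_name[blocs$index] <- blocs$name
    assignments$provenance[blocs$index] <- "duplicated"
  }
  assignments
}

#' Full nomenclature pass over an ordered gene-call table
#'
#' Runs orthology chaining, duplicated-bloc detection and inserted-gene
#' naming, returning one name per gene.
#'
#' @inheritParams assign_ortholog_names
#' @inheritParams detect_duplicated_blocs
#' @param subgroups optional per-gene subgroup labels (see
#'   [assign_inserted_names()]).
#' @return Assignment tibble: `index`, `base_name`, `provenance`
#'   (`ortholog`/`duplicated`/`inserted`), `synteny_support`.
#' @export
assign_gene_names <- function(genes, ref_order, subgroups = NULL,
                              config = igloci_config()) {
  a <- assign_ortholog_names(genes, ref_order)
  if (!nrow(genes)) return(a)
  blocs <- detect_duplicated_blocs(genes, a, config)
  a <- apply_bloc_names(a, blocs)
  if (anyNA(a$base_name)) a <- assign_inserted_names(genes, a, subgroups)
  a
}
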