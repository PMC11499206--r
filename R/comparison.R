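#' Build a gene presence matrix across assemblies
#'
#' Matches genes across assemblies by assigned name. The union gene list is
#' ordered by locus position (mean normalised position over the assemblies
#' carrying the gene, which reproduces reference order with inserted genes
#' interleaved). Alleles are identified by the core-region nucleotide
#' sequence, so the same novel allele seen in two assemblies counts once.
#' A gene absent from an assembly is gap-masked when the interval between
#' its nearest present neighbours in that assembly overlaps an assembly gap
#' — a gap is missing evidence, not absence.
#'
#' @param tables a list of per-assembly gene tables
#'   ([write_gene_table()] rows, or `tidy()` of an annotation), all for the
#'   same locus, with `assembly_id`, `gene_name`, `core_seq`, `start`,
#'   `end`, `locus_order` columns.
#' @param gaps optional tibble of assembly gaps with `assembly_id`,
#'   `seq_id`, `start`, `end` (chromosome coordinates); used for gap
#'   masking.
#' @return An object of class `ig_presence`: list with `locus`,
#'   `gene_names` (ordered union), `assemblies`, `present` (gene x assembly
#'   logical matrix), `allele_of` (character matrix of allele keys),
#'   `gap_masked` (logical matrix), `long` (tidy tibble).
#' @export
build_presence_matrix <- function(tables, gaps = NULL) {
  tab <- bind_rows(tables)
  stopifnot(nrow(tab) > 0)
  locus <- unique(tab$locus)
  if (length(locus) > 1) abort("all tables must describe the same locus")
  dup <- tab |> count(.data$assembly_id, .data$gene_name) |> filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("integrity error: gene '%s' appears twice in assembly '%s'",
                  dup$gene_name[1], dup$assembly_id[1]))
  }
  assemblies <- unique(tab$assembly_id)
  gene_names <- merge_gene_orders(tab)
  present <- matrix(FALSE, length(gene_names), length(assemblies),
                    dimnames = list(gene_names, assemblies))
  allele_of <- matrix(NA_character_, length(gene_names), length(assemblies),
                      dimnames = list(gene_names, assemblies))
  for (i in seq_len(nrow(tab))) {
    present[tab$gene_name[i], tab$assembly_id[i]] <- TRUE
    allele_of[tab$gene_name[i], tab$assembly_id[i]] <- tab$core_seq[i]
  }
  gap_masked <- gap_mask_matrix(tab, gene_names, assemblies, present, gaps)
  long <- tidyr::expand_grid(gene_name = gene_names, assembly_id = assemblies) |>
    mutate(present = map2_lgl_mat(present, .data$gene_name, .data$assembly_id),
           gap_masked = map2_lgl_mat(gap_masked, .data$gene_name, .data$assembly_id))
  structure(list(locus = locus, gene_names = gene_names,
                 assemblies = assemblies, present = present,
                 allele_of = allele_of, gap_masked = gap_masked, long = long),
            class = "ig_presence")
}

map2_lgl_mat <- function(m, i, j) m[cbind(i, j)]

# Merge the per-assembly gene orders into one union order: topological sort
# over the successor edges observed in each assembly (the orders are
# projections of one underlying locus order), breaking ties by mean
# relative position then name.
merge_gene_orders <- function(tab) {
  tab <- tab |>
    group_by(.data$assembly_id) |>
    arrange(.data$locus_order, .by_group = TRUE) |>
    mutate(.relpos = (.data$locus_order - 1) / max(1L, n() - 1L)) |>
    ungroup()
  genes <- unique(tab$gene_name)
  relpos <- tab |>
    group_by(.data$gene_name) |>
    summarise(.pos = mean(.data$.relpos), .groups = "drop")
  pos <- setNames(relpos$.pos, relpos$gene_name)
  succ <- setNames(vector("list", length(genes)), genes)
  indeg <- setNames(rep(0L, length(genes)), genes)
  for (a in unique(tab$assembly_id)) {
    g <- tab$gene_name[tab$assembly_id == a]
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1L)) {
      u <- g[i]; v <- g[i + 1L]
      if (!v %in% succ[[u]]) {
        succ[[u]] <- c(succ[[u]], v)
        indeg[v] <- indeg[v] + 1L
      }
    }
  }
  out <- character(0)
  avail <- names(indeg)[indeg == 0L]
  while (length(avail)) {
    nxt <- avail[order(pos[avail], avail)][1]
    out <- c(out, nxt)
    avail <- setdiff(avail, nxt)
    for (v in succ[[nxt]]) {
      indeg[v] <- indeg[v] - 1L
      if (indeg[v] == 0L) avail <- c(avail, v)
    }
  }
  if (length(out) < length(genes)) {
    # conflicting orders (cycle): fall back to mean relative position
    rest <- setdiff(genes, out)
    out <- c(out, rest[order(pos[rest], rest)])
  }
  out
}

gap_mask_matrix <- function(tab, gene_names, assemblies, present, gaps) {
  gm <- matrix(FALSE, length(gene_names), length(assemblies),
               dimnames = list(gene_names, assemblies))
  if (is.null(gaps) || !nrow(gaps)) return(gm)
  for (a in assemblies) {
    ga <- gaps[gaps$assembly_id == a, , drop = FALSE]
    if (!nrow(ga)) next
    ta <- tab[tab$assembly_id == a, ]
    for (g in gene_names[!present[, a]]) {
      gi <- match(g, gene_names)
      lefts <- gene_names[seq_len(gi - 1)[present[seq_len(gi - 1), a]]]
      rights_idx <- seq_along(gene_names) > gi & present[, a]
      rights <- gene_names[rights_idx]
      lo <- if (length(lefts)) {
        r <- ta[ta$gene_name == lefts[length(lefts)], ]
        min(r$start, r$end)
      } else -Inf
      hi <- if (length(rights)) {
        r <- ta[ta$gene_name == rights[1], ]
        max(r$start, r$end)
      } else Inf
      win <- sort(c(lo, hi))
      if (any(ga$start <= win[2] & ga$end >= win[1])) gm[gi, a] <- TRUE
    }
  }
  gm
}

#' Venn partition of genes across assemblies
#'
#' Counts the genes present in every non-empty subset of assemblies
#' (exactly that subset), plus the shared percentage: genes present in all
#' assemblies over the union, as a rounded integer percentage.
#'
#' @param matrix an `ig_presence` object.
#' @return A list: `partition` (tibble `assemblies` (key `"A+B"`),
#'   `n_genes`), `shared_percentage`, `n_union`, `n_common`.
#' @export
venn_partition <- function(matrix) {
  stopifnot(inherits(matrix, "ig_presence"))
  pres <- matrix$present
  if (ncol(pres) < 2) abort("venn_partition needs at least 2 assemblies")
  key <- apply(pres, 1, function(r) paste(colnames(pres)[r], collapse = "+"))
  counts <- table(key[key != ""])
  subsets <- unlist(lapply(seq_along(matrix$assemblies), function(k) {
    utils::combn(matrix$assemblies, k, paste, collapse = "+", simplify = TRUE)
  }))
  partition <- tibble(assemblies = subsets,
                      n_genes = as.integer(counts[subsets]))
  partition$n_genes[is.na(partition$n_genes)] <- 0L
  n_union <- sum(rowSums(pres) > 0)
  n_common <- sum(rowSums(pres) == ncol(pres))
  list(partition = partition,
       shared_percentage = round(100 * n_common / n_union),
       n_union = n_union, n_common = n_common)
}

#' Allele polymorphism rate across assemblies
#'
#' The fraction of union genes whose allele set over the assemblies where
#' the gene is present contains at least two distinct alleles (by core
#' sequence), as a rounded integer percentage. A gene seen once is
#' monomorphic.
#'
#' @param matrix an `ig_presence` object.
#' @return A list: `percentage`, `n_polymorphic`, `n_union`, `per_gene`
#'   (tibble `gene_name`, `n_alleles`, `polymorphic`).
#' @export
polymorphism_stats <- function(matrix) {
  stopifnot(inherits(matrix, "ig_presence"))
  per_gene <- tibble(
    gene_name = matrix$gene_names,
    n_alleles = apply(matrix$allele_of, 1,
                      function(r) length(unique(r[!is.na(r)]))),
    n_observed = rowSums(matrix$present)) |>
    mutate(polymorphic = .data$n_alleles >= 2)
  n_union <- nrow(per_gene)
  n_poly <- sum(per_gene$polymorphic)
  list(percentage = round(100 * n_poly / n_union),
       n_polymorphic = n_poly, n_union = n_union, per_gene = per_gene)
}

#' Call copy number variations across assemblies
#'
#' A candidate CNV region is a maximal run of union genes each absent from
#' at least one assembly and present in at least one, with no gap-masked
#' absence anywhere in the run (absence behind an assembly gap is missing
#' evidence and disqualifies the run). A region whose genes all lie between
#' the limit genes of a known CNV definition takes the known name;
#' remaining regions are named `CNVp1`, `CNVp2`, ... 5' to 3'.
#'
#' @param matrix an `ig_presence` object.
#' @param known optional tibble of known CNV definitions
#'   ([read_cnv_definitions()]).
#' @return A tibble of CNV calls: `name`, `locus`, `five_prime_limit`,
#'   `three_prime_limit`, `genes` (list), `known` (logical).
#' @export
call_cnvs <- function(matrix, known = NULL) {
  stopifnot(inherits(matrix, "ig_presence"))
  pres <- matrix$present
  gm <- matrix$gap_masked
  variable <- rowSums(pres) > 0 & rowSums(!pres) > 0
  gap_evidence <- rowSums(!pres & gm) > 0
  runs <- split_runs(which(variable))
  calls <- list()
  for (run in runs) {
    if (any(gap_evidence[run])) next
    run_genes <- matrix$gene_names[run]
    lim5 <- if (min(run) > 1) matrix$gene_names[min(run) - 1] else NA_character_
    lim3 <- if (max(run) < nrow(pres)) matrix$gene_names[max(run) + 1] else NA_character_
    name <- NA_character_
    if (!is.null(known) && nrow(known)) {
      for (nm in unique(known$name)) {
        kd <- known[known$name == nm, ][1, ]
        i5 <- match(kd$five_prime_limit_gene, matrix$gene_names)
        i3 <- match(kd$three_prime_limit_gene, matrix$gene_names)
        if (is.na(i5) || is.na(i3)) next
        lo <- min(i5, i3); hi <- max(i5, i3)
        if (min(run) > lo && max(run) < hi) { name <- nm; break }
      }
    }
    calls[[length(calls) + 1L]] <- tibble(
      name = name, locus = matrix$locus, five_prime_limit = lim5,
      three_prime_limit = lim3, genes = list(run_genes), known = !is.na(name))
  }
  if (!length(calls)) {
    return(tibble(name = character(), locus = character(),
                  five_prime_limit = character(), three_prime_limit = character(),
                  genes = list(), known = logical()))
  }
  out <- bind_rows(calls)
  k <- 0L
  for (i in seq_len(nrow(out))) {
    if (is.na(out$name[i])) {
      k <- k + 1L
      out$name[i] <- paste0("CNVp", k)
    }
  }
  out
}

#' Enumerate the forms of a CNV across assemblies
#'
#' The form of a CNV in one assembly is the exact gene content between the
#' 5' and 3' limit genes. Contents matching a known form take its letter;
#' novel contents get new letters continuing alphabetically after the
#' maximum known letter (then `AA`, `AB`, ...), in order of first
#' occurrence over the assembly input order. Identical contents always
#' share one letter.
#'
#' @param cnv one row of [call_cnvs()] output.
#' @param matrix the `ig_presence` object the CNV was called from.
#' @param known_forms optional named list: form letter -> character vector
#'   of gene content.
#' @return A tibble `assembly_id`, `form`, `content` (list), `novel`.
#' @export
enumerate_cnv_forms <- function(cnv, matrix, known_forms = NULL) {
  stopifnot(inherits(matrix, "ig_presence"))
  i5 <- if (!is.na(cnv$five_prime_limit)) match(cnv$five_prime_limit, matrix$gene_names) else 0L
  i3 <- if (!is.na(cnv$three_prime_limit)) match(cnv$three_prime_limit, matrix$gene_names) else length(matrix$gene_names) + 1L
  inside <- seq_along(matrix$gene_names) > i5 & seq_along(matrix$gene_names) < i3
  known_forms <- known_forms %||% list()
  next_k <- if (length(known_forms)) {
    max(map_int(names(known_forms), letters_to_int))
  } else 0L
  seen <- list()
  out <- list()
  for (a in matrix$assemblies) {
    content <- matrix$gene_names[inside & matrix$present[, a]]
    letter <- NULL
    for (nm in names(known_forms)) {
      if (identical(unname(content), unname(known_forms[[nm]]))) { letter <- nm; break }
    }
    novel <- is.null(letter)
    if (novel) {
      for (nm in names(seen)) {
        if (identical(unname(content), seen[[nm]])) { letter <- nm; break }
      }
    }
    if (is.null(letter)) {
      next_k <- next_k + 1L
      letter <- int_to_letters(next_k)
      seen[[letter]] <- content
    }
    out[[length(out) + 1L]] <- tibble(assembly_id = a, form = letter,
                                      content = list(content), novel = novel)
  }
  bind_rows(out)
}

#' Compare locus annotations across assemblies
#'
#' Runs the whole comparison stage: presence matrix, Venn partition and
#' shared-gene percentage, allele polymorphism rate, CNV calls with form
#' enumeration.
#'
#' @param annotations a list of `ig_annotation` objects (same locus), or a
#'   list of gene tables (tibbles).
#' @param cnv_definitions optional known-CNV definition tibble
#'   ([read_cnv_definitions()]).
#' @return An object of class `ig_comparison`: list with `presence`,
#'   `venn`, `polymorphism`, `cnvs` (calls tibble), `forms` (named list of
#'   per-CNV form tibbles), `stars` (per gene/allele star confidence).
#' @export
compare_annotations <- function(annotations, cnv_definitions = NULL) {
  is_ann <- map_lgl(annotations, inherits, "ig_annotation")
  tables <- map(seq_along(annotations), function(i) {
    if (is_ann[i]) tidy.ig_annotation(annotations[[i]]) else annotations[[i]]
  })
  gaps <- bind_rows(map(seq_along(annotations), function(i) {
    if (is_ann[i]) {
      g <- annotations[[i]]$gaps
      if (nrow(g)) mutate(g, assembly_id = annotations[[i]]$region$assembly_id)
      else NULL
    } else NULL
  }))
  if (!nrow(gaps)) gaps <- NULL
  pm <- build_presence_matrix(tables, gaps)
  venn <- if (length(pm$assemblies) >= 2) venn_partition(pm) else NULL
  poly <- polymorphism_stats(pm)
  cnvs <- call_cnvs(pm, cnv_definitions)
  forms <- list()
  for (i in seq_len(nrow(cnvs))) {
    kf <- NULL
    if (!is.null(cnv_definitions) && isTRUE(cnvs$known[i])) {
      kd <- cnv_definitions[cnv_definitions$name == cnvs$name[i], ]
      kf <- setNames(kd$genes, kd$form)
    }
    forms[[cnvs$name[i]]] <- enumerate_cnv_forms(cnvs[i, ], pm, kf)
  }
  stars <- allele_stars_table(pm)
  structure(list(presence = pm, venn = venn, polymorphism = poly,
                 cnvs = cnvs, forms = forms, stars = stars),
            class = "ig_comparison")
}

# per gene/allele star confidence: number of distinct assemblies carrying
# the allele (core sequence), capped at 3
allele_stars_table <- function(pm) {
  out <- list()
  for (g in pm$gene_names) {
    row <- pm$allele_of[g, ]
    row <- row[!is.na(row)]
    if (!length(row)) next
    for (core in unique(row)) {
      out[[length(out) + 1L]] <- tibble(
        gene_name = g, core_seq = core,
        observations = sum(row == core),
        stars = assign_stars(sum(row == core)))
    }
  }
  bind_rows(out)
}
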