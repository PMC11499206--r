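#' Annotate the IG loci of one assembly
#'
#' Runs the full annotation pipeline for each requested locus: locus
#' localization against the reference set, borne search (IGK/IGL),
#' candidate gene detection and delimitation, RSS and splice checks,
#' functionality classification, subgroup and allele assignment, and
#' orthology-based naming with duplicated-bloc and inserted-gene rules.
#'
#' @param assembly a named [Biostrings::DNAStringSet] or a FASTA path.
#' @param refs an `ig_reference_set` covering the loci.
#' @param assembly_id identifier recorded in all outputs.
#' @param loci loci to annotate (default: all loci in `refs`).
#' @param bornes optional tibble of [borne_definition()] rows.
#' @param config see [igloci_config()].
#' @return An object of class `ig_annotation_set`: named list of
#'   `ig_annotation` per locus found; loci not found are reported in
#'   `attr(, "not_found")`. Each `ig_annotation` holds `region` (locus
#'   interval, orientation, delimitation rules), `genes` (ordered gene
#'   calls, chromosome coordinates), `gaps`, `bornes`.
#' @export
annotate_assembly <- function(assembly, refs, assembly_id = "assembly",
                              loci = NULL, bornes = NULL,
                              config = igloci_config()) {
  if (is.character(assembly) && length(assembly) == 1) {
    assembly <- read_assembly(assembly)
  }
  loci <- loci %||% unique(refs$locus)
  out <- list()
  not_found <- character(0)
  for (locus in loci) {
    ann <- tryCatch(
      annotate_locus(assembly, refs, locus, assembly_id, bornes, config),
      igloci_locus_not_found = function(e) {
        message("locus ", locus, " not found in ", assembly_id)
        NULL
      })
    if (is.null(ann)) not_found <- c(not_found, locus) else out[[locus]] <- ann
  }
  structure(out, not_found = not_found, class = "ig_annotation_set")
}

annotate_locus <- function(assembly, refs, locus, assembly_id, bornes,
                           config) {
  lrefs <- refs[refs$locus == locus, ]
  attr(lrefs, "gene_order") <- intersect(attr(refs, "gene_order"),
                                         lrefs$gene_name)
  region <- localize_locus(assembly, lrefs, locus, config)
  region$assembly_id <- assembly_id
  lbornes <- if (!is.null(bornes)) bornes[bornes$locus == locus, ] else NULL
  bornes_found <- if (locus == "IGH") list() else
    find_bornes(assembly, region, lbornes, config)
  chrom_len <- base::nchar(as.character(assembly[[region$seq_id]]))
  margin <- max(config$flank_5, config$flank_3_igh, config$flank) + 2000L
  es <- max(1L, region$start - margin)
  ee <- min(chrom_len, region$end + margin)
  o <- region$orientation
  ext_seq <- extract_locus_sequence(assembly, region$seq_id, es, ee, o)
  ext2chrom <- function(s, e) chrom_interval_from_locus(s, e, es, ee, o)
  hits <- scan_candidates(ext_seq, lrefs, config)
  calls <- delimit_hits(ext_seq, hits, lrefs, locus, config)
  if (!nrow(calls)) {
    abort(paste0("locus not found: no gene call for ", locus),
          class = "igloci_locus_not_found")
  }
  # classification
  calls$functionality <- NA_character_
  calls$subgroup <- NA_character_
  calls$allele <- NA_character_
  for (i in seq_len(nrow(calls))) {
    cl <- assign_functionality(calls[i, ], lrefs)
    calls$functionality[i] <- cl$functionality
    calls$reasons[i] <- cl$reasons
    if (calls$gene_type[i] == "V") {
      # fast path: the scan's best hit is the highest-identity reference,
      # so its subgroup applies whenever its identity clears the threshold
      if (calls$identity[i] >= config$subgroup) {
        calls$subgroup[i] <-
          lrefs$subgroup[match(calls$best_hit[i], lrefs$gene_name)]
      } else {
        calls$subgroup[i] <- assign_subgroup(calls[i, ], lrefs, config)
      }
    }
    known <- lrefs[lrefs$gene_name == calls$best_hit[i], ]
    if (nrow(known)) {
      m <- match_allele(calls[i, ], known)
      calls$allele[i] <- if (identical(m$allele, "new")) "new" else
        sprintf("%02d", m$allele)
    } else {
      calls$allele[i] <- "new"
    }
  }
  # nomenclature (calls are already 5'->3' in locus orientation)
  naming <- assign_gene_names(calls, attr(lrefs, "gene_order"),
                              subgroups = calls$subgroup, config)
  calls$assigned_name <- naming$base_name
  calls$provenance <- naming$provenance
  calls$provenance[is.na(calls$provenance)] <- "ortholog"
  calls$synteny_support <- naming$synteny_support
  # locus delimitation from terminal genes
  fg <- calls[1, ]; lg <- calls[nrow(calls), ]
  fg_chrom <- ext2chrom(fg$sense_start, fg$sense_end)
  lg_chrom <- ext2chrom(lg$sense_start, lg$sense_end)
  dl <- delimit_locus(region, bornes_found,
                      tibble(start = fg_chrom$start, end = fg_chrom$end),
                      tibble(start = lg_chrom$start, end = lg_chrom$end),
                      chrom_len, config)
  # gaps (in extracted frame -> chromosome)
  gaps <- find_gaps(ext_seq, config$gap_min)
  if (nrow(gaps)) {
    gc <- ext2chrom(gaps$start, gaps$end)
    gaps$start <- gc$start; gaps$end <- gc$end
    gaps <- gaps |>
      filter(.data$start <= dl$end, .data$end >= dl$start) |>
      mutate(seq_id = region$seq_id, .before = 1)
  } else {
    gaps$seq_id <- character(0)
  }
  # chromosome coordinates for genes, exons and RSS motifs
  L_ext <- base::nchar(ext_seq)
  calls$seq_id <- region$seq_id
  gi <- ext2chrom(calls$sense_start, calls$sense_end)
  calls$start <- gi$start; calls$end <- gi$end
  calls$strand <- ifelse((calls$strand == "sense") == (o == "FWD"),
                         "FWD", "REV")
  conv_feat <- function(tb, frame) {
    if (is.null(tb) || !nrow(tb)) return(tb)
    s <- tb$start; e <- tb$end
    if (frame == "antisense") {  # frame coords -> sense ext coords
      s2 <- L_ext - e + 1; e2 <- L_ext - s + 1
      s <- s2; e <- e2
    }
    ci <- ext2chrom(s, e)
    tb$start <- ci$start; tb$end <- ci$end
    arrange(tb, .data$start)
  }
  frames <- ifelse((calls$strand == "FWD") == (o == "FWD"), "sense", "antisense")
  calls$exons <- map2(calls$exons, frames, conv_feat)
  calls$rss <- map2(calls$rss, frames, conv_feat)
  calls$spans_gap <- map_lgl(seq_len(nrow(calls)), function(i) {
    nrow(gaps) > 0 && any(gaps$start <= calls$end[i] & gaps$end >= calls$start[i])
  })
  calls$stars <- 1L
  region_tbl <- tibble(assembly_id = assembly_id, locus = locus,
                       seq_id = region$seq_id, start = dl$start,
                       end = dl$end, orientation = o, rule_5 = dl$rule_5,
                       rule_3 = dl$rule_3,
                       length = dl$end - dl$start + 1)
  structure(list(region = region_tbl,
                 genes = calls |> select(-"sense_start", -"sense_end"),
                 gaps = gaps, bornes = bornes_found),
            class = "ig_annotation")
}

#' @export
print.ig_annotation <- function(x, ...) {
  r <- x$region
  cat(sprintf("IG locus annotation: %s %s %s:%s-%s (%s), %d genes, %d gap(s)\n",
              r$assembly_id, r$locus, r$seq_id,
              format(r$start, big.mark = ","), format(r$end, big.mark = ","),
              r$orientation, nrow(x$genes), nrow(x$gaps)))
  tb <- table(x$genes$gene_type)
  cat("  gene types: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  tb <- table(x$genes$functionality)
  cat("  functionality: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ig_annotation_set <- function(x, ...) {
  cat("IG annotation set:", length(x), "locus/loci annotated\n")
  for (ann in x) print(ann)
  nf <- attr(x, "not_found")
  if (length(nf)) cat("  not found:", paste(nf, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ig_comparison <- function(x, ...) {
  cat(sprintf("IG locus comparison: %s, %d assemblies, %d union genes\n",
              x$presence$locus, length(x$presence$assemblies),
              length(x$presence$gene_names)))
  if (!is.null(x$venn)) {
    cat(sprintf("  shared genes: %d/%d (%d%%)\n", x$venn$n_common,
                x$venn$n_union, x$venn$shared_percentage))
  }
  cat(sprintf("  polymorphic genes: %d/%d (%d%%)\n",
              x$polymorphism$n_polymorphic, x$polymorphism$n_union,
              x$polymorphism$percentage))
  cat(sprintf("  CNV calls: %s\n",
              if (nrow(x$cnvs)) paste(x$cnvs$name, collapse = ", ") else "none"))
  invisible(x)
}
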