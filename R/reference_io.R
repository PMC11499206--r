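#' Read a genome assembly FASTA
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are upper-cased and validated against the `{A,C,G,T,N}`
#' alphabet. Runs of `N` (assembly gaps) are preserved verbatim.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_assembly <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  seqs <- tryCatch(readBStringSet(path),
                   error = function(e) abort(paste0("FASTA format error in ",
                                                    path, ": ", conditionMessage(e))))
  if (length(seqs) == 0) abort(paste0("FASTA format error: ", path, " is empty"))
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    abort(paste0("FASTA format error: duplicate sequence id '",
                 ids[duplicated(ids)][1], "' in ", path))
  }
  chars <- toupper(as.character(seqs))
  bad <- regexpr("[^ACGTN]", chars)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("FASTA format error: non-IUPAC character in '%s' at offset %d",
                  ids[i], bad[i]))
  }
  out <- DNAStringSet(chars)
  names(out) <- ids
  out
}

#' Read a reference gene/allele set from FASTA with structured headers
#'
#' Each record header carries seven pipe-delimited fields:
#' `gene_name|allele|gene_type|locus|subgroup|functionality|region_label`.
#' Records sharing `gene_name` and `allele` are merged into one reference
#' allele whose `regions` are an ordered, named vector of sequences
#' (V alleles: `L-PART1` then `V-EXON`; C alleles: exons in genomic order).
#' Clan-level representatives carry a parenthesised subgroup label, e.g.
#' `IGHV(III)`.
#'
#' @param path path to the reference FASTA.
#' @return A tibble of class `ig_reference_set` with one row per allele:
#'   `gene_name`, `allele`, `gene_type`, `locus`, `subgroup`,
#'   `functionality`, `regions` (named character list-column). The attribute
#'   `gene_order` records reference gene order (order of first appearance).
#' @export
read_reference_set <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  seqs <- readBStringSet(path)
  if (length(seqs) == 0) {
    return(empty_reference_set())
  }
  fields <- strsplit(names(seqs), "|", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 7)) {
    abort(sprintf("reference header format error: expected 7 pipe-delimited fields, got %d in '%s'",
                  n_fields[n_fields != 7][1], names(seqs)[n_fields != 7][1]))
  }
  rec <- tibble(
    gene_name = map_chr(fields, 1), allele = as.integer(map_chr(fields, 2)),
    gene_type = map_chr(fields, 3), locus = map_chr(fields, 4),
    subgroup = map_chr(fields, 5), functionality = map_chr(fields, 6),
    region_label = map_chr(fields, 7),
    sequence = toupper(as.character(seqs))
  )
  bad_type <- setdiff(unique(rec$gene_type), c("V", "D", "J", "C"))
  if (length(bad_type)) {
    abort(paste0("reference format error: unknown gene_type '", bad_type[1], "'"))
  }
  dup <- rec |> count(.data$gene_name, .data$allele, .data$region_label) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("reference format error: duplicate region label '%s' for %s*%02d",
                  dup$region_label[1], dup$gene_name[1], dup$allele[1]))
  }
  gene_order <- unique(rec$gene_name)
  out <- rec |>
    group_by(.data$gene_name, .data$allele) |>
    summarise(
      gene_type = .data$gene_type[1], locus = .data$locus[1],
      subgroup = .data$subgroup[1], functionality = .data$functionality[1],
      regions = list(order_regions(setNames(.data$sequence, .data$region_label),
                                   .data$gene_type[1])),
      .groups = "drop"
    ) |>
    arrange(match(.data$gene_name, gene_order), .data$allele)
  validate_reference_set(out)
  attr(out, "gene_order") <- gene_order
  class(out) <- c("ig_reference_set", class(out))
  out
}

empty_reference_set <- function() {
  out <- tibble(gene_name = character(), allele = integer(),
                gene_type = character(), locus = character(),
                subgroup = character(), functionality = character(),
                regions = list())
  attr(out, "gene_order") <- character()
  class(out) <- c("ig_reference_set", class(out))
  out
}

# V regions are ordered L-PART1 then V-EXON; C exons follow genomic order
# CH1, hinges H1..Hn, CH2.., CHS, M*.
order_regions <- function(regions, gene_type) {
  canonical <- c("L-PART1", "V-EXON", "D-REGION", "J-REGION",
                 "CH1", paste0("H", 1:5), "CH2", "CH3", "CH4", "CHS",
                 "M", "M1", "M2")
  regions[order(match(names(regions), canonical))]
}

validate_reference_set <- function(refs) {
  for (i in seq_len(nrow(refs))) {
    labs <- names(refs$regions[[i]])
    tp <- refs$gene_type[i]
    ok <- switch(tp,
      V = all(c("L-PART1", "V-EXON") %in% labs),
      D = identical(labs, "D-REGION"),
      J = identical(labs, "J-REGION"),
      C = any(grepl("^CH|^H[1-5]$|^M", labs)))
    if (!ok) {
      abort(sprintf("reference format error: %s*%02d (%s) has invalid regions [%s]",
                    refs$gene_name[i], refs$allele[i], tp,
                    paste(labs, collapse = ", ")))
    }
  }
  invisible(refs)
}

#' Write a reference set back to structured-header FASTA
#'
#' Inverse of [read_reference_set()]; one record per region.
#' @param refs an `ig_reference_set` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(refs, path) {
  lines <- character(0)
  for (i in seq_len(nrow(refs))) {
    for (lab in names(refs$regions[[i]])) {
      hdr <- paste(refs$gene_name[i], refs$allele[i], refs$gene_type[i],
                   refs$locus[i], refs$subgroup[i], refs$functionality[i],
                   lab, sep = "|")
      lines <- c(lines, paste0(">", hdr), refs$regions[[i]][[lab]])
    }
  }
  writeLines(lines, path)
  invisible(path)
}

gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Write a locus annotation as GFF3
#'
#' Emits one `gene` feature per call plus child `exon` features and RSS
#' features (type `recombination_signal_sequence`), all in chromosome
#' coordinates (1-based inclusive, GFF3 native). Gene attributes carry the
#' assigned name, allele, functionality, star confidence and provenance.
#'
#' @param annotation an `ig_annotation` object (see [annotate_assembly()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(annotation, path) {
  stopifnot(inherits(annotation, "ig_annotation"))
  genes <- annotation$genes
  rows <- character(0)
  ids <- character(0)
  seqid <- annotation$region$seq_id
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gid <- paste0("gene-", g$assigned_name)
    if (gid %in% ids) abort(paste0("duplicate feature id in GFF output: ", gid))
    ids <- c(ids, gid)
    strand <- if (g$strand == "FWD") "+" else "-"
    attrs <- paste0(
      "ID=", gff3_escape(gid),
      ";Name=", gff3_escape(g$assigned_name),
      ";gene_type=", g$gene_type,
      ";allele=", g$allele,
      ";functionality=", g$functionality,
      ";stars=", g$stars,
      ";provenance=", g$provenance)
    rows <- c(rows, paste(seqid, "igloci", "gene", g$start, g$end, ".",
                          strand, ".", attrs, sep = "\t"))
    ex <- g$exons[[1]]
    if (!is.null(ex) && nrow(ex)) {
      ex <- arrange(ex, .data$start)
      for (j in seq_len(nrow(ex))) {
        rows <- c(rows, paste(seqid, "igloci", "exon", ex$start[j], ex$end[j],
                              ".", strand, ".",
                              paste0("ID=", gff3_escape(paste0(gid, "-exon-", j)),
                                     ";Parent=", gff3_escape(gid),
                                     ";exon_label=", gff3_escape(ex$label[j])),
                              sep = "\t"))
      }
    }
    rs <- g$rss[[1]]
    if (!is.null(rs) && nrow(rs)) {
      rs <- arrange(rs, .data$start)
      for (j in seq_len(nrow(rs))) {
        rows <- c(rows, paste(seqid, "igloci", "recombination_signal_sequence",
                              rs$start[j], rs$end[j],
                              formatC(rs$score[j], digits = 3, format = "f"),
                              strand, ".",
                              paste0("ID=", gff3_escape(paste0(gid, "-rss-", j)),
                                     ";Parent=", gff3_escape(gid),
                                     ";spacer_class=", rs$class[j],
                                     ";side=", rs$side[j]),
                              sep = "\t"))
      }
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Write / read the per-assembly gene table (TSV)
#'
#' One row per (assembly, gene, allele) with locus, functionality, star
#' confidence, chromosome interval and naming provenance
#' (`ortholog`/`inserted`/`duplicated`). The table is the interchange format
#' consumed by the comparison module.
#'
#' @param annotations a list of `ig_annotation` objects.
#' @param path output path.
#' @return The table written, invisibly (a tibble).
#' @export
write_gene_table <- function(annotations, path) {
  tab <- purrr::map_dfr(annotations, gene_table_rows)
  readr::write_tsv(tab, path)
  invisible(tab)
}

gene_table_rows <- function(annotation) {
  stopifnot(inherits(annotation, "ig_annotation"))
  g <- annotation$genes
  tibble(assembly_id = annotation$region$assembly_id,
         locus = annotation$region$locus,
         gene_name = g$assigned_name, allele = g$allele,
         gene_type = g$gene_type, functionality = g$functionality,
         stars = g$stars, seq_id = g$seq_id, start = g$start, end = g$end,
         strand = g$strand, provenance = g$provenance,
         spans_gap = g$spans_gap, locus_order = seq_len(nrow(g)))
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    assembly_id = "c", locus = "c", gene_name = "c", allele = "c",
    gene_type = "c", functionality = "c", stars = "i", seq_id = "c",
    start = "d", end = "d", strand = "c", provenance = "c",
    spans_gap = "l", locus_order = "i"))
}

#' Read a known-CNV definition table
#'
#' TSV with columns `name`, `locus`, `five_prime_limit_gene`,
#' `three_prime_limit_gene`, `form`, `genes` (comma-separated gene content of
#' the form between the limits; empty = full deletion). One row per known
#' form; rows with the same `name` describe one CNV.
#'
#' @param path TSV path.
#' @return A tibble with a `genes` list-column.
#' @export
read_cnv_definitions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c")) |>
    mutate(genes = map(.data$genes, function(x) {
      if (is.na(x) || x == "") character() else strsplit(x, ",", fixed = TRUE)[[1]]
    }))
}

#' Define a locus borne (conserved flanking non-IG gene)
#'
#' IGK and IGL loci are delimited with the help of conserved flanking genes
#' (e.g. PAX8/RPIA for IGK, TOP3B/RSPH14 for IGL); IGH has none.
#'
#' @param locus `"IGK"` or `"IGL"`.
#' @param side `"five_prime"` or `"three_prime"`.
#' @param gene_symbol the flanking gene's symbol.
#' @param probe_sequence nucleotide probe used to locate the gene.
#' @return A one-row tibble.
#' @export
borne_definition <- function(locus, side, gene_symbol, probe_sequence) {
  if (locus == "IGH") abort("IGH has no locus bornes")
  stopifnot(side %in% c("five_prime", "three_prime"))
  tibble(locus = locus, side = side, gene_symbol = gene_symbol,
         probe_sequence = toupper(probe_sequence))
}

#' Published gorilla IG locus coordinates
#'
#' Locus positions, orientation, reported sequence lengths and gene counts
#' of the IGH, IGK and IGL loci in the four public gorilla genome
#' assemblies (NCBI chromosome sequences), as shipped in
#' `extdata/gorilla_ig_locus_coordinates.tsv`. The 1-based inclusive
#' coordinate convention reproduces every reported length as
#' `end - start + 1` (see [interval_length()]).
#'
#' @return A tibble with one row per assembly and locus.
#' @examples
#' x <- gorilla_locus_coordinates()
#' all(interval_length(x$start, x$end) == x$reported_length_bp)
#' @export
gorilla_locus_coordinates <- function() {
  path <- system.file("extdata", "gorilla_ig_locus_coordinates.tsv",
                      package = "igloci", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    assembly_id = "c", locus = "c", chromosome = "c", seq_id = "c",
    start = "d", end = "d", strand = "c", reported_length_bp = "d",
    ig_gene_number = "i"))
}
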