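#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a locus annotation into a gene table
#'
#' One row per gene call with name, allele, functionality, star
#' confidence, chromosome interval and provenance — the same schema as
#' [write_gene_table()].
#'
#' @param x an `ig_annotation`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.ig_annotation <- function(x, ...) {
  gene_table_rows(x) |>
    mutate(core_seq = x$genes$core_seq,
           subgroup = x$genes$subgroup,
           synteny_support = x$genes$synteny_support)
}

#' @rdname tidy.ig_annotation
#' @exportS3Method generics::tidy
tidy.ig_annotation_set <- function(x, ...) {
  bind_rows(lapply(unclass(x), tidy.ig_annotation))
}

#' One-row summary of a locus annotation
#'
#' @param x an `ig_annotation`.
#' @param ... unused.
#' @return A tibble: locus, interval, orientation, length, gene counts by
#'   type and functionality, gap count.
#' @exportS3Method generics::glance
glance.ig_annotation <- function(x, ...) {
  g <- x$genes
  tibble(assembly_id = x$region$assembly_id, locus = x$region$locus,
         seq_id = x$region$seq_id, start = x$region$start,
         end = x$region$end, orientation = x$region$orientation,
         length = x$region$length, n_genes = nrow(g),
         n_v = sum(g$gene_type == "V"), n_d = sum(g$gene_type == "D"),
         n_j = sum(g$gene_type == "J"), n_c = sum(g$gene_type == "C"),
         n_functional = sum(g$functionality == "functional"),
         n_orf = sum(g$functionality == "ORF"),
         n_pseudogene = sum(g$functionality == "pseudogene"),
         n_gaps = nrow(x$gaps))
}

#' Tidy a cross-assembly comparison
#'
#' Long gene-by-assembly presence tibble with gap masking.
#'
#' @param x an `ig_comparison`.
#' @param ... unused.
#' @return A tibble `gene_name`, `assembly_id`, `present`, `gap_masked`.
#' @exportS3Method generics::tidy
tidy.ig_comparison <- function(x, ...) {
  x$presence$long
}

#' One-row summary of a comparison
#'
#' @param x an `ig_comparison`.
#' @param ... unused.
#' @return A tibble with union/common gene counts, shared and polymorphism
#'   percentages and CNV call count.
#' @exportS3Method generics::glance
glance.ig_comparison <- function(x, ...) {
  tibble(locus = x$presence$locus,
         n_assemblies = length(x$presence$assemblies),
         n_union = length(x$presence$gene_names),
         n_common = x$venn$n_common %||% NA_integer_,
         shared_percentage = x$venn$shared_percentage %||% NA_real_,
         n_polymorphic = x$polymorphism$n_polymorphic,
         polymorphic_percentage = x$polymorphism$percentage,
         n_cnvs = nrow(x$cnvs))
}
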