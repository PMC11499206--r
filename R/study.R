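#' Built-in synthetic study scenarios
#'
#' The package ships three standard desk-scale study designs used by its
#' validation suite: a four-assembly detection/classification study with a
#' defect mix covering every functionality reason code and the 5/2/4 hinge
#' designs plus the 15-bp (in-frame) and 2-bp (frameshift) hinge
#' deletions; a nomenclature study with a duplicated bloc and inserted
#' V/D/J-C genes; and a CNV study with a known CNV, a planted multi-gene
#' deletion and a gap-masked absence. Each is deterministic for its seed.
#'
#' @param seed integer seed driving every random choice.
#' @return A list with the elements described per function.
#' @name ig_studies
NULL

#' @describeIn ig_studies Four assemblies, one IGH-like locus of ~53 genes
#'   (32 V, 8 D, 5 J, 8 C), 1% allelic substitution, full defect mix.
#'   Returns `refs`, `sim`, `defects` and the `assembly_ids`.
#' @export
simulate_detection_study <- function(seed = 1) {
  refs <- generate_reference_set("IGH", n_v = 32, n_d = 8, n_j = 5, n_c = 8,
                                 seed = seed)
  go <- attr(refs, "gene_order")
  vn <- go[1:32]; dn <- go[33:40]; jn <- go[41:45]; cn <- go[46:53]
  # cn: IGHM(0) IGHG3A(5) IGHG3B(2) IGHG3C(4) IGHG1(1) IGHA1(1) IGHA2(1) IGHE(0)
  defects <- tibble::tribble(
    ~gene_name, ~code,
    vn[3], "STOP_CODON",
    vn[7], "FRAMESHIFT",
    vn[11], "DEFECTIVE_SPLICE",
    vn[15], "DEFECTIVE_RSS",
    vn[19], "TRUNCATED",
    vn[23], "REPEAT_INSERTION",
    vn[27], "NO_INIT_CODON",
    dn[3], "DEFECTIVE_RSS",
    jn[2], "NO_CANONICAL_MOTIF",
    jn[4], "DEFECTIVE_RSS",
    cn[6], "HINGE_DEL_15",
    cn[5], "HINGE_DEL_2",
    cn[7], "MISSING_EXON",
    cn[8], "REARRANGED")
  assembly_ids <- paste0("asm", 1:4)
  sim <- generate_assembly_set(refs, assembly_ids = assembly_ids,
                               substitution_rate = 0.01, defects = defects,
                               seed = seed + 1)
  list(refs = refs, sim = sim, defects = defects,
       assembly_ids = assembly_ids,
       hinge_del_genes = c(inframe = cn[6], frameshift = cn[5]))
}

#' @describeIn ig_studies Noiseless nomenclature study: an IGH-like locus
#'   with a three-gene bloc duplicated at a target identity (default
#'   99.8%), an inserted V gene, two inserted D genes, and an IGL-like
#'   locus with an extra J-C tandem in one assembly only. Returns `igh`
#'   (refs + sim) and `igl` (refs + sim).
#' @param bloc_identity target identity of the duplicated bloc.
#' @export
simulate_nomenclature_study <- function(seed = 1, bloc_identity = 0.998) {
  refs <- generate_reference_set("IGH", n_v = 10, n_d = 4, n_j = 3, n_c = 4,
                                 seed = seed)
  go <- attr(refs, "gene_order")
  vn <- go[1:10]; dn <- go[11:14]
  sim <- generate_assembly_set(
    refs, assembly_ids = "n1",
    duplicated_bloc = list(genes = vn[4:6], identity = bloc_identity),
    inserted = tibble::tibble(
      after_gene = c(vn[8], dn[2], dn[2]),
      source_gene = c(vn[2], dn[4], dn[4]),
      divergence = 0.06),
    seed = seed + 2)
  refs_l <- generate_reference_set("IGL", n_v = 4, n_d = 0, n_j = 3, n_c = 3,
                                   seed = seed + 3)
  sim_l <- generate_assembly_set(
    refs_l, assembly_ids = c("p1", "p2"),
    inserted = tibble::tibble(
      after_gene = "IGLC2", source_gene = c("IGLJ2", "IGLC2"),
      divergence = 0.01, assemblies = list("p2", "p2")),
    seed = seed + 4)
  list(igh = list(refs = refs, sim = sim, bloc_genes = vn[4:6]),
       igl = list(refs = refs_l, sim = sim_l))
}

#' @describeIn ig_studies CNV study: three assemblies of a 22-gene
#'   IGH-like locus; a known CNV (named `CNV3`, known forms `A`, `C`, `G`)
#'   contains a six-gene deletion in one assembly; a two-gene region in
#'   another assembly is replaced by an assembly gap (which must not
#'   become a CNV). Returns `refs`, `sim`, `cnv_definitions`,
#'   `deleted_genes`, `gap_genes`.
#' @export
simulate_cnv_study <- function(seed = 1) {
  refs <- generate_reference_set("IGH", n_v = 12, n_d = 4, n_j = 3, n_c = 3,
                                 seed = seed + 5)
  go <- attr(refs, "gene_order")
  vn <- go[1:12]
  deleted <- vn[4:9]
  gap_genes <- vn[11:12]
  cnv_definitions <- tibble::tibble(
    name = "CNV3", locus = "IGH",
    five_prime_limit_gene = vn[3], three_prime_limit_gene = vn[10],
    form = c("A", "C", "G"),
    genes = list(deleted, deleted[1:4], deleted[5:6]))
  sim <- generate_assembly_set(
    refs, assembly_ids = paste0("c", 1:3),
    cnv_deletions = tibble::tibble(assembly_id = "c2", genes = list(deleted)),
    gap_ranges = tibble::tibble(assembly_id = "c3", genes = list(gap_genes)),
    polymorphic_genes = vn[1:4],
    seed = seed + 6)
  list(refs = refs, sim = sim, cnv_definitions = cnv_definitions,
       deleted_genes = deleted, gap_genes = gap_genes)
}
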