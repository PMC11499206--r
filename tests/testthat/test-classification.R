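PSEUDO <- c("STOP_CODON", "FRAMESHIFT", "TRUNCATED", "REPEAT_INSERTION",
            "REARRANGED", "MISSING_EXON", "NO_INIT_CODON")
ORFISH <- c("DEFECTIVE_SPLICE", "DEFECTIVE_RSS", "NO_CANONICAL_MOTIF")

test_that("functionality is a total function over the reason-code power set", {
  codes <- c(PSEUDO, ORFISH)
  # every subset of the ten codes maps deterministically per the algebra
  for (mask in 0:(2^length(codes) - 1)) {
    subset <- codes[bitwAnd(mask, 2^(seq_along(codes) - 1)) > 0]
    state <- functionality_state(subset)
    expected <- if (any(subset %in% PSEUDO)) "pseudogene"
    else if (length(subset)) "ORF" else "functional"
    expect_equal(state, expected)
  }
  expect_error(functionality_state("NOT_A_CODE"), "unknown reason code")
})

test_that("star confidence counts distinct genomic sequences, capped at 3", {
  expect_equal(assign_stars(1), 1L)
  expect_equal(assign_stars(2), 2L)
  expect_equal(assign_stars(3), 3L)
  expect_equal(assign_stars(4), 3L)
  expect_error(assign_stars(0), ">= 1")
})

test_that("allele matching is exact on core regions with tie to lower number", {
  core <- rand_seq(90, seed = 7)
  core2 <- mutate_k(core, 2, seed = 8)
  known <- tibble::tibble(
    gene_name = "IGHV1-1", allele = c(1L, 2L), gene_type = "V",
    locus = "IGH", subgroup = "IGHV1", functionality = "functional",
    regions = list(c("L-PART1" = "ATG", "V-EXON" = core),
                   c("L-PART1" = "ATG", "V-EXON" = core2)))
  # exact match to allele 1
  m <- match_allele(call_from_seq(core), known)
  expect_equal(m$allele, 1L)
  expect_equal(nrow(m$differences), 0)
  # novel allele: numbered after the max existing, nearest reported
  novel <- mutate_k(core, 1, seed = 9)
  m2 <- match_allele(call_from_seq(novel), known)
  expect_equal(m2$allele, "new")
  expect_equal(m2$new_number, 3L)
  expect_equal(m2$nearest, 1L)
  expect_equal(nrow(m2$differences), 1)
  expect_equal(m2$differences$type, "sub")
  # equidistant from both alleles: nearest is the lower allele number
  chars <- strsplit(core, "")[[1]]
  pos2 <- which(strsplit(core2, "")[[1]] != chars)
  mid <- core
  substr(mid, pos2[1], pos2[1]) <- substr(core2, pos2[1], pos2[1])
  d1 <- as.integer(adist(mid, core)); d2 <- as.integer(adist(mid, core2))
  expect_equal(d1, d2)  # constructed to be equidistant
  m3 <- match_allele(call_from_seq(mid), known)
  expect_equal(m3$allele, "new")
  expect_equal(m3$nearest, 1L)
})

test_that("numbering projection of a sequence onto itself is the identity", {
  core <- paste(rep(c("TGC", "TGG", "GCA", "AAA"), 10), collapse = "")
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(core)))
  num <- project_unique_numbering(call_from_seq(core), seq_len(nchar(ref_aa)),
                                  ref_aa)
  expect_equal(num$position, as.character(seq_len(nchar(ref_aa))))
  expect_equal(paste(num$aa, collapse = ""), ref_aa)
})

test_that("a one-codon deletion drops exactly one reference position", {
  # oracle by construction: removing codon 5 of the call leaves reference
  # positions 1..4, 6..40
  set.seed(13)
  codons <- sample(setdiff(apply(expand.grid(c("A","C","G","T"),
                                             c("A","C","G","T"),
                                             c("A","C","G","T")),
                                 1, paste, collapse = ""),
                           c("TAA", "TAG", "TGA")), 40, replace = TRUE)
  core <- paste(codons, collapse = "")
  del <- paste(codons[-5], collapse = "")
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(core)))
  num <- project_unique_numbering(call_from_seq(del), seq_len(40), ref_aa)
  expect_equal(nrow(num), 39)
  expect_false("5" %in% num$position)
  expect_true(all(as.character(c(1:4, 6:40)) %in% num$position))
})

test_that("numbering is refused below 40% identity", {
  core <- paste(rep("GCA", 40), collapse = "")   # poly-A protein
  ref_aa <- paste(rep("W", 40), collapse = "")
  expect_error(project_unique_numbering(call_from_seq(core), 1:40, ref_aa),
               class = "igloci_numbering_refused")
})

test_that("subgroup assignment honours thresholds and clan fallback", {
  base <- rand_seq(300, seed = 20)
  refs <- tibble::tibble(
    gene_name = c("IGHV1-1", "IGHV2-1", "IGHV(III)-1"),
    allele = 1L, gene_type = "V", locus = "IGH",
    subgroup = c("IGHV1", "IGHV2", "IGHV(III)"),
    functionality = "functional",
    regions = list(c("L-PART1" = "ATG", "V-EXON" = base),
                   c("L-PART1" = "ATG", "V-EXON" = mutate_k(base, 60, 21)),
                   c("L-PART1" = "ATG", "V-EXON" = mutate_k(base, 15, 22))))
  # identical to the IGHV1 member: subgroup
  expect_equal(assign_subgroup(call_from_seq(base), refs), "IGHV1")
  # ~72% best identity: clan of the best clan-level representative
  far <- mutate_k(base, 84, seed = 23)   # 216/300 = 72% to IGHV1-1
  expect_equal(assign_subgroup(call_from_seq(far), refs), "IGHV(III)")
  # dissimilar: unclassified
  expect_equal(assign_subgroup(call_from_seq(rand_seq(300, 99)), refs),
               "unclassified")
})

test_that("subgroup ties break lexicographically", {
  base <- rand_seq(120, seed = 30)
  refs <- tibble::tibble(
    gene_name = c("IGHV2-1", "IGHV1-1"), allele = 1L, gene_type = "V",
    locus = "IGH", subgroup = c("IGHV2", "IGHV1"),
    functionality = "functional",
    regions = list(c("L-PART1" = "ATG", "V-EXON" = base),
                   c("L-PART1" = "ATG", "V-EXON" = base)))
  expect_equal(assign_subgroup(call_from_seq(base), refs), "IGHV1")
})

test_that("designed defects map to their designed functionality state", {
  # confusion matrix over the annotated defect scenario is diagonal
  refs <- generate_reference_set("IGH", n_v = 8, n_d = 3, n_j = 3, n_c = 4,
                                 seed = 42)
  go <- attr(refs, "gene_order")
  defects <- tibble::tibble(
    gene_name = c(go[2], go[3], go[4], go[5], go[10], go[13], go[16]),
    code = c("STOP_CODON", "FRAMESHIFT", "DEFECTIVE_SPLICE", "DEFECTIVE_RSS",
             "DEFECTIVE_RSS", "NO_CANONICAL_MOTIF", "HINGE_DEL_2"))
  sim <- generate_assembly_set(refs, assembly_ids = "c1", defects = defects,
                               seed = 31)
  ann <- annotate_assembly(sim$assemblies$c1, refs, assembly_id = "c1")
  tt <- tidy(ann)
  truth <- sim$truth$genes
  expect_equal(tt$functionality, truth$functionality)
  cm <- table(truth = truth$functionality, called = tt$functionality)
  expect_true(all(cm[row(cm) != col(cm)] == 0))
})
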