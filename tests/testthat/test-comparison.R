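# Build a presence object directly from per-assembly gene name lists (and
# optional allele/core labels), bypassing the pipeline.
presence_from_sets <- function(sets, alleles = NULL, gaps = NULL) {
  tables <- purrr::imap(sets, function(genes, aid) {
    tibble::tibble(
      assembly_id = aid, locus = "IGH", gene_name = genes,
      allele = "01", gene_type = "V", functionality = "functional",
      stars = 1L, seq_id = "chr", start = seq_along(genes) * 1000,
      end = seq_along(genes) * 1000 + 500, strand = "FWD",
      provenance = "ortholog", spans_gap = FALSE,
      locus_order = seq_along(genes),
      core_seq = if (is.null(alleles)) paste0("SEQ_", genes)
      else alleles[[aid]])
  })
  build_presence_matrix(tables, gaps)
}

test_that("venn partition matches brute-force set algebra", {
  pm <- presence_from_sets(list(
    a1 = c("G1", "G2", "G3"), a2 = c("G1", "G2"), a3 = c("G1", "G2", "G3")))
  v <- venn_partition(pm)
  expect_equal(v$n_common, 2)
  expect_equal(v$n_union, 3)
  expect_equal(v$shared_percentage, 67)
  part <- setNames(v$partition$n_genes, v$partition$assemblies)
  expect_equal(unname(part[["a1+a2+a3"]]), 2L)
  expect_equal(unname(part[["a1+a3"]]), 1L)
  expect_equal(sum(v$partition$n_genes), v$n_union)
})

test_that("identical and disjoint assemblies give 100% and 0%", {
  pm <- presence_from_sets(list(a = c("G1", "G2"), b = c("G1", "G2")))
  expect_equal(venn_partition(pm)$shared_percentage, 100)
  pm2 <- presence_from_sets(list(a = c("G1", "G2"), b = c("G3", "G4")))
  expect_equal(venn_partition(pm2)$shared_percentage, 0)
})

test_that("venn partition counts sum to the union for random matrices", {
  set.seed(1234)
  for (rep in 1:1000) {
    n_genes <- sample(2:12, 1)
    n_asm <- sample(2:4, 1)
    m <- matrix(runif(n_genes * n_asm) < 0.6, n_genes, n_asm)
    # every gene present somewhere, every assembly non-empty
    m[rowSums(m) == 0, 1] <- TRUE
    m[1, colSums(m) == 0] <- TRUE
    sets <- lapply(seq_len(n_asm), function(a) paste0("G", which(m[, a])))
    names(sets) <- paste0("asm", seq_len(n_asm))
    v <- venn_partition(presence_from_sets(sets))
    expect_equal(sum(v$partition$n_genes), v$n_union)
    expect_equal(v$n_union, n_genes)
  }
})

test_that("polymorphism counts genes with at least two distinct alleles", {
  sets <- list(a = paste0("G", 1:10), b = paste0("G", 1:10))
  alleles <- list(a = paste0("S", 1:10),
                  b = c(paste0("X", 1:4), paste0("S", 5:10)))
  pm <- presence_from_sets(sets, alleles)
  ps <- polymorphism_stats(pm)
  expect_equal(ps$percentage, 40)
  expect_equal(ps$n_polymorphic, 4)
  # all monomorphic
  pm2 <- presence_from_sets(sets, list(a = paste0("S", 1:10),
                                       b = paste0("S", 1:10)))
  expect_equal(polymorphism_stats(pm2)$percentage, 0)
  # a gene present once counts as monomorphic
  pm3 <- presence_from_sets(list(a = c("G1", "G2"), b = "G1"),
                            list(a = c("S1", "S2"), b = "S1"))
  expect_equal(polymorphism_stats(pm3)$n_polymorphic, 0)
})

test_that("CNV calls respect known limits, CNVp numbering and the gap rule", {
  sets <- list(a = paste0("G", 1:10),
               b = paste0("G", c(1:3, 7:10)),   # G4-G6 absent
               c = paste0("G", c(1:8, 10)))     # G9 absent
  known <- tibble::tibble(name = "CNV3", locus = "IGH",
                          five_prime_limit_gene = "G3",
                          three_prime_limit_gene = "G7",
                          form = "A", genes = list(paste0("G", 4:6)))
  pm <- presence_from_sets(sets)
  cnvs <- call_cnvs(pm, known)
  expect_equal(nrow(cnvs), 2)
  expect_equal(cnvs$name, c("CNV3", "CNVp1"))  # numbered 5' to 3'
  expect_equal(cnvs$genes[[1]], paste0("G", 4:6))
  expect_equal(cnvs$genes[[2]], "G9")

  # an absence fully explained by an assembly gap is not a CNV
  # in assembly b the flanking present genes sit at 3000-3500 (G3) and
  # 4000-4500 (G7); the gap lies between them
  gaps <- tibble::tibble(assembly_id = "b", seq_id = "chr",
                         start = 3600, end = 3900)
  pmg <- presence_from_sets(list(a = paste0("G", 1:10),
                                 b = paste0("G", c(1:3, 7:10))), gaps = gaps)
  expect_true(any(pmg$gap_masked))
  expect_equal(nrow(call_cnvs(pmg)), 0)
})

test_that("CNV forms reuse known letters and continue after them", {
  sets <- list(a = paste0("G", 1:10),
               b = paste0("G", c(1:3, 7:10)),
               c = paste0("G", c(1:4, 7:10)))
  known_def <- tibble::tibble(
    name = "CNV3", locus = "IGH", five_prime_limit_gene = "G3",
    three_prime_limit_gene = "G7",
    form = c("A", "B", "C", "D", "E", "F", "G"),
    genes = c(list(paste0("G", 4:6)), purrr::map(1:6, ~ paste0("Z", .x))))
  pm <- presence_from_sets(sets)
  cnvs <- call_cnvs(pm, known_def)
  expect_equal(cnvs$name, "CNV3")
  kf <- setNames(known_def$genes, known_def$form)
  forms <- enumerate_cnv_forms(cnvs[1, ], pm, kf)
  # full content matches known form A; the two deletions are novel and
  # continue after the maximum known letter G
  expect_equal(forms$form[forms$assembly_id == "a"], "A")
  expect_equal(forms$form[forms$assembly_id == "b"], "H")
  expect_equal(forms$form[forms$assembly_id == "c"], "I")
  # identical contents share a letter; re-running is stable; appending an
  # assembly with a previously seen form reuses its letter
  sets2 <- c(sets, list(d = paste0("G", c(1:3, 7:10))))
  pm2 <- presence_from_sets(sets2)
  forms2 <- enumerate_cnv_forms(call_cnvs(pm2, known_def)[1, ], pm2, kf)
  expect_equal(forms2$form, c("A", "H", "I", "H"))
})

test_that("letter suffixes roll over past Z", {
  expect_equal(igloci:::int_to_letters(26), "Z")
  expect_equal(igloci:::int_to_letters(27), "AA")
  expect_equal(igloci:::int_to_letters(28), "AB")
  expect_equal(igloci:::letters_to_int("AA"), 27)
})

test_that("duplicate gene names within one assembly are an integrity error", {
  t1 <- presence_from_sets(list(a = "G1"))  # build a valid table first
  tab <- t1$long
  bad <- tibble::tibble(
    assembly_id = "a", locus = "IGH", gene_name = c("G1", "G1"),
    allele = "01", gene_type = "V", functionality = "functional",
    stars = 1L, seq_id = "chr", start = c(1, 2), end = c(10, 20),
    strand = "FWD", provenance = "ortholog", spans_gap = FALSE,
    locus_order = 1:2, core_seq = c("A", "B"))
  expect_error(build_presence_matrix(list(bad)), "integrity error")
})

test_that("comparison of identical annotations: 100% shared, no CNVs", {
  anns <- igk_annotations()
  cmp <- compare_annotations(list(anns[[1]]$IGK, anns[[2]]$IGK))
  expect_equal(cmp$venn$shared_percentage, 100)
  expect_equal(nrow(cmp$cnvs), 0)
  g <- glance(cmp)
  expect_equal(g$n_union, nrow(anns[[1]]$IGK$genes))
})
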