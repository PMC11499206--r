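test_that("interval lengths reproduce the published locus table exactly", {
  x <- gorilla_locus_coordinates()
  expect_equal(nrow(x), 12)
  expect_equal(interval_length(x$start, x$end), x$reported_length_bp)
  # the quoted flagship row: IGH of the Kamilah assembly
  k <- x[x$assembly_id == "Kamilah_GGO_v0" & x$locus == "IGH", ]
  expect_equal(interval_length(k$start, k$end), 1141211)
})

test_that("genomic_interval validates its invariants", {
  gi <- genomic_interval("chr14", 86452632, 87593842, "REV")
  expect_equal(interval_length(gi), 1141211)
  expect_error(genomic_interval("c", 0, 5), "start")
  expect_error(genomic_interval("c", 10, 5), "end")
  expect_error(genomic_interval("c", 1, 5, "minus"), "strand")
})

test_that("read_assembly reads, uppercases and validates FASTA", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr14 some description", strrep("acgt", 25)), p)
  a <- read_assembly(p)
  expect_equal(names(a), "chr14")
  expect_equal(nchar(as.character(a[[1]])), 100)
  expect_equal(as.character(a[[1]]), strrep("ACGT", 25))

  writeLines(c(">x", "ACGTNNNNACGT"), p)
  expect_equal(as.character(read_assembly(p)[[1]]), "ACGTNNNNACGT")

  writeLines(c(">x", "ACGT", ">x", "TTTT"), p)
  expect_error(read_assembly(p), "duplicate sequence id 'x'")

  writeLines(c(">x", "ACGR"), p)
  expect_error(read_assembly(p), "non-IUPAC character in 'x' at offset 4")

  writeLines(character(0), p)
  expect_error(read_assembly(p), "empty|format")
})

test_that("assembly FASTA round-trips byte-identically up to line wrapping", {
  p <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(chrA = rand_seq(257, 1), chrB = paste0(rand_seq(40, 2),
                                                   strrep("N", 120),
                                                   rand_seq(40, 3)))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), p)
  a <- read_assembly(p)
  p2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(a, p2, width = 60)
  b <- read_assembly(p2)
  expect_identical(as.character(a), as.character(b))
  expect_identical(unname(as.character(b)), unname(seqs))
})

test_that("reference set round-trips through structured-header FASTA", {
  refs <- small_refs()
  p <- withr::local_tempfile(fileext = ".fa")
  write_reference_set(refs, p)
  back <- read_reference_set(p)
  expect_equal(back$gene_name, refs$gene_name)
  expect_equal(back$gene_type, refs$gene_type)
  expect_equal(back$regions, refs$regions)
  # V regions are ordered L-PART1 then V-EXON
  v <- back[back$gene_type == "V", ]
  expect_true(all(purrr::map_lgl(v$regions, ~ identical(
    names(.x), c("L-PART1", "V-EXON")))))
})

test_that("reference reader enforces the header contract", {
  p <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">IGHX1|1|X|IGH|IGHX|functional|V-EXON", "ACGT"), p)
  expect_error(read_reference_set(p), "unknown gene_type 'X'")

  writeLines(c(">IGHV1-2|1|V|IGH|IGHV1|functional|L-PART1", "ATGACA",
               ">IGHV1-2|1|V|IGH|IGHV1|functional|L-PART1", "ATGACC"), p)
  expect_error(read_reference_set(p), "duplicate region label")

  writeLines(character(0), p)
  expect_equal(nrow(read_reference_set(p)), 0)
})

test_that("C alleles carry their hinge exons in order", {
  p <- withr::local_tempfile(fileext = ".fa")
  lines <- character(0)
  for (lab in c("CH1", "H2", "H1", "H3", "H4", "CH2", "CH3")) {
    lines <- c(lines, paste0(">IGHG3C|1|C|IGH|IGHC|functional|", lab),
               strrep("ACG", 5))
  }
  writeLines(lines, p)
  refs <- read_reference_set(p)
  expect_equal(names(refs$regions[[1]]),
               c("CH1", "H1", "H2", "H3", "H4", "CH2", "CH3"))
  expect_equal(sum(grepl("^H", names(refs$regions[[1]]))), 4)
})

test_that("GFF3 output round-trips and respects strand", {
  ann <- small_annotation()$IGH
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff(ann, p)
  lines <- readLines(p)
  expect_equal(lines[1], "##gff-version 3")
  suppressWarnings(gff <- rtracklayer::import(p))
  genes <- gff[gff$type == "gene"]
  exons <- gff[gff$type == "exon"]
  rss <- gff[gff$type == "recombination_signal_sequence"]
  expect_equal(length(genes), nrow(ann$genes))
  expect_equal(length(exons), sum(purrr::map_int(ann$genes$exons, nrow)))
  expect_equal(length(rss), sum(purrr::map_int(ann$genes$rss, nrow)))
  # intervals preserved through the round trip
  got <- sort(BiocGenerics::start(genes))
  expect_equal(got, sort(ann$genes$start))
  # every feature of a FWD locus annotation on the + strand here
  expect_true(all(as.character(BiocGenerics::strand(genes)) == "+"))
})

test_that("gene table round-trips and feeds the comparison unchanged", {
  ann <- small_annotation()
  p <- withr::local_tempfile(fileext = ".tsv")
  tab <- tidy(ann)
  readr::write_tsv(tab, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$gene_name, tab$gene_name)
  expect_equal(back$start, tab$start)
  expect_equal(back$core_seq, tab$core_seq)
})

test_that("write_gene_table emits one row per assembly-gene pair", {
  anns <- igk_annotations()
  p <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_gene_table(list(anns[[1]]$IGK, anns[[2]]$IGK), p)
  expect_equal(nrow(tab), nrow(anns[[1]]$IGK$genes) + nrow(anns[[2]]$IGK$genes))
  back <- read_gene_table(p)
  expect_equal(back$gene_name, tab$gene_name)
  expect_equal(back$locus_order, tab$locus_order)
})

test_that("CNV definition tables parse with per-form gene content", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tlocus\tfive_prime_limit_gene\tthree_prime_limit_gene\tform\tgenes",
               "CNV3\tIGH\tIGHV4-34\tIGHV(II)-28-1\tA\tIGHV4-31,IGHV3-30",
               "CNV3\tIGH\tIGHV4-34\tIGHV(II)-28-1\tB\t"), p)
  defs <- read_cnv_definitions(p)
  expect_equal(defs$genes[[1]], c("IGHV4-31", "IGHV3-30"))
  expect_equal(defs$genes[[2]], character(0))
})

test_that("borne definitions refuse IGH", {
  expect_error(borne_definition("IGH", "five_prime", "X", "ACGT"),
               "no locus bornes")
  b <- borne_definition("IGK", "five_prime", "PAX8", "acgt")
  expect_equal(b$probe_sequence, "ACGT")
})
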