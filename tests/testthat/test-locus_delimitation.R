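region_stub <- function(locus = "IGK", orientation = "FWD", start = 50000,
                        end = 90000) {
  structure(list(locus = locus, seq_id = "chr", start = start, end = end,
                 orientation = orientation),
            class = "ig_locus_region")
}

test_that("IGH delimitation uses the 10 kb / 11 kb flanks", {
  r <- region_stub("IGH")
  dl <- delimit_locus(r, list(), tibble::tibble(start = 50000, end = 50500),
                      tibble::tibble(start = 89000, end = 90000),
                      seq_length = 1e6)
  expect_equal(dl$start, 50000 - 10000)
  expect_equal(dl$end, 90000 + 11000)
  expect_equal(dl$rule_5, "fixed_flank")
  expect_equal(dl$rule_3, "fixed_flank")
})

test_that("IGK uses the borne edge within 10 kb, else the fixed flank", {
  r <- region_stub("IGK")
  # borne 8 kb upstream of the first gene: boundary just inside the borne
  bornes <- list(five_prime = list(start = 41500, end = 41999,
                                   gene_symbol = "PAX8"))
  dl <- delimit_locus(r, bornes, tibble::tibble(start = 50000, end = 50500),
                      tibble::tibble(start = 89000, end = 90000),
                      seq_length = 1e6)
  expect_equal(dl$start, 42000)
  expect_equal(dl$rule_5, "borne")
  expect_equal(dl$end, 90000 + 10000)
  expect_equal(dl$rule_3, "fixed_flank")
  # borne 125 kb away (outside 10 kb): fixed flank applies on that side
  far <- list(five_prime = list(start = 1, end = 500, gene_symbol = "PAX8"))
  dl2 <- delimit_locus(region_stub("IGK", start = 130000, end = 150000), far,
                       tibble::tibble(start = 130000, end = 130500),
                       tibble::tibble(start = 149000, end = 150000),
                       seq_length = 1e6)
  expect_equal(dl2$start, 120000)
  expect_equal(dl2$rule_5, "fixed_flank")
})

test_that("boundaries clamp to the sequence ends", {
  r <- region_stub("IGK", start = 3000, end = 9000)
  dl <- delimit_locus(r, list(), tibble::tibble(start = 3000, end = 3400),
                      tibble::tibble(start = 8000, end = 9000),
                      seq_length = 12000)
  expect_equal(dl$start, 1)
  expect_equal(dl$end, 12000)
})

test_that("gene order sanity is enforced", {
  r <- region_stub("IGK")
  expect_error(
    delimit_locus(r, list(), tibble::tibble(start = 89000, end = 90000),
                  tibble::tibble(start = 50000, end = 50500),
                  seq_length = 1e6),
    "3' of last_gene")
})

test_that("extraction returns the oriented subsequence and round-trips", {
  asm <- Biostrings::DNAStringSet(c(chr = "AAACCCGGGTTTACGTACGTAAACCCGGGT"))
  expect_equal(extract_locus_sequence(asm, "chr", 11, 20, "FWD"),
               "TTACGTACGT")
  expect_equal(extract_locus_sequence(asm, "chr", 11, 14, "REV"),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString("TTAC"))))
  # extract -> re-embed restores the original
  sub <- extract_locus_sequence(asm, "chr", 5, 25, "REV")
  back <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sub)))
  expect_equal(back, substr(as.character(asm[[1]]), 5, 25))
  expect_error(extract_locus_sequence(asm, "chr", 25, 40), "out of bounds")
  expect_error(extract_locus_sequence(asm, "nope", 1, 5), "no sequence")
})

test_that("localization finds the planted locus envelope and orientation", {
  sim <- small_sim()
  refs <- small_refs()
  region <- localize_locus(sim$assemblies$a1, refs, "IGH")
  truth <- sim$truth$genes
  expect_equal(region$orientation, "FWD")
  expect_lte(region$start, min(truth$start))
  expect_gte(region$end, max(truth$end))
  # reverse complement: same locus, mirrored envelope, REV orientation
  L <- nchar(as.character(sim$assemblies$a1[[1]]))
  rc <- Biostrings::DNAStringSet(setNames(as.character(
    Biostrings::reverseComplement(sim$assemblies$a1[[1]])), "chr_rc"))
  region_rc <- localize_locus(rc, refs, "IGH")
  expect_equal(region_rc$orientation, "REV")
  expect_lte(region_rc$start, L - max(truth$end) + 1)
  expect_gte(region_rc$end, L - min(truth$start) + 1)
})

test_that("an assembly with no IG content raises locus-not-found", {
  refs <- small_refs()
  empty <- Biostrings::DNAStringSet(c(chr1 = rand_seq(50000, 123)))
  expect_error(localize_locus(empty, refs, "IGH"),
               class = "igloci_locus_not_found")
})

test_that("borne probes are found at their planted positions, decoys are not", {
  sim <- igk_sim()
  refs <- igk_refs()
  defs <- igk_borne_defs()
  region <- localize_locus(sim$assemblies$k1, refs, "IGK")
  region$assembly_id <- "k1"
  found <- find_bornes(sim$assemblies$k1, region, defs)
  tb <- sim$truth$bornes
  for (side in c("five_prime", "three_prime")) {
    truth_row <- tb[tb$assembly_id == "k1" & tb$side == side, ]
    expect_equal(found[[side]]$start, truth_row$start)
    expect_equal(found[[side]]$end, truth_row$end)
  }
  # a low-identity decoy probe is reported absent
  decoy <- defs
  decoy$probe_sequence[1] <- rand_seq(nchar(decoy$probe_sequence[1]), 321)
  found2 <- find_bornes(sim$assemblies$k1, region, decoy[1, ])
  expect_null(found2$five_prime)
  # no probe planted: absent
  expect_equal(length(find_bornes(sim$assemblies$k1, region, NULL)), 0)
})
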