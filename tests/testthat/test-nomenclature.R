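# brute-force longest-increasing-subsequence oracle (exhaustive over all
# index subsets, n <= 12)
brute_lis_length <- function(ranks) {
  n <- length(ranks)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    r <- ranks[idx]
    if (anyNA(r)) next
    if (all(diff(r) > 0) || length(r) <= 1) best <- max(best, length(r))
  }
  best
}

genes_from <- function(best_hit, identity = rep(1, length(best_hit)),
                       gene_type = rep("V", length(best_hit)),
                       core_seq = replicate(length(best_hit),
                                            rand_seq(60, sample(1e6, 1)))) {
  tibble::tibble(best_hit = best_hit, identity = identity,
                 gene_type = gene_type, core_seq = core_seq)
}

test_that("the orthology chain is a longest increasing subsequence", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    ranks <- sample(1:15, n, replace = TRUE)
    ref_order <- paste0("G", 1:15)
    genes <- genes_from(ref_order[ranks])
    a <- assign_ortholog_names(genes, ref_order)
    chain <- which(a$synteny_support)
    # the assigned chain is strictly increasing in reference rank ...
    expect_true(all(diff(match(a$base_name[chain], ref_order)) > 0))
    # ... and as long as the brute-force optimum
    expect_equal(length(chain), brute_lis_length(ranks))
  }
})

test_that("in-order hits are all named; an out-of-order hit is left unset", {
  ref_order <- paste0("G", 1:8)
  a <- assign_ortholog_names(genes_from(ref_order[1:5]), ref_order)
  expect_equal(a$base_name, ref_order[1:5])
  expect_true(all(a$synteny_support))

  # gene 3 best-hits a far-upstream reference, out of order
  a2 <- assign_ortholog_names(genes_from(c("G4", "G5", "G1", "G6")), ref_order)
  expect_equal(a2$base_name, c("G4", "G5", NA, "G6"))
  expect_false(a2$synteny_support[3])

  expect_equal(nrow(assign_ortholog_names(genes_from(character(0)),
                                          ref_order)), 0)
})

test_that("duplicated blocs are detected at the 99.5% threshold", {
  ref_order <- paste0("G", 1:6)
  cores <- purrr::map_chr(1:4, ~ rand_seq(400, .x))
  # bloc copy of genes 2-3 at ~99.75% identity (1 substitution in 400)
  dup <- c(mutate_k(cores[2], 1, 5), mutate_k(cores[3], 1, 6))
  genes <- genes_from(c("G1", "G2", "G3", "G2", "G3", "G4"),
                      identity = c(1, 1, 1, 0.99, 0.99, 1),
                      core_seq = c(cores[1:3], dup, cores[4]))
  a <- assign_ortholog_names(genes, ref_order)
  expect_equal(a$base_name, c("G1", "G2", "G3", NA, NA, "G4"))
  blocs <- detect_duplicated_blocs(genes, a)
  expect_equal(blocs$index, c(4L, 5L))
  expect_equal(blocs$name, c("G2D", "G3D"))
  expect_true(all(blocs$mean_identity >= 0.995))

  # at ~98% identity the run is not a duplication
  dup98 <- c(mutate_k(cores[2], 8, 7), mutate_k(cores[3], 8, 8))
  genes98 <- genes
  genes98$core_seq[4:5] <- dup98
  expect_equal(nrow(detect_duplicated_blocs(genes98, a)), 0)
})

test_that("a single duplicated gene takes the D suffix", {
  ref_order <- c("G1", "G2", "G3")
  core <- rand_seq(400, 31)
  genes <- genes_from(c("G1", "G2", "G2", "G3"),
                      identity = c(1, 1, 0.999, 1),
                      core_seq = c(rand_seq(400, 30), core,
                                   mutate_k(core, 1, 32), rand_seq(400, 33)))
  a <- assign_ortholog_names(genes, ref_order)
  blocs <- detect_duplicated_blocs(genes, a)
  expect_equal(blocs$name, "G2D")
  full <- assign_gene_names(genes, ref_order)
  expect_equal(full$base_name, c("G1", "G2", "G2D", "G3"))
  expect_equal(full$provenance[3], "duplicated")
})

test_that("inserted V genes take 3'-anchor sub-positions counted 3' to 5'", {
  ref_order <- c("IGHV6-5", "IGHV1-7")
  genes <- genes_from(c("IGHV6-5", "IGHV6-5", "IGHV6-5", "IGHV1-7"))
  a <- tibble::tibble(index = 1:4,
                      base_name = c("IGHV6-5", NA, NA, "IGHV1-7"),
                      provenance = c("ortholog", NA, NA, "ortholog"),
                      synteny_support = c(TRUE, FALSE, FALSE, TRUE))
  done <- assign_inserted_names(genes, a)
  # walking 3' -> 5' from the 3' anchor IGHV1-7
  expect_equal(done$base_name, c("IGHV6-5", "IGHV1-7-2", "IGHV1-7-1",
                                 "IGHV1-7"))
  expect_equal(done$provenance[2:3], c("inserted", "inserted"))
})

test_that("inserted D genes anchor 5' and count 5' to 3'", {
  genes <- genes_from(c("IGHD6-5", "x", "y", "IGHD6-6"),
                      gene_type = rep("D", 4))
  a <- tibble::tibble(index = 1:4,
                      base_name = c("IGHD6-5", NA, NA, "IGHD6-6"),
                      provenance = c("ortholog", NA, NA, "ortholog"),
                      synteny_support = c(TRUE, FALSE, FALSE, TRUE))
  done <- assign_inserted_names(genes, a)
  expect_equal(done$base_name, c("IGHD6-5", "IGHD6-5-1", "IGHD6-5-2",
                                 "IGHD6-6"))
})

test_that("extra J-C tandems take letter suffixes (J2A / C2A)", {
  genes <- genes_from(c("IGLJ2", "IGLC2", "j", "c", "IGLJ3", "IGLC3"),
                      gene_type = c("J", "C", "J", "C", "J", "C"))
  a <- tibble::tibble(index = 1:6,
                      base_name = c("IGLJ2", "IGLC2", NA, NA, "IGLJ3", "IGLC3"),
                      provenance = c("ortholog", "ortholog", NA, NA,
                                     "ortholog", "ortholog"),
                      synteny_support = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  done <- assign_inserted_names(genes, a)
  expect_equal(done$base_name[3:4], c("IGLJ2A", "IGLC2A"))
})

test_that("genes 5' of all named genes get incremented position numbers", {
  genes <- genes_from(c("x", "y", "IGKV1-44", "IGKV1-43"))
  a <- tibble::tibble(index = 1:4,
                      base_name = c(NA, NA, "IGKV1-44", "IGKV1-43"),
                      provenance = c(NA, NA, "ortholog", "ortholog"),
                      synteny_support = c(FALSE, FALSE, TRUE, TRUE))
  done <- assign_inserted_names(genes, a, subgroups = c("IGKV1", "IGKV2",
                                                        "IGKV1", "IGKV1"))
  # positions increment walking 5'-ward from the locus extreme (44)
  expect_equal(done$base_name[1:2], c("IGKV1-46", "IGKV2-45"))
})

test_that("sub-position numbering continues past existing sub-positions", {
  genes <- genes_from(c("IGHV1-7-1", "x", "IGHV1-7"))
  a <- tibble::tibble(index = 1:3,
                      base_name = c("IGHV1-7-1", NA, "IGHV1-7"),
                      provenance = c("ortholog", NA, "ortholog"),
                      synteny_support = c(TRUE, FALSE, TRUE))
  done <- assign_inserted_names(genes, a)
  expect_equal(done$base_name[2], "IGHV1-7-2")
})

test_that("naming is deterministic and refuses an anchorless locus", {
  ref_order <- paste0("G", 1:5)
  genes <- genes_from(c("G1", "G3", "G2", "G5"))
  n1 <- assign_gene_names(genes, ref_order)
  n2 <- assign_gene_names(genes, ref_order)
  expect_identical(n1, n2)
  expect_false(anyNA(n1$base_name))
  expect_false(anyDuplicated(n1$base_name) > 0)

  none <- genes_from("ZZZ")
  a <- tibble::tibble(index = 1L, base_name = NA_character_,
                      provenance = NA_character_, synteny_support = FALSE)
  expect_error(assign_inserted_names(none, a), "no named anchor")
})

test_that("a bloc matching two initial blocs is an ambiguity error", {
  core <- rand_seq(400, 40)
  genes <- genes_from(c("G1", "G2", "G2"),
                      identity = c(1, 1, 0.999),
                      core_seq = c(core, core, mutate_k(core, 1, 41)))
  a <- tibble::tibble(index = 1:3, base_name = c("G1", "G2", NA),
                      provenance = c("ortholog", "ortholog", NA),
                      synteny_support = c(TRUE, TRUE, FALSE))
  expect_error(detect_duplicated_blocs(genes, a),
               class = "igloci_bloc_ambiguity")
})
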