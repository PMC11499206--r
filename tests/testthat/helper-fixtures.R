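# Shared fixtures, built once per test run. Kept deliberately small so the
# full-pipeline tests stay fast; acceptance tests build their own larger
# scenarios.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, build(), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

small_refs <- function() {
  fixture("small_refs", function() {
    generate_reference_set("IGH", n_v = 6, n_d = 3, n_j = 2, n_c = 3,
                           seed = 11)
  })
}

small_sim <- function() {
  fixture("small_sim", function() {
    generate_assembly_set(small_refs(), assembly_ids = "a1", seed = 5)
  })
}

small_annotation <- function() {
  fixture("small_annotation", function() {
    annotate_assembly(small_sim()$assemblies$a1, small_refs(),
                      assembly_id = "a1")
  })
}

# IGK pair with bornes, an antisense gene and one REV assembly
igk_refs <- function() {
  fixture("igk_refs", function() {
    generate_reference_set("IGK", n_v = 8, n_d = 0, n_j = 3, n_c = 1,
                           seed = 4)
  })
}

igk_sim <- function() {
  fixture("igk_sim", function() {
    goK <- attr(igk_refs(), "gene_order")
    bp <- tibble::tibble(side = c("five_prime", "three_prime"),
                         gene_symbol = c("PAX8", "RPIA"),
                         distance = c(15000L, 8000L))
    generate_assembly_set(igk_refs(), assembly_ids = c("k1", "k2"),
                          antisense_genes = goK[8], borne_probes = bp,
                          rev_assemblies = "k2", seed = 33)
  })
}

igk_borne_defs <- function() {
  sim <- igk_sim()
  tb <- sim$truth$bornes
  chrom <- as.character(sim$assemblies$k1[[1]])
  probe <- function(side) {
    r <- tb[tb$side == side & tb$assembly_id == "k1", ]
    substr(chrom, r$start, r$end)
  }
  dplyr::bind_rows(
    borne_definition("IGK", "five_prime", "PAX8", probe("five_prime")),
    borne_definition("IGK", "three_prime", "RPIA", probe("three_prime")))
}

igk_annotations <- function() {
  fixture("igk_annotations", function() {
    sim <- igk_sim()
    defs <- igk_borne_defs()
    lapply(c("k1", "k2"), function(a) {
      annotate_assembly(sim$assemblies[[a]], igk_refs(), assembly_id = a,
                        bornes = defs)
    })
  })
}

# a reference V gene as a raw one-row call tibble (for classification tests)
call_from_seq <- function(core_seq, gene_type = "V", best_hit = "X",
                          coding_seq = core_seq,
                          exons = tibble::tibble(label = "V-EXON", start = 1,
                                                 end = nchar(core_seq),
                                                 sequence = core_seq)) {
  tibble::tibble(gene_type = gene_type, strand = "sense",
                 start = 1, end = nchar(core_seq),
                 exons = list(exons), rss = list(tibble::tibble()),
                 best_hit = best_hit, identity = 1, coverage = 1,
                 reasons = list(character(0)), core_seq = core_seq,
                 coding_seq = coding_seq, hinge_count = NA_integer_)
}

# deterministic k-substitution mutant (no indels): identity is exactly
# (n - k) / n under an indel-free alignment
mutate_k <- function(seq, k, seed = 1) {
  set.seed(seed)
  pos <- sample(nchar(seq), k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[sample(3, 1)]
  }
  paste(chars, collapse = "")
}

rand_seq <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
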