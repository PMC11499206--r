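#' Ground-truthed synthetic assemblies
#'
#' The generator builds a toy "human-like" reference gene set and plants
#' its genes, with designed defects, duplications, insertions, copy number
#' deletions, assembly gaps and allelic variation, into random background
#' chromosomes — one per simulated assembly — together with a truth table
#' for every planted feature. Everything is deterministic for a seed.
#'
#' @name synthetic_data
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NONSTOP_CODONS <- {
  all3 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

rand_coding <- function(n_codons) {
  paste(sample(NONSTOP_CODONS, n_codons, replace = TRUE), collapse = "")
}

set_codon <- function(seq_chr, codon_idx, codon) {
  substr(seq_chr, (codon_idx - 1) * 3 + 1, codon_idx * 3) <- codon
  seq_chr
}

get_codon <- function(seq_chr, codon_idx) {
  substr(seq_chr, (codon_idx - 1) * 3 + 1, codon_idx * 3)
}

# Substitute one base at a codon-aligned coding position without creating
# an in-frame stop codon; returns the sequence unchanged when impossible.
substitute_base_safe <- function(seq_chr, pos, coding = TRUE) {
  cur <- substr(seq_chr, pos, pos)
  for (alt in sample(setdiff(c("A", "C", "G", "T"), cur))) {
    cand <- seq_chr
    substr(cand, pos, pos) <- alt
    if (coding) {
      ci <- (pos - 1) %/% 3 + 1
      if (get_codon(cand, ci) %in% STOP_CODONS) next
    }
    return(cand)
  }
  seq_chr
}

# n safe substitutions over allowed positions of a coding part
mutate_coding <- function(seq_chr, n, protected = integer(0), coding = TRUE) {
  allowed <- setdiff(seq_len(base::nchar(seq_chr)), protected)
  if (!length(allowed) || n <= 0) return(seq_chr)
  for (pos in sample(allowed, min(n, length(allowed)))) {
    seq_chr <- substitute_base_safe(seq_chr, pos, coding)
  }
  seq_chr
}

mk_intron <- function(min_len = 80, max_len = 160) {
  n <- sample(min_len:max_len, 1)
  paste0("GT", rand_dna(n - 4), "AG")
}

v_exon_seq <- function() {
  s <- rand_coding(104)
  s <- set_codon(s, 23, "TGC")   # conserved C23
  s <- set_codon(s, 41, "TGG")   # conserved W41
  s <- set_codon(s, 104, "TGC")  # conserved C104
  s
}

v_exon_protected <- function() as.integer(c(67:69, 121:123, 310:312))

l_part1_seq <- function() paste0("ATG", rand_coding(14))

j_region_seq <- function() {
  s <- rand_coding(16)
  s <- set_codon(s, 11, "TGG")  # W
  s <- set_codon(s, 12, "GGT")  # G
  s <- set_codon(s, 13, "CAA")
  s <- set_codon(s, 14, "GGA")  # G
  s
}

#' Generate a toy reference gene/allele set
#'
#' Builds a reference set with valid leader/intron/V-exon structure,
#' canonical RSS context, FR4-bearing J regions and C genes with designed
#' hinge-exon counts, grouped into subgroups and clans. Deterministic for a
#' seed; a fraction of genes get a second allele differing by two core
#' substitutions.
#'
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @param n_v,n_d,n_j,n_c gene counts per type (D only meaningful for IGH).
#' @param n_subgroups,n_clans how many V subgroups and clan labels to use.
#' @param hinge_counts integer vector of hinge-exon counts for the C genes
#'   (recycled); defaults exercise the 0/5/2/4/1 designs of the IGH
#'   constant cluster.
#' @param extra_allele_fraction fraction of genes receiving an allele 2.
#' @param seed RNG seed.
#' @return An `ig_reference_set` tibble (see [read_reference_set()]).
#' @export
generate_reference_set <- function(locus = "IGH", n_v = 12, n_d = 6, n_j = 4,
                                   n_c = 5, n_subgroups = 3, n_clans = 1,
                                   hinge_counts = NULL,
                                   extra_allele_fraction = 0.25, seed = 1) {
  with_seed(seed, {
    rows <- list()
    add <- function(gene_name, allele, gene_type, subgroup, regions) {
      rows[[length(rows) + 1L]] <<- tibble(
        gene_name = gene_name, allele = as.integer(allele),
        gene_type = gene_type, locus = locus, subgroup = subgroup,
        functionality = "functional", regions = list(regions))
    }
    if (n_d > 0 && locus != "IGH") n_d <- 0L
    # --- V genes ---------------------------------------------------------
    sub_labels <- paste0(locus, "V", seq_len(max(n_subgroups, 1)))
    clan_labels <- if (n_clans > 0) {
      paste0(locus, "V(", c("I", "II", "III", "IV", "V")[seq_len(n_clans)], ")")
    } else character()
    membership <- rep(c(sub_labels, clan_labels), length.out = n_v)
    bases <- lapply(c(sub_labels, clan_labels), function(x) {
      list(lp = l_part1_seq(), vx = v_exon_seq())
    })
    names(bases) <- c(sub_labels, clan_labels)
    for (i in seq_len(n_v)) {
      lab <- membership[i]
      lp <- mutate_coding(bases[[lab]]$lp, rpois(1, 2), protected = 1:3)
      vx <- mutate_coding(bases[[lab]]$vx, rpois(1, 12),
                          protected = v_exon_protected())
      pos <- n_v - i + 1L  # V position numbers increase toward 5'
      nm <- paste0(lab, "-", pos)
      add(nm, 1, "V", lab, c("L-PART1" = lp, "V-EXON" = vx))
      if (runif(1) < extra_allele_fraction) {
        add(nm, 2, "V", lab,
            c("L-PART1" = lp,
              "V-EXON" = mutate_coding(vx, 2, protected = v_exon_protected())))
      }
    }
    # --- D genes ---------------------------------------------------------
    for (i in seq_len(n_d)) {
      nm <- paste0(locus, "D", (i - 1L) %% 7L + 1L, "-", i)
      reg <- rand_dna(24)
      add(nm, 1, "D", paste0(locus, "D", (i - 1L) %% 7L + 1L),
          c("D-REGION" = reg))
      if (runif(1) < extra_allele_fraction) {
        add(nm, 2, "D", paste0(locus, "D", (i - 1L) %% 7L + 1L),
            c("D-REGION" = mutate_coding(reg, 1, coding = FALSE)))
      }
    }
    # --- J genes ---------------------------------------------------------
    for (i in seq_len(n_j)) {
      nm <- paste0(locus, "J", i)
      add(nm, 1, "J", paste0(locus, "J"), c("J-REGION" = j_region_seq()))
    }
    # --- C genes ---------------------------------------------------------
    c_names <- switch(locus,
      IGH = c("IGHM", "IGHG3A", "IGHG3B", "IGHG3C", "IGHG1", "IGHA1",
              "IGHA2", "IGHE"),
      IGK = "IGKC",
      IGL = paste0("IGLC", seq_len(max(n_c, 1))))
    hinge_default <- switch(locus,
      IGH = c(0L, 5L, 2L, 4L, 1L, 1L, 1L, 0L), IGK = 0L,
      IGL = rep(0L, max(n_c, 1)))
    if (is.null(hinge_counts)) hinge_counts <- hinge_default
    hinge_counts <- rep(hinge_counts, length.out = n_c)
    for (i in seq_len(n_c)) {
      nm <- if (i <= length(c_names)) c_names[i] else paste0(locus, "C", i)
      h <- hinge_counts[i]
      regions <- c("CH1" = rand_coding(98))
      if (h > 0) {
        for (k in seq_len(h)) regions[paste0("H", k)] <- rand_coding(15)
      }
      regions["CH2"] <- rand_coding(98)
      regions["CH3"] <- rand_coding(98)
      add(nm, 1, "C", paste0(locus, "C"), regions)
    }
    out <- bind_rows(rows)
    gene_order <- unique(out$gene_name)
    # IGL layout interleaves J and C genes as J-C tandems
    if (locus == "IGL") {
      jg <- gene_order[grepl("^IGLJ", gene_order)]
      cg <- gene_order[grepl("^IGLC", gene_order)]
      k <- min(length(jg), length(cg))
      tandem <- as.vector(rbind(jg[seq_len(k)], cg[seq_len(k)]))
      gene_order <- c(setdiff(gene_order, c(jg, cg)), tandem,
                      jg[-seq_len(k)], cg[-seq_len(k)])
      out <- out |> arrange(match(.data$gene_name, gene_order), .data$allele)
    }
    attr(out, "gene_order") <- gene_order
    class(out) <- c("ig_reference_set", class(out))
    out
  })
}

# ---------------------------------------------------------------------------
# gene templates: parts (exon/intron/rss) assembled into a plantable block
# ---------------------------------------------------------------------------

# A template is a tibble of parts: kind (exon/intron/rss/ctx), label, seq,
# protected (list of protected positions within the part, for exon parts).
build_gene_template <- function(ref_row, locus) {
  tp <- ref_row$gene_type
  regions <- ref_row$regions[[1]]
  parts <- list()
  add <- function(kind, label, seq, protected = integer(0)) {
    parts[[length(parts) + 1L]] <<- tibble(kind = kind, label = label,
                                           seq = seq,
                                           protected = list(as.integer(protected)))
  }
  if (tp == "V") {
    add("exon", "L-PART1", regions[["L-PART1"]], protected = 1:3)
    add("intron", "V-INTRON", mk_intron())
    add("exon", "V-EXON", regions[["V-EXON"]], protected = v_exon_protected())
    cls <- if (locus == "IGK") 12L else 23L
    add("rss", "RSS3", rss_canonical(cls))
  } else if (tp == "D") {
    add("rss", "RSS5", revcomp_chr(rss_canonical(12L)))
    add("exon", "D-REGION", regions[["D-REGION"]])
    add("rss", "RSS3", rss_canonical(12L))
  } else if (tp == "J") {
    add("rss", "RSS5", revcomp_chr(rss_canonical(23L)))
    add("exon", "J-REGION", regions[["J-REGION"]],
        protected = c(31:33, 34:36, 40:42))
    add("ctx", "J-DONOR", paste0("GT", rand_dna(6)))
  } else if (tp == "C") {
    labs <- names(regions)
    for (k in seq_along(labs)) {
      if (k > 1) add("intron", paste0("I", k - 1), mk_intron(150, 260))
      add("exon", labs[k], regions[[labs[k]]])
    }
  }
  bind_rows(parts)
}

# Designed defect edits on a template; returns list(template, reasons).
apply_defect <- function(template, code) {
  t <- template
  reasons <- character(0)
  exon_i <- function(lab) {
    i <- which(t$kind == "exon" & t$label == lab)
    if (!length(i)) {
      abort(paste0("designed defect ", code, " needs a ", lab,
                   " exon, which this gene lacks"))
    }
    i
  }
  randomize_rss <- function(i) {
    repeat {
      cand <- rand_dna(base::nchar(t$seq[i]))
      hept <- if (t$label[i] == "RSS3") substr(cand, 1, 7) else
        substr(revcomp_chr(cand), 1, 7)
      if (rss_consensus_score(substr(cand, 1, 7), 23,
                              substr(cand, base::nchar(cand) - 8, base::nchar(cand)),
                              23) < 0.5) return(cand)
    }
  }
  switch(code,
    STOP_CODON = {
      i <- exon_i(if (any(t$label == "V-EXON")) "V-EXON" else "CH1")
      t$seq[i] <- set_codon(t$seq[i], 50, "TAA")
      t$protected[[i]] <- c(t$protected[[i]], 148:150)
      reasons <- "STOP_CODON"
    },
    FRAMESHIFT = {
      i <- exon_i(if (any(t$label == "V-EXON")) "V-EXON" else "CH2")
      s <- t$seq[i]
      t$seq[i] <- paste0(substr(s, 1, 149), substr(s, 151, base::nchar(s)))
      t$protected[[i]] <- seq_len(base::nchar(t$seq[i]))
      reasons <- "FRAMESHIFT"
    },
    DEFECTIVE_SPLICE = {
      i <- which(t$kind == "intron")[1]
      substr(t$seq[i], 1, 2) <- "GC"
      reasons <- "DEFECTIVE_SPLICE"
    },
    DEFECTIVE_RSS = {
      i <- which(t$kind == "rss")
      i <- i[length(i)]  # ablate the 3' (or only) RSS
      t$seq[i] <- randomize_rss(i)
      reasons <- "DEFECTIVE_RSS"
    },
    TRUNCATED = {
      drop <- which(t$label %in% c("L-PART1", "V-INTRON"))
      t <- t[-drop, ]
      reasons <- "TRUNCATED"
    },
    REPEAT_INSERTION = {
      i <- exon_i("V-EXON")
      s <- t$seq[i]
      t$seq[i] <- paste0(substr(s, 1, 60), rand_dna(150),
                         substr(s, 61, base::nchar(s)))
      t$protected[[i]] <- seq_len(base::nchar(t$seq[i]))
      reasons <- "REPEAT_INSERTION"
    },
    NO_CANONICAL_MOTIF = {
      i <- exon_i("J-REGION")
      t$seq[i] <- set_codon(t$seq[i], 11, "CGG")
      stopifnot(!has_fr4_motif(t$seq[i]))
      reasons <- "NO_CANONICAL_MOTIF"
    },
    NO_INIT_CODON = {
      i <- exon_i("L-PART1")
      substr(t$seq[i], 1, 3) <- "ACG"
      reasons <- "NO_INIT_CODON"
    },
    REARRANGED = {
      i2 <- exon_i("CH2"); i3 <- exon_i("CH3")
      tmp <- t$seq[i2]; t$seq[i2] <- t$seq[i3]; t$seq[i3] <- tmp
      reasons <- "REARRANGED"
    },
    MISSING_EXON = {
      i <- exon_i("CH2")
      t <- t[-c(i - 1L, i), ]  # drop CH2 and its preceding intron
      reasons <- "MISSING_EXON"
    },
    HINGE_DEL_15 = {
      i <- exon_i("H1")
      s <- t$seq[i]
      t$seq[i] <- paste0(substr(s, 1, 15), substr(s, 31, base::nchar(s)))
      t$protected[[i]] <- seq_len(base::nchar(t$seq[i]))
      reasons <- character(0)  # in-frame deletion: still functional
    },
    HINGE_DEL_2 = {
      i <- exon_i("H1")
      s <- t$seq[i]
      t$seq[i] <- paste0(substr(s, 1, 21), substr(s, 24, base::nchar(s)))
      t$protected[[i]] <- seq_len(base::nchar(t$seq[i]))
      reasons <- "FRAMESHIFT"
    },
    abort(paste0("unknown designed defect: ", code)))
  list(template = t, reasons = reasons)
}

template_core_labels <- function(t) {
  t$label[t$kind == "exon"]
}

template_seq <- function(t) paste(t$seq, collapse = "")

template_features <- function(t) {
  w <- base::nchar(t$seq)
  e <- cumsum(w)
  s <- e - w + 1L
  tibble(kind = t$kind, label = t$label, start = s, end = e)
}

template_core_seq <- function(t) {
  paste(t$seq[t$kind == "exon" &
                t$label %in% c("V-EXON", "D-REGION", "J-REGION") |
                grepl("^CH|^H[0-9]+$", t$label)], collapse = "")
}

# per-assembly allelic substitutions over exon parts
mutate_template_cores <- function(t, rate) {
  if (rate <= 0) return(t)
  for (i in which(t$kind == "exon")) {
    len <- base::nchar(t$seq[i])
    n <- rbinom(1, len, rate)
    coding <- t$label[i] != "D-REGION"
    t$seq[i] <- mutate_coding(t$seq[i], n, protected = t$protected[[i]],
                              coding = coding)
  }
  t
}

#' Generate a set of synthetic assemblies with truth
#'
#' Plants the reference genes, in reference order, into a random background
#' chromosome per assembly, with designed defects, a duplicated bloc,
#' inserted genes, per-assembly gene deletions (CNVs), N-run gaps, locus
#' borne probes, antisense genes, designed polymorphic variants and
#' per-assembly allelic substitution noise. Assemblies listed in
#' `rev_assemblies` are emitted reverse-complemented (REV locus
#' orientation).
#'
#' @param refs an `ig_reference_set` ([generate_reference_set()]).
#' @param assembly_ids character vector of assembly names.
#' @param substitution_rate per-base allelic substitution rate applied to
#'   gene core regions per assembly (safe: never creates stop codons or
#'   touches motifs).
#' @param defects optional tibble `gene_name`, `code` of designed defects
#'   (codes: the functionality reason codes plus `HINGE_DEL_15` /
#'   `HINGE_DEL_2` for the constant-gene hinge deletions).
#' @param duplicated_bloc optional list `genes` (character vector of
#'   consecutive reference gene names), `identity` (target, e.g. 0.998).
#' @param inserted optional tibble `after_gene` (5' neighbour reference
#'   gene, NA for the 5' extremity), `source_gene` (reference gene the
#'   insertion derives from), `divergence` (core substitution fraction),
#'   optional `name` (designed name override), optional `assemblies`
#'   (list-column restricting which assemblies carry it).
#' @param cnv_deletions optional tibble `assembly_id`, `genes`
#'   (list-column of gene names deleted in that assembly).
#' @param gap_ranges optional tibble `assembly_id`, `genes` (list-column):
#'   those genes and their spacers are replaced by an N run in that
#'   assembly.
#' @param polymorphic_genes genes given a designed variant allele carried
#'   by the second half of the assemblies.
#' @param antisense_genes genes planted in antisense locus orientation.
#' @param borne_probes optional tibble `side` (`five_prime`/`three_prime`),
#'   `gene_symbol`, `distance` (bp from the terminal gene), optional
#'   `probe` sequence.
#' @param rev_assemblies assemblies emitted reverse-complemented.
#' @param flank_bp background flank outside the borne/locus region.
#' @param spacer_range min/max intergenic spacer length.
#' @param seed RNG seed; everything is deterministic given it.
#' @return A list of class `ig_simulation`: `assemblies` (named list of
#'   DNAStringSet), `refs`, `truth` (list: `genes` tibble with designed
#'   name/functionality/intervals/core sequences per assembly, `loci`
#'   designed locus spans and rules, `gaps`, `bornes`, `cnv_deletions`),
#'   `seed`.
#' @export
generate_assembly_set <- function(refs,
                                  assembly_ids = paste0("asm", 1:4),
                                  substitution_rate = 0,
                                  defects = NULL,
                                  duplicated_bloc = NULL,
                                  inserted = NULL,
                                  cnv_deletions = NULL,
                                  gap_ranges = NULL,
                                  polymorphic_genes = character(),
                                  antisense_genes = character(),
                                  borne_probes = NULL,
                                  rev_assemblies = character(),
                                  flank_bp = 20000L,
                                  spacer_range = c(700L, 1400L),
                                  seed = 1) {
  locus <- unique(refs$locus)
  gene_order <- attr(refs, "gene_order")
  reps <- representative_refs(refs) |>
    arrange(match(.data$gene_name, gene_order))
  with_seed(seed, {
    # --- shared layout ---------------------------------------------------
    templates <- list()
    layout <- list()
    for (i in seq_len(nrow(reps))) {
      t <- build_gene_template(reps[i, ], locus)
      reasons <- character(0)
      if (!is.null(defects)) {
        codes <- defects$code[defects$gene_name == reps$gene_name[i]]
        for (code in codes) {
          res <- apply_defect(t, code)
          t <- res$template
          reasons <- c(reasons, res$reasons)
        }
      }
      templates[[length(templates) + 1L]] <- t
      layout[[length(layout) + 1L]] <- tibble(
        name = reps$gene_name[i], source_gene = reps$gene_name[i],
        gene_type = reps$gene_type[i], subgroup = reps$subgroup[i],
        role = "base", designed_reasons = list(unique(reasons)))
    }
    layout <- bind_rows(layout)
    # duplicated bloc: copies appended directly 3' of the source run
    if (!is.null(duplicated_bloc)) {
      idx <- match(duplicated_bloc$genes, layout$name)
      stopifnot(!anyNA(idx), all(diff(idx) == 1))
      ins_at <- max(idx)
      new_rows <- layout[idx, ]
      new_rows$name <- paste0(new_rows$name, "D")
      new_rows$role <- "duplicated"
      n_mut <- function(t) {
        core_len <- sum(base::nchar(t$seq[t$kind == "exon"]))
        round((1 - duplicated_bloc$identity) * core_len)
      }
      dup_templates <- lapply(templates[idx], function(t) {
        k <- n_mut(t)
        for (i in which(t$kind == "exon")) {
          share <- round(k * base::nchar(t$seq[i]) /
                           sum(base::nchar(t$seq[t$kind == "exon"])))
          coding <- t$label[i] != "D-REGION"
          t$seq[i] <- mutate_coding(t$seq[i], share,
                                    protected = t$protected[[i]],
                                    coding = coding)
        }
        t
      })
      layout <- bind_rows(layout[seq_len(ins_at), ], new_rows,
                          layout[-seq_len(ins_at), ])
      templates <- c(templates[seq_len(ins_at)], dup_templates,
                     templates[-seq_len(ins_at)])
    }
    # inserted genes
    if (!is.null(inserted)) {
      for (r in rev(seq_len(nrow(inserted)))) {
        row <- inserted[r, ]
        src <- reps[reps$gene_name == row$source_gene, ]
        t <- build_gene_template(src, locus)
        div <- row$divergence %||% 0.06
        for (i in which(t$kind == "exon")) {
          t$seq[i] <- mutate_coding(t$seq[i],
                                    round(div * base::nchar(t$seq[i])),
                                    protected = t$protected[[i]],
                                    coding = t$label[i] != "D-REGION")
        }
        at <- if (is.na(row$after_gene)) 0L else match(row$after_gene, layout$name)
        stopifnot(!is.na(at))
        asms <- if ("assemblies" %in% names(inserted) &&
                    !is.null(row$assemblies[[1]])) row$assemblies[[1]] else assembly_ids
        new_row <- tibble(name = if ("name" %in% names(inserted) &&
                                     !is.na(row$name)) row$name else NA_character_,
                          source_gene = row$source_gene,
                          gene_type = src$gene_type, subgroup = src$subgroup,
                          role = "inserted",
                          designed_reasons = list(character(0)),
                          only_in = list(asms))
        layout <- bind_rows(layout[seq_len(at), ], new_row,
                            layout[-seq_len(at), ])
        templates <- append(templates, list(t), after = at)
      }
    }
    if (!"only_in" %in% names(layout)) layout$only_in <- list(NULL)
    layout$only_in <- map(layout$only_in, ~ .x %||% assembly_ids)
    n_genes <- nrow(layout)
    layout$antisense <- layout$name %in% antisense_genes |
      layout$source_gene %in% antisense_genes & layout$role == "base"
    # designed inserted names where not overridden
    layout$name <- designed_inserted_names(layout)
    layout$designed_functionality <-
      map_chr(layout$designed_reasons, functionality_state)
    # designed variant cores for polymorphic genes
    variant_templates <- list()
    for (g in intersect(polymorphic_genes, layout$name)) {
      i <- match(g, layout$name)
      t <- templates[[i]]
      for (k in which(t$kind == "exon")) {
        t$seq[k] <- mutate_coding(t$seq[k], 2, protected = t$protected[[k]],
                                  coding = t$label[k] != "D-REGION")
      }
      variant_templates[[g]] <- t
    }
    spacers <- sample(spacer_range[1]:spacer_range[2], n_genes + 1L,
                      replace = TRUE)
    spacer_seqs <- vapply(spacers, rand_dna, character(1))
    probes <- NULL
    if (!is.null(borne_probes)) {
      probes <- borne_probes
      if (!"probe" %in% names(probes)) probes$probe <- NA_character_
      probes$probe <- map_chr(probes$probe,
                              ~ if (is.na(.x)) rand_dna(400) else .x)
    }
    asm_seeds <- sample.int(1e8, length(assembly_ids))
    # --- per-assembly construction --------------------------------------
    assemblies <- list()
    truth_genes <- list()
    truth_loci <- list()
    truth_gaps <- list()
    truth_bornes <- list()
    second_half <- assembly_ids[seq_along(assembly_ids) >
                                  length(assembly_ids) / 2]
    for (ai in seq_along(assembly_ids)) {
      aid <- assembly_ids[ai]
      res <- with_seed(asm_seeds[ai], build_one_assembly(
        aid, locus, layout, templates, variant_templates, spacer_seqs,
        probes, substitution_rate, cnv_deletions, gap_ranges,
        aid %in% second_half, aid %in% rev_assemblies, flank_bp))
      assemblies[[aid]] <- res$assembly
      truth_genes[[aid]] <- res$genes
      truth_loci[[aid]] <- res$locus_row
      truth_gaps[[aid]] <- res$gaps
      truth_bornes[[aid]] <- res$bornes
    }
    structure(list(
      assemblies = assemblies, refs = refs,
      truth = list(genes = bind_rows(truth_genes),
                   loci = bind_rows(truth_loci),
                   gaps = bind_rows(truth_gaps),
                   bornes = bind_rows(truth_bornes),
                   cnv_deletions = cnv_deletions),
      seed = seed), class = "ig_simulation")
  })
}

# naming rules applied at design time for inserted genes (anchored on the
# 3' neighbour for V with sub-positions 3'->5', the 5' neighbour for D
# 5'->3', letters for J/C, new top positions at the 5' extremity)
designed_inserted_names <- function(layout) {
  nm <- layout$name
  ins <- which(layout$role == "inserted" & is.na(nm))
  for (run in split_runs(ins)) {
    tp <- layout$gene_type[run[1]]
    if (tp == "V" && run[1] > 1) {
      after <- run[length(run)] + 1L
      if (after <= nrow(layout)) {
        base <- nm[after]
        k <- 0L
        for (i in rev(run)) { k <- k + 1L; nm[i] <- paste0(base, "-", k) }
        next
      }
    }
    if (tp == "V" && run[1] == 1L) {
      m <- str_match(nm[!is.na(nm)], "^([A-Z0-9()]+)-([0-9]+)")
      pos <- max(as.integer(m[, 3]), na.rm = TRUE)
      for (i in rev(run)) {
        pos <- pos + 1L
        nm[i] <- paste0(layout$subgroup[i], "-", pos)
      }
      next
    }
    if (tp == "D") {
      base <- nm[run[1] - 1L]
      k <- 0L
      for (i in run) { k <- k + 1L; nm[i] <- paste0(base, "-", k) }
      next
    }
    # J/C: letter suffix on the nearest named same-type 5' neighbour
    for (i in run) {
      sib <- which(!is.na(nm) & layout$gene_type == layout$gene_type[i])
      sib <- sib[sib < i]
      base <- nm[max(sib)]
      used <- sum(grepl(paste0("^", escape_regex(base), "[A-Z]+$"), nm),
                  na.rm = TRUE)
      nm[i] <- paste0(base, int_to_letters(used + 1L))
    }
  }
  nm
}

build_one_assembly <- function(aid, locus, layout, templates,
                               variant_templates, spacer_seqs, probes,
                               substitution_rate, cnv_deletions, gap_ranges,
                               use_variant, rev_assembly, flank_bp) {
  n <- nrow(layout)
  deleted <- character(0)
  if (!is.null(cnv_deletions)) {
    rows <- cnv_deletions[cnv_deletions$assembly_id == aid, ]
    if (nrow(rows)) deleted <- unlist(rows$genes)
  }
  masked <- character(0)
  if (!is.null(gap_ranges)) {
    rows <- gap_ranges[gap_ranges$assembly_id == aid, ]
    if (nrow(rows)) masked <- unlist(rows$genes)
  }
  pieces <- character(0)
  pos <- 0L
  add_piece <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + base::nchar(s)
  }
  add_piece(rand_dna(flank_bp))
  borne_rows <- list()
  if (!is.null(probes) && any(probes$side == "five_prime")) {
    p <- probes[probes$side == "five_prime", ][1, ]
    bs <- pos + 1L
    add_piece(p$probe)
    borne_rows[["five_prime"]] <- tibble(assembly_id = aid, locus = locus,
                                         side = "five_prime",
                                         gene_symbol = p$gene_symbol,
                                         start = bs, end = pos,
                                         distance = p$distance)
    add_piece(rand_dna(p$distance))
  }
  genes <- list()
  gap_rows <- list()
  in_gap_run <- FALSE
  gap_start <- NA_integer_
  flush_gap <- function(end_pos) {
    if (in_gap_run) {
      gap_rows[[length(gap_rows) + 1L]] <<- tibble(
        assembly_id = aid, locus = locus, start = gap_start, end = end_pos,
        length = end_pos - gap_start + 1L)
      in_gap_run <<- FALSE
    }
  }
  for (i in seq_len(n)) {
    present <- aid %in% layout$only_in[[i]] && !(layout$name[i] %in% deleted)
    is_masked <- layout$name[i] %in% masked
    # spacer before gene i (masked stretches become N)
    sp <- spacer_seqs[i]
    nxt_masked <- is_masked
    prv_masked <- i > 1 && layout$name[i - 1L] %in% masked
    if (nxt_masked || prv_masked) {
      half <- base::nchar(sp) %/% 2
      sp1 <- if (prv_masked) strrep("N", half) else substr(sp, 1, half)
      sp2 <- if (nxt_masked) strrep("N", base::nchar(sp) - half)
      else substr(sp, half + 1, base::nchar(sp))
      if (prv_masked && !in_gap_run) { }
      if (!prv_masked && nxt_masked) { gap_start <- pos + half + 1L; in_gap_run <- TRUE }
      if (prv_masked && !nxt_masked) flush_gap(pos + half)
      add_piece(paste0(sp1, sp2))
    } else {
      flush_gap(pos)
      add_piece(sp)
    }
    if (!present && !is_masked) next
    t <- templates[[i]]
    if (use_variant && layout$name[i] %in% names(variant_templates)) {
      t <- variant_templates[[layout$name[i]]]
    }
    t <- mutate_template_cores(t, substitution_rate)
    tseq <- template_seq(t)
    feats <- template_features(t)
    if (layout$antisense[i]) {
      tlen <- base::nchar(tseq)
      tseq_out <- revcomp_chr(tseq)
      feats <- feats |>
        mutate(s2 = tlen - .data$end + 1L, e2 = tlen - .data$start + 1L) |>
        mutate(start = .data$s2, end = .data$e2) |> select(-"s2", -"e2")
    } else {
      tseq_out <- tseq
    }
    if (is_masked) {
      add_piece(strrep("N", base::nchar(tseq_out)))
      next
    }
    g_start <- pos + 1L
    add_piece(tseq_out)
    ex <- feats[feats$kind == "exon", ]
    genes[[length(genes) + 1L]] <- tibble(
      assembly_id = aid, locus = locus, gene_name = layout$name[i],
      source_gene = layout$source_gene[i], gene_type = layout$gene_type[i],
      role = layout$role[i], subgroup = layout$subgroup[i],
      antisense = layout$antisense[i],
      functionality = layout$designed_functionality[i],
      designed_reasons = layout$designed_reasons[i],
      start = g_start + min(ex$start) - 1L, end = g_start + max(ex$end) - 1L,
      core_seq = template_core_seq(t),
      hinge_count = sum(grepl("^H[0-9]+$", ex$label)),
      exons = list(mutate(ex, start = g_start + .data$start - 1L,
                          end = g_start + .data$end - 1L)))
  }
  flush_gap(pos)
  sp <- spacer_seqs[n + 1L]
  add_piece(sp)
  if (!is.null(probes) && any(probes$side == "three_prime")) {
    p <- probes[probes$side == "three_prime", ][1, ]
    add_piece(rand_dna(max(0L, p$distance - base::nchar(sp))))
    bs <- pos + 1L
    add_piece(p$probe)
    borne_rows[["three_prime"]] <- tibble(assembly_id = aid, locus = locus,
                                          side = "three_prime",
                                          gene_symbol = p$gene_symbol,
                                          start = bs, end = pos,
                                          distance = p$distance)
  }
  add_piece(rand_dna(flank_bp))
  chrom <- paste(pieces, collapse = "")
  L <- base::nchar(chrom)
  genes <- bind_rows(genes)
  gaps <- if (length(gap_rows)) bind_rows(gap_rows) else
    tibble(assembly_id = character(), locus = character(), start = integer(),
           end = integer(), length = integer())
  bornes <- bind_rows(borne_rows)
  # designed locus span (locus-forward coordinates)
  fg <- min(genes$start); lg <- max(genes$end)
  cfg <- igloci_config()
  span <- designed_locus_span(locus, fg, lg, bornes, L, cfg)
  if (rev_assembly) {
    flip <- function(s, e) list(start = L - e + 1L, end = L - s + 1L)
    g2 <- flip(genes$start, genes$end)
    genes$start <- g2$start; genes$end <- g2$end
    genes$exons <- map(genes$exons, function(ex) {
      f <- flip(ex$start, ex$end)
      ex$start <- f$start; ex$end <- f$end
      arrange(ex, .data$start)
    })
    if (nrow(gaps)) {
      f <- flip(gaps$start, gaps$end); gaps$start <- f$start; gaps$end <- f$end
    }
    if (nrow(bornes)) {
      f <- flip(bornes$start, bornes$end)
      bornes$start <- f$start; bornes$end <- f$end
    }
    f <- flip(span$start, span$end); span$start <- f$start; span$end <- f$end
    chrom <- revcomp_chr(chrom)
    # truth genes stay in 5'->3' locus order (matching annotation output)
  }
  seq_id <- paste0("chr_", locus, "_sim")
  asm <- DNAStringSet(setNames(chrom, seq_id))
  genes$seq_id <- seq_id
  locus_row <- tibble(assembly_id = aid, locus = locus, seq_id = seq_id,
                      start = span$start, end = span$end,
                      orientation = if (rev_assembly) "REV" else "FWD",
                      rule_5 = span$rule_5, rule_3 = span$rule_3,
                      n_genes = nrow(genes))
  list(assembly = asm, genes = genes, locus_row = locus_row, gaps = gaps,
       bornes = bornes)
}

# arithmetic truth for the locus span, locus-forward coordinates
designed_locus_span <- function(locus, first_gene_start, last_gene_end,
                                bornes, seq_len, cfg) {
  rule_5 <- "fixed_flank"; rule_3 <- "fixed_flank"
  if (locus == "IGH") {
    s <- first_gene_start - cfg$flank_5
    e <- last_gene_end + cfg$flank_3_igh
  } else {
    s <- first_gene_start - cfg$flank
    e <- last_gene_end + cfg$flank
    if (nrow(bornes)) {
      b5 <- bornes[bornes$side == "five_prime", ]
      if (nrow(b5) && (first_gene_start - b5$end[1] - 1) <= cfg$flank) {
        s <- b5$end[1] + 1L
        rule_5 <- "borne"
      }
      b3 <- bornes[bornes$side == "three_prime", ]
      if (nrow(b3) && (b3$start[1] - last_gene_end - 1) <= cfg$flank) {
        e <- b3$start[1] - 1L
        rule_3 <- "borne"
      }
    }
  }
  list(start = max(1L, s), end = min(seq_len, e), rule_5 = rule_5,
       rule_3 = rule_3)
}
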