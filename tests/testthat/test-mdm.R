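brute_force_exact <- function(queries, references) {
  # independent oracle: plain string scan on both strands
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  vapply(as.character(queries), function(q) {
    any(vapply(as.character(references), function(r) {
      grepl(q, r, fixed = TRUE) || grepl(revcomp(q), r, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
}

test_that("exact matching is strand-aware and equals a brute-force scan", {
  refs <- Biostrings::DNAStringSet(c(
    R1 = "AAACCCGGGTTTACGTACGT",
    R2 = "TGCATGCAAGGTCCTTAGCA"
  ))
  qs <- Biostrings::DNAStringSet(c(
    identical = "AAACCCGGGTTTACGTACGT",    # full reference
    sub = "CCCGGGTTT",                     # internal substring
    rc = "CCTTGCATGC",                     # revcomp of R2[2:11], fwd-absent
    mism = "AAACCCGGGTTTACGTACGA"          # one substitution
  ))
  m <- match_exact(qs, refs)
  expect_equal(m$ref_id[m$query_id == "identical"], "R1")
  expect_equal(m$identity[m$query_id == "identical"], 1)
  expect_equal(m$coverage[m$query_id == "identical"], 1)
  expect_equal(m$ref_id[m$query_id == "sub"], "R1")
  expect_equal(m$ref_id[m$query_id == "rc"], "R2")
  expect_equal(m$strand[m$query_id == "rc"], "-")
  expect_true(is.na(m$ref_id[m$query_id == "mism"]))

  # random fixtures agree with the oracle
  qsr <- random_dna(25, width = 40, seed = 31)
  pair <- generate_reference_set(qsr, include_fraction = 0.4,
                                 mutation_rate = 0.05, seed = 32)
  got <- match_exact(pair$queries, pair$references)
  expect_equal(!is.na(got$ref_id),
               unname(brute_force_exact(pair$queries, pair$references)))
})

test_that("identity matching honours the 97% species cutoff", {
  withr::with_seed(41, {
    base <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  })
  mutate_at <- function(s, k, seed) {
    withr::with_seed(seed, {
      ch <- strsplit(s, "")[[1]]
      pos <- sample(length(ch), k)
      ch[pos] <- vapply(ch[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      paste(ch, collapse = "")
    })
  }
  refs <- Biostrings::DNAStringSet(c(src = base))
  qs <- Biostrings::DNAStringSet(c(
    same = base,
    six = mutate_at(base, 6, 1),     # 294/300 = 0.98
    twelve = mutate_at(base, 12, 2)  # 288/300 = 0.96
  ))
  m <- match_identity(qs, refs, min_identity = 0.97)
  expect_equal(m$identity[m$query_id == "same"], 1)
  expect_equal(m$ref_id[m$query_id == "same"], "src")
  expect_equal(m$identity[m$query_id == "six"], 294 / 300,
               tolerance = 1e-12)
  expect_equal(m$ref_id[m$query_id == "six"], "src")
  expect_equal(m$identity[m$query_id == "twelve"], 288 / 300,
               tolerance = 1e-12)
  expect_true(is.na(m$ref_id[m$query_id == "twelve"]))

  # at threshold 1 on equal-length pairs it reduces to the exact criterion
  m1 <- match_identity(qs, refs, min_identity = 1)
  ex <- match_exact(qs, refs)
  expect_equal(is.na(m1$ref_id), is.na(ex$ref_id))
})

test_that("MDM proportions follow the worked example and are monotone in references", {
  # 2 of 4 taxa matched with mean abundances 0.4 and 0.2 -> P_number 0.5,
  # P_abundance 0.6
  m <- matrix(c(40L, 20L, 30L, 10L), 4, 1,
              dimnames = list(c("q1", "q2", "q3", "q4"), "s"))
  tab <- otu_table(m)
  matches <- tibble::tibble(
    query_id = c("q1", "q2", "q3", "q4"),
    ref_id = c("r1", NA, NA, "r2")
  )
  rep1 <- mdm_proportions(tab, matches)
  expect_equal(rep1$overall$p_number, 0.5)
  expect_equal(rep1$overall$p_abundance, (0.4 + 0.1) / 1, tolerance = 1e-12)

  all_hit <- matches |> dplyr::mutate(ref_id = paste0("r", 1:4))
  rep2 <- mdm_proportions(tab, all_hit)
  expect_equal(rep2$overall$p_number, 1)
  expect_equal(rep2$overall$p_abundance, 1)

  # duplicating references never changes, adding references never decreases
  qs <- random_dna(20, width = 60, seed = 51)
  pair <- generate_reference_set(qs, include_fraction = 0.5, seed = 52)
  tab2 <- random_table(20, 3, lambda = 30, seed = 53)
  rownames_tab <- rownames(tab2)
  names(qs) <- rownames_tab
  refs <- pair$references
  names(refs) <- paste0("R", seq_along(refs))
  base_m <- match_exact(qs, refs)
  base_rep <- mdm_proportions(tab2, base_m)
  dup <- c(refs, refs)
  names(dup) <- paste0("R", seq_along(dup))
  dup_rep <- mdm_proportions(tab2, match_exact(qs, dup))
  expect_equal(dup_rep$overall$p_number, base_rep$overall$p_number)
  expect_equal(dup_rep$overall$p_abundance, base_rep$overall$p_abundance)
  extra <- c(refs, qs[is.na(base_m$ref_id)][1])
  names(extra) <- paste0("R", seq_along(extra))
  ext_rep <- mdm_proportions(tab2, match_exact(qs, extra))
  expect_gte(ext_rep$overall$p_number, base_rep$overall$p_number)
  expect_gte(ext_rep$overall$p_abundance, base_rep$overall$p_abundance)
})

test_that("wanted-list mapping reports planted presences above threshold", {
  # 9 wanted sequences; 5 planted as study OTUs with >0.1% abundance
  otus <- random_dna(12, width = 80, seed = 61)
  wanted <- c(otus[1:5], random_dna(4, width = 80, seed = 62))
  names(wanted) <- paste0("W", 1:9)
  counts <- matrix(0L, 12, 2,
                   dimnames = list(names(otus), c("s1", "s2")))
  counts[1:5, ] <- 100L    # well above 0.1%
  counts[6:12, ] <- 10L
  counts[1, ] <- counts[1, ] + (10000L - colSums(counts))
  tab <- otu_table(counts)
  res <- wanted_list_map(otus, wanted, tab, min_mean_rel = 1e-3)
  expect_equal(sum(res$above_threshold), 5)
  expect_setequal(res$wanted_id[res$above_threshold], paste0("W", 1:5))
  # wanted sequences absent from the study are reported unmatched
  expect_true(all(is.na(res$otu_id[res$wanted_id %in% paste0("W", 6:9)])))
})
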