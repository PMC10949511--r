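test_that("OTU table TSV round-trip is bit-identical and orientation-aware", {
  tab <- toy_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path)
  expect_identical(unclass(back)[, ], unclass(tab)[, ])

  # transposed file read with the samples-rows hint gives the same table
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- tibble::tibble(sample_id = colnames(tab))
  for (tx in rownames(tab)) df[[tx]] <- unclass(tab)[tx, ]
  readr::write_tsv(df, tpath)
  back_t <- read_otu_table(tpath, orientation = "samples_rows")
  expect_identical(unclass(back_t)[, ], unclass(tab)[, ])
  # and the id-column heuristic alone resolves it too
  expect_identical(unclass(read_otu_table(tpath))[, ], unclass(tab)[, ])
})

test_that("constructor rejects invalid tables", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(otu_table(m), "Duplicated taxon")
  m2 <- matrix(c(1, -1, 2, 3), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(otu_table(m2), "Negative count")
  m3 <- matrix(c(1, 1.5, 2, 3), 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(otu_table(m3), "Non-integer")
})

test_that("singleton removal matches a brute-force scan and is idempotent", {
  m <- matrix(c(1L, 0L, 0L,
                1L, 1L, 0L,
                0L, 0L, 0L,
                2L, 5L, 1L), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  out <- remove_singletons(otu_table(m))
  expect_setequal(rownames(out), c("t2", "t3", "t4"))

  tab <- random_table(50, 6, lambda = 0.3, seed = 42)
  out <- remove_singletons(tab)
  expected <- rownames(tab)[vapply(seq_len(nrow(tab)), function(i) {
    sum(unclass(tab)[i, ]) != 1
  }, logical(1))]
  expect_identical(rownames(out), expected)
  expect_identical(unclass(remove_singletons(out))[, ], unclass(out)[, ])
})

test_that("rarefaction is exact-depth, never increases counts, drops shallow samples", {
  tab <- random_table(30, 5, lambda = 20, seed = 7)
  depth <- min(colSums(unclass(tab)))
  out <- rarefy(tab, depth, seed = 3)
  expect_true(all(colSums(unclass(out)) == depth))
  expect_true(all(unclass(out) <= unclass(tab)[, colnames(out)]))
  expect_identical(rarefy(tab, depth, seed = 3), out)

  # a sample at exactly the target depth is returned unchanged
  m <- matrix(c(10L, 15L, 3L, 2L), 2,
              dimnames = list(c("a", "b"), c("deep", "shallow")))
  expect_warning(out2 <- rarefy(otu_table(m), 25, seed = 1), "shallow")
  expect_identical(colnames(out2), "deep")
  expect_identical(unclass(out2)[, "deep"], c(a = 10L, b = 15L))
  expect_error(rarefy(tab, 0), "depth")
})

test_that("rarefaction draws follow the hypergeometric mean", {
  m <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s"))
  tab <- otu_table(m)
  draws <- vapply(1:2000, function(s) {
    unclass(rarefy(tab, 10, seed = s))["a", 1]
  }, integer(1))
  # hypergeometric(20, 10, 10): mean 5, var 10*0.5*0.5*(10/19)
  se <- sqrt(10 * 0.25 * 10 / 19 / 2000)
  expect_lt(abs(mean(draws) - 5), 3 * se)
})

test_that("relative abundance closes samples to one", {
  tab <- toy_table()
  rel <- relative_abundance(tab)
  expect_true(all(abs(colSums(rel) - 1) < 1e-12))
  expect_equal(unname(rel[, "s2"]), c(0, 1, 0))
  expect_equal(
    unname(relative_abundance(
      otu_table(matrix(c(1L, 3L), 2, 1,
                       dimnames = list(c("a", "b"), "s")))
    )[, 1]),
    c(0.25, 0.75)
  )
  zero <- otu_table(matrix(c(1L, 0L, 0L, 0L), 2,
                           dimnames = list(c("a", "b"), c("ok", "empty"))))
  expect_error(relative_abundance(zero), "empty")
})

test_that("mean-abundance filter is strict and matches brute force", {
  tab <- random_table(40, 8, seed = 11)
  thr <- 0.02
  out <- filter_by_mean_abundance(tab, thr)
  rel <- relative_abundance(tab)
  expect_identical(rownames(out), rownames(tab)[rowMeans(rel) > thr])

  # boundary: a taxon sitting exactly at the threshold is dropped
  m <- matrix(c(1L, 1L, 99L, 99L), 2, byrow = TRUE,
              dimnames = list(c("edge", "big"), c("s1", "s2")))
  out2 <- filter_by_mean_abundance(otu_table(m), 0.01)
  expect_identical(rownames(out2), "big")
})

test_that("taxonomy, metadata and sequence readers validate their formats", {
  tpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "OTU_1\td__Bacteria;p__Nitrospirota;c__Nitrospiria;o__Nitrospirales;f__Nitrospiraceae;g__Nitrospira",
    "OTU_2\td__Bacteria;p__Proteobacteria"
  ), tpath)
  tax <- read_taxonomy(tpath)
  expect_equal(tax$genus, c("Nitrospira", ""))
  expect_equal(tax$phylum, c("Nitrospirota", "Proteobacteria"))
  rt <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, rt)
  expect_equal(read_taxonomy(rt)$genus[1], "Nitrospira")

  mpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,plant,date,sample_type",
               "ST_2018-01,ST,2018-01,AS",
               "ST_2018-01b,ST,2018-01,XX"), mpath)
  expect_error(read_sample_info(mpath), "IN/AS/EFF")

  fpath <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">q1", "ACGTN"), fpath)
  expect_warning(read_sequences(fpath), "IUPAC")
})

test_that("rank collapse pools counts by label", {
  tab <- toy_table()
  tax <- toy_taxonomy(rownames(tab), genus = c("g1", "g1", "g2"))
  tax$phylum <- c("P1", "P1", "P2")
  out <- collapse_rank(tab, tax, "phylum")
  expect_equal(unname(unclass(out)["P1", ]), c(6L, 3L, 6L))
  expect_equal(unname(unclass(out)["P2", ]), c(0L, 0L, 7L))
})
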