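# shared fixtures, all built in code

toy_table <- function() {
  m <- matrix(
    c(5L, 0L, 2L,
      1L, 3L, 4L,
      0L, 0L, 7L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("OTU_a", "OTU_b", "OTU_c"), c("s1", "s2", "s3"))
  )
  otu_table(m)
}

random_table <- function(n_taxa, n_samples, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                                sprintf("s%02d", seq_len(n_samples))))
    otu_table(m)
  })
}

toy_taxonomy <- function(taxon_ids, genus) {
  tibble::tibble(
    taxon_id = taxon_ids,
    domain = "Bacteria", phylum = "Proteobacteria", class = "c",
    order = "o", family = "f", genus = genus, species = ""
  )
}

# edge tibble helper for set-arithmetic tests
edges_of <- function(pairs, sign = "+") {
  tibble::tibble(
    taxon_a = pmin(pairs[, 1], pairs[, 2]),
    taxon_b = pmax(pairs[, 1], pairs[, 2]),
    rho = ifelse(sign == "+", 0.9, -0.9),
    p_value = 0.001,
    sign = sign,
    method = "spearman"
  )
}

# independent Hellinger for ordination oracles
hellinger_oracle <- function(y) sqrt(y / rowSums(y))
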