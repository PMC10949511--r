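test_that("neutral simulator is deterministic and saturates at huge Nm", {
  a <- simulate_neutral_community(S = 40, n_samples = 5, N = 2000, m = 0.5,
                                  seed = 9)
  b <- simulate_neutral_community(S = 40, n_samples = 5, N = 2000, m = 0.5,
                                  seed = 9)
  expect_identical(a, b)

  # m = 1 with enormous N: every taxon present in every sample
  sat <- simulate_neutral_community(S = 2, n_samples = 20, N = 1e6, m = 1,
                                    p = c(0.5, 0.5), seed = 1)
  expect_true(all(unclass(sat$table) > 0))
})

test_that("neutral simulator occupancy tracks the finite-depth detection curve", {
  # one abundance bin at a time: many taxa of equal p, check mean occupancy
  S <- 3000
  N <- 25000
  nm <- 2089
  sim <- simulate_neutral_community(S = S, n_samples = 13, N = N,
                                    m = nm / N, seed = 5)
  f_obs <- rowMeans(unclass(sim$table) > 0)
  # bin taxa by true p; compare binned occupancy with the read-aware
  # prediction, which accounts for multinomial read sampling
  pred <- predict_occurrence(sim$p, nm / N, N, detection = "reads")
  bins <- cut(log10(sim$p), breaks = 8)
  for (b in levels(bins)) {
    idx <- bins == b
    n_eff <- sum(idx) * 13
    if (n_eff < 500) next
    se <- sqrt(mean(pred[idx]) * (1 - mean(pred[idx])) / n_eff)
    expect_lt(abs(mean(f_obs[idx]) - mean(pred[idx])), 4 * se + 0.01)
  }
})

test_that("neutral marginal mean relative abundance converges to p", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  sim <- simulate_neutral_community(S = 4, n_samples = 1000, N = 5000,
                                    m = 0.2, p = p, seed = 3)
  rel <- relative_abundance(sim$table)
  for (i in seq_along(p)) {
    se <- sd(rel[i, ]) / sqrt(1000)
    expect_lt(abs(mean(rel[i, ]) - p[i]), 3 * se + 1e-4)
  }
})

test_that("graph simulator plants recoverable partial correlations", {
  # chain edges carry larger latent partial correlations than non-edges
  hits <- vapply(1:20, function(s) {
    sim <- simulate_graph_community(p = 10, n_samples = 500, graph = "chain",
                                    strength = 0.3, N = 10000, seed = s)
    prec <- solve(cov(sim$latent))
    pc <- -prec / sqrt(diag(prec) %o% diag(prec))
    chain <- cbind(1:9, 2:10)
    on_edge <- mean(abs(pc[chain]))
    off <- abs(pc[upper.tri(pc)])
    all_pairs <- which(upper.tri(pc), arr.ind = TRUE)
    is_chain <- (all_pairs[, 2] - all_pairs[, 1]) == 1
    on_edge > mean(off[!is_chain])
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # empty graph: empirical partial correlations stay near zero at n = 500
  sim0 <- simulate_graph_community(p = 10, n_samples = 500,
                                   edges = matrix(integer(0), 0, 2),
                                   N = 10000, seed = 4)
  prec0 <- solve(cov(sim0$latent))
  pc0 <- -prec0 / sqrt(diag(prec0) %o% diag(prec0))
  expect_lt(max(abs(pc0[upper.tri(pc0)])), 0.15)

  expect_identical(
    simulate_graph_community(p = 8, n_samples = 20, seed = 2),
    simulate_graph_community(p = 8, n_samples = 20, seed = 2)
  )
  expect_error(
    simulate_graph_community(p = 10, n_samples = 20, graph = "chain",
                             strength = 0.9, seed = 1),
    "positive definite"
  )
})

test_that("planted guild taxonomy has exact member counts and recovers labels", {
  ids <- sprintf("OTU_%03d", 1:100)
  tax0 <- generate_taxonomy_and_guilds(ids, c(AOB = 0, NOB = 0), seed = 1)
  tab <- random_table(100, 4, seed = 1)
  rownames_tab <- rownames(tab)
  tax0$taxon_id <- rownames_tab
  g0 <- extract_guilds(tab, tax0)
  expect_equal(nrow(g0$members), 0)

  tax <- generate_taxonomy_and_guilds(ids, c(AOB = 0.1, NOB = 0.05,
                                             BFB = 0.1), seed = 2)
  expect_equal(sum(tax$true_guild == "AOB", na.rm = TRUE), 10)
  expect_equal(sum(tax$true_guild == "NOB", na.rm = TRUE), 5)
  tax$taxon_id <- rownames_tab
  g <- extract_guilds(tab, tax)
  # planted truth is recovered exactly, guild by guild
  for (gl in c("AOB", "NOB", "BFB")) {
    planted <- tax$taxon_id[!is.na(tax$true_guild) & tax$true_guild == gl]
    expect_setequal(g$members$taxon_id[g$members$guild == gl], planted)
  }
})

test_that("reference-set generator pins exact-match counts by construction", {
  qs <- random_dna(40, width = 120, seed = 6)
  pair <- generate_reference_set(qs, include_fraction = 0.5,
                                 mutation_rate = 0.01, seed = 7)
  expect_length(pair$included, 20)
  matches <- match_exact(pair$queries, pair$references)
  expect_setequal(matches$query_id[!is.na(matches$ref_id)], pair$included)

  all_in <- generate_reference_set(qs, include_fraction = 1, seed = 8)
  m1 <- match_exact(all_in$queries, all_in$references)
  expect_true(all(!is.na(m1$ref_id)))

  none <- generate_reference_set(qs, include_fraction = 0,
                                 mutation_rate = 0.02, seed = 9)
  m0 <- match_exact(none$queries, none$references)
  expect_true(all(is.na(m0$ref_id)))
})
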