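test_that("Spearman edges equal a brute-force rank-then-Pearson oracle", {
  tab <- random_table(6, 10, lambda = 8, seed = 13)
  edges <- spearman_network(tab, min_mean_rel = 0, alpha = 1)
  rel <- relative_abundance(tab)
  n <- ncol(rel)
  for (k in seq_len(nrow(edges))) {
    a <- rank(rel[edges$taxon_a[k], ])
    b <- rank(rel[edges$taxon_b[k], ])
    rho <- cor(a, b)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    expect_equal(edges$rho[k], rho, tolerance = 1e-12)
    expect_equal(edges$p_value[k], 2 * pt(-abs(tstat), n - 2),
                 tolerance = 1e-12)
    expect_equal(edges$sign[k], ifelse(rho >= 0, "+", "-"))
  }
  expect_equal(nrow(edges), choose(6, 2))
})

test_that("Spearman screen is invariant to monotone transforms and catches perfect trends", {
  # equal-total samples (as after rarefaction); a ballast taxon absorbs the
  # difference so per-taxon monotone transforms keep every relative-abundance
  # rank
  base <- withr::with_seed(17, matrix(rpois(5 * 13, 10) + 1L, 5, 13))
  make_closed <- function(m, total) {
    m <- rbind(m, ballast = total - colSums(m))
    rownames(m)[1:5] <- paste0("t", 1:5)
    colnames(m) <- paste0("s", 1:13)
    otu_table(m)
  }
  e1 <- spearman_network(make_closed(base, 1000L), min_mean_rel = 0,
                         alpha = 1)
  e2 <- spearman_network(make_closed(base^3, 100000L), min_mean_rel = 0,
                         alpha = 1)
  keep <- e1$taxon_a != "ballast" & e1$taxon_b != "ballast"
  expect_equal(e1$rho[keep], e2$rho[keep], tolerance = 1e-12)

  # strictly monotone pair over 13 samples -> rho 1, kept at any alpha
  m <- rbind(up1 = 1:13, up2 = (1:13)^2 + 5L)
  m <- rbind(m, ballast = 1000L - colSums(m))
  colnames(m) <- paste0("s", 1:13)
  e3 <- spearman_network(otu_table(m), min_mean_rel = 0, alpha = 0.001)
  pair <- e3[e3$taxon_a == "up1" & e3$taxon_b == "up2", ]
  expect_equal(pair$rho, 1)
  expect_equal(pair$p_value, 0)
})

test_that("CLR transform centers samples and matches hand arithmetic", {
  # counts [1,3] with pseudocount 1 -> log(2), log(4), centered
  m <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("a", "b"), "s"))
  z <- clr_transform(m)
  expect_equal(unname(z[, 1]), c(-log(2) / 2 - log(4) / 2 + log(2),
                                 log(4) - (log(2) + log(4)) / 2),
               tolerance = 1e-12)
  expect_equal(unname(z["a", 1]), -0.3466, tolerance = 1e-4)

  tab <- random_table(10, 5, seed = 3)
  z2 <- clr_transform(tab)
  expect_true(all(abs(colSums(z2)) < 1e-9))
  equal <- matrix(5L, 3, 2, dimnames = list(letters[1:3], c("x", "y")))
  expect_true(all(clr_transform(equal) == 0))
})

test_that("neighborhood selection is empty at lambda_max and recovers a planted chain", {
  sim <- simulate_graph_community(p = 30, n_samples = 120, graph = "chain",
                                  strength = 0.3, N = 10000, seed = 41)
  # at the top of the path the lasso selects nothing
  z <- clr_transform(sim$table)
  x <- scale(t(z))
  cv <- cov(x)
  lmax <- max(abs(cv[upper.tri(cv)]))
  e_top <- mb_network(sim$table, lambda = lmax * 1.0001)
  expect_equal(nrow(e_top), 0)

  e <- mb_network(sim$table, seed = 42)
  truth <- paste(sim$edges$taxon_a, sim$edges$taxon_b)
  est <- paste(e$taxon_a, e$taxon_b)
  tp <- sum(est %in% truth)
  f1 <- 2 * tp / (length(est) + length(truth))
  expect_gt(f1, 0.6)
  # instability bounded by 1/2 by construction
  expect_true(all(attr(e, "instability") <= 0.5 + 1e-12))
})

test_that("edge sets shrink along increasing penalty", {
  sim <- simulate_graph_community(p = 15, n_samples = 80, graph = "chain",
                                  strength = 0.3, N = 5000, seed = 51)
  z <- clr_transform(sim$table)
  x <- scale(t(z))
  cv <- cov(x)
  lmax <- max(abs(cv[upper.tri(cv)]))
  path <- exp(seq(log(lmax), log(0.01 * lmax), length.out = 10))
  sizes <- vapply(path, function(l) {
    nrow(mb_network(sim$table, lambda = l))
  }, numeric(1))
  # nearly nested: counts non-increasing as lambda grows (path is decreasing)
  expect_true(all(diff(sizes) >= -1))
})

test_that("method intersection is set arithmetic keeping Spearman annotations", {
  sp <- edges_of(rbind(c("A", "B"), c("A", "C"), c("B", "D")))
  mb <- tibble::tibble(taxon_a = c("A", "B", "C"),
                       taxon_b = c("B", "D", "D"), method = "mb")
  both <- intersect_methods(sp, mb)
  expect_setequal(paste(both$taxon_a, both$taxon_b), c("A B", "B D"))
  expect_true(all(both$method == "spearman+mb"))
  expect_true(all(c("rho", "p_value", "sign") %in% names(both)))

  # identical sets: intersection equals either
  same <- intersect_methods(sp, sp |> dplyr::mutate(method = "mb"))
  expect_equal(nrow(same), nrow(sp))
  # disjoint universes error
  mb2 <- tibble::tibble(taxon_a = "X", taxon_b = "Y", method = "mb")
  expect_error(intersect_methods(sp, mb2), "no taxa")
})

test_that("core taxa follow the strict prevalence and abundance rules", {
  make_tab <- function(hits, n = 13) {
    # focal taxon at 0.2% in `hits` samples, 0.05% otherwise; filler taxon
    focal <- ifelse(seq_len(n) <= hits, 20L, 5L)
    m <- rbind(focal = focal, filler = 10000L - focal)
    colnames(m) <- paste0("s", 1:n)
    otu_table(m)
  }
  expect_true("focal" %in% core_taxa(make_tab(11)))   # 11/13 = 84.6%
  expect_false("focal" %in% core_taxa(make_tab(10)))  # 10/13 = 76.9%

  # exactly at the abundance threshold everywhere -> not core (strict >)
  m <- rbind(edge = rep(1L, 13), rest = rep(999L, 13))
  colnames(m) <- paste0("s", 1:13)
  expect_false("edge" %in% core_taxa(otu_table(m)))
})

test_that("cross-plant consensus applies plant-count, sign and endpoint rules", {
  nets <- list(
    ST = edges_of(rbind(c("A", "B"), c("C", "D"), c("E", "F"))),
    TP = edges_of(rbind(c("A", "B"), c("E", "F"))),
    SWH = edges_of(rbind(c("A", "B"), c("G", "H")))
  )
  # flip the sign of E-F in TP: sign agreement drops it
  nets$TP$sign[2] <- "-"
  nets$TP$rho[2] <- -0.5
  cons <- cross_plant_consensus(nets, core_sets = "A", guild_sets = "Z",
                                min_plants = 2)
  expect_equal(paste(cons$edges$taxon_a, cons$edges$taxon_b), "A B")
  expect_equal(cons$edges$n_plants, 3)
  expect_setequal(cons$edges$plants[[1]], c("ST", "TP", "SWH"))

  # an NOB-guild endpoint rescues an edge seen in >= 2 plants
  cons2 <- cross_plant_consensus(nets, core_sets = character(),
                                 guild_sets = "E", min_plants = 2,
                                 require_sign_agreement = FALSE)
  expect_true("E F" %in% paste(cons2$edges$taxon_a, cons2$edges$taxon_b))
  # single-plant edges never survive
  expect_false("C D" %in% paste(cons2$edges$taxon_a, cons2$edges$taxon_b))
  # both-endpoint rule is stricter
  cons3 <- cross_plant_consensus(nets, core_sets = c("A"), guild_sets = "E",
                                 min_plants = 2, endpoint_rule = "both")
  expect_equal(nrow(cons3$edges), 0)
})

test_that("network statistics match hand-computed modularity", {
  # two disjoint triangles: Q = 2 * (3/6 - (6/12)^2) = 0.5
  tri <- edges_of(rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                        c("b1", "b2"), c("b1", "b3"), c("b2", "b3")))
  st <- network_stats(tri)
  expect_equal(st$n_nodes, 6L)
  expect_equal(st$n_edges, 6L)
  expect_equal(st$modularity, 0.5, tolerance = 1e-12)
  expect_equal(st$n_modules, 2L)
  expect_equal(st$positive_fraction, 1)
  expect_equal(st$mean_degree, 2)

  # complete graph: no structure to find
  k5 <- t(utils::combn(paste0("n", 1:5), 2))
  stk <- network_stats(edges_of(k5))
  expect_lt(stk$modularity, 1e-12)

  empty <- network_stats(tri[0, ])
  expect_equal(empty$n_edges, 0L)
  expect_true(is.na(empty$modularity))
})

test_that("graph exports write GraphML and GEXF", {
  nets <- list(ST = edges_of(rbind(c("A", "B"))),
               TP = edges_of(rbind(c("A", "B"))))
  cons <- cross_plant_consensus(nets, core_sets = "A", min_plants = 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_graphml(cons, gml)
  write_gexf(cons, gexf)
  expect_true(file.size(gml) > 0)
  gx <- readLines(gexf)
  expect_true(any(grepl("<node id=\"A\"", gx)))
  expect_true(any(grepl("source=\"A\" target=\"B\"", gx)))
})

test_that("BH adjustment and exact rank p-values are available on the screen", {
  tab <- random_table(6, 8, lambda = 10, seed = 23)
  raw <- spearman_network(tab, min_mean_rel = 0, alpha = 1)
  bh <- spearman_network(tab, min_mean_rel = 0, alpha = 1, p_adjust = "BH")
  expect_equal(bh$p_value, p.adjust(raw$p_value, "BH"), tolerance = 1e-12)

  ex <- spearman_network(tab, min_mean_rel = 0, alpha = 1, exact = TRUE)
  rel <- relative_abundance(tab)
  k <- 1
  ref <- suppressWarnings(cor.test(rel[ex$taxon_a[k], ], rel[ex$taxon_b[k], ],
                                   method = "spearman", exact = TRUE))
  expect_equal(ex$p_value[k], ref$p.value, tolerance = 1e-12)
})
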