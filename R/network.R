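# Co-occurrence network inference: Spearman screen, CLR + neighborhood
# selection with StARS, method intersection, core/guild filtering, consensus
# across plants, and graph statistics/export.

#' Spearman co-occurrence edges
#'
#' All pairwise Spearman rank correlations (mid-ranks for ties) between taxa
#' on per-sample relative abundances, with two-sided p-values from the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))`. Taxa are pre-filtered
#' to mean relative abundance strictly above `min_mean_rel` (the survey's
#' 0.01% screen); zero-variance taxa are excluded with a warning. Edges with
#' `p < alpha` are returned.
#'
#' @param table An [otu_table()].
#' @param min_mean_rel Mean relative-abundance screen (default `1e-4`).
#' @param alpha Per-edge significance threshold (0.05 for the per-plant
#'   screen; 0.01 for the method-intersection step).
#' @param p_adjust Optional multiple-testing correction applied before the
#'   `alpha` cut (any method of [stats::p.adjust()], e.g. `"BH"`); `"none"`
#'   (default) matches the raw thresholds of survey practice.
#' @param exact Use the exact null distribution of the rank statistic
#'   (via [stats::cor.test()], sensible for n <= 10 without ties) instead
#'   of the t-approximation.
#' @return Tibble of edges: `taxon_a < taxon_b`, `rho`, `p_value`, `sign`,
#'   `method = "spearman"`.
#' @export
spearman_network <- function(table, min_mean_rel = 1e-4, alpha = 0.05,
                             p_adjust = "none", exact = FALSE) {
  stopifnot_otu(table)
  if (ncol(table) < 4) abort("Need >= 4 samples for rank correlations.")
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  tab <- filter_by_mean_abundance(table, min_mean_rel)
  rel <- relative_abundance(tab)
  variances <- apply(rel, 1, var)
  if (any(variances == 0)) {
    warn(sprintf("Excluding %d zero-variance taxon/taxa from the Spearman screen.",
                 sum(variances == 0)))
    rel <- rel[variances > 0, , drop = FALSE]
  }
  p_taxa <- nrow(rel)
  if (p_taxa < 2) abort("Fewer than two variable taxa after filtering.")
  n <- ncol(rel)
  ranks <- t(apply(rel, 1, rank))       # mid-ranks
  rho <- cor(t(ranks))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[abs(rho) >= 1 - 1e-15] <- 0
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  if (exact) {
    pval_exact <- vapply(seq_len(nrow(ut)), function(k) {
      suppressWarnings(stats::cor.test(rel[ut[k, 1], ], rel[ut[k, 2], ],
                                       method = "spearman",
                                       exact = TRUE)$p.value)
    }, numeric(1))
  }
  out <- tibble(
    taxon_a = rownames(rel)[ut[, 1]],
    taxon_b = rownames(rel)[ut[, 2]],
    rho = rho[ut],
    p_value = if (exact) pval_exact else pval[ut]
  ) |>
    mutate(p_value = stats::p.adjust(.data$p_value, method = p_adjust)) |>
    filter(.data$p_value < alpha) |>
    mutate(
      sign = ifelse(.data$rho >= 0, "+", "-"),
      method = "spearman"
    )
  # canonical unordered order a < b
  swap <- out$taxon_a > out$taxon_b
  tmp <- out$taxon_a[swap]
  out$taxon_a[swap] <- out$taxon_b[swap]
  out$taxon_b[swap] <- tmp
  arrange(out, .data$taxon_a, .data$taxon_b)
}

#' Centered log-ratio transform
#'
#' `z_ij = log(c_ij + pseudocount) - mean_i log(c_ij + pseudocount)` within
#' each sample; the standard compositional preprocessing before
#' covariance-based network inference. Each sample's transformed values sum
#' to zero.
#'
#' @param table An [otu_table()] (or a non-negative count matrix).
#' @param pseudocount Added to every count before the log (default 1).
#' @return A numeric matrix, taxa by samples, columns summing to zero.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  m <- if (inherits(table, "otu_table")) unwrap(table) else as.matrix(table)
  if (any(m < 0)) abort("Counts must be non-negative.")
  logm <- log(m + pseudocount)
  sweep(logm, 2, colMeans(logm))
}

# one neighborhood-selection pass: adjacency (OR-rule) at each lambda
mb_path_adjacency <- function(x, lambda) {
  p <- ncol(x)
  adj <- array(FALSE, dim = c(p, p, length(lambda)))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(x[, -j, drop = FALSE], x[, j], lambda = lambda,
                          standardize = FALSE, intercept = FALSE)
    beta <- as.matrix(fit$beta)
    others <- seq_len(p)[-j]
    for (l in seq_len(ncol(beta))) {
      nz <- others[beta[, l] != 0]
      adj[j, nz, l] <- TRUE
    }
  }
  lapply(seq_along(lambda), function(l) adj[, , l] | t(adj[, , l]))
}

#' Conditional-dependence network by neighborhood selection with StARS
#'
#' The "mb" graph estimator on CLR-transformed counts: each taxon's CLR
#' profile is lasso-regressed on all others over a log-spaced penalty path
#' from `lambda_max` (the largest absolute empirical covariance of the
#' standardized CLR matrix) down to `lambda_min_ratio * lambda_max`; edges
#' are the union (OR rule) of nonzero coefficients. The penalty is chosen by
#' StARS stability selection: over `stars_B` subsamples of size
#' `floor(subsample_ratio * n)` drawn without replacement, per-edge selection
#' frequencies give the instability `D(lambda) = mean(2 * theta * (1 -
#' theta))`; the densest lambda whose monotonized instability stays at or
#' below `stars_beta` is kept and the graph refitted on the full data there.
#'
#' CLR profiles are standardized to unit variance before regression, the
#' convention of neighborhood-selection implementations in this field.
#'
#' @param table An [otu_table()], already screened to the taxa of interest
#'   (see [filter_by_mean_abundance()]).
#' @param lambda_path_length Number of penalties on the path (default 20).
#' @param lambda_min_ratio Smallest penalty as a fraction of `lambda_max`
#'   (default 0.01).
#' @param stars_B Number of StARS subsamples (default 50).
#' @param stars_beta Instability threshold (default 0.05).
#' @param subsample_ratio Subsample fraction (default 0.8, without
#'   replacement).
#' @param lambda Optional fixed penalty: skips StARS and fits the full data
#'   at this value.
#' @param seed Integer seed for the subsampling.
#' @return Tibble of edges (`taxon_a`, `taxon_b`, `method = "mb"`) with
#'   attributes `lambda_selected`, `lambda_path`, `instability` and
#'   `taxon_ids`.
#' @export
mb_network <- function(table, lambda_path_length = 20,
                       lambda_min_ratio = 0.01, stars_B = 50,
                       stars_beta = 0.05, subsample_ratio = 0.8,
                       lambda = NULL, seed = 0) {
  stopifnot_otu(table)
  seed <- check_seed(seed)
  z <- clr_transform(table)
  keep <- apply(z, 1, var) > 0
  if (any(!keep)) {
    warn(sprintf("Excluding %d constant CLR profile(s).", sum(!keep)))
    z <- z[keep, , drop = FALSE]
  }
  taxa <- rownames(z)
  x <- scale(t(z))                      # samples x taxa, unit variance
  n <- nrow(x)
  p <- ncol(x)
  if (n < 6) abort("Need >= 6 samples for neighborhood selection.")
  cv <- cov(x)
  lambda_max <- max(abs(cv[upper.tri(cv)]))
  path <- exp(seq(log(lambda_max), log(lambda_min_ratio * lambda_max),
                  length.out = lambda_path_length))
  if (!is.null(lambda)) {
    adj <- mb_path_adjacency(x, lambda)[[1]]
    return(adjacency_to_edges(adj, taxa, lambda, path, NULL))
  }
  m_sub <- floor(subsample_ratio * n)
  sel_counts <- array(0, dim = c(p, p, length(path)))
  with_seed(seed, {
    for (b in seq_len(stars_B)) {
      idx <- sample.int(n, m_sub)
      sub_adj <- mb_path_adjacency(scale(x[idx, , drop = FALSE]), path)
      for (l in seq_along(path)) {
        sel_counts[, , l] <- sel_counts[, , l] + sub_adj[[l]]
      }
    }
  })
  ut <- upper.tri(diag(p))
  instability <- vapply(seq_along(path), function(l) {
    theta <- sel_counts[, , l][ut] / stars_B
    mean(2 * theta * (1 - theta))
  }, numeric(1))
  # path runs dense-ward; monotonize along increasing density
  mono <- cummax(instability)
  ok <- which(mono <= stars_beta)
  sel <- if (length(ok)) max(ok) else 1L
  adj <- mb_path_adjacency(x, path)[[sel]]
  adjacency_to_edges(adj, taxa, path[sel], path, instability)
}

adjacency_to_edges <- function(adj, taxa, lambda_selected, path,
                               instability) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  out <- tibble(
    taxon_a = taxa[idx[, 1]],
    taxon_b = taxa[idx[, 2]],
    method = rep("mb", nrow(idx))
  )
  swap <- out$taxon_a > out$taxon_b
  tmp <- out$taxon_a[swap]
  out$taxon_a[swap] <- out$taxon_b[swap]
  out$taxon_b[swap] <- tmp
  out <- arrange(out, .data$taxon_a, .data$taxon_b)
  structure(out, lambda_selected = lambda_selected, lambda_path = path,
            instability = instability, taxon_ids = taxa)
}

#' Intersect Spearman and conditional-dependence edge sets
#'
#' Keeps unordered taxon pairs present in both inputs; correlation strength,
#' p-value and sign are carried from the Spearman side. The two edge sets
#' must come from the same taxon universe.
#'
#' @param spearman_edges Edges from [spearman_network()] (typically at
#'   `alpha = 0.01` for this step).
#' @param mb_edges Edges from [mb_network()].
#' @return Tibble of intersected edges with `method = "spearman+mb"`.
#' @export
intersect_methods <- function(spearman_edges, mb_edges) {
  sp_taxa <- unique(c(spearman_edges$taxon_a, spearman_edges$taxon_b))
  mb_universe <- attr(mb_edges, "taxon_ids") %||%
    unique(c(mb_edges$taxon_a, mb_edges$taxon_b))
  if (length(sp_taxa) && length(mb_universe) &&
      !length(intersect(sp_taxa, mb_universe))) {
    abort("Spearman and MB edge sets share no taxa; were they computed on the same table?")
  }
  spearman_edges |>
    inner_join(mb_edges |> select("taxon_a", "taxon_b"),
               by = c("taxon_a", "taxon_b")) |>
    mutate(method = "spearman+mb")
}

#' Core taxa of a table
#'
#' Taxa whose relative abundance strictly exceeds `min_rel` in strictly more
#' than a `prevalence` fraction of samples — the survey's definition of core
#' membership (above 0.1% abundance in more than 80% of samples).
#'
#' @param table An [otu_table()].
#' @param prevalence Prevalence fraction threshold (strict, default 0.8).
#' @param min_rel Relative-abundance threshold (strict, default `1e-3`).
#' @return Character vector of core taxon ids.
#' @export
core_taxa <- function(table, prevalence = 0.8, min_rel = 1e-3) {
  stopifnot_otu(table)
  rel <- relative_abundance(table)
  hit <- rowMeans(rel > min_rel)
  rownames(rel)[hit > prevalence]
}

#' Consensus network across plants
#'
#' Combines per-plant intersected networks: an unordered pair is kept when it
#' is detected (with the same sign, by default) in at least `min_plants`
#' plants and at least one endpoint belongs to the union of the core and
#' functional-guild taxon sets. Node metadata records the relationship
#' frequency (number of retained edges touching the node) used for node
#' sizing in co-occurrence figures.
#'
#' @param per_plant_networks Named list (plant id -> edge tibble as from
#'   [intersect_methods()] or [spearman_network()]).
#' @param core_sets Character vector (or list thereof) of core taxon ids.
#' @param guild_sets Character vector (or list thereof) of functional taxon
#'   ids.
#' @param min_plants Minimum number of plants an edge must appear in
#'   (default 2).
#' @param require_sign_agreement Count an edge only when its sign is
#'   consistent across plants (default TRUE).
#' @param endpoint_rule `"any"` (default): one endpoint in the privileged
#'   set suffices; `"both"`: both endpoints required.
#' @return A `consensus_network`: list with `edges` (tibble incl. `plants`
#'   and `n_plants`) and `nodes` (tibble with core/guild flags and
#'   `relationship_frequency`).
#' @export
cross_plant_consensus <- function(per_plant_networks, core_sets = character(),
                                  guild_sets = character(), min_plants = 2,
                                  require_sign_agreement = TRUE,
                                  endpoint_rule = c("any", "both")) {
  endpoint_rule <- match.arg(endpoint_rule)
  if (length(per_plant_networks) < 2) {
    abort("Consensus needs networks from >= 2 plants.")
  }
  if (is.null(names(per_plant_networks))) {
    abort("`per_plant_networks` must be named by plant id.")
  }
  privileged <- union(unlist(core_sets, use.names = FALSE),
                      unlist(guild_sets, use.names = FALSE))
  all_edges <- purrr::imap(per_plant_networks, function(e, plant) {
    e$plant <- plant
    if (!"sign" %in% names(e)) e$sign <- NA_character_
    if (!"rho" %in% names(e)) e$rho <- NA_real_
    e[c("taxon_a", "taxon_b", "sign", "rho", "plant")]
  }) |>
    bind_rows()
  grouping <- if (require_sign_agreement) {
    c("taxon_a", "taxon_b", "sign")
  } else {
    c("taxon_a", "taxon_b")
  }
  edges <- all_edges |>
    group_by(across(all_of(grouping))) |>
    summarise(
      n_plants = dplyr::n_distinct(.data$plant),
      plants = list(sort(unique(.data$plant))),
      rho_mean = mean(.data$rho),
      sign = if (require_sign_agreement) dplyr::first(.data$sign) else {
        ifelse(mean(.data$rho) >= 0, "+", "-")
      },
      .groups = "drop"
    ) |>
    filter(.data$n_plants >= min_plants)
  if (length(privileged)) {
    keep <- if (endpoint_rule == "any") {
      edges$taxon_a %in% privileged | edges$taxon_b %in% privileged
    } else {
      edges$taxon_a %in% privileged & edges$taxon_b %in% privileged
    }
    edges <- edges[keep, ]
  }
  node_ids <- sort(unique(c(edges$taxon_a, edges$taxon_b)))
  freq <- table(c(edges$taxon_a, edges$taxon_b))
  nodes <- tibble(
    taxon_id = node_ids,
    core = node_ids %in% unlist(core_sets, use.names = FALSE),
    guild = node_ids %in% unlist(guild_sets, use.names = FALSE),
    relationship_frequency = as.integer(freq[node_ids])
  )
  structure(
    list(edges = arrange(edges, .data$taxon_a, .data$taxon_b),
         nodes = nodes,
         provenance = list(min_plants = min_plants,
                           require_sign_agreement = require_sign_agreement,
                           endpoint_rule = endpoint_rule,
                           n_plants_input = length(per_plant_networks),
                           per_plant_edge_counts =
                             vapply(per_plant_networks, nrow, integer(1)))),
    class = "consensus_network"
  )
}

#' @exportS3Method base::print
print.consensus_network <- function(x, ...) {
  cat(sprintf("<consensus_network> %d edges over %d nodes (>= %d plants)\n",
              nrow(x$edges), nrow(x$nodes), x$provenance$min_plants))
  invisible(x)
}

edges_to_igraph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) {
    nodes <- tibble(taxon_id = sort(unique(c(edges$taxon_a, edges$taxon_b))))
  }
  igraph::graph_from_data_frame(
    d = as.data.frame(edges[c("taxon_a", "taxon_b",
                              intersect(names(edges),
                                        c("rho", "sign", "n_plants")))]),
    directed = FALSE,
    vertices = as.data.frame(nodes)
  )
}

#' Summary statistics of a co-occurrence network
#'
#' Node/edge counts, fraction of positive edges, mean degree, and modularity
#' by greedy agglomerative maximization of Newman's Q on the unsigned graph
#' (with module count and memberships).
#'
#' @param network A `consensus_network` or an edge tibble.
#' @return A list: `n_nodes`, `n_edges`, `positive_fraction`, `mean_degree`,
#'   `modularity`, `n_modules`, `membership` (named vector; `NULL` for an
#'   empty graph).
#' @export
network_stats <- function(network) {
  edges <- if (inherits(network, "consensus_network")) {
    network$edges
  } else {
    network
  }
  if (nrow(edges) == 0) {
    return(list(n_nodes = 0L, n_edges = 0L, positive_fraction = NA_real_,
                mean_degree = 0, modularity = NA_real_, n_modules = 0L,
                membership = NULL))
  }
  g <- edges_to_igraph(edges)
  comm <- igraph::cluster_fast_greedy(g)
  pos_frac <- if ("sign" %in% names(edges) && !all(is.na(edges$sign))) {
    mean(edges$sign == "+", na.rm = TRUE)
  } else {
    NA_real_
  }
  list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    positive_fraction = pos_frac,
    mean_degree = mean(igraph::degree(g)),
    modularity = igraph::modularity(comm),
    n_modules = length(unique(igraph::membership(comm))),
    membership = setNames(as.integer(igraph::membership(comm)),
                          igraph::V(g)$name)
  )
}

#' Export a network to GraphML
#' @param network A `consensus_network` or edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  nodes <- if (inherits(network, "consensus_network")) network$nodes else NULL
  edges <- if (inherits(network, "consensus_network")) {
    network$edges
  } else {
    network
  }
  g <- edges_to_igraph(edges, nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Export a network to GEXF
#'
#' Minimal GEXF 1.2 writer carrying node attributes (core and guild flags,
#' relationship frequency) and edge attributes (sign, plant count).
#'
#' @param network A `consensus_network` or edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(network, path) {
  nodes <- if (inherits(network, "consensus_network")) {
    network$nodes
  } else {
    tibble(taxon_id = sort(unique(c(network$taxon_a, network$taxon_b))),
           core = NA, guild = NA, relationship_frequency = NA_integer_)
  }
  edges <- if (inherits(network, "consensus_network")) {
    network$edges
  } else {
    network
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph defaultedgetype="undirected">')
  w('    <attributes class="node">')
  w('      <attribute id="0" title="core" type="boolean"/>')
  w('      <attribute id="1" title="guild" type="boolean"/>')
  w('      <attribute id="2" title="relationship_frequency" type="integer"/>')
  w('    </attributes>')
  w('    <nodes>')
  for (i in seq_len(nrow(nodes))) {
    w('      <node id="%s" label="%s">', xml_escape(nodes$taxon_id[i]),
      xml_escape(nodes$taxon_id[i]))
    w('        <attvalues>')
    w('          <attvalue for="0" value="%s"/>',
      tolower(as.character(isTRUE(nodes$core[i]))))
    w('          <attvalue for="1" value="%s"/>',
      tolower(as.character(isTRUE(nodes$guild[i]))))
    w('          <attvalue for="2" value="%s"/>',
      ifelse(is.na(nodes$relationship_frequency[i]), "0",
             nodes$relationship_frequency[i]))
    w('        </attvalues>')
    w('      </node>')
  }
  w('    </nodes>')
  w('    <edges>')
  for (i in seq_len(nrow(edges))) {
    lab <- if ("sign" %in% names(edges)) edges$sign[i] else ""
    w('      <edge id="%d" source="%s" target="%s" label="%s"/>', i,
      xml_escape(edges$taxon_a[i]), xml_escape(edges$taxon_b[i]),
      xml_escape(lab %||% ""))
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}
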