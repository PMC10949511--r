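#' Draw abundances from a Fisher log-series
#'
#' Integer abundances with P(k) proportional to `p^k / k`, the classic
#' long-tailed species-abundance model. Used as the default metacommunity for
#' [simulate_neutral_community()].
#'
#' @param n Number of draws.
#' @param p Log-series parameter in (0, 1); values near 1 give heavier tails.
#'   The default 0.999 leaves roughly half of a 3,000-taxon metacommunity
#'   below the one-read detection limit at 25,000 reads/sample.
#' @param kmax Truncation of the support (the renormalized tail mass beyond
#'   `kmax` is negligible at the default).
#' @return Integer vector of abundances.
#' @export
rlogseries <- function(n, p = 0.999, kmax = 2e5) {
  check_number(p, "p", lower = 0, upper = 1, strict_lower = TRUE,
               strict_upper = TRUE)
  k <- seq_len(kmax)
  sample.int(kmax, n, replace = TRUE, prob = p^k / k)
}

#' Simulate a neutral local-community OTU table
#'
#' Generates count tables under the Sloan neutral model: metacommunity
#' relative abundances `p` are drawn from a log-series (or lognormal) and
#' normalized; each sample's composition is drawn from a
#' `Dirichlet(N * m * p)` — so each taxon's marginal relative abundance is
#' `Beta(Nmp, Nm(1-p))` — and `N` reads are then drawn multinomially.
#'
#' Note that the final read-sampling step means detection (count >= 1) is
#' governed by the beta-binomial tail, not the Beta tail at `1/N`; see
#' [fit_ncm()]'s `detection` argument for the matching fit.
#'
#' @param S Number of taxa in the metacommunity (>= 2).
#' @param n_samples Number of local communities (samples).
#' @param N Reads per sample.
#' @param m Migration rate in (0, 1]; `Nm = N * m` is the dispersal parameter.
#' @param metacommunity `"logseries"` or `"lognormal"`.
#' @param ls_p Log-series parameter (see [rlogseries()]).
#' @param meanlog,sdlog Lognormal parameters when
#'   `metacommunity = "lognormal"`.
#' @param p Optional metacommunity relative-abundance vector (length `S`),
#'   e.g. to share one metacommunity across several simulated plants;
#'   overrides `metacommunity`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A list with `table` (an [otu_table()]) and `p` (the true
#'   metacommunity relative abundances, named by taxon).
#' @export
#' @examples
#' sim <- simulate_neutral_community(S = 50, n_samples = 6, N = 1000,
#'                                   m = 0.5, seed = 1)
#' sim$table
simulate_neutral_community <- function(S, n_samples, N, m,
                                       metacommunity = c("logseries",
                                                         "lognormal"),
                                       ls_p = 0.999, meanlog = 0, sdlog = 2,
                                       p = NULL, seed = 0) {
  metacommunity <- match.arg(metacommunity)
  check_number(S, "S", lower = 2)
  check_number(n_samples, "n_samples", lower = 1)
  check_number(N, "N", lower = 1)
  check_number(m, "m", lower = 0, upper = 1, strict_lower = TRUE)
  seed <- check_seed(seed)
  with_seed(seed, {
    if (is.null(p)) {
      p <- switch(metacommunity,
        logseries = rlogseries(S, ls_p),
        lognormal = stats::rlnorm(S, meanlog, sdlog)
      )
    } else if (length(p) != S || any(p <= 0)) {
      abort("`p` must be a positive vector of length S.")
    }
    p <- p / sum(p)
    counts <- vapply(seq_len(n_samples), function(j) {
      g <- rgamma(S, shape = N * m * p)
      if (sum(g) <= 0) abort("Degenerate Dirichlet draw; increase N*m.")
      rmultinom(1, N, prob = g / sum(g))[, 1]
    }, integer(S))
    dimnames(counts) <- list(sprintf("OTU_%04d", seq_len(S)),
                             sprintf("S%02d", seq_len(n_samples)))
    list(table = otu_table(counts), p = setNames(p, rownames(counts)))
  })
}

#' Simulate an OTU table with a known conditional-dependence graph
#'
#' Latent multivariate normal with a sparse precision matrix implied by the
#' requested graph (partial correlation `strength` on each edge), pushed
#' through a softmax to compositions and sampled multinomially at depth `N`.
#' The planted edge set is returned for recovery scoring of network methods.
#'
#' @param p Number of taxa.
#' @param n_samples Number of samples.
#' @param graph `"chain"`, `"band"` or `"random"`; alternatively pass an
#'   explicit two-column edge matrix via `edges`.
#' @param edges Optional integer matrix (edges x 2) overriding `graph`.
#' @param band_width Band width when `graph = "band"`.
#' @param density Edge density when `graph = "random"`.
#' @param strength Partial-correlation magnitude on each edge (default 0.3).
#' @param N Sequencing depth per sample (default 25,000, the survey's
#'   rarefaction depth).
#' @param seed Integer seed.
#' @return A list with `table` (an [otu_table()]), `edges` (tibble of the
#'   planted taxon pairs) and `latent` (the samples-by-taxa latent Gaussian
#'   matrix, useful as an oracle when scoring recovery).
#' @export
simulate_graph_community <- function(p, n_samples,
                                     graph = c("chain", "band", "random"),
                                     edges = NULL, band_width = 2,
                                     density = 0.04, strength = 0.3,
                                     N = 25000, seed = 0) {
  check_number(p, "p", lower = 2)
  check_number(n_samples, "n_samples", lower = 1)
  seed <- check_seed(seed)
  with_seed(seed, {
    if (is.null(edges)) {
      graph <- match.arg(graph)
      edges <- switch(graph,
        chain = cbind(seq_len(p - 1), seq_len(p - 1) + 1L),
        band = {
          e <- NULL
          for (w in seq_len(band_width)) {
            if (p - w >= 1) e <- rbind(e, cbind(seq_len(p - w),
                                                seq_len(p - w) + w))
          }
          e
        },
        random = {
          all_pairs <- t(utils::combn(p, 2))
          take <- runif(nrow(all_pairs)) < density
          all_pairs[take, , drop = FALSE]
        }
      )
    }
    edges <- matrix(as.integer(edges), ncol = 2)
    omega <- diag(p)
    if (nrow(edges)) {
      for (k in seq_len(nrow(edges))) {
        i <- edges[k, 1]; j <- edges[k, 2]
        if (i == j) abort("Self-edges are not allowed.")
        omega[i, j] <- omega[j, i] <- -strength
      }
    }
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      abort("Implied precision matrix is not positive definite; lower `strength` or `density`.")
    }
    sigma <- solve(omega)
    z <- matrix(rnorm(n_samples * p), n_samples, p) %*% chol(sigma)
    counts <- vapply(seq_len(n_samples), function(s) {
      w <- exp(z[s, ])
      rmultinom(1, N, prob = w / sum(w))[, 1]
    }, integer(p))
    taxa <- sprintf("OTU_%04d", seq_len(p))
    dimnames(counts) <- list(taxa, sprintf("S%03d", seq_len(n_samples)))
    edge_tbl <- order_pair(taxa[edges[, 1]], taxa[edges[, 2]]) |>
      distinct()
    dimnames(z) <- list(colnames(counts), taxa)
    list(table = otu_table(counts), edges = edge_tbl, latent = z)
  })
}

# synthetic lineage building blocks: guild-bearing genera per the survey's
# functional-group reading, plus neutral background genera
guild_genus_pool <- function() {
  list(
    AOB = c("Nitrosomonas", "oc32", "Ellin6067", "DSSD61", "mle1-7", "966-1",
            "Nitrosococcus", "Nitrosospira"),
    NOB = c("Nitrospira", "Nitrobacter", "Candidatus Nitrotoga",
            "Nitrolancea", "Nitrococcus", "Nitrospina"),
    PAO = c("Candidatus Accumulibacter", "Tetrasphaera"),
    BFB = c("Acinetobacter", "Caldilinea", "Gordonia", "Moraxella",
            "Mycobacterium", "Skermania", "Thiothrix", "Defluviicoccus",
            "Candidatus Microthrix"),
    anammox = c("Candidatus Brocadia")
  )
}

#' Generate a synthetic taxonomy with planted functional guilds
#'
#' Assigns full 7-rank lineages to the given taxa. Requested fractions of the
#' taxa receive guild-bearing genera (e.g. `g__Nitrosomonas` for AOB,
#' `g__Nitrospira` for NOB) so that guild extraction can be scored against a
#' planted truth; the remainder get neutral background lineages.
#'
#' @param taxon_ids Character vector of taxon identifiers.
#' @param guild_fractions Named numeric vector over any of
#'   `AOB, NOB, PAO, BFB, anammox`; fractions must sum to at most 1. The
#'   planted member count per guild is `round(fraction * n)`.
#' @param seed Integer seed.
#' @return A taxonomy tibble (as from [read_taxonomy()]) with an additional
#'   `true_guild` column (`NA` for background taxa).
#' @export
generate_taxonomy_and_guilds <- function(taxon_ids,
                                         guild_fractions = c(AOB = 0.05,
                                                             NOB = 0.05),
                                         seed = 0) {
  if (sum(guild_fractions) > 1 + 1e-12) {
    abort("`guild_fractions` must sum to at most 1.")
  }
  bad <- setdiff(names(guild_fractions), names(guild_genus_pool()))
  if (length(bad)) {
    abort(sprintf("Unknown guild(s): %s", paste(bad, collapse = ", ")))
  }
  seed <- check_seed(seed)
  n <- length(taxon_ids)
  with_seed(seed, {
    pool <- guild_genus_pool()
    background <- c("Dechloromonas", "Zoogloea", "Flavobacterium",
                    "Haliangium", "Terrimonas", "Ferruginibacter",
                    "Rhodobacter", "Pseudomonas", "Hyphomicrobium",
                    "Comamonas", "Paracoccus", "Sphingomonas")
    phyla <- c("Proteobacteria", "Bacteroidota", "Chloroflexi",
               "Actinobacteriota", "Nitrospirota", "Planctomycetota")
    guild <- rep(NA_character_, n)
    genus <- sample(background, n, replace = TRUE)
    free <- seq_len(n)
    for (g in names(guild_fractions)) {
      k <- round(guild_fractions[[g]] * n)
      if (k == 0) next
      take <- sample(free, k)
      guild[take] <- g
      genus[take] <- sample(pool[[g]], k, replace = TRUE)
      free <- setdiff(free, take)
    }
    tibble(
      taxon_id = as.character(taxon_ids),
      domain = "Bacteria",
      phylum = sample(phyla, n, replace = TRUE),
      class = paste0(genus, "ia"),
      order = paste0(genus, "ales"),
      family = paste0(genus, "aceae"),
      genus = genus,
      species = "",
      true_guild = guild
    )
  })
}

#' Random DNA sequences
#' @param n Number of sequences.
#' @param width Sequence length in nt.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet].
#' @export
random_dna <- function(n, width = 300, seed = 0) {
  seed <- check_seed(seed)
  with_seed(seed, {
    s <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(setNames(s, sprintf("OTU_%04d", seq_len(n))))
  })
}

#' Generate a query/reference FASTA pair with known match structure
#'
#' A chosen fraction of the query sequences is embedded verbatim (inside
#' longer flanking sequence) in the reference set; the remaining queries are
#' copied with at least one substitution so they can never match under the
#' exact criterion. The construction pins the downstream genome-sequenced
#' proportions exactly.
#'
#' @param otu_sequences Queries as a [Biostrings::DNAStringSet] (or named
#'   character vector).
#' @param include_fraction Fraction of queries present verbatim in the
#'   references; the included count is `round(fraction * n)`.
#' @param mutation_rate Per-base substitution probability applied to excluded
#'   queries (at least one substitution is always forced).
#' @param flank Width of random flanking sequence on each side of an embedded
#'   query.
#' @param seed Integer seed.
#' @return A list of two `DNAStringSet`s: `queries` and `references`, plus
#'   `included`, the ids of the verbatim-embedded queries.
#' @export
generate_reference_set <- function(otu_sequences, include_fraction = 0.5,
                                   mutation_rate = 0.02, flank = 50,
                                   seed = 0) {
  check_number(include_fraction, "include_fraction", lower = 0, upper = 1)
  check_number(mutation_rate, "mutation_rate", lower = 0, upper = 1)
  seed <- check_seed(seed)
  if (!methods::is(otu_sequences, "DNAStringSet")) {
    otu_sequences <- Biostrings::DNAStringSet(otu_sequences)
  }
  n <- length(otu_sequences)
  if (n == 0) abort("Empty query set.")
  with_seed(seed, {
    k <- round(include_fraction * n)
    inc <- sort(sample.int(n, k))
    bases <- c("A", "C", "G", "T")
    refs <- character(n)
    for (i in seq_len(n)) {
      q <- as.character(otu_sequences[[i]])
      if (i %in% inc) {
        left <- paste(sample(bases, flank, TRUE), collapse = "")
        right <- paste(sample(bases, flank, TRUE), collapse = "")
        refs[i] <- paste0(left, q, right)
      } else {
        ch <- strsplit(q, "")[[1]]
        hit <- which(runif(length(ch)) < mutation_rate)
        if (!length(hit)) hit <- sample(length(ch), 1)
        ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1),
                          character(1))
        refs[i] <- paste(ch, collapse = "")
      }
    }
    names(refs) <- sprintf("REF_%04d", seq_len(n))
    list(
      queries = otu_sequences,
      references = Biostrings::DNAStringSet(refs),
      included = names(otu_sequences)[inc]
    )
  })
}
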