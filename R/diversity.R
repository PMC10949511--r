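#' Per-sample alpha diversity
#'
#' Richness (observed taxa), Shannon entropy `H = -sum(q * log(q))` over
#' non-zero relative abundances (natural log), and Pielou evenness
#' `H / log(richness)` (reported as `NA` for single-taxon samples, where it
#' is undefined).
#'
#' @param table An [otu_table()].
#' @return A tibble with one row per sample: `sample_id`, `richness`,
#'   `shannon`, `pielou_evenness`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 4, 4), nrow = 3,
#'             dimnames = list(paste0("t", 1:3), c("a", "b")))
#' alpha_diversity(otu_table(m))
alpha_diversity <- function(table) {
  stopifnot_otu(table)
  rel <- relative_abundance(table)
  richness <- colSums(rel > 0)
  shannon <- vegan::diversity(t(unwrap(table)), index = "shannon")
  tibble(
    sample_id = colnames(table),
    richness = as.integer(richness),
    shannon = unname(shannon),
    pielou_evenness = ifelse(richness > 1, unname(shannon) / log(richness),
                             NA_real_)
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(u, v) = sum|u - v| / sum(u + v)`, computed on per-sample relative
#' abundances (after rarefaction this equals the count-based value). Pass a
#' taxonomy and `rank` to aggregate first, as in phylum-level community
#' comparisons.
#'
#' @param table An [otu_table()].
#' @param taxonomy Optional taxonomy tibble for rank aggregation.
#' @param rank Rank used when `taxonomy` is given.
#' @return A symmetric `dist`-convertible matrix in `[0, 1]` with zero
#'   diagonal and samples as dimnames.
#' @export
bray_curtis <- function(table, taxonomy = NULL, rank = "phylum") {
  stopifnot_otu(table)
  if (ncol(table) < 2) abort("Need at least two samples.")
  if (!is.null(taxonomy)) table <- collapse_rank(table, taxonomy, rank)
  rel <- relative_abundance(table)
  d <- as.matrix(vegan::vegdist(t(rel), method = "bray"))
  dimnames(d) <- list(colnames(table), colnames(table))
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling: Gower double-centering of the squared
#' dissimilarities followed by an eigendecomposition. Negative eigenvalues
#' (non-Euclidean input) are reported, not corrected; coordinates are
#' returned for the positive axes only.
#'
#' @param dm Symmetric dissimilarity matrix (as from [bray_curtis()]).
#' @param n_axes Number of axes to retain (capped at the positive-eigenvalue
#'   count).
#' @return An object of class `ascomm_pcoa`: list with `coordinates` (tibble,
#'   one row per sample), `eigenvalues`, and `proportion_explained` (over the
#'   positive eigenvalues).
#' @export
pcoa <- function(dm, n_axes = 2) {
  check_number(n_axes, "n_axes", lower = 1)
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-12) {
    abort("`dm` must be a symmetric square matrix.")
  }
  if (any(abs(diag(dm)) > 1e-12)) abort("`dm` must have a zero diagonal.")
  n <- nrow(dm)
  a <- -0.5 * dm^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  eig <- eigen((g + t(g)) / 2, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(values[1], 0) * 1e-12 & values > 0)
  k <- min(n_axes, length(pos))
  coords <- if (k > 0) {
    sweep(eig$vectors[, pos[seq_len(k)], drop = FALSE], 2,
          sqrt(values[pos[seq_len(k)]]), "*")
  } else {
    matrix(0, n, 0)
  }
  ids <- rownames(dm) %||% paste0("sample", seq_len(n))
  colnames(coords) <- if (k > 0) paste0("axis", seq_len(k)) else character(0)
  coord_tbl <- as_tibble(coords, .name_repair = "minimal")
  structure(
    list(
      coordinates = bind_cols(tibble(sample_id = ids), coord_tbl),
      eigenvalues = values,
      proportion_explained = if (length(pos)) {
        values[pos] / sum(values[pos])
      } else numeric(0),
      n_axes = k
    ),
    class = "ascomm_pcoa"
  )
}

#' @exportS3Method base::print
print.ascomm_pcoa <- function(x, ...) {
  cat(sprintf("<pcoa> %d samples, %d positive axes retained\n",
              nrow(x$coordinates), x$n_axes))
  if (length(x$proportion_explained)) {
    cat("  proportion explained:",
        paste(sprintf("%.1f%%", 100 * head(x$proportion_explained, 4)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.ascomm_pcoa <- function(x, ...) x$coordinates

#' Ordination scatter plot
#' @param object An `ascomm_pcoa` object.
#' @param colour Optional vector (length = samples) mapped to point colour,
#'   e.g. plant or sample type.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ascomm_pcoa <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (object$n_axes < 2) abort("Need at least two retained axes to plot.")
  if (!is.null(colour)) df$colour <- colour
  pe <- 100 * object$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", pe[1]),
      y = sprintf("PCo2 (%.1f%%)", pe[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}
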