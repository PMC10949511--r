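# Redundancy analysis of community (guild-OTU) abundances against
# operational parameters, implemented from first principles, plus simple
# parameter-taxon correlation over time.

hellinger <- function(y) {
  totals <- rowSums(y)
  if (any(totals <= 0)) abort("Hellinger transform needs positive row sums.")
  sqrt(y / totals)
}

#' Redundancy analysis (RDA)
#'
#' Constrained ordination of a community matrix `Y` (samples x taxa) on an
#' explanatory matrix `X` (samples x parameters). `Y` is optionally
#' Hellinger-transformed then column-centered; `X` is standardized. The
#' fitted values `Yhat = X (X'X)^-1 X' Y` are decomposed by SVD into
#' canonical axes; the constrained proportion is `||Yhat||^2 / ||Y||^2`.
#' Per-parameter marginal importance is the constrained proportion of a
#' single-variable RDA, and significance comes from permuting the sample
#' rows of `X` against the pseudo-F statistic.
#'
#' @param Y Samples-by-taxa abundance matrix or data frame.
#' @param X Samples-by-parameters numeric matrix or data frame (rows aligned
#'   with `Y`).
#' @param transform `"hellinger"` (default) or `"none"`.
#' @param n_perm Number of permutations for p-values (default 999).
#' @param seed Integer seed for the permutations.
#' @return An `rda_result`: canonical `eigenvalues`,
#'   `constrained_proportion`, `site_scores`, `species_scores`,
#'   `biplot_scores`, `pseudo_f`, `p_value`, and `parameters` — a tibble
#'   ranking each parameter by marginal constrained proportion with its
#'   permutation p-value.
#' @export
rda <- function(Y, X, transform = c("hellinger", "none"), n_perm = 999,
                seed = 0) {
  transform <- match.arg(transform)
  seed <- check_seed(seed)
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) abort("Y and X must have the same samples (rows).")
  n <- nrow(Y)
  q <- ncol(X)
  if (n <= q + 1) abort("Need more samples than parameters (n > p + 1).")
  if (is.null(colnames(X))) colnames(X) <- paste0("param", seq_len(q))
  qr_x <- qr(scale(X))
  if (qr_x$rank < q) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):q]]
    abort(sprintf("Explanatory matrix is rank-deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  if (transform == "hellinger") Y <- hellinger(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X)

  fit_prop <- function(Xmat, Ymat) {
    qx <- qr(Xmat)
    yhat <- qr.fitted(qx, Ymat)
    list(yhat = yhat, ss_fit = sum(yhat^2), ss_tot = sum(Ymat^2),
         rank = qx$rank)
  }
  full <- fit_prop(Xs, Yc)
  constrained <- full$ss_fit / full$ss_tot
  resid_ss <- full$ss_tot - full$ss_fit
  df_res <- n - q - 1
  pseudo_f <- (full$ss_fit / q) / (resid_ss / df_res)

  sv <- svd(full$yhat / sqrt(n - 1))
  keep <- sv$d^2 > max(sv$d^2[1], 0) * 1e-12
  eigenvalues <- (sv$d^2)[keep]
  site <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep],
                                              nrow = sum(keep))
  colnames(site) <- paste0("RDA", seq_len(ncol(site)))
  species <- sv$v[, keep, drop = FALSE]
  dimnames(species) <- list(colnames(Y), colnames(site))
  biplot <- cor(Xs, site)

  perm_stats <- function(Ymat, Xmat) {
    f <- fit_prop(Xmat, Ymat)
    (f$ss_fit / q) / ((f$ss_tot - f$ss_fit) / df_res)
  }
  marg <- purrr::map(seq_len(q), function(j) {
    fj <- fit_prop(Xs[, j, drop = FALSE], Yc)
    fstat <- (fj$ss_fit / 1) / ((fj$ss_tot - fj$ss_fit) / (n - 2))
    tibble(parameter = colnames(X)[j],
           marginal_proportion = fj$ss_fit / fj$ss_tot,
           pseudo_f = fstat)
  }) |>
    bind_rows()

  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(b) sample.int(n))
  })
  p_global <- (1 + sum(vapply(perms, function(idx) {
    perm_stats(Yc, Xs[idx, , drop = FALSE])
  }, numeric(1)) >= pseudo_f - 1e-12)) / (n_perm + 1)
  marg$p_value <- vapply(seq_len(q), function(j) {
    obs <- marg$pseudo_f[j]
    exceed <- vapply(perms, function(idx) {
      fj <- fit_prop(Xs[idx, j, drop = FALSE], Yc)
      fstat <- fj$ss_fit / ((fj$ss_tot - fj$ss_fit) / (n - 2))
      fstat >= obs - 1e-12
    }, logical(1))
    (1 + sum(exceed)) / (n_perm + 1)
  }, numeric(1))
  marg <- arrange(marg, dplyr::desc(.data$marginal_proportion))

  structure(
    list(
      eigenvalues = eigenvalues,
      constrained_proportion = constrained,
      total_variance = full$ss_tot / (n - 1),
      site_scores = bind_cols(
        tibble(sample_id = rownames(Y) %||% paste0("s", seq_len(n))),
        as_tibble(site, .name_repair = "minimal")
      ),
      species_scores = species,
      biplot_scores = biplot,
      pseudo_f = pseudo_f,
      p_value = p_global,
      parameters = marg,
      n = n, q = q, n_perm = n_perm, transform = transform
    ),
    class = "rda_result"
  )
}

#' @exportS3Method base::print
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "<rda_result> constrained %.1f%% of variance (pseudo-F = %.2f, p = %.3g, %d permutations)\n",
    100 * x$constrained_proportion, x$pseudo_f, x$p_value, x$n_perm))
  print(x$parameters)
  invisible(x)
}

#' Parameter ranking of an RDA
#' @param x An `rda_result`.
#' @param ... Unused.
#' @return Tibble of parameters ranked by marginal constrained proportion.
#' @export
tidy.rda_result <- function(x, ...) x$parameters

#' One-row RDA summary
#' @param x An `rda_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.rda_result <- function(x, ...) {
  tibble(constrained_proportion = x$constrained_proportion,
         pseudo_f = x$pseudo_f, p_value = x$p_value,
         n = x$n, n_parameters = x$q, n_perm = x$n_perm)
}

#' RDA triplot
#' @param object An `rda_result`.
#' @param ... Unused.
#' @return A ggplot with sample scores and parameter arrows on the first two
#'   canonical axes.
#' @export
autoplot.rda_result <- function(object, ...) {
  if (length(object$eigenvalues) < 2) {
    abort("Need at least two canonical axes to plot.")
  }
  sites <- object$site_scores
  arrows <- as_tibble(object$biplot_scores, rownames = "parameter")
  scale_arrow <- 0.9 * max(abs(c(sites$RDA1, sites$RDA2)))
  pe <- 100 * object$eigenvalues / sum(object$eigenvalues) *
    object$constrained_proportion
  ggplot2::ggplot(sites, ggplot2::aes(.data$RDA1, .data$RDA2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = 0, y = 0, xend = .data$RDA1 * scale_arrow,
                   yend = .data$RDA2 * scale_arrow),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = arrows,
      ggplot2::aes(x = .data$RDA1 * scale_arrow * 1.08,
                   y = .data$RDA2 * scale_arrow * 1.08,
                   label = .data$parameter),
      colour = "steelblue", size = 3
    ) +
    ggplot2::labs(x = sprintf("RDA1 (%.1f%%)", pe[1]),
                  y = sprintf("RDA2 (%.1f%%)", pe[2])) +
    ggplot2::theme_minimal()
}

#' Forward selection of operational parameters
#'
#' Greedy alternative to the marginal ranking of [rda()]: parameters are
#' added one at a time, each step picking the column that most increases
#' the constrained proportion of variance given those already selected.
#'
#' @inheritParams rda
#' @return Tibble, one row per step: `parameter`, `added_proportion`,
#'   `cumulative_proportion`.
#' @export
rda_forward_selection <- function(Y, X, transform = c("hellinger",
                                                      "none")) {
  transform <- match.arg(transform)
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) abort("Y and X must have the same samples (rows).")
  if (is.null(colnames(X))) colnames(X) <- paste0("param", seq_len(ncol(X)))
  if (transform == "hellinger") Y <- hellinger(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X)
  ss_tot <- sum(Yc^2)
  chosen <- integer(0)
  remaining <- seq_len(ncol(Xs))
  steps <- list()
  prev <- 0
  while (length(remaining)) {
    props <- vapply(remaining, function(j) {
      sum(qr.fitted(qr(Xs[, c(chosen, j), drop = FALSE]), Yc)^2) / ss_tot
    }, numeric(1))
    best <- which.max(props)
    steps[[length(steps) + 1]] <- tibble(
      parameter = colnames(Xs)[remaining[best]],
      added_proportion = props[best] - prev,
      cumulative_proportion = props[best]
    )
    prev <- props[best]
    chosen <- c(chosen, remaining[best])
    remaining <- remaining[-best]
  }
  bind_rows(steps)
}

#' Correlation between an operational parameter and a taxon over time
#'
#' Spearman (default) or Pearson correlation of two aligned time series with
#' a two-sided p-value, e.g. temperature against a genus abundance.
#' Constant series are flagged rather than producing `NaN`.
#'
#' @param series_x,series_y Aligned numeric vectors (n >= 4).
#' @param method `"spearman"` or `"pearson"`.
#' @return One-row tibble: `coefficient`, `p_value`, `direction`, `n`,
#'   `constant` (TRUE when undefined).
#' @export
param_taxon_correlation <- function(series_x, series_y,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(series_x, series_y)
  x <- series_x[ok]
  y <- series_y[ok]
  if (length(x) < 4) abort("Need at least 4 aligned time points.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(coefficient = NA_real_, p_value = NA_real_,
                  direction = NA_character_, n = length(x),
                  constant = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  tibble(
    coefficient = unname(ct$estimate),
    p_value = ct$p.value,
    direction = unname(ifelse(ct$estimate >= 0, "positive", "negative")),
    n = length(x),
    constant = FALSE
  )
}
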