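#' Assemble the inputs of the Sloan neutral-model fit
#'
#' For each taxon detected at least once: `p` = mean of per-sample relative
#' abundances and `f` = occurrence frequency (fraction of samples with a
#' non-zero count). `N` is the rounded mean sample total and the detection
#' limit defaults to one read, `d = 1/N`.
#'
#' @param table An [otu_table()], ideally rarefied so all totals agree; a
#'   warning is raised when totals deviate from their mean by more than 1%.
#' @return An `ncm_input`: a tibble (`taxon_id`, `p`, `f`) with attributes
#'   `N`, `d` and `n_samples`.
#' @export
build_ncm_input <- function(table) {
  stopifnot_otu(table)
  if (ncol(table) < 2) abort("Neutral-model fitting needs >= 2 samples.")
  m <- unwrap(table)
  totals <- colSums(m)
  if (any(abs(totals - mean(totals)) > 0.01 * mean(totals))) {
    warn("Sample totals differ by more than 1% of their mean; rarefy first for a clean fit.")
  }
  rel <- relative_abundance(table)
  p <- rowMeans(rel)
  f <- rowMeans(m > 0)
  keep <- f > 0
  n_reads <- round(mean(totals))
  structure(
    tibble(taxon_id = rownames(m)[keep], p = unname(p[keep]),
           f = unname(f[keep])),
    class = c("ncm_input", class(tibble())),
    N = n_reads, d = 1 / n_reads, n_samples = ncol(m)
  )
}

#' Predicted occurrence frequency under the neutral model
#'
#' The Sloan prediction for the probability that a taxon of metacommunity
#' relative abundance `p` is detected in a local community:
#'
#' * `detection = "threshold"`: `F = 1 - I_d(Nmp, Nm(1-p))`, the probability
#'   that the `Beta(Nmp, Nm(1-p))` local relative abundance exceeds the
#'   detection limit `d` (classically `1/N`).
#' * `detection = "reads"`: the exact probability of observing at least one
#'   read when `N` reads are drawn from the Beta-distributed composition,
#'   `F = 1 - B(Nmp, Nm(1-p) + N) / B(Nmp, Nm(1-p))` (beta-binomial tail).
#'   This is the consistent choice when occupancy is measured on sampled
#'   reads of finite depth; the threshold form is its large-`N`
#'   approximation.
#'
#' @param p Metacommunity relative abundance(s) in (0, 1).
#' @param m Migration rate in (0, 1].
#' @param N Community size (reads per sample).
#' @param d Detection limit as a relative abundance (threshold form only).
#' @param detection `"threshold"` (default) or `"reads"`.
#' @return Predicted occurrence frequencies in `[0, 1]`.
#' @export
predict_occurrence <- function(p, m, N, d = 1 / N,
                               detection = c("threshold", "reads")) {
  detection <- match.arg(detection)
  check_number(m, "m", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(N, "N", lower = 1)
  a <- N * m * p
  b <- N * m * (1 - p)
  if (any(a <= 0) || any(b <= 0)) {
    abort("Beta parameters N*m*p and N*m*(1-p) must be positive.")
  }
  if (detection == "threshold") {
    check_number(d, "d", lower = 0, upper = 1, strict_lower = TRUE,
                 strict_upper = TRUE)
    1 - pbeta(d, a, b)
  } else {
    1 - exp(lbeta(a, b + N) - lbeta(a, b))
  }
}

ncm_sse <- function(m, pp, ff, N, d, detection) {
  sum((ff - predict_occurrence(pp, m, N, d, detection))^2)
}

fit_ncm_m_hat <- function(p, f, N, d, detection, lower = 1e-6, upper = 1) {
  opt <- optimize(ncm_sse, c(lower, upper), pp = p, ff = f, N = N, d = d,
                  detection = detection, tol = 1e-8)
  sst <- sum((f - mean(f))^2)
  list(m = opt$minimum,
       r2 = if (sst > 0) 1 - opt$objective / sst else NA_real_,
       sse = opt$objective, sst = sst)
}

# Wilson 95% score interval for a binomial proportion
wilson_bounds <- function(phat, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  cbind(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Fit the Sloan neutral community model
#'
#' Estimates the migration rate `m` by bounded one-dimensional least squares
#' of observed occurrence frequencies against [predict_occurrence()],
#' computes `R^2 = 1 - SSE/SST`, percentile bootstrap confidence intervals
#' (resampling taxa, the regression's units), and partitions taxa into
#' `above` / `within` / `below` the 95% prediction band (Wilson score
#' interval of the predicted frequency at the realized sample count).
#'
#' @param input An `ncm_input` from [build_ncm_input()].
#' @param n_boot Bootstrap replicates for the confidence intervals (default
#'   1,000; set 0 to skip).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level for intervals and bands.
#' @param detection Occupancy model passed to [predict_occurrence()]; use
#'   `"reads"` when occupancy was measured on finite-depth read counts (as in
#'   tables from [simulate_neutral_community()]).
#' @param d Detection limit override (defaults to the input's `1/N`).
#' @return An `ncm_fit` object; see [tidy.ncm_fit()], [glance.ncm_fit()] and
#'   [autoplot.ncm_fit()].
#' @export
fit_ncm <- function(input, n_boot = 1000, seed = 0, conf = 0.95,
                    detection = c("threshold", "reads"), d = NULL) {
  if (!inherits(input, "ncm_input")) {
    abort("`input` must come from build_ncm_input().")
  }
  detection <- match.arg(detection)
  seed <- check_seed(seed)
  n_taxa <- nrow(input)
  if (n_taxa < 20) {
    warn(sprintf("Only %d taxa; the fit is unreliable below ~20.", n_taxa))
  }
  N <- attr(input, "N")
  d <- d %||% attr(input, "d")
  n_samples <- attr(input, "n_samples")

  base <- fit_ncm_m_hat(input$p, input$f, N, d, detection)
  if (is.na(base$r2)) {
    warn("SST is zero (constant occupancy); R^2 is undefined.")
  }

  boot <- NULL
  ci <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(n_taxa, n_taxa, replace = TRUE)
        fb <- fit_ncm_m_hat(input$p[idx], input$f[idx], N, d, detection)
        c(fb$m, fb$r2)
      }, numeric(2))
    })
    probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
    ci <- tibble(
      term = c("m", "Nm", "R2"),
      lower = c(quantile(boot[1, ], probs[1], names = FALSE),
                N * quantile(boot[1, ], probs[1], names = FALSE),
                quantile(boot[2, ], probs[1], names = FALSE, na.rm = TRUE)),
      upper = c(quantile(boot[1, ], probs[2], names = FALSE),
                N * quantile(boot[1, ], probs[2], names = FALSE),
                quantile(boot[2, ], probs[2], names = FALSE, na.rm = TRUE))
    )
  }

  pred <- predict_occurrence(input$p, base$m, N, d, detection)
  bands <- wilson_bounds(pred, n_samples, conf)
  class <- ifelse(input$f > bands[, "upper"], "above",
                  ifelse(input$f < bands[, "lower"], "below", "within"))

  grid_p <- exp(seq(log(min(input$p)), log(max(input$p)),
                    length.out = 200))
  grid_f <- predict_occurrence(grid_p, base$m, N, d, detection)
  grid_bands <- wilson_bounds(grid_f, n_samples, conf)

  structure(
    list(
      m_hat = base$m,
      Nm = N * base$m,
      r_squared = base$r2,
      ci = ci,
      taxa = bind_cols(
        input,
        tibble(predicted = pred, band_lower = bands[, "lower"],
               band_upper = bands[, "upper"], class = class)
      ),
      curve = tibble(p = grid_p, predicted = grid_f,
                     band_lower = grid_bands[, "lower"],
                     band_upper = grid_bands[, "upper"]),
      N = N, d = d, n_samples = n_samples, n_taxa = n_taxa,
      detection = detection, n_boot = n_boot, conf = conf, seed = seed
    ),
    class = "ncm_fit"
  )
}

#' @exportS3Method base::print
print.ncm_fit <- function(x, ...) {
  cat(sprintf(
    "<ncm_fit> Nm = %.0f (m = %.4g), R^2 = %.3f, %d taxa, N = %d, detection = %s\n",
    x$Nm, x$m_hat, x$r_squared, x$n_taxa, x$N, x$detection
  ))
  if (!is.null(x$ci)) {
    nm <- x$ci[x$ci$term == "Nm", ]
    cat(sprintf("  %d%% bootstrap CI for Nm: [%.0f, %.0f] (%d replicates)\n",
                round(100 * x$conf), nm$lower, nm$upper, x$n_boot))
  }
  tab <- table(x$taxa$class)
  cat("  partition:", paste(sprintf("%s %d", names(tab), tab),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Per-taxon table of a neutral-model fit
#' @param x An `ncm_fit`.
#' @param ... Unused.
#' @return Tibble with `taxon_id`, `p`, `f`, `predicted`, band bounds and
#'   `class` (above/within/below).
#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' One-row summary of a neutral-model fit
#' @param x An `ncm_fit`.
#' @param ... Unused.
#' @return One-row tibble with `m`, `Nm`, `r_squared`, CI bounds, sizes.
#' @export
glance.ncm_fit <- function(x, ...) {
  out <- tibble(
    m = x$m_hat, Nm = x$Nm, r_squared = x$r_squared,
    n_taxa = x$n_taxa, n_samples = x$n_samples, N = x$N,
    detection = x$detection
  )
  if (!is.null(x$ci)) {
    out$Nm_lower <- x$ci$lower[x$ci$term == "Nm"]
    out$Nm_upper <- x$ci$upper[x$ci$term == "Nm"]
    out$r_squared_lower <- x$ci$lower[x$ci$term == "R2"]
    out$r_squared_upper <- x$ci$upper[x$ci$term == "R2"]
  }
  out
}

#' Occupancy-abundance plot of a neutral-model fit
#' @param object An `ncm_fit`.
#' @param ... Unused.
#' @return A ggplot: observed occupancy against log10 mean relative
#'   abundance, the fitted neutral curve, its prediction band, and taxa
#'   coloured by partition.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  ggplot2::ggplot(object$taxa, ggplot2::aes(log10(.data$p), .data$f)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), alpha = 0.6,
                        size = 1) +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(log10(.data$p), .data$predicted),
                       colour = "blue") +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(log10(.data$p), .data$band_lower),
                       colour = "blue", linetype = "dashed") +
    ggplot2::geom_line(data = object$curve,
                       ggplot2::aes(log10(.data$p), .data$band_upper),
                       colour = "blue", linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(above = "#2ca02c",
                                            within = "grey40",
                                            below = "#d62728")) +
    ggplot2::labs(
      x = "log10 mean relative abundance",
      y = "occurrence frequency",
      colour = NULL,
      subtitle = sprintf("Nm = %.0f, R² = %.3f", object$Nm,
                         object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
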