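#' Construct an OTU count table
#'
#' The central container of the package: a taxa-by-samples matrix of
#' non-negative integer read counts with unique taxon and sample identifiers.
#' Every downstream stage (diversity, neutral-model fitting, network
#' inference, guild and dark-matter accounting) consumes this object.
#'
#' @param counts Numeric matrix of non-negative integers, taxa in rows and
#'   samples in columns. Row and column names are taken as identifiers unless
#'   `taxon_ids` / `sample_ids` are given.
#' @param taxon_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `counts`.
#' @param depth_note Optional integer recording a rarefaction depth already
#'   applied to the table.
#'
#' @return An `otu_table`: an integer matrix with class attribute and
#'   (optionally) a `depth_note` attribute.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 2, 1, 3, 4), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' otu_table(m)
otu_table <- function(counts, taxon_ids = NULL, sample_ids = NULL,
                      depth_note = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    abort("`counts` must be a numeric matrix.")
  }
  if (!is.null(taxon_ids)) rownames(counts) <- taxon_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("An OTU table needs taxon (row) and sample (column) identifiers.")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    abort(sprintf("Duplicated taxon id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- unique(colnames(counts)[duplicated(colnames(counts))])
    abort(sprintf("Duplicated sample id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyNA(counts)) abort("Counts must not contain missing values.")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Negative count at taxon '%s', sample '%s'.",
      rownames(counts)[bad[1]], colnames(counts)[bad[2]]
    ))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-integer count at taxon '%s', sample '%s'.",
      rownames(counts)[bad[1]], colnames(counts)[bad[2]]
    ))
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("otu_table", "matrix", "array"),
            depth_note = if (!is.null(depth_note)) as.integer(depth_note))
}

#' @exportS3Method base::print
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "<otu_table> %d taxa x %d samples, %s total reads%s\n",
    nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ","),
    if (!is.null(attr(x, "depth_note"))) {
      sprintf(" (rarefied to %d)", attr(x, "depth_note"))
    } else ""
  ))
  invisible(x)
}

#' @export
as_tibble.otu_table <- function(x, ...) {
  tibble(taxon_id = rownames(x)) |>
    bind_cols(as_tibble(unclass(x), .name_repair = "minimal"))
}

# drop class/attrs, keep dimnames
unwrap <- function(table) {
  m <- unclass(table)
  attr(m, "depth_note") <- NULL
  m
}

stopifnot_otu <- function(table) {
  if (!inherits(table, "otu_table")) {
    abort("Expected an `otu_table`; see `otu_table()` or `read_otu_table()`.")
  }
  invisible(table)
}

#' Read an OTU table from TSV (or BIOM)
#'
#' Reads a tab-separated count table with one identifier column (conventionally
#' `#OTU ID`) and one column per sample. Orientation is auto-detected with
#' taxa-as-rows as the default reading; pass `orientation = "samples_rows"`
#' for transposed files. Files ending in `.biom` are delegated to the
#' \pkg{biomformat} package when it is installed.
#'
#' @param path Path to a TSV (or BIOM) file.
#' @param orientation One of `"auto"`, `"taxa_rows"`, `"samples_rows"`.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path, orientation = c("auto", "taxa_rows",
                                                 "samples_rows")) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Reading BIOM files requires the 'biomformat' package.")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m))
  }
  df <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(df) < 2) abort(sprintf("'%s': need an id column plus data.", path))
  ids <- as.character(df[[1]])
  num <- df[-1]
  not_num <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(not_num)) {
    abort(sprintf("'%s': non-numeric cells in column(s) %s.",
                  path, paste(not_num, collapse = ", ")))
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  id_name <- names(df)[1]
  if (orientation == "auto") {
    # heuristic: a leading "#OTU ID"-style header marks taxa-as-rows;
    # otherwise default to taxa-as-rows.
    orientation <- if (grepl("sample", id_name, ignore.case = TRUE)) {
      "samples_rows"
    } else {
      "taxa_rows"
    }
  }
  if (orientation == "samples_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()]; integer tables round-trip bit-identically.
#'
#' @param table An [otu_table()].
#' @param path Output path.
#' @param id_column Name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, id_column = "#OTU ID") {
  stopifnot_otu(table)
  df <- tibble(!!id_column := rownames(table)) |>
    bind_cols(as_tibble(unwrap(table), .name_repair = "minimal"))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Remove singleton taxa
#'
#' Drops taxa whose total count across all samples equals exactly one, the
#' standard read-quality guard applied before rarefaction.
#'
#' @param table An [otu_table()].
#' @return The filtered [otu_table()].
#' @export
remove_singletons <- function(table) {
  stopifnot_otu(table)
  keep <- rowSums(unwrap(table)) != 1
  otu_table(unwrap(table)[keep, , drop = FALSE],
            depth_note = attr(table, "depth_note"))
}

#' Rarefy samples to a common depth
#'
#' Each sample with at least `depth` reads is replaced by a uniform
#' without-replacement subsample of exactly `depth` reads (multivariate
#' hypergeometric); samples below `depth` are dropped with a warning.
#'
#' @param table An [otu_table()].
#' @param depth Target reads per sample (default 25,000, the survey's
#'   normalization depth).
#' @param seed Integer seed; the draw is deterministic given `(table, depth,
#'   seed)`.
#' @return A rarefied [otu_table()] with a `depth_note` attribute.
#' @export
rarefy <- function(table, depth = 25000, seed = 0) {
  stopifnot_otu(table)
  check_number(depth, "depth", lower = 1)
  seed <- check_seed(seed)
  m <- unwrap(table)
  totals <- colSums(m)
  low <- totals < depth
  if (any(low)) {
    warn(sprintf(
      "Dropping %d sample(s) below depth %d: %s",
      sum(low), depth, paste(colnames(m)[low], collapse = ", ")
    ))
    m <- m[, !low, drop = FALSE]
    totals <- totals[!low]
  }
  if (ncol(m) == 0) abort("No sample reaches the rarefaction depth.")
  out <- with_seed(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      if (totals[j] == depth) return(x)
      pool <- rep.int(seq_along(x), x)
      drawn <- sample(pool, depth, replace = FALSE)
      tabulate(drawn, nbins = length(x))
    }, integer(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  otu_table(out, depth_note = depth)
}

#' Per-sample relative abundances
#'
#' Closes each sample (column) to sum one.
#'
#' @param table An [otu_table()].
#' @return A numeric matrix, taxa by samples, columns summing to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot_otu(table)
  m <- unwrap(table)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("All-zero sample(s): %s",
                  paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  sweep(m, 2, totals, "/")
}

#' Filter taxa by mean relative abundance
#'
#' Keeps taxa whose mean relative abundance across samples strictly exceeds
#' `min_mean_rel`. The default reproduces the network screen of taxa above
#' 0.01 percent average relative abundance.
#'
#' @param table An [otu_table()].
#' @param min_mean_rel Threshold on the mean relative abundance, in `[0, 1)`.
#' @return The filtered [otu_table()].
#' @export
filter_by_mean_abundance <- function(table, min_mean_rel = 1e-4) {
  stopifnot_otu(table)
  check_number(min_mean_rel, "min_mean_rel", lower = 0, upper = 1,
               strict_upper = TRUE)
  keep <- rowMeans(relative_abundance(table)) > min_mean_rel
  otu_table(unwrap(table)[keep, , drop = FALSE],
            depth_note = attr(table, "depth_note"))
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums counts of taxa sharing the same label at `rank` (e.g. phylum-level
#' profiles for ordination). Taxa with an empty label at that rank are pooled
#' under `"unassigned"`.
#'
#' @param table An [otu_table()].
#' @param taxonomy A taxonomy tibble from [read_taxonomy()] or
#'   [generate_taxonomy_and_guilds()].
#' @param rank One of the seven ranks (`"domain"` ... `"species"`).
#' @return An [otu_table()] with one row per label.
#' @export
collapse_rank <- function(table, taxonomy, rank = "phylum") {
  stopifnot_otu(table)
  if (!rank %in% tax_ranks()) {
    abort(sprintf("`rank` must be one of: %s", paste(tax_ranks(),
                                                     collapse = ", ")))
  }
  lab <- taxonomy[[rank]][match(rownames(table), taxonomy$taxon_id)]
  lab[is.na(lab) | lab == ""] <- "unassigned"
  m <- rowsum(unwrap(table), group = lab)
  otu_table(m, depth_note = attr(table, "depth_note"))
}
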