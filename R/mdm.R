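# Genome-sequenced proportion ("microbial dark matter") accounting:
# exact and 97%-identity matching of OTU representative sequences against
# reference 16S sets, and the P_number / P_abundance statistics.

as_dna <- function(x, what) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  if (length(x) == 0) abort(sprintf("Empty %s set.", what))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    names(x) <- sprintf("%s_%04d", toupper(substr(what, 1, 3)),
                        seq_along(x))
  }
  x
}

#' Exact-criterion sequence matching
#'
#' A query matches when it — or its reverse complement — occurs as an exact
#' contiguous substring of any reference (100% query coverage, zero
#' mismatches). The first hit in reference order is reported. IUPAC
#' ambiguity codes never match under this criterion.
#'
#' @param queries,references [Biostrings::DNAStringSet] objects (or named
#'   character vectors).
#' @return Tibble, one row per query: `query_id`, `ref_id` (`NA` when
#'   unmatched), `identity`, `coverage`, `strand`, `criterion = "exact"`.
#' @export
match_exact <- function(queries, references) {
  queries <- as_dna(queries, "query")
  references <- as_dna(references, "reference")
  ref_names <- names(references)
  out <- purrr::map(seq_along(queries), function(i) {
    q <- queries[[i]]
    hit_f <- Biostrings::vcountPattern(q, references, fixed = TRUE) > 0
    hit_r <- Biostrings::vcountPattern(Biostrings::reverseComplement(q),
                                       references, fixed = TRUE) > 0
    first_f <- if (any(hit_f)) which(hit_f)[1] else NA_integer_
    first_r <- if (any(hit_r)) which(hit_r)[1] else NA_integer_
    hit <- suppressWarnings(min(first_f, first_r, na.rm = TRUE))
    matched <- is.finite(hit)
    tibble(
      query_id = names(queries)[i],
      ref_id = if (matched) ref_names[hit] else NA_character_,
      identity = if (matched) 1 else NA_real_,
      coverage = if (matched) 1 else NA_real_,
      strand = if (!matched) {
        NA_character_
      } else if (!is.na(first_f) && hit == first_f) "+" else "-",
      criterion = "exact"
    )
  })
  bind_rows(out)
}

#' Identity-threshold sequence matching
#'
#' Semi-global alignment (global in the query, local in the reference, so
#' genome-derived references longer than the 16S query are not penalized)
#' with unit match score, mismatch -1 and gap -2 by default. Identity is
#' matched columns over alignment columns; the best-identity reference is
#' reported when it reaches `min_identity` (top-hit criterion). Both strands
#' are searched.
#'
#' @param queries,references [Biostrings::DNAStringSet] objects (or named
#'   character vectors).
#' @param min_identity Identity threshold in (0, 1]; default 0.97, the
#'   conventional species-level 16S cutoff.
#' @param match,mismatch,gap Alignment scores.
#' @return Tibble, one row per query: `query_id`, `ref_id` (`NA` below
#'   threshold), `identity`, `coverage`, `strand`,
#'   `criterion = "identity>=..."`.
#' @export
match_identity <- function(queries, references, min_identity = 0.97,
                           match = 1, mismatch = -1, gap = 2) {
  check_number(min_identity, "min_identity", lower = 0, upper = 1,
               strict_lower = TRUE)
  queries <- as_dna(queries, "query")
  references <- as_dna(references, "reference")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  align_identity <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = rep(Biostrings::DNAStringSet(q), length(references)),
      subject = references,
      type = "global-local", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = gap
    )
    # identity over alignment columns (internal gaps included)
    Biostrings::pid(aln, type = "PID1") / 100
  }
  out <- purrr::map(seq_along(queries), function(i) {
    q <- queries[[i]]
    id_f <- align_identity(q)
    id_r <- align_identity(Biostrings::reverseComplement(q))
    best_f <- max(id_f)
    best_r <- max(id_r)
    strand <- if (best_f >= best_r) "+" else "-"
    ids <- if (strand == "+") id_f else id_r
    best <- which.max(ids)
    identity <- ids[best]
    matched <- identity >= min_identity
    tibble(
      query_id = names(queries)[i],
      ref_id = if (matched) names(references)[best] else NA_character_,
      identity = identity,
      coverage = 1,
      strand = if (matched) strand else NA_character_,
      criterion = sprintf("identity>=%g", min_identity)
    )
  })
  bind_rows(out)
}

#' Genome-sequenced proportions P_number and P_abundance
#'
#' `P_number` is the fraction of taxa with a reference match; `P_abundance`
#' is the matched taxa's share of total relative abundance. Both are
#' computed overall and, when `groups` is given, per sample group
#' restricted to the taxa observed in that group.
#'
#' @param table An [otu_table()] whose row names are the query ids of
#'   `matches`.
#' @param matches Match tibble from [match_exact()] or [match_identity()];
#'   must cover the table's taxa.
#' @param groups Optional named vector mapping `sample_id` to a group (e.g.
#'   plant).
#' @return An `mdm_report`: list with `overall` (one-row tibble `p_number`,
#'   `p_abundance`, `n_taxa`, `n_matched`), `by_group` (tibble or `NULL`)
#'   and `matches`.
#' @export
mdm_proportions <- function(table, matches, groups = NULL) {
  stopifnot_otu(table)
  missing_taxa <- setdiff(rownames(table), matches$query_id)
  if (length(missing_taxa)) {
    abort(sprintf("Matches do not cover %d table taxon/taxa (e.g. %s).",
                  length(missing_taxa), missing_taxa[1]))
  }
  matched_ids <- matches$query_id[!is.na(matches$ref_id)]
  rel <- relative_abundance(table)
  prop_for <- function(cols) {
    sub <- rel[, cols, drop = FALSE]
    present <- rownames(sub)[rowSums(sub) > 0]
    hit <- intersect(present, matched_ids)
    mean_ab <- rowMeans(sub)[present]
    tibble(
      n_taxa = length(present),
      n_matched = length(hit),
      p_number = length(hit) / length(present),
      p_abundance = sum(mean_ab[hit]) / sum(mean_ab)
    )
  }
  overall <- prop_for(colnames(rel))
  by_group <- NULL
  if (!is.null(groups)) {
    gs <- unname(groups[colnames(rel)])
    by_group <- purrr::map(unique(gs), function(g) {
      prop_for(colnames(rel)[gs == g]) |> mutate(group = g, .before = 1)
    }) |>
      bind_rows()
  }
  structure(list(overall = overall, by_group = by_group, matches = matches),
            class = "mdm_report")
}

#' @exportS3Method base::print
print.mdm_report <- function(x, ...) {
  cat(sprintf("<mdm_report> P_number = %.1f%%, P_abundance = %.1f%% (%d/%d taxa matched)\n",
              100 * x$overall$p_number, 100 * x$overall$p_abundance,
              x$overall$n_matched, x$overall$n_taxa))
  invisible(x)
}

#' Map study OTUs onto a wanted list
#'
#' Exact-criterion matching of study OTU sequences against a wanted-list
#' reference set (taxa flagged for genome recovery), reporting which wanted
#' sequences are present in the study and whether their mean relative
#' abundance exceeds a threshold, overall and per group.
#'
#' @param queries Study OTU sequences ([Biostrings::DNAStringSet]); names
#'   must be row names of `table`.
#' @param wanted_list Wanted-list sequences (`DNAStringSet`).
#' @param table An [otu_table()].
#' @param min_mean_rel Mean relative-abundance threshold (strict, default
#'   `1e-3`).
#' @param groups Optional named vector mapping `sample_id` to group.
#' @return Tibble, one row per wanted sequence (x group): `wanted_id`,
#'   `group`, `otu_id` (`NA` when absent), `mean_rel_abundance`,
#'   `above_threshold`.
#' @export
wanted_list_map <- function(queries, wanted_list, table,
                            min_mean_rel = 1e-3, groups = NULL) {
  stopifnot_otu(table)
  wanted_list <- as_dna(wanted_list, "wanted")
  matches <- match_exact(wanted_list, queries)
  rel <- relative_abundance(table)
  group_of <- if (is.null(groups)) {
    setNames(rep("all", ncol(rel)), colnames(rel))
  } else {
    groups
  }
  gs <- unname(group_of[colnames(rel)])
  purrr::map(unique(gs), function(g) {
    sub <- rel[, gs == g, drop = FALSE]
    mean_ab <- rowMeans(sub)
    tibble(
      wanted_id = matches$query_id,
      group = g,
      otu_id = matches$ref_id,
      mean_rel_abundance = ifelse(is.na(matches$ref_id), 0,
                                  unname(mean_ab[matches$ref_id])),
      above_threshold = !is.na(matches$ref_id) &
        ifelse(is.na(matches$ref_id), FALSE,
               unname(mean_ab[matches$ref_id]) > min_mean_rel)
    )
  }) |>
    bind_rows()
}
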