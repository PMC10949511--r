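# Functional-guild extraction: nitrifiers (AOB/NOB), phosphorus removers
# (PAO), bulking/foaming bacteria (BFB) and anammox organisms.

#' Default functional-guild definitions
#'
#' Rank-level taxon patterns mapping OTUs to the five guilds tracked in
#' activated-sludge surveys: ammonia oxidizers (AOB), nitrite oxidizers
#' (NOB), polyphosphate-accumulating organisms (PAO), bulking/foaming
#' bacteria (BFB) and anammox organisms. Patterns are matched
#' case-insensitively with the `Candidatus` prefix normalized away; edit or
#' replace via [read_guild_definitions()].
#'
#' @return A tibble with columns `guild`, `rank`, `label`.
#' @export
default_guild_definitions <- function() {
  pool <- guild_genus_pool()
  defs <- bind_rows(
    tibble(guild = "AOB", rank = "family", label = "Nitrosomonadaceae"),
    tibble(guild = "AOB", rank = "genus", label = pool$AOB),
    tibble(guild = "NOB", rank = "genus",
           label = c(pool$NOB, "Nitrotoga")),
    tibble(guild = "NOB", rank = "class", label = "P9X2b3D02"),
    tibble(guild = "PAO", rank = "genus", label = pool$PAO),
    tibble(guild = "BFB", rank = "genus", label = pool$BFB),
    tibble(guild = "anammox", rank = "genus", label = pool$anammox)
  )
  defs
}

#' Read guild definitions from YAML
#'
#' Format: `guild: [{rank: genus, label: Nitrosomonas}, ...]`.
#'
#' @param path Path to a YAML file.
#' @return A definitions tibble as in [default_guild_definitions()].
#' @export
read_guild_definitions <- function(path) {
  y <- yaml::read_yaml(path)
  if (!length(y)) abort("Empty guild definition file.")
  purrr::imap(y, function(patterns, g) {
    tibble(
      guild = g,
      rank = vapply(patterns, `[[`, character(1), "rank"),
      label = vapply(patterns, `[[`, character(1), "label")
    )
  }) |>
    bind_rows()
}

#' Write guild definitions to YAML
#' @param defs Definitions tibble (`guild`, `rank`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guild_definitions <- function(defs, path) {
  y <- split(defs, defs$guild) |>
    lapply(function(d) {
      purrr::map2(d$rank, d$label, function(r, l) list(rank = r, label = l))
    })
  yaml::write_yaml(y, path)
  invisible(path)
}

norm_label <- function(x) {
  x <- tolower(trimws(x))
  sub("^candidatus[ _]", "", x)
}

#' Extract functional guilds from a table and taxonomy
#'
#' An OTU joins a guild when its lineage label at a pattern's rank equals the
#' pattern label (case-insensitive; `Candidatus` prefixes are normalized).
#' Patterns above genus level (e.g. family Nitrosomonadaceae for AOB) apply
#' only when the genus is unassigned or itself matches the same guild, so a
#' classified non-guild genus inside a guild-bearing family is not swept in.
#'
#' @param table An [otu_table()].
#' @param taxonomy Taxonomy tibble covering the table's taxa (taxa absent
#'   from it are treated as fully unassigned).
#' @param defs Guild definitions tibble (default
#'   [default_guild_definitions()]).
#' @return A `guild_summary`: list with `members` (tibble `guild`,
#'   `taxon_id`, `matched_rank`, `matched_label`), `abundance` (tibble
#'   `guild`, `sample_id`, `rel_abundance` — per-sample totals), and
#'   `summary` (tibble `guild`, `n_taxa`, `mean_abundance`, `prevalence`).
#' @export
extract_guilds <- function(table, taxonomy,
                           defs = default_guild_definitions()) {
  stopifnot_otu(table)
  if (is.null(defs) || nrow(defs) == 0) abort("Empty guild definitions.")
  bad_rank <- setdiff(unique(defs$rank), tax_ranks())
  if (length(bad_rank)) {
    abort(sprintf("Unknown rank(s) in definitions: %s",
                  paste(bad_rank, collapse = ", ")))
  }
  taxa <- rownames(table)
  tax <- taxonomy[match(taxa, taxonomy$taxon_id), ]
  tax$taxon_id <- taxa
  tax[tax_ranks()] <- lapply(tax[tax_ranks()], function(x) {
    ifelse(is.na(x), "", x)
  })

  members <- purrr::map(unique(defs$guild), function(g) {
    d <- defs[defs$guild == g, ]
    genus_labels <- norm_label(d$label[d$rank == "genus"])
    hits <- purrr::pmap(d, function(guild, rank, label, ...) {
      match_vec <- norm_label(tax[[rank]]) == norm_label(label)
      if (rank != "genus") {
        # coarse-rank pattern only for unassigned or same-guild genera
        genus_ok <- tax$genus == "" | norm_label(tax$genus) %in% genus_labels
        match_vec <- match_vec & genus_ok
      }
      tibble(taxon_id = tax$taxon_id[match_vec], matched_rank = rank,
             matched_label = label)
    }) |>
      bind_rows()
    if (nrow(hits) == 0) return(hits |> mutate(guild = character(0)))
    hits |>
      distinct(.data$taxon_id, .keep_all = TRUE) |>
      mutate(guild = g)
  }) |>
    bind_rows()

  if (nrow(members)) {
    overlap <- members |>
      group_by(.data$taxon_id) |>
      filter(n() > 1)
    if (nrow(overlap)) {
      warn(sprintf("%d taxon/taxa matched more than one guild.",
                   dplyr::n_distinct(overlap$taxon_id)))
    }
  }

  rel <- relative_abundance(table)
  abundance <- purrr::map(unique(defs$guild), function(g) {
    ids <- members$taxon_id[members$guild == g]
    total <- if (length(ids)) {
      colSums(rel[ids, , drop = FALSE])
    } else {
      setNames(rep(0, ncol(rel)), colnames(rel))
    }
    tibble(guild = g, sample_id = colnames(rel),
           rel_abundance = unname(total))
  }) |>
    bind_rows()

  summary <- abundance |>
    group_by(.data$guild) |>
    summarise(
      mean_abundance = mean(.data$rel_abundance),
      prevalence = mean(.data$rel_abundance > 0),
      .groups = "drop"
    ) |>
    left_join(
      members |> group_by(.data$guild) |> summarise(n_taxa = n()),
      by = "guild"
    ) |>
    mutate(n_taxa = ifelse(is.na(.data$n_taxa), 0L, .data$n_taxa)) |>
    select("guild", "n_taxa", "mean_abundance", "prevalence")

  structure(
    list(members = members, abundance = abundance, summary = summary,
         sample_ids = colnames(table)),
    class = "guild_summary"
  )
}

#' @exportS3Method base::print
print.guild_summary <- function(x, ...) {
  cat("<guild_summary>\n")
  print(x$summary)
  invisible(x)
}

#' AOB/NOB abundance ratio
#'
#' Ratio of mean total AOB relative abundance to mean total NOB relative
#' abundance, per grouping (e.g. plant). Groups without NOB are flagged
#' (`nob_absent = TRUE`) rather than given an infinite ratio.
#'
#' @param summary A `guild_summary` from [extract_guilds()].
#' @param groups Optional named vector mapping `sample_id` to a group label
#'   (e.g. plant); defaults to a single overall group.
#' @return Tibble: `group`, `aob_mean`, `nob_mean`, `ratio`, `nob_absent`.
#' @export
aob_nob_ratio <- function(summary, groups = NULL) {
  if (!inherits(summary, "guild_summary")) {
    abort("`summary` must come from extract_guilds().")
  }
  need <- c("AOB", "NOB")
  if (!all(need %in% summary$abundance$guild)) {
    abort("Both AOB and NOB must be present in the summary.")
  }
  ab <- summary$abundance |> filter(.data$guild %in% need)
  ab$group <- if (is.null(groups)) {
    "all"
  } else {
    unname(groups[ab$sample_id])
  }
  ab |>
    group_by(.data$group, .data$guild) |>
    summarise(mean_ab = mean(.data$rel_abundance), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "guild", values_from = "mean_ab") |>
    mutate(
      aob_mean = .data$AOB, nob_mean = .data$NOB,
      nob_absent = .data$NOB == 0,
      ratio = ifelse(.data$nob_absent, NA_real_, .data$AOB / .data$NOB)
    ) |>
    select("group", "aob_mean", "nob_mean", "ratio", "nob_absent")
}

#' Guild member abundance matrix for display
#'
#' Per-OTU (or per-guild) relative abundances of guild members, optionally
#' screened at a mean-abundance threshold and log10-transformed for heatmap
#' display; zero cells become `NA` under the log, never `-Inf`.
#'
#' @param summary A `guild_summary` from [extract_guilds()].
#' @param table The [otu_table()] the summary was computed from.
#' @param rank `"otu"` (default) for per-member rows or `"guild"` for guild
#'   totals.
#' @param min_mean_rel Optional strict mean-abundance screen (e.g. `1e-4`);
#'   `NULL` keeps everything.
#' @param log10_transform Return `log10` values (default TRUE).
#' @return A tibble in long format: `guild`, `taxon_id` (or guild again),
#'   `sample_id`, `value`.
#' @export
guild_abundance_matrix <- function(summary, table, rank = c("otu", "guild"),
                                   min_mean_rel = 1e-4,
                                   log10_transform = TRUE) {
  rank <- match.arg(rank)
  stopifnot_otu(table)
  rel <- relative_abundance(table)
  long <- if (rank == "otu") {
    mem <- summary$members
    purrr::map(seq_len(nrow(mem)), function(i) {
      tibble(guild = mem$guild[i], taxon_id = mem$taxon_id[i],
             sample_id = colnames(rel),
             value = unname(rel[mem$taxon_id[i], ]))
    }) |>
      bind_rows()
  } else {
    summary$abundance |>
      mutate(taxon_id = .data$guild) |>
      rename(value = "rel_abundance") |>
      select("guild", "taxon_id", "sample_id", "value")
  }
  if (!is.null(min_mean_rel)) {
    long <- long |>
      group_by(.data$guild, .data$taxon_id) |>
      filter(mean(.data$value) > min_mean_rel) |>
      ungroup()
  }
  if (log10_transform) {
    long$value <- ifelse(long$value > 0, log10(long$value), NA_real_)
  }
  long
}
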