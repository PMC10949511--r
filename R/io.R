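# readers/writers for taxonomy, metadata, operational parameters, sequences

tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Read a Silva/GTDB-style taxonomy table
#'
#' Expects a two-column TSV `taxon_id<TAB>lineage` where the lineage is a
#' semicolon-separated string with rank prefixes
#' (`d__...;p__...;c__...;o__...;f__...;g__...[;s__...]`). Unassigned ranks
#' may be empty or absent.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `taxon_id` and the seven ranks
#'   (`domain` ... `species`), empty strings for unassigned ranks.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, comment = "", show_col_types = FALSE,
                        progress = FALSE,
                        col_names = c("taxon_id", "lineage"), skip = 0)
  # tolerate a header row
  if (identical(tolower(df$taxon_id[1]), "taxon_id") ||
      grepl("otu id", tolower(df$taxon_id[1]), fixed = TRUE)) {
    df <- df[-1, ]
  }
  if (anyDuplicated(df$taxon_id)) {
    abort("Duplicated taxon_id in taxonomy file.")
  }
  parse_lineage(df$taxon_id, df$lineage)
}

parse_lineage <- function(taxon_id, lineage) {
  parts <- strsplit(ifelse(is.na(lineage), "", lineage), ";", fixed = TRUE)
  ranks <- tax_ranks()
  prefix <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  mat <- matrix("", length(taxon_id), 7,
                dimnames = list(NULL, ranks))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) > 7) abort(sprintf(
      "Taxon '%s': more than 7 lineage ranks.", taxon_id[i]))
    for (k in seq_along(p)) {
      val <- p[k]
      # strip a rank prefix if present at any position
      hit <- which(startsWith(val, prefix))
      if (length(hit) == 1) {
        mat[i, hit] <- sub("^[a-z]__", "", val)
      } else if (nzchar(val)) {
        mat[i, k] <- val
      }
    }
  }
  bind_cols(tibble(taxon_id = as.character(taxon_id)),
            as_tibble(mat, .name_repair = "minimal"))
}

#' Write a taxonomy tibble back to lineage TSV
#' @param taxonomy Tibble as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  prefix <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  ranks <- tax_ranks()
  lineage <- apply(as.matrix(taxonomy[ranks]), 1, function(r) {
    paste0(prefix, r, collapse = ";")
  })
  readr::write_tsv(tibble(taxon_id = taxonomy$taxon_id, lineage = lineage),
                   path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with header containing at least `sample_id`, `plant`, `date`
#' (ISO `YYYY-MM`) and `sample_type` (one of IN, AS, EFF).
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_sample_info <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_info(df)
}

validate_sample_info <- function(df) {
  need <- c("sample_id", "plant", "date", "sample_type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Sample metadata lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(df$sample_type), c("IN", "AS", "EFF"))
  if (length(bad)) {
    abort(sprintf("sample_type must be IN/AS/EFF; found: %s",
                  paste(bad, collapse = ", ")))
  }
  if (!all(grepl("^\\d{4}-\\d{2}$", df$date))) {
    abort("Dates must be ISO YYYY-MM.")
  }
  if (anyDuplicated(df[c("plant", "date", "sample_type")])) {
    abort("(plant, date, sample_type) combinations must be unique.")
  }
  as_tibble(df)
}

#' Read an operational-parameter table
#'
#' CSV with header: `plant`, `date` (`YYYY-MM`) and one numeric column per
#' parameter (temperature in deg C, mean cell residence time in days,
#' hydraulic retention time in hours, ...).
#'
#' @param path Path to the CSV file.
#' @return A tibble with consistent parameter columns.
#' @export
read_operational_params <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("plant", "date")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Operational table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  params <- setdiff(names(df), need)
  not_num <- params[!vapply(df[params], is.numeric, logical(1))]
  if (length(not_num)) {
    abort(sprintf("Non-numeric parameter column(s): %s",
                  paste(not_num, collapse = ", ")))
  }
  as_tibble(df)
}

#' Read a FASTA file of 16S sequences
#'
#' Wraps [Biostrings::readDNAStringSet()], upper-cases the alphabet and warns
#' when IUPAC ambiguity codes are present (they never match under the exact
#' criterion of [match_exact()]).
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs, collapse = TRUE)
  extra <- sum(freq) - sum(freq[c("A", "C", "G", "T")])
  if (extra > 0) {
    warn(sprintf(
      "%d non-ACGT (IUPAC ambiguity) base(s) present; they are treated as mismatches.",
      extra))
  }
  seqs
}

#' Write sequences to FASTA
#' @param seqs A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
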