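#' Default keyword sets for annotation screening
#'
#' `qs_keywords()` returns the positive-collection keywords (quorum-sensing
#' related annotation phrases); `qs_exclusion_keywords()` returns the broader
#' exclusion list used to build negative candidate sets by removing anything
#' directly or indirectly associated with quorum sensing.
#'
#' @return Character vector of keywords (matched case-insensitively as
#'   substrings).
#' @export
qs_keywords <- function() {
  c("quorum sensing", "quorum-sensing", "qs", "luxr", "tryptophanase",
    "two-component")
}

#' @rdname qs_keywords
#' @export
qs_exclusion_keywords <- function() {
  c("quorum", "qs", "luxr", "two-component", "homoserine lactone",
    "homoserine-lactone", "histidine kinase", "biofilm", "autoinducer",
    "bacteriocin", "competence", "virulence", "signal", "sensor",
    "response", "regulator", "membrane", "binding", "transcriptional activator")
}

#' Deduplicate entries by gene name, keeping the longest sequence
#'
#' When several entries carry the same gene name, only the one with the
#' longest sequence is kept; ties are broken by the lexicographically
#' smallest `entry_id`, so the result does not depend on input order.
#'
#' @param entries Protein-entry tibble with `entry_id`, `gene_name`,
#'   `sequence` columns.
#' @return A tibble with one row per gene name.
#' @export
dedup_longest <- function(entries) {
  entries <- as_tibble(entries)
  if (nrow(entries) == 0L) return(entries)
  assert_columns(entries, c("entry_id", "gene_name", "sequence"), "entries")
  entries |>
    dplyr::mutate(.len = nchar(.data$sequence)) |>
    dplyr::group_by(.data$gene_name) |>
    dplyr::arrange(dplyr::desc(.data$.len), .data$entry_id, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$entry_id) |>
    dplyr::select(-".len")
}

#' Collect entries whose annotation matches quorum-sensing keywords
#'
#' Case-insensitive substring matching (annotation categories such as
#' "two-component" occur embedded inside longer annotation strings).
#'
#' @param annotations Tibble with `entry_id` and `annotation` columns.
#' @param keywords Keywords to match; default [qs_keywords()].
#' @return Character vector of matching `entry_id`s, sorted.
#' @export
keyword_collect <- function(annotations, keywords = qs_keywords()) {
  annotations <- as_tibble(annotations)
  assert_columns(annotations, c("entry_id", "annotation"), "annotations")
  if (!length(keywords)) abort("`keywords` must be non-empty")
  ann <- tolower(annotations$annotation)
  hit <- Reduce(`|`, lapply(tolower(keywords), function(k) {
    stringr::str_detect(ann, stringr::fixed(k))
  }))
  sort(annotations$entry_id[hit])
}

#' Retain entries matching no exclusion keyword (negative candidates)
#'
#' @param annotations Tibble with `entry_id` and `annotation` columns.
#' @param exclusion_keywords Keywords whose presence disqualifies an entry;
#'   default [qs_exclusion_keywords()].
#' @return Character vector of retained `entry_id`s, sorted.
#' @export
keyword_exclude <- function(annotations, exclusion_keywords = qs_exclusion_keywords()) {
  annotations <- as_tibble(annotations)
  assert_columns(annotations, c("entry_id", "annotation"), "annotations")
  if (!length(exclusion_keywords)) abort("`exclusion_keywords` must be non-empty")
  excluded <- keyword_collect(annotations, exclusion_keywords)
  sort(setdiff(annotations$entry_id, excluded))
}

#' Load the curated gene-to-role/language mapping
#'
#' Ships as a versioned TSV resource seeded with canonical synthase and
#' receptor gene names (luxI/luxR, luxS, cqsA/cqsS, rpfF/rpfC, pqsA/pqsR,
#' darB, tnaA, agrB/agrC, ...). Users may point `path` at an extended table.
#' AIP synthases are representable but flagged low-confidence.
#'
#' @param path TSV file with columns `gene_name`, `role`, `language`,
#'   `low_confidence`; defaults to the bundled table.
#' @return A tibble; conflicting rows for one gene are rejected at load.
#' @export
read_gene_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_language_map.tsv",
                                package = "qsmine", mustWork = TRUE)
  map <- readr::read_tsv(path, col_types = readr::cols(
    gene_name = readr::col_character(),
    role = readr::col_character(),
    language = readr::col_character(),
    low_confidence = readr::col_logical()
  ))
  if (anyDuplicated(map$gene_name)) {
    dup <- unique(map$gene_name[duplicated(map$gene_name)])
    abort(sprintf("conflicting mapping rows for gene(s): %s",
                  paste(dup, collapse = ", ")))
  }
  bad <- setdiff(map$language, c(qs_languages(), "none"))
  if (length(bad)) abort(sprintf("unknown language(s) in mapping: %s",
                                 paste(bad, collapse = ", ")))
  map
}

#' Classify entries into role and signal language via the curated mapping
#'
#' Genes covered by the mapping receive its role and language; unmapped
#' genes pass through with `role = "unknown"`, `language = "none"`.
#'
#' @param entries Protein-entry tibble with a `gene_name` column.
#' @param mapping Mapping tibble from [read_gene_map()].
#' @return `entries` with `role`, `language` and `low_confidence` columns set.
#' @export
classify_seed <- function(entries, mapping = read_gene_map()) {
  entries <- as_tibble(entries)
  assert_columns(entries, "gene_name", "entries")
  mapping <- dplyr::select(as_tibble(mapping), "gene_name",
                           map_role = "role", map_language = "language",
                           "low_confidence")
  entries |>
    dplyr::select(-dplyr::any_of(c("role", "language", "low_confidence"))) |>
    dplyr::left_join(mapping, by = "gene_name") |>
    dplyr::mutate(
      role = dplyr::coalesce(.data$map_role, "unknown"),
      language = dplyr::coalesce(.data$map_language, "none"),
      low_confidence = dplyr::coalesce(.data$low_confidence, FALSE)
    ) |>
    dplyr::select(-"map_role", -"map_language")
}

#' Summarise a classified catalog
#'
#' Counts entries by role and synthases by language, and reports the
#' fraction of quorum-sensing bacteria (QSB): a species is QSB iff it owns
#' at least one entry with role synthase or receptor. The species
#' denominator is an explicit argument because the set of surveyed species
#' is generally larger than the set of species appearing in the catalog.
#'
#' @param catalog Classified protein-entry tibble (`species_id`, `role`,
#'   `language` columns).
#' @param n_species Species denominator for the QSB percentage; defaults to
#'   the number of distinct species in the catalog.
#' @return An object of class `qs_summary` (see [tidy.qs_summary()] and
#'   [glance.qs_summary()]).
#' @export
qs_summarize <- function(catalog, n_species = NULL) {
  catalog <- as_tibble(catalog)
  if (nrow(catalog)) assert_columns(catalog, c("species_id", "role", "language"),
                                    "catalog")
  role <- if (nrow(catalog)) catalog$role else character()
  n_synthase <- sum(role == "synthase")
  n_receptor <- sum(role == "receptor")
  per_language <- catalog |>
    dplyr::filter(.data$role == "synthase") |>
    dplyr::count(.data$language, name = "count")
  per_language <- setNames(
    as.integer(per_language$count[match(qs_languages(), per_language$language)]),
    qs_languages())
  per_language[is.na(per_language)] <- 0L
  qsb_species <- catalog |>
    dplyr::filter(.data$role %in% c("synthase", "receptor"),
                  !is.na(.data$species_id)) |>
    dplyr::distinct(.data$species_id)
  n_qsb <- nrow(qsb_species)
  n_sp <- n_species %||% dplyr::n_distinct(catalog$species_id[!is.na(catalog$species_id)])
  qsb_percent <- if (n_sp > 0) round(100 * n_qsb / n_sp, 2) else NA_real_
  structure(list(
    n_entries = nrow(catalog),
    n_total = n_synthase + n_receptor,
    n_synthase = n_synthase,
    n_receptor = n_receptor,
    n_none = sum(role == "none"),
    n_unknown = sum(role == "unknown"),
    per_language_synthase = per_language,
    n_species = as.integer(n_sp),
    n_qsb = n_qsb,
    qsb_percent = qsb_percent
  ), class = "qs_summary")
}

#' @export
print.qs_summary <- function(x, ...) {
  cat("QS catalog summary\n")
  cat(sprintf("  entries: %d (synthases %d, receptors %d, none %d, unknown %d)\n",
              x$n_entries, x$n_synthase, x$n_receptor, x$n_none, x$n_unknown))
  cat(sprintf("  species: %d, of which QSB: %d (%s%%)\n", x$n_species, x$n_qsb,
              ifelse(is.na(x$qsb_percent), "NA", format(x$qsb_percent))))
  lang <- x$per_language_synthase
  cat("  synthases per language:\n")
  for (l in names(lang)) cat(sprintf("    %-7s %d\n", l, lang[[l]]))
  invisible(x)
}
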