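#' Build the binary species-by-language incidence matrix
#'
#' A species is linked to a signal language iff it owns at least one
#' synthase of that language: production implies the ability to receive,
#' so synthase ownership defines the communication edges, while
#' receptor-only links are recorded separately and excluded from the graph.
#'
#' @param catalog Classified entry tibble (`species_id`, `role`, `language`).
#' @return A tibble of class `qs_incidence`: `species_id` plus one 0/1
#'   column per language (all eight, in [qs_languages()] order). The
#'   receptor-only species/language pairs are attached as attribute
#'   `receptor_only`.
#' @export
build_incidence <- function(catalog) {
  catalog <- as_tibble(catalog)
  assert_columns(catalog, c("species_id", "role", "language"), "catalog")
  catalog <- dplyr::filter(catalog, !is.na(.data$species_id))
  species <- sort(unique(catalog$species_id))
  langs <- qs_languages()
  m <- matrix(0L, nrow = length(species), ncol = length(langs),
              dimnames = list(species, langs))
  syn <- dplyr::filter(catalog, .data$role == "synthase",
                       .data$language %in% langs)
  if (nrow(syn)) m[cbind(syn$species_id, syn$language)] <- 1L
  rec <- catalog |>
    dplyr::filter(.data$role == "receptor", .data$language %in% langs) |>
    dplyr::distinct(.data$species_id, .data$language) |>
    dplyr::anti_join(
      dplyr::distinct(syn, .data$species_id, .data$language),
      by = c("species_id", "language"))
  out <- dplyr::bind_cols(tibble(species_id = species),
                          as_tibble(m, .name_repair = "minimal"))
  class(out) <- c("qs_incidence", class(out))
  attr(out, "receptor_only") <- rec
  out
}

# numeric 0/1 matrix view of an incidence tibble
incidence_matrix <- function(incidence) {
  m <- as.matrix(incidence[, qs_languages(), drop = FALSE])
  rownames(m) <- incidence$species_id
  storage.mode(m) <- "integer"
  m
}

#' Per-language prevalence counts and percentages
#'
#' Column sums of the incidence matrix with percentages over an explicit
#' species denominator (never inferred: the set of surveyed species is a
#' modelling choice, not a property of the matrix).
#'
#' @param incidence A [build_incidence()] result.
#' @param denominator Species count used for the percentages; must be at
#'   least the largest per-language count.
#' @return A tibble `language`, `count`, `percent` (2 decimals), with the
#'   denominator attached as an attribute.
#' @export
prevalence <- function(incidence, denominator) {
  m <- incidence_matrix(incidence)
  counts <- colSums(m)
  assert_scalar_number(denominator, "denominator", lower = 1)
  if (denominator < max(counts)) {
    abort("`denominator` is smaller than a per-language count")
  }
  out <- tibble(language = colnames(m), count = as.integer(counts),
                percent = unname(round(100 * counts / denominator, 2)))
  attr(out, "denominator") <- denominator
  out
}

#' Restrict the incidence matrix to multilingual species
#'
#' Keeps species possessing at least `min_languages` languages (row sum
#' >= `min_languages`, i.e. "more than (including)" the threshold).
#'
#' @param incidence A [build_incidence()] result.
#' @param min_languages Minimum number of languages (>= 1).
#' @return The filtered `qs_incidence`, row order preserved.
#' @export
multilingual_matrix <- function(incidence, min_languages = 5) {
  assert_scalar_number(min_languages, "min_languages", lower = 1)
  keep <- rowSums(incidence_matrix(incidence)) >= min_languages
  out <- incidence[keep, , drop = FALSE]
  class(out) <- c("qs_incidence", setdiff(class(out), "qs_incidence"))
  out
}

#' Exact species counts per observed language set
#'
#' Groups species by the exact set of languages they possess (upset-plot
#' counts). Species with no language are excluded; the counts therefore sum
#' to the number of species with at least one language.
#'
#' @param incidence A [build_incidence()] result.
#' @param drop Languages excluded before grouping (default `"AIP"`).
#' @return A tibble `languages` (labels joined by `+`), `n`, sorted by
#'   decreasing count.
#' @export
language_intersections <- function(incidence, drop = "AIP") {
  m <- incidence_matrix(incidence)
  m <- m[, setdiff(colnames(m), drop), drop = FALSE]
  sets <- unname(apply(m, 1L, function(r) {
    paste(colnames(m)[r == 1L], collapse = "+")
  }))
  sets <- sets[sets != ""]
  out <- tibble(languages = sets) |>
    dplyr::count(.data$languages, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$languages)
  out
}

#' Hierarchical clustering of species by language profile
#'
#' Agglomerative clustering of the binary rows under Jaccard distance
#' (R's asymmetric-binary distance) with average linkage by default;
#' deterministic, and the dendrogram is serialisable to Newick.
#'
#' @param incidence A (typically [multilingual_matrix()]-filtered)
#'   incidence object with >= 2 rows.
#' @param metric `"jaccard"` (binary) or any [stats::dist()] method.
#' @param linkage [stats::hclust()] agglomeration method.
#' @param k Optional number of flat clusters to cut.
#' @return A list of class `qs_dendro`: `hclust`, `tree` (an ape `phylo`),
#'   and, if `k` is given, `clusters` (named membership vector).
#' @export
cluster_species <- function(incidence, metric = "jaccard",
                            linkage = "average", k = NULL) {
  m <- incidence_matrix(incidence)
  if (nrow(m) < 2) abort("need >= 2 species to cluster")
  method <- if (identical(metric, "jaccard")) "binary" else metric
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warn(sprintf("dropping %d species with no language (undefined Jaccard distance)",
                 sum(zero)))
    m <- m[!zero, , drop = FALSE]
  }
  d <- dist(m, method = method)
  hc <- hclust(d, method = linkage)
  out <- list(hclust = hc, tree = ape::as.phylo(hc))
  if (!is.null(k)) out$clusters <- cutree(hc, k = k)
  structure(out, class = "qs_dendro")
}

#' Incidence matrix as a bipartite igraph / edge list
#'
#' @param incidence A [build_incidence()] result.
#' @return `as_bipartite_graph()`: an igraph object whose nodes carry a
#'   `bipartite` attribute (`"species"` or `"language"`);
#'   `incidence_edges()`: a tibble `species_id`, `language` with one row
#'   per edge.
#' @export
as_bipartite_graph <- function(incidence) {
  edges <- incidence_edges(incidence)
  langs <- qs_languages()
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble(name = c(incidence$species_id, langs),
                      bipartite = c(rep("species", nrow(incidence)),
                                    rep("language", length(langs)))))
  g
}

#' @rdname as_bipartite_graph
#' @export
incidence_edges <- function(incidence) {
  m <- incidence_matrix(incidence)
  idx <- which(m == 1L, arr.ind = TRUE)
  tibble(species_id = rownames(m)[idx[, 1]],
         language = colnames(m)[idx[, 2]]) |>
    dplyr::arrange(.data$species_id, .data$language)
}
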