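# FASTA / table / graph I/O helpers

#' Read and write protein entries as FASTA
#'
#' Sequences travel as plain character columns inside entry tibbles;
#' Biostrings handles the on-disk FASTA format.
#'
#' @param entries Tibble with `entry_id` and `sequence` columns.
#' @param path FASTA file path.
#' @return `read_entries_fasta()` returns a tibble with `entry_id` and
#'   `sequence`; `write_entries_fasta()` returns `path` invisibly.
#' @export
write_entries_fasta <- function(entries, path) {
  entries <- as_tibble(entries)
  assert_columns(entries, c("entry_id", "sequence"), "entries")
  x <- Biostrings::AAStringSet(entries$sequence)
  names(x) <- entries$entry_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_entries_fasta
#' @export
read_entries_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  tibble(entry_id = sub("\\s.*$", "", names(x)),
         sequence = as.character(unname(x)))
}

#' Export a bipartite species-language graph to GraphML
#'
#' Nodes carry a `bipartite` attribute (`"species"` or `"language"`).
#'
#' @param graph An igraph object, e.g. from [as_bipartite_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
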