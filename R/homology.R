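#' Alignment search parameters
#'
#' Defaults mirror protein-BLAST conventions: BLOSUM62 with affine gap
#' penalties 11/1 and ungapped Karlin-Altschul constants K = 0.041,
#' lambda = 0.267 (the gapped approximations), E-value cutoff 1e-5.
#'
#' @param substitution_matrix Name of a substitution matrix bundled with
#'   Biostrings (e.g. `"BLOSUM62"`), or a numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param K,lambda Karlin-Altschul constants for [evalue_of()].
#' @param e_threshold Expectation-value cutoff for [expand_seeds()].
#' @return A list of class `qs_search_params`.
#' @export
search_params <- function(substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          K = 0.041, lambda = 0.267,
                          e_threshold = 1e-5) {
  assert_scalar_number(gap_open, "gap_open", lower = 1e-9)
  assert_scalar_number(gap_extend, "gap_extend", lower = 1e-9)
  assert_scalar_number(e_threshold, "e_threshold", lower = 1e-300)
  mat <- substitution_matrix
  if (is.character(mat)) {
    e <- new.env()
    utils::data(list = mat, package = "Biostrings", envir = e)
    mat <- get(mat, envir = e)
  }
  structure(list(substitution_matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend, K = K, lambda = lambda,
                 e_threshold = e_threshold),
            class = "qs_search_params")
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gaps under the given
#' substitution matrix. Residues outside the 20 standard amino acids are
#' mapped to X before aligning.
#'
#' @param query,subject Amino-acid strings (non-empty).
#' @param params A [search_params()] object.
#' @return A list with `raw_score` (optimal local score), `identity`
#'   (fraction of identical positions over the alignment length, gaps
#'   included) and `aln_length`.
#' @export
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE", search_params())
local_align <- function(query, subject, params = search_params()) {
  if (!nzchar(query) || !nzchar(subject)) abort("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = sanitize_seq(query), subject = sanitize_seq(subject),
    type = "local", substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = FALSE)
  aln_len <- nchar(as.character(Biostrings::alignedPattern(pa)))
  list(raw_score = Biostrings::score(pa),
       identity = Biostrings::nmatch(pa) / aln_len,
       aln_length = aln_len)
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance local
#' alignments scoring at least `S` between a length-`m` query and a
#' length-`n` database. Strictly decreasing in `S`, linear in `m` and `n`.
#'
#' @param raw_score Alignment score(s) `S`.
#' @param m Query length (residues).
#' @param n Database length (total residues searched).
#' @param params A [search_params()] object supplying `K` and `lambda`.
#' @return Numeric E-value(s).
#' @export
evalue_of <- function(raw_score, m, n, params = search_params()) {
  assert_scalar_number(m, "m", lower = 1)
  assert_scalar_number(n, "n", lower = 1)
  params$K * m * n * exp(-params$lambda * raw_score)
}

# bit score under the same constants
bit_score <- function(raw_score, params) {
  (params$lambda * raw_score - log(params$K)) / log(2)
}

#' Expand seed entries against proteomes by local alignment
#'
#' Aligns every seed against every proteome protein and keeps hits whose
#' E-value is below `params$e_threshold`. The database length is the total
#' residue count of the searched proteome set. Each hit inherits its seed's
#' role and language as a provisional label; a protein hit by seeds of
#' several languages keeps one row per label (multi-label).
#'
#' @param seeds Classified seed tibble (`entry_id`, `sequence`, `role`,
#'   `language`).
#' @param proteome Proteome tibble (`entry_id`, `species_id`, `sequence`).
#' @param params A [search_params()] object.
#' @return Tibble of hits sorted by (`query_id`, `evalue`): `query_id`,
#'   `subject_id`, `species_id`, `raw_score`, `bitscore`, `evalue`,
#'   `identity`, `aln_length`, `role`, `language`.
#' @export
expand_seeds <- function(seeds, proteome, params = search_params()) {
  seeds <- as_tibble(seeds)
  proteome <- as_tibble(proteome)
  if (nrow(proteome) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  species_id = character(), raw_score = numeric(),
                  bitscore = numeric(), evalue = numeric(),
                  identity = numeric(), aln_length = integer(),
                  role = character(), language = character()))
  }
  assert_columns(seeds, c("entry_id", "sequence", "role", "language"), "seeds")
  assert_columns(proteome, c("entry_id", "species_id", "sequence"), "proteome")
  proteome <- dplyr::arrange(proteome, .data$entry_id)
  subjects <- Biostrings::AAStringSet(sanitize_seq(proteome$sequence))
  names(subjects) <- proteome$entry_id
  db_n <- sum(Biostrings::width(subjects))

  hits <- purrr::map(seq_len(nrow(seeds)), function(i) {
    q <- sanitize_seq(seeds$sequence[i])
    pa <- Biostrings::pairwiseAlignment(
      pattern = subjects, subject = q, type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    s <- Biostrings::score(pa)
    ev <- evalue_of(s, m = nchar(q), n = db_n, params = params)
    keep <- which(ev < params$e_threshold)
    if (!length(keep)) return(NULL)
    aln_len <- unname(nchar(as.character(Biostrings::alignedPattern(pa[keep]))))
    tibble(
      query_id = seeds$entry_id[i],
      subject_id = proteome$entry_id[keep],
      species_id = proteome$species_id[keep],
      raw_score = unname(s[keep]),
      bitscore = unname(bit_score(s[keep], params)),
      evalue = unname(ev[keep]),
      identity = unname(Biostrings::nmatch(pa[keep])) / aln_len,
      aln_length = aln_len,
      role = seeds$role[i],
      language = seeds$language[i]
    )
  })
  dplyr::bind_rows(hits) |>
    dplyr::arrange(.data$query_id, .data$evalue, .data$subject_id)
}

#' Remove hits whose subject is an already-reported entry
#'
#' @param hits Hit tibble from [expand_seeds()].
#' @param reported_ids Character vector of reported entry ids.
#' @return The hits whose `subject_id` is not in `reported_ids`.
#' @export
subtract_reported <- function(hits, reported_ids) {
  dplyr::filter(as_tibble(hits), !.data$subject_id %in% reported_ids)
}

#' Read or write BLAST tabular (outfmt 6) hit files
#'
#' `read_blast_tab()` parses the standard 12-column tabular output of an
#' external BLAST+ run into the same hit shape produced by
#' [expand_seeds()]; `write_blast_tab()` writes hits in that format, so
#' either alignment path flows through identical downstream code.
#'
#' @param path File path.
#' @param hits Hit tibble.
#' @return `read_blast_tab()` returns a hit tibble (identity rescaled to
#'   `[0, 1]`); `write_blast_tab()` returns `path` invisibly.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "aln_length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- readr::read_tsv(path, col_names = cols, col_types = readr::cols(
    query_id = "c", subject_id = "c", .default = "d"))
  dplyr::transmute(x,
    query_id = .data$query_id, subject_id = .data$subject_id,
    identity = .data$pident / 100, aln_length = as.integer(.data$aln_length),
    evalue = .data$evalue, bitscore = .data$bitscore)
}

#' @rdname read_blast_tab
#' @export
write_blast_tab <- function(hits, path) {
  hits <- as_tibble(hits)
  out <- tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(100 * hits$identity, 2), length = hits$aln_length,
    mismatch = NA_integer_, gapopen = NA_integer_,
    qstart = NA_integer_, qend = NA_integer_,
    sstart = NA_integer_, send = NA_integer_,
    evalue = hits$evalue, bitscore = round(hits$bitscore, 1))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Run an external BLAST+ search (optional adapter)
#'
#' Thin adapter over `makeblastdb`/`blastp` for users who prefer the
#' heuristic search engine on large inputs; requires BLAST+ on the PATH.
#' Results are parsed with [read_blast_tab()] so they are interchangeable
#' with [expand_seeds()] output.
#'
#' @param seeds,proteome Entry tibbles with `entry_id` and `sequence`.
#' @param e_threshold Expectation cutoff passed to `blastp -evalue`.
#' @return A hit tibble.
#' @export
run_blastp <- function(seeds, proteome, e_threshold = 1e-5) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    abort("BLAST+ (blastp/makeblastdb) not found on PATH")
  }
  dir <- tempfile("blastdb")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  db_fa <- file.path(dir, "db.fasta")
  q_fa <- file.path(dir, "query.fasta")
  write_entries_fasta(proteome, db_fa)
  write_entries_fasta(seeds, q_fa)
  out <- file.path(dir, "hits.tsv")
  system2("makeblastdb", c("-in", db_fa, "-dbtype", "prot"),
          stdout = FALSE, stderr = FALSE)
  system2("blastp", c("-query", q_fa, "-db", db_fa, "-outfmt", "6",
                      "-evalue", format(e_threshold), "-out", out),
          stdout = FALSE, stderr = FALSE)
  read_blast_tab(out)
}
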