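# the OTU x sample matrix view of a wide abundance tibble
abundance_matrix <- function(table, check = TRUE) {
  table <- as_tibble(table)
  assert_columns(table, "otu_id", "table")
  m <- as.matrix(table[, setdiff(names(table), "otu_id"), drop = FALSE])
  rownames(m) <- table$otu_id
  if (check && nrow(m) > 0 && ncol(m) > 0 && any(abs(colSums(m) - 1) > 1e-6)) {
    abort("sample columns must sum to 1 (relative abundances)")
  }
  m
}

#' Identify the core community of an abundance table
#'
#' An OTU is core iff it satisfies all three complementary criteria:
#' (1) its mean relative abundance is at least `abund_frac`;
#' (2) it is detected (value > 0) in more than `prev_frac` of the samples;
#' (3) it belongs to the minimal OTU set covering `top_reads_frac` of the
#' reads (greedy by descending abundance) in more than
#' `top_reads_sample_frac` of the samples.
#'
#' @param table Wide abundance tibble (`otu_id` plus one numeric column per
#'   sample; columns sum to 1).
#' @param abund_frac Mean relative-abundance floor (default 0.001, i.e.
#'   0.1% read as an absolute fraction).
#' @param prev_frac Prevalence fraction (default 0.80).
#' @param top_reads_frac Read-coverage fraction (default 0.80).
#' @param top_reads_sample_frac Fraction of samples in which criterion 3
#'   must hold (default 0.50).
#' @return Character vector of core OTU ids.
#' @export
core_community <- function(table, abund_frac = 0.001, prev_frac = 0.80,
                           top_reads_frac = 0.80,
                           top_reads_sample_frac = 0.50) {
  m <- abundance_matrix(table)
  if (nrow(m) == 0 || ncol(m) == 0) return(character())
  c1 <- rowMeans(m) >= abund_frac
  c2 <- rowMeans(m > 0) > prev_frac
  in_top <- apply(m, 2L, function(col) {
    o <- order(col, decreasing = TRUE)
    need <- which(cumsum(col[o]) >= top_reads_frac)[1]
    if (is.na(need)) need <- length(col)
    member <- logical(length(col))
    member[o[seq_len(need)]] <- TRUE
    member
  })
  c3 <- rowMeans(in_top) > top_reads_sample_frac
  rownames(m)[c1 & c2 & c3]
}

#' Spearman co-occurrence edges between OTUs
#'
#' All unordered OTU pairs whose Spearman rank correlation satisfies
#' `|rho| > rho_min` and whose two-sided p-value (t approximation,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`) is below `p_max`. Ties receive
#' average ranks. Following the source filter, no multiple-testing
#' correction is applied by default; a Benjamini-Hochberg switch is
#' available.
#'
#' @param table Wide abundance tibble (>= 4 samples).
#' @param rho_min Absolute-correlation floor (default 0.58).
#' @param p_max Significance cutoff (default 0.05).
#' @param fdr If `TRUE`, apply Benjamini-Hochberg to the p-values before
#'   filtering (off by default).
#' @return A tibble of class `qs_cooc`: `otu_a < otu_b`, `rho`, `p`,
#'   `sign` (`"positive"`/`"negative"`).
#' @export
spearman_edges <- function(table, rho_min = 0.58, p_max = 0.05, fdr = FALSE) {
  m <- abundance_matrix(table, check = FALSE)  # rank-based: scale-free
  n <- ncol(m)
  if (n < 4) abort("need >= 4 samples")
  const <- apply(m, 1L, function(r) length(unique(r)) == 1L)
  if (any(const)) {
    warn(sprintf("skipping %d constant OTU row(s): Spearman rho undefined",
                 sum(const)))
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2) {
    return(structure(tibble(otu_a = character(), otu_b = character(),
                            rho = numeric(), p = numeric(), sign = character()),
                     class = c("qs_cooc", class(tibble()))))
  }
  rho <- cor(t(m), method = "spearman")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  out <- tibble(
    otu_a = pmin(rownames(rho)[idx[, 1]], colnames(rho)[idx[, 2]]),
    otu_b = pmax(rownames(rho)[idx[, 1]], colnames(rho)[idx[, 2]]),
    rho = r, p = p,
    sign = ifelse(r >= 0, "positive", "negative")
  ) |>
    dplyr::filter(abs(.data$rho) > rho_min, .data$p < p_max) |>
    dplyr::arrange(.data$otu_a, .data$otu_b)
  class(out) <- c("qs_cooc", class(out))
  out
}

#' Metabolite-interchange network edges
#'
#' Links each pair of species sharing at least `min_shared` metabolites;
#' the edge weight is the size of the shared-metabolite set.
#'
#' @param metab_table Wide binary tibble (`species_id` plus 0/1 metabolite
#'   columns).
#' @param min_shared Minimum shared-metabolite count (default 2).
#' @return A tibble `species_a < species_b`, `shared`.
#' @export
build_min <- function(metab_table, min_shared = 2) {
  metab_table <- as_tibble(metab_table)
  assert_columns(metab_table, "species_id", "metab_table")
  m <- as.matrix(metab_table[, setdiff(names(metab_table), "species_id"),
                             drop = FALSE])
  if (!all(m %in% c(0, 1))) abort("metabolite table must be binary")
  rownames(m) <- metab_table$species_id
  shared <- m %*% t(m)
  idx <- which(upper.tri(shared) & shared >= min_shared, arr.ind = TRUE)
  tibble(
    species_a = pmin(rownames(shared)[idx[, 1]], colnames(shared)[idx[, 2]]),
    species_b = pmax(rownames(shared)[idx[, 1]], colnames(shared)[idx[, 2]]),
    shared = as.integer(shared[idx])
  ) |>
    dplyr::arrange(.data$species_a, .data$species_b)
}

#' Label co-occurrence edges by candidate mechanism
#'
#' Each co-occurrence edge is labelled `"metabolite"` if the species pair
#' has a metabolite-interchange edge only, `"qs"` if the pair shares at
#' least one signal language only, `"both"` if both hold, and
#' `"unexplained"` otherwise. OTUs are mapped to species via an explicit
#' mapping table; edges with an unmapped endpoint are labelled
#' `"no-data"` and excluded from the summary counts.
#'
#' @param cooc Co-occurrence edge tibble from [spearman_edges()].
#' @param min_edges Metabolite edges from [build_min()].
#' @param incidence Species-language incidence from [build_incidence()].
#' @param mapping Optional tibble `otu_id`, `species_id`; `NULL` means OTU
#'   ids are species ids.
#' @return A tibble of class `qs_explained` with the edge columns plus
#'   `species_a`, `species_b`, `label`; summary counts are attached as the
#'   `counts` attribute (see [glance.qs_explained()]).
#' @export
explain_edges <- function(cooc, min_edges, incidence, mapping = NULL) {
  cooc <- as_tibble(cooc)
  assert_columns(cooc, c("otu_a", "otu_b"), "cooc")
  map_id <- function(x) {
    if (is.null(mapping)) return(x)
    mapping <- as_tibble(mapping)
    assert_columns(mapping, c("otu_id", "species_id"), "mapping")
    mapping$species_id[match(x, mapping$otu_id)]
  }
  sp_a <- map_id(cooc$otu_a)
  sp_b <- map_id(cooc$otu_b)
  min_key <- paste(min_edges$species_a, min_edges$species_b)
  has_min <- paste(pmin(sp_a, sp_b), pmax(sp_a, sp_b)) %in% min_key
  m <- incidence_matrix(incidence)
  shares_lang <- function(a, b) {
    if (is.na(a) || is.na(b)) return(FALSE)
    if (!a %in% rownames(m) || !b %in% rownames(m)) return(FALSE)
    any(m[a, ] == 1L & m[b, ] == 1L)
  }
  has_qs <- purrr::map2_lgl(sp_a, sp_b, shares_lang)
  label <- dplyr::case_when(
    is.na(sp_a) | is.na(sp_b) ~ "no-data",
    has_min & has_qs ~ "both",
    has_min ~ "metabolite",
    has_qs ~ "qs",
    TRUE ~ "unexplained"
  )
  out <- dplyr::mutate(cooc, species_a = sp_a, species_b = sp_b,
                       label = label)
  counts <- table(factor(label[label != "no-data"],
                         levels = c("metabolite", "qs", "both", "unexplained")))
  class(out) <- c("qs_explained", class(out))
  attr(out, "counts") <- counts
  out
}
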