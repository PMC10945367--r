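#' Proportion of differing sites between two aligned sequences
#'
#' Pairwise-deletion p-distance: columns where either sequence has a gap or
#' a non-standard residue are excluded, and the distance is the fraction of
#' the remaining comparable sites that differ.
#'
#' @param seq_a,seq_b Aligned amino-acid strings of equal length.
#' @param gap_handling `"pairwise"` (default; per-pair column exclusion) or
#'   `"complete"` is handled at the matrix level by
#'   [poisson_dist_matrix()].
#' @return A fraction in `[0, 1]`.
#' @export
p_distance <- function(seq_a, seq_b, gap_handling = "pairwise") {
  if (nchar(seq_a) != nchar(seq_b) || nchar(seq_a) < 1) {
    abort("sequences must be aligned (equal, positive length)")
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% aa_standard() & b %in% aa_standard()
  if (!any(ok)) abort("zero comparable sites")
  mean(a[ok] != b[ok])
}

#' Poisson correction of a p-distance
#'
#' `d = -ln(1 - p)`, the expected number of substitutions per site under a
#' Poisson model of equal-rate substitutions; satisfies `d >= p` and is
#' monotone increasing, diverging as `p` approaches 1 (saturation).
#'
#' @param p Fraction(s) of differing sites, `0 <= p < 1`.
#' @return Corrected evolutionary distance(s).
#' @export
#' @examples
#' poisson_correct(0.5)  # log(2)
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) abort("`p` must satisfy 0 <= p < 1 (p >= 1 is saturated)")
  -log(1 - p)
}

#' Poisson-corrected distance matrix from an alignment
#'
#' @param entries Tibble with `entry_id` and aligned `sequence` columns
#'   (equal lengths).
#' @param gap_handling `"pairwise"` (default) excludes gap/non-standard
#'   columns per pair; `"complete"` drops such columns across all
#'   sequences first.
#' @param saturated Handling of fully saturated pairs (p-distance 1, where
#'   the correction diverges): `"cap"` (default) caps p at `1 - 1/L` over
#'   the L comparable sites, the largest resolvable difference; `"error"`
#'   rejects.
#' @return A symmetric matrix with zero diagonal, labelled by `entry_id`.
#' @export
poisson_dist_matrix <- function(entries, gap_handling = c("pairwise", "complete"),
                                saturated = c("cap", "error")) {
  gap_handling <- match.arg(gap_handling)
  saturated <- match.arg(saturated)
  entries <- as_tibble(entries)
  assert_columns(entries, c("entry_id", "sequence"), "entries")
  seqs <- toupper(entries$sequence)
  if (length(unique(nchar(seqs))) != 1) abort("sequences must be aligned")
  if (gap_handling == "complete") {
    chars <- do.call(rbind, strsplit(seqs, ""))
    keep <- apply(chars, 2L, function(col) all(col %in% aa_standard()))
    if (!any(keep)) abort("zero comparable sites after complete deletion")
    seqs <- apply(chars[, keep, drop = FALSE], 1L, paste, collapse = "")
  }
  n <- length(seqs)
  L <- nchar(seqs[1])
  d <- matrix(0, n, n, dimnames = list(entries$entry_id, entries$entry_id))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    p <- p_distance(seqs[i], seqs[j])
    if (p >= 1 && saturated == "cap") p <- 1 - 1 / L
    d[i, j] <- d[j, i] <- poisson_correct(p)
  }
  d
}

#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i, j) = (n - 2) d(i, j) - r_i - r_j` (with `r_i` the row sums over
#' active nodes) is joined, branch lengths follow the standard split
#' formula, and distances to the new node are
#' `(d(i, k) + d(j, k) - d(i, j)) / 2`. Ties are broken by the smallest
#' label pair, and negative branch lengths are clamped to zero with the
#' number of clamped branches recorded in the `negative_branches`
#' attribute.
#'
#' @param d Symmetric distance matrix with labels (>= 2 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) abort("need >= 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  labels <- rownames(d)
  n_clamped <- 0L
  clamp <- function(v) {
    if (v < 0) {
      n_clamped <<- n_clamped + 1L
      0
    } else v
  }
  fmt <- function(x) sprintf("%.10g", x)
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labels[1],
                                        fmt(d[1, 2] / 2), labels[2],
                                        fmt(d[1, 2] / 2)))
    attr(tr, "negative_branches") <- 0L
    return(tr)
  }
  # subtree Newick strings for the active nodes
  sub <- setNames(as.list(labels), labels)
  active <- labels
  while (length(active) > 3) {
    m <- length(active)
    dd <- d[active, active]
    r <- rowSums(dd)
    q <- (m - 2) * dd - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    # ties: smallest (i, j) label pair, lexicographically
    pick <- best[order(pmin(rownames(dd)[best[, 1]], colnames(dd)[best[, 2]]),
                       pmax(rownames(dd)[best[, 1]], colnames(dd)[best[, 2]]))[1], ]
    i <- rownames(dd)[pick[1]]; j <- colnames(dd)[pick[2]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    vi <- clamp(vi); vj <- clamp(vj)
    new_lab <- paste0("(", i, "|", j, ")")
    others <- setdiff(active, c(i, j))
    newd <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d <- rbind(cbind(d, 0), 0)
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_lab
    d[new_lab, others] <- d[others, new_lab] <- newd
    sub[[new_lab]] <- sprintf("(%s:%s,%s:%s)", sub[[i]], fmt(vi),
                              sub[[j]], fmt(vj))
    active <- c(others, new_lab)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- clamp((d[a, b] + d[a, c3] - d[b, c3]) / 2)
  vb <- clamp((d[a, b] + d[b, c3] - d[a, c3]) / 2)
  vc <- clamp((d[a, c3] + d[b, c3] - d[a, b]) / 2)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", sub[[a]], fmt(va), sub[[b]],
                 fmt(vb), sub[[c3]], fmt(vc))
  tr <- ape::read.tree(text = txt)
  attr(tr, "negative_branches") <- n_clamped
  tr
}

#' Newick serialisation round trip
#'
#' `write_newick()` serialises an `ape::phylo` tree (optionally to a file);
#' `parse_newick()` parses Newick text back into a tree, reporting the
#' offset of the first unbalanced parenthesis on malformed input. A
#' write/parse round trip preserves topology and branch lengths.
#'
#' @param tree An `ape::phylo` object.
#' @param path Optional output file; if `NULL` the Newick string is
#'   returned.
#' @param text Newick text to parse.
#' @return `write_newick()`: the Newick string (invisibly if written to
#'   file); `parse_newick()`: an `ape::phylo` tree.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @export
parse_newick <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) abort(sprintf("malformed Newick: unbalanced ')' at offset %d", i))
  }
  if (depth != 0L) {
    abort(sprintf("malformed Newick: %d unclosed '(' at end of input", depth))
  }
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) abort("malformed Newick: parse failed")
  tr
}
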