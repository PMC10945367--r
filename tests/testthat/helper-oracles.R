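# Independent brute-force oracles. These are deliberately naive
# implementations, written separately from the package code paths they
# check.

# Full-DP Smith-Waterman with affine gaps (gap of length L costs
# open + L * extend), cell-by-cell, no vectorisation.
oracle_smith_waterman <- function(a, b, mat, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]], E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Friedman statistic straight from ranks, loop-based.
oracle_friedman <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  ranks <- matrix(0, n, k)
  for (i in seq_len(n)) ranks[i, ] <- rank(-scores[i, ])
  rbar <- colMeans(ranks)
  12 * n / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
}

# Spearman rho as rank-then-Pearson.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact language-set counts by enumeration over all 2^k subsets.
oracle_intersections <- function(m, drop = "AIP") {
  m <- m[, setdiff(colnames(m), drop), drop = FALSE]
  k <- ncol(m)
  out <- list()
  for (code in seq_len(2^k) - 1L) {
    sel <- as.logical(bitwAnd(code, 2^(seq_len(k) - 1L)))
    if (!any(sel)) next
    cnt <- sum(apply(m, 1L, function(r) all(r[sel] == 1L) & all(r[!sel] == 0L)))
    if (cnt > 0) {
      out[[paste(colnames(m)[sel], collapse = "+")]] <- cnt
    }
  }
  out
}

# Pairwise shared-metabolite counts by explicit set intersection.
oracle_min_edges <- function(tab, min_shared = 2) {
  sp <- tab$species_id
  mets <- setdiff(names(tab), "species_id")
  profiles <- lapply(seq_along(sp), function(i) mets[tab[i, mets] == 1])
  res <- list()
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (i < j) {
      shared <- length(intersect(profiles[[i]], profiles[[j]]))
      if (shared >= min_shared) {
        a <- min(sp[i], sp[j]); b <- max(sp[i], sp[j])
        res[[paste(a, b)]] <- shared
      }
    }
  }
  res
}
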