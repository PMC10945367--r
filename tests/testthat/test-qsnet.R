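toy_catalog <- function() {
  tibble::tibble(
    entry_id = sprintf("E%d", 1:8),
    species_id = c("S1", "S1", "S2", "S2", "S3", "S3", "S4", "S4"),
    role = c("synthase", "synthase", "synthase", "receptor",
             "receptor", "receptor", "synthase", "synthase"),
    language = c("AHL", "DSF", "DSF", "AHL", "AHL", "DSF", "AHL", "HAQ")
  )
}

test_that("incidence is built from synthase ownership only", {
  inc <- build_incidence(toy_catalog())
  m <- as.matrix(inc[, qs_languages()])
  rownames(m) <- inc$species_id
  # hand-built expectation
  expect_equal(unname(m["S1", c("AHL", "DSF")]), c(1L, 1L))
  expect_equal(unname(m["S2", c("AHL", "DSF")]), c(0L, 1L))
  expect_equal(sum(m["S3", ]), 0L)  # receptor-only species: all-zero row
  expect_equal(unname(m["S4", c("AHL", "HAQ")]), c(1L, 1L))
  expect_equal(sum(m), 5L)
  # receptor-only links are recorded separately, not as graph edges
  rec <- attr(inc, "receptor_only")
  expect_true(all(paste(rec$species_id, rec$language) %in%
                    c("S2 AHL", "S3 AHL", "S3 DSF")))
  # bipartite graph edge count equals the incidence sum
  g <- as_bipartite_graph(inc)
  expect_equal(igraph::ecount(g), sum(m))
  expect_setequal(unique(igraph::V(g)$bipartite), c("species", "language"))
  expect_equal(nrow(incidence_edges(inc)), sum(m))
})

test_that("prevalence uses an explicit denominator", {
  inc <- build_incidence(toy_catalog())
  prev <- prevalence(inc, denominator = 4)
  expect_equal(prev$count[prev$language == "AHL"], 2L)
  expect_equal(prev$percent[prev$language == "AHL"], 50)
  # recomputing percents from counts matches to 0.01 for any denominator
  for (den in c(4, 7, 1936)) {
    p <- prevalence(inc, denominator = den)
    expect_true(all(abs(p$percent - round(100 * p$count / den, 2)) < 0.01))
  }
  expect_error(prevalence(inc, denominator = 1), "smaller than")
  # column sums are invariant under row permutation
  perm <- inc[rev(seq_len(nrow(inc))), ]
  class(perm) <- class(inc)
  expect_equal(prevalence(perm, 4)$count, prev$count)
})

test_that("multilingual filtering keeps row sums >= the threshold", {
  catalog <- tibble::tibble(
    entry_id = sprintf("E%d", 1:12),
    species_id = rep(c("S5", "S4", "S1"), times = c(5, 4, 3)),
    role = "synthase",
    language = c(qs_languages()[1:5], qs_languages()[1:4], qs_languages()[1:3])
  )
  inc <- build_incidence(catalog)
  m5 <- multilingual_matrix(inc, min_languages = 5)
  expect_equal(m5$species_id, "S5")  # row sum 5 retained ("including five")
  m4 <- multilingual_matrix(inc, min_languages = 4)
  expect_setequal(m4$species_id, c("S4", "S5"))
  # monotone nonincreasing row count in the threshold
  counts <- sapply(1:8, function(k) nrow(multilingual_matrix(inc, k)))
  expect_true(all(diff(counts) <= 0))
})

test_that("language-set intersection counts equal subset enumeration", {
  # three species all {DSF}
  cat3 <- tibble::tibble(entry_id = sprintf("E%d", 1:3),
                         species_id = c("A", "B", "C"),
                         role = "synthase", language = "DSF")
  li <- language_intersections(build_incidence(cat3))
  expect_equal(li$languages, "DSF")
  expect_equal(li$n, 3L)
  # random binary matrices against brute-force 2^k enumeration
  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(rbinom(10 * 8, 1, 0.4), nrow = 10,
                dimnames = list(sprintf("S%02d", 1:10), qs_languages()))
    inc <- dplyr::bind_cols(tibble::tibble(species_id = rownames(m)),
                            tibble::as_tibble(m))
    class(inc) <- c("qs_incidence", class(inc))
    got <- language_intersections(inc)
    want <- oracle_intersections(m)
    expect_equal(nrow(got), length(want))
    for (i in seq_len(nrow(got))) {
      expect_equal(got$n[i], want[[got$languages[i]]])
    }
    # counts partition the species with >= 1 (non-AIP) language
    expect_equal(sum(got$n),
                 sum(rowSums(m[, setdiff(colnames(m), "AIP")]) > 0))
  }
})

test_that("species cluster by language profile", {
  m <- rbind(
    g1a = c(1, 1, 1, 0, 0, 0, 0, 0), g1b = c(1, 1, 1, 0, 0, 0, 0, 0),
    g2a = c(0, 0, 0, 1, 1, 1, 0, 0), g2b = c(0, 0, 0, 1, 1, 1, 0, 0),
    g3a = c(0, 0, 0, 0, 0, 0, 1, 1), g3b = c(0, 0, 0, 0, 0, 1, 1, 1))
  colnames(m) <- qs_languages()
  inc <- dplyr::bind_cols(tibble::tibble(species_id = rownames(m)),
                          tibble::as_tibble(m))
  class(inc) <- c("qs_incidence", class(inc))
  cl <- cluster_species(inc, k = 3)
  # identical rows merge at height 0; disjoint groups merge last at 1
  expect_equal(min(cl$hclust$height), 0)
  expect_equal(max(cl$hclust$height), 1)
  groups <- split(names(cl$clusters), cl$clusters)
  expect_setequal(lapply(groups, sort),
                  list(c("g1a", "g1b"), c("g2a", "g2b"), c("g3a", "g3b")))
  # dendrogram serialises to Newick and parses back
  nwk <- write_newick(cl$tree)
  expect_setequal(parse_newick(nwk)$tip.label, rownames(m))
})
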