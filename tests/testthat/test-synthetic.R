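test_that("seed families embed their motif and carry correct metadata", {
  sp <- tibble::tibble(family = "luxI", language = "AHL", role = "synthase",
                       motif = "WCWHMYFQWCWHMY", n_members = 3,
                       min_length = 60, max_length = 90)
  fam <- make_seed_families(sp, seed = 4)
  expect_equal(nrow(fam$entries), 3)
  expect_true(all(grepl("WCWHMYFQWCWHMY", fam$entries$sequence, fixed = TRUE)))
  expect_true(all(fam$entries$language == "AHL"))
  expect_true(all(fam$entries$role == "synthase"))
  expect_true(all(nchar(fam$entries$sequence) >= 60 &
                    nchar(fam$entries$sequence) <= 90))

  all8 <- make_seed_families(default_seed_specs(), seed = 2)
  expect_setequal(unique(all8$entries$language), qs_languages())
})

test_that("seed-family generation is deterministic and validates input", {
  specs <- default_seed_specs()
  a <- make_seed_families(specs, seed = 99)
  b <- make_seed_families(specs, seed = 99)
  expect_identical(a, b)
  fa <- tempfile(fileext = ".fasta"); fb <- tempfile(fileext = ".fasta")
  write_entries_fasta(a$entries, fa)
  write_entries_fasta(b$entries, fb)
  expect_identical(readLines(fa), readLines(fb))

  dup <- rbind(specs, specs[1, ])
  expect_error(make_seed_families(dup, seed = 1), "overlapping")
  bad <- specs
  bad$motif[1] <- "WCWHMYFQWCJZ12"
  expect_error(make_seed_families(bad, seed = 1), "standard residues")
  near <- specs[1:2, ]
  near$motif[2] <- sub("^.", "C", near$motif[1])  # differs at 1 position only
  expect_error(make_seed_families(near, seed = 1), "50%")
})

test_that("planted homologs mutate seeds at the requested rate", {
  fam <- make_seed_families(default_seed_specs(), seed = 3)
  plan <- tibble::tibble(species_id = sprintf("SP_%03d", 1:10),
                         language = rep(c("AHL", "DSF"), 5),
                         mutation_rate = 0.1, n_copies = 3L)
  prot <- make_proteomes(10, 20, plan, fam$entries, seed = 17)
  hom <- prot$truth$homologs
  expect_equal(nrow(hom), 30)
  # referential integrity: every planted id resolves to a proteome record
  expect_true(all(hom$protein_id %in% prot$proteome$entry_id))
  expect_equal(anyDuplicated(prot$proteome$entry_id), 0L)
  # Hamming distance to the source seed is exactly the recorded mutation
  # count, and within 4 binomial s.d. of L * rate
  L <- 120
  sdev <- sqrt(L * 0.1 * 0.9)
  for (i in seq_len(nrow(hom))) {
    seq_p <- prot$proteome$sequence[prot$proteome$entry_id == hom$protein_id[i]]
    seq_s <- fam$entries$sequence[fam$entries$entry_id == hom$source_entry[i]]
    d <- sum(strsplit(seq_p, "")[[1]] != strsplit(seq_s, "")[[1]])
    expect_identical(d, hom$n_mutations[i])
    expect_lt(abs(d - L * 0.1), 4 * sdev)
  }
  # the mean over 30 plants is a much tighter binomial check
  expect_lt(abs(mean(hom$n_mutations) - L * 0.1), 4 * sdev / sqrt(nrow(hom)))
})

test_that("proteome generation handles edge cases and rejects bad plans", {
  fam <- make_seed_families(default_seed_specs(), seed = 3)
  zero <- make_proteomes(
    3, 5, tibble::tibble(species_id = "SP_001", language = "AHL",
                         mutation_rate = 0),
    fam$entries, seed = 5)
  planted <- zero$truth$homologs
  seq_p <- zero$proteome$sequence[zero$proteome$entry_id == planted$protein_id]
  seq_s <- fam$entries$sequence[fam$entries$entry_id == planted$source_entry]
  expect_identical(seq_p, seq_s)
  expect_identical(planted$n_mutations, 0L)

  empty <- make_proteomes(3, 5, tibble::tibble(), fam$entries, seed = 5)
  expect_equal(nrow(empty$truth$homologs), 0)
  expect_equal(nrow(empty$proteome), 15)

  expect_error(
    make_proteomes(3, 5, tibble::tibble(species_id = "SP_099",
                                        language = "AHL", mutation_rate = 0.1),
                   fam$entries, seed = 5),
    "unknown species")
  expect_error(
    make_proteomes(3, 5, tibble::tibble(species_id = "SP_001",
                                        language = "AHL", mutation_rate = 0.6),
                   fam$entries, seed = 5),
    "rate")
})

test_that("training sets are disjoint, correctly sized and separable", {
  fam <- make_seed_families(default_seed_specs(), seed = 3)
  plan <- tibble::tibble(species_id = sprintf("SP_%03d", 1:5),
                         language = "AHL", mutation_rate = 0.1,
                         n_copies = 2L)
  prot <- make_proteomes(5, 50, plan, fam$entries, seed = 7)
  tr <- make_training_sets(fam$entries, prot$proteome, prot$truth,
                           n_neg = 100, seed = 9)
  expect_equal(nrow(tr$positives), nrow(fam$entries) + 10)
  expect_equal(nrow(tr$negatives), 100)
  expect_length(intersect(tr$positives$entry_id, tr$negatives$entry_id), 0)
  expect_false(any(tr$negatives$entry_id %in% prot$truth$homologs$protein_id))
  # AAC centroids differ because the motifs are skewed to rare residues
  cp <- colMeans(aac(tr$positives$sequence))
  cn <- colMeans(aac(tr$negatives$sequence))
  expect_gt(sqrt(sum((cp - cn)^2)), 0.02)
  expect_error(
    make_training_sets(fam$entries, prot$proteome, prot$truth,
                       n_neg = 10000, seed = 9),
    "insufficient background")
})

test_that("abundance tables are compositional with planted correlation", {
  blocks <- list(sprintf("OTU_%03d", 6:10), sprintf("OTU_%03d", 11:15))
  ab <- make_abundance(40, 200, blocks = blocks, block_strength = 0.9,
                       n_core = 5, seed = 21)
  m <- as.matrix(ab$table[, -1])
  expect_true(all(abs(colSums(m) - 1) < 1e-9))
  expect_identical(ab$truth$core, sprintf("OTU_%03d", 1:5))

  # block_strength = 0: off-block pairs are uncorrelated on average
  ab0 <- make_abundance(25, 200, blocks = list(), block_strength = 0,
                        n_core = 0, seed = 22)
  m0 <- as.matrix(ab0$table[, -1])
  pairs <- utils::combn(nrow(m0), 2)[, 1:100]
  rhos <- apply(pairs, 2, function(p) {
    suppressWarnings(cor(m0[p[1], ], m0[p[2], ], method = "spearman"))
  })
  expect_lt(abs(mean(rhos)), 0.1)

  # strong blocks: within-block rank correlation dominates between-block
  ab9 <- make_abundance(30, 100, blocks = blocks, block_strength = 0.9,
                        n_core = 5, seed = 23)
  m9 <- as.matrix(ab9$table[, -1])
  rownames(m9) <- ab9$table$otu_id
  rho <- cor(t(m9), method = "spearman")
  within <- c(rho[blocks[[1]], blocks[[1]]][upper.tri(diag(5))],
              rho[blocks[[2]], blocks[[2]]][upper.tri(diag(5))])
  between <- as.vector(rho[blocks[[1]], blocks[[2]]])
  expect_gt(median(within), median(between))

  expect_error(make_abundance(5, 10, n_core = 9, seed = 1), "n_core")
  expect_error(
    make_abundance(20, 10, blocks = list(c("OTU_006", "OTU_007"),
                                         c("OTU_007", "OTU_008")),
                   n_core = 2, seed = 1),
    "disjoint")
})

test_that("metabolite tables realise the overlap plan exactly", {
  plan <- tibble::tibble(species_a = c("A", "B"), species_b = c("B", "C"),
                         shared = c(2L, 5L))
  mt <- make_metabolite_table(c("A", "B", "C", "D"), 20, plan, seed = 2)
  profiles <- lapply(c(A = "A", B = "B", C = "C", D = "D"), function(s) {
    names(mt$table)[-1][mt$table[mt$table$species_id == s, -1] == 1]
  })
  expect_length(intersect(profiles$A, profiles$B), 2)
  expect_length(intersect(profiles$B, profiles$C), 5)
  expect_length(intersect(profiles$A, profiles$C), 0)
  expect_length(intersect(profiles$A, profiles$D), 0)
  # downstream MIN edge weights equal the plan
  edges <- build_min(mt$table)
  expect_equal(edges$shared[edges$species_a == "A" & edges$species_b == "B"], 2)
  expect_equal(edges$shared[edges$species_a == "B" & edges$species_b == "C"], 5)

  disjoint <- make_metabolite_table(c("A", "B", "C"), 12, NULL, seed = 3)
  expect_equal(nrow(build_min(disjoint$table)), 0)

  expect_error(
    make_metabolite_table(c("A", "B"), 4,
                          tibble::tibble(species_a = "A", species_b = "B",
                                         shared = 5L), seed = 1),
    "exceed|infeasible")
})

test_that("all generators are deterministic given their seed", {
  expect_identical(qs_demo_fixture(seed = 5, n_species = 4, proteome_size = 10,
                                   n_neg = 20, n_otus = 12, n_samples = 10,
                                   n_core = 2),
                   qs_demo_fixture(seed = 5, n_species = 4, proteome_size = 10,
                                   n_neg = 20, n_otus = 12, n_samples = 10,
                                   n_core = 2))
})
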