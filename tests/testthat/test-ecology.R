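test_that("core community applies the three joint criteria", {
  # one dominant OTU in every sample of a 3-OTU table
  tab <- tibble::tibble(otu_id = c("big", "mid", "rare"),
                        s1 = c(0.5, 0.4995, 0.0005),
                        s2 = c(0.5, 0.4995, 0.0005),
                        s3 = c(0.5, 0.4995, 0.0005))
  expect_true("big" %in% core_community(tab))
  expect_false("rare" %in% core_community(tab))  # fails the abundance floor
  # an OTU present in only half the samples fails the prevalence screen
  tab2 <- tibble::tibble(otu_id = c("a", "b"),
                         s1 = c(1, 0), s2 = c(1, 0),
                         s3 = c(0.6, 0.4), s4 = c(0.6, 0.4))
  expect_false("b" %in% core_community(tab2))
  expect_true("a" %in% core_community(tab2))
  # read-coverage criterion: abundant+prevalent but outside the top-80%
  # set in every sample
  tab3 <- tibble::tibble(otu_id = c("x", "y", "z"),
                         s1 = c(0.85, 0.10, 0.05),
                         s2 = c(0.85, 0.10, 0.05))
  expect_equal(core_community(tab3), "x")
  expect_equal(core_community(tab3[0, ]), character())
})

test_that("the planted core is recovered exactly on the fixture", {
  fx <- std_fixture()
  expect_identical(core_community(fx$abundance), fx$abundance_truth$core)
})

test_that("Spearman edges match the rank-then-Pearson oracle", {
  # an OTU against an exact monotone transform of itself: rho = 1, retained
  x <- c(0.1, 0.3, 0.2, 0.4, 0.35, 0.05)
  tab <- tibble::tibble(otu_id = c("u", "v"))
  tab[sprintf("s%d", 1:6)] <- as.data.frame(rbind(x, exp(x)))
  ed <- spearman_edges(tab, rho_min = 0.58, p_max = 0.05)
  expect_equal(ed$rho, 1)
  expect_equal(ed$sign, "positive")
  # tie-containing toy vectors against the oracle
  a <- c(1, 2, 2, 3, 5, 4); b <- c(2, 1, 4, 4, 6, 5)
  tab2 <- tibble::tibble(otu_id = c("p", "q"))
  tab2[sprintf("s%d", 1:6)] <- as.data.frame(rbind(a, b))
  ed2 <- spearman_edges(tab2, rho_min = 0, p_max = 1)
  expect_equal(ed2$rho, oracle_spearman(a, b), tolerance = 1e-12)
  # constant rows are skipped with a warning
  tab3 <- tibble::tibble(otu_id = c("c1", "n1"),
                         s1 = c(0.5, 0.5), s2 = c(0.5, 0.5),
                         s3 = c(0.5, 0.5), s4 = c(0.5, 0.5))
  expect_warning(spearman_edges(tab3), "constant")
})

test_that("independent noise yields almost no significant edges", {
  set.seed(14)
  m <- matrix(runif(15 * 200), nrow = 15)
  m <- sweep(m, 2, colSums(m), "/")
  tab <- dplyr::bind_cols(tibble::tibble(otu_id = sprintf("o%02d", 1:15)),
                          tibble::as_tibble(as.data.frame(m)))
  ed <- spearman_edges(tab)
  expect_lt(nrow(ed) / choose(15, 2), 0.01)
})

test_that("planted blocks are recovered with high precision and recall", {
  fx <- std_fixture()
  ed <- spearman_edges(fx$abundance)
  planted <- planted_block_pairs(fx)
  pk <- paste(planted$otu_a, planted$otu_b)
  ek <- paste(ed$otu_a, ed$otu_b)
  expect_gte(mean(ek %in% pk), 0.9)  # precision
  expect_gte(mean(pk %in% ek), 0.9)  # recall
  # every retained edge satisfies both filters by direct recheck
  expect_true(all(abs(ed$rho) > 0.58 & ed$p < 0.05))
  # result invariant under OTU reordering
  ed2 <- spearman_edges(fx$abundance[rev(seq_len(nrow(fx$abundance))), ])
  expect_equal(dplyr::arrange(tibble::as_tibble(ed), otu_a, otu_b),
               dplyr::arrange(tibble::as_tibble(ed2), otu_a, otu_b))
})

test_that("Brody fits distinguish Poisson from Wigner spacings", {
  set.seed(6)
  expect_lte(fit_brody(rexp(5000))$beta, 0.1)
  wigner <- sqrt(-4 * log(1 - runif(5000)) / pi)
  expect_gte(fit_brody(wigner)$beta, 0.8)
  # the closed-form endpoints of the family
  s <- seq(0.01, 3, by = 0.01)
  expect_equal(brody_pdf(s, 0), exp(-s), tolerance = 1e-12)
  expect_equal(brody_pdf(s, 1), pi / 2 * s * exp(-pi * s^2 / 4),
               tolerance = 1e-12)
})

test_that("RMT scan finds a threshold between noise and module correlation", {
  pc <- planted_corr_matrix(seed = 5)
  res <- rmt_threshold(pc$corr)
  expect_gt(res$threshold, 0.2)
  expect_lt(res$threshold, 0.8)
  expect_true(res$converged)
  expect_true(res$threshold %in% res$scan$cutoff)
  expect_true(all(res$scan$beta[!is.na(res$scan$beta)] >= 0 &
                    res$scan$beta[!is.na(res$scan$beta)] <= 1.2))
  # monotone-safe: raising the cutoff never adds nonzero entries
  nonzero <- sapply(res$scan$cutoff, function(ct) {
    a <- pc$corr; a[abs(a) < ct] <- 0; sum(a != 0)
  })
  expect_true(all(diff(nonzero) <= 0))
  expect_error(rmt_threshold(matrix(c(1, 0.5, 0.4, 1), 2)), "symmetric")
})

test_that("metabolite network edges equal brute-force intersections", {
  set.seed(19)
  m <- matrix(rbinom(5 * 8, 1, 0.5), nrow = 5,
              dimnames = list(sprintf("sp%d", 1:5), sprintf("M%d", 1:8)))
  tab <- dplyr::bind_cols(tibble::tibble(species_id = rownames(m)),
                          tibble::as_tibble(m))
  got <- build_min(tab, min_shared = 2)
  want <- oracle_min_edges(tab, min_shared = 2)
  expect_equal(nrow(got), length(want))
  for (i in seq_len(nrow(got))) {
    expect_equal(got$shared[i],
                 want[[paste(got$species_a[i], got$species_b[i])]])
  }
  # a single shared metabolite is not an edge
  one <- tibble::tibble(species_id = c("A", "B"),
                        M1 = c(1, 1), M2 = c(1, 0), M3 = c(0, 1))
  expect_equal(nrow(build_min(one)), 0)
  expect_equal(build_min(one, min_shared = 1)$shared, 1L)
})

test_that("edge explanations reproduce the planted map and partition edges", {
  fx <- make_explained_fixture(seed = 1)
  out <- explain_edges(fx$cooc, build_min(fx$metab_table), fx$incidence)
  expect_equal(out$label, fx$expected$label)
  counts <- attr(out, "counts")
  expect_equal(sum(counts), nrow(fx$cooc))
  expect_equal(unname(counts[c("metabolite", "qs", "both", "unexplained")]),
               c(2L, 2L, 1L, 1L), ignore_attr = TRUE)
  g <- glance(out)
  expect_equal(g$total, nrow(fx$cooc))
  # unmapped OTUs get the no-data label and leave the counts
  mapping <- tibble::tibble(otu_id = setdiff(unique(c(fx$cooc$otu_a,
                                                      fx$cooc$otu_b)), "G"),
                            species_id = setdiff(unique(c(fx$cooc$otu_a,
                                                          fx$cooc$otu_b)), "G"))
  out2 <- explain_edges(fx$cooc, build_min(fx$metab_table), fx$incidence,
                        mapping = mapping)
  expect_equal(sum(out2$label == "no-data"), 1)
  expect_equal(sum(attr(out2, "counts")), nrow(fx$cooc) - 1)
})
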