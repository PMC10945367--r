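test_that("amino-acid composition is a normalised 20-vector", {
  f <- aac("AAAA")
  expect_equal(unname(f[1, "A"]), 1)
  expect_equal(sum(f), 1)
  f2 <- aac("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(f2 - 0.05) < 1e-12))
  # non-standard residues are dropped from numerator and denominator
  f3 <- aac("AAXB")
  expect_equal(unname(f3[1, "A"]), 1)
  expect_error(aac("XXBZ"), "zero standard")
  expect_error(aac(""), "non-empty")
  # property: rows sum to 1 for random sequences
  set.seed(1)
  aa <- colnames(f)
  seqs <- replicate(50, paste(sample(c(aa, "X"), sample(5:80, 1),
                                     replace = TRUE), collapse = ""))
  seqs <- seqs[vapply(seqs, function(s) grepl("[A-WY]", s), logical(1))]
  expect_true(all(abs(rowSums(aac(seqs)) - 1) < 1e-9))
})

test_that("cross-validation separates planted positives from background", {
  cv <- std_cv()
  g <- glance(cv)
  expect_gte(g$accuracy[g$classifier == "knn"], 0.9)
  expect_gte(g$accuracy[g$classifier == "rf"], 0.9)
  tr <- std_training_features()
  # the stratified dummy's expected accuracy is the sum of squared priors
  pr <- as.vector(table(tr$train$label)) / nrow(tr$train)
  expect_lt(abs(g$accuracy[g$classifier == "dummy"] - sum(pr^2)), 0.1)
  # all metrics are proportions, k folds per classifier
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  expect_true(all(table(cv$classifier) == 5))
  td <- tidy(cv)
  expect_true(all(td$conf_low <= td$mean & td$mean <= td$conf_high))
})

test_that("shuffled labels drop every classifier to the class prior", {
  tr <- std_training_features()
  set.seed(33)
  idx <- sample(nrow(tr$x), 150)
  y_perm <- sample(tr$train$label[idx])
  cv <- crossvalidate(tr$x[idx, ], y_perm, k = 5, seed = 13)
  prior <- max(table(y_perm)) / length(y_perm)
  g <- glance(cv)
  expect_true(all(abs(g$accuracy - prior) < 0.15))
})

test_that("fold assignment depends only on labels and seed", {
  tr <- std_training_features()
  idx <- seq_len(120)
  a <- crossvalidate(tr$x[idx, ], tr$train$label[idx],
                     classifiers = c("dummy", "knn", "rf"), seed = 7)
  b <- crossvalidate(tr$x[idx, ], tr$train$label[idx],
                     classifiers = c("rf", "knn", "dummy"), seed = 7)
  for (cl in c("knn", "rf", "dummy")) {
    expect_equal(dplyr::filter(tibble::as_tibble(a), classifier == cl),
                 dplyr::filter(tibble::as_tibble(b), classifier == cl))
  }
  # a class with fewer members than folds cannot be stratified
  pos <- which(tr$train$label == "positive")[1:6]
  neg <- which(tr$train$label == "negative")[1:3]
  expect_error(crossvalidate(tr$x[c(pos, neg), ],
                             tr$train$label[c(pos, neg)], k = 5,
                             classifiers = "dummy", seed = 1),
               "stratification")
})

test_that("Friedman statistic matches hand and brute-force computation", {
  # strict ordering A > B > C in every block: ranks 1, 2, 3 -> stat 8
  sc <- matrix(rep(c(3, 2, 1), 4), nrow = 4, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  ft <- friedman_test(sc)
  expect_equal(ft$statistic, 8)
  # identical scores everywhere: stat 0, p 1
  same <- matrix(1, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  ft0 <- friedman_test(same)
  expect_equal(ft0$statistic, 0)
  expect_equal(ft0$p_value, 1)
  # random 5x6 matrices against the independent rank-based oracle
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(runif(30), 5, 6, dimnames = list(NULL, letters[1:6]))
    expect_equal(friedman_test(m)$statistic, oracle_friedman(m),
                 tolerance = 1e-10)
    # and against the reference implementation (tie-free input)
    expect_equal(friedman_test(m)$statistic,
                 unname(stats::friedman.test(m)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Nemenyi selection picks dominant classifiers over the baseline", {
  # two classifiers dominate every block by a large rank margin
  mk <- function(vals, n) {
    matrix(rep(vals, n), nrow = n, byrow = TRUE,
           dimnames = list(NULL, c("a", "b", "c", "d", "dummy")))
  }
  # CD at N = 20 is ~1.36, so ranks 1-3 clear the baseline at rank 5 but
  # the rank-4 classifier (difference 1) does not
  sel2 <- nemenyi_select(mk(c(0.95, 0.90, 0.60, 0.55, 0.40), 20))
  expect_true(sel2$friedman_significant)
  expect_setequal(sel2$selected, c("a", "b", "c"))
  # with only 5 blocks the critical difference admits just the top two
  sel5 <- nemenyi_select(mk(c(0.95, 0.90, 0.60, 0.55, 0.40), 5))
  expect_setequal(sel5$selected, c("a", "b"))
  # single strong classifier
  sel1 <- nemenyi_select(mk(c(0.9, 0.6, 0.6, 0.6, 0.3), 5))
  expect_equal(sel1$selected, "a")
  # all equal: nothing selected, flagged not significant
  sel0 <- nemenyi_select(mk(rep(0.5, 5), 5))
  expect_false(sel0$friedman_significant)
  expect_length(sel0$selected, 0)
  expect_error(nemenyi_select(mk(c(1, 2, 3, 4, 5), 5), baseline = "nope"),
               "unknown baseline")
  # the baseline is never selected
  expect_false("dummy" %in% sel2$selected)
})

test_that("positive unions and partitions behave as set operations", {
  preds <- list(knn = c("a", "b"), rf = c("b", "c"), svm = c("z"))
  expect_setequal(union_positives(preds, c("knn", "rf")), c("a", "b", "c"))
  expect_setequal(union_positives(preds, "knn"), c("a", "b"))
  u <- union_positives(preds, c("knn", "rf", "svm"))
  for (s in names(preds)) expect_true(all(preds[[s]] %in% u))
  expect_warning(out <- union_positives(preds, character()), "no classifiers")
  expect_length(out, 0)
  expect_error(union_positives(preds, "xgb"), "subset")

  ann <- tibble::tibble(
    entry_id = c("a", "b", "c", "d"),
    annotation = c("hypothetical protein",
                   "LuxR family transcriptional regulator",
                   "", "DUF1234 domain-containing protein"))
  part <- partition_positives(ann$entry_id, ann)
  expect_setequal(part$uncharacterized, c("a", "c", "d"))
  expect_setequal(part$annotated, "b")
  expect_setequal(c(part$annotated, part$uncharacterized), ann$entry_id)
})

test_that("rule-based re-annotation honours priorities", {
  entries <- tibble::tibble(
    entry_id = c("e1", "e2", "e3", "e4"),
    annotation = c("helix-turn-helix domain-containing protein",
                   "OmpR/PhoB family response regulator",
                   "mystery protein of no known family",
                   "enolase"))
  lab <- rule_annotate(entries)
  expect_equal(lab$cluster,
               c("HTH-domain", "OmpR/PhoB family", "other", "no-QS-function"))
  # the OmpR rule outranks the response-regulator rule by priority
  rules <- default_cluster_rules()
  expect_lt(rules$priority[rules$label == "OmpR/PhoB family"],
            rules$priority[rules$label == "response regulator"])
  expect_error(
    rule_annotate(entries, dplyr::mutate(rules, priority = 1L)),
    "unique")
})

test_that("classifier union recovers planted positives on held-out data", {
  ev <- std_screen_eval()
  recovery <- mean(ev$eval_plants %in% ev$union)
  fpr <- mean(ev$background %in% ev$union)
  expect_gte(recovery, 0.9)
  expect_lte(fpr, 0.1)
})
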