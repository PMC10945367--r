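# The standard seeded fixture and its derived products are expensive
# (full homology search, classifier training), so they are computed once
# per test run and cached here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

std_fixture <- function() cached("fx", qs_demo_fixture(seed = 1))

std_hits <- function() {
  cached("hits", {
    fx <- std_fixture()
    expand_seeds(classify_seed(fx$seeds), fx$proteome)
  })
}

std_training_features <- function() {
  cached("train", {
    fx <- std_fixture()
    train <- rbind(fx$training$positives, fx$training$negatives)
    list(train = train, x = aac(train$sequence))
  })
}

std_cv <- function() {
  cached("cv", {
    tr <- std_training_features()
    crossvalidate(tr$x, tr$train$label, k = 5, seed = 11)
  })
}

# Held-out screening evaluation: planted homologs not used in training
# plus fresh background proteins.
std_screen_eval <- function() {
  cached("screen", {
    fx <- std_fixture()
    tr <- std_training_features()
    bg_ids <- sort(setdiff(fx$proteome$entry_id,
                           c(fx$truth$homologs$protein_id,
                             tr$train$entry_id)))[1:500]
    cand <- c(fx$eval_plants, bg_ids)
    px <- aac(fx$proteome$sequence[match(cand, fx$proteome$entry_id)])
    preds <- screen_classify(tr$x, tr$train$label, px, cand, seed = 11)
    list(preds = preds, eval_plants = fx$eval_plants, background = bg_ids,
         union = union_positives(preds, names(preds)))
  })
}

planted_block_pairs <- function(fx) {
  do.call(rbind, lapply(fx$abundance_truth$blocks, function(b) {
    p <- t(utils::combn(sort(b), 2))
    data.frame(otu_a = p[, 1], otu_b = p[, 2])
  }))
}

# Correlation matrix with planted modules over a weaker global factor,
# for threshold-scan tests: within-block correlation ~0.8, between ~0.35.
planted_corr_matrix <- function(seed = 5, n_blocks = 40, block_size = 6,
                                n_samples = 40) {
  set.seed(seed)
  n <- n_blocks * block_size
  blocks <- rep(seq_len(n_blocks), each = block_size)
  g <- matrix(rnorm(n_samples), 1)
  fb <- matrix(rnorm(n_blocks * n_samples), n_blocks)
  x <- 0.9 * g[rep(1, n), ] + 1.1 * fb[blocks, ] +
    matrix(rnorm(n * n_samples, sd = 0.7), n)
  list(corr = cor(t(x)), blocks = blocks)
}
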