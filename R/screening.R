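#' Amino-acid composition features
#'
#' Computes, for each sequence, the frequency of each of the 20 standard
#' residues: `count(a) / L`, where `L` counts standard residues only
#' (non-standard letters are ignored in both numerator and denominator).
#' Each row sums to one.
#'
#' @param sequences Character vector of amino-acid strings.
#' @return A numeric matrix with one row per sequence and 20 named columns.
#' @export
#' @examples
#' aac(c("AAAA", "ACDEFGHIKLMNPQRSTVWY"))
aac <- function(sequences) {
  if (!length(sequences) || any(!nzchar(sequences))) {
    abort("sequences must be non-empty")
  }
  x <- Biostrings::AAStringSet(toupper(sequences))
  counts <- Biostrings::alphabetFrequency(x)[, aa_standard(), drop = FALSE]
  tot <- rowSums(counts)
  if (any(tot == 0)) abort("sequence with zero standard residues")
  counts / tot
}

# stratified k-fold assignment: a deterministic function of (y, seed) only
stratified_folds <- function(y, k, seed) {
  if (k < 2) abort("`k` must be >= 2")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k) {
        abort(sprintf("stratification error: class '%s' has %d < k = %d members",
                      cl, length(idx), k))
      }
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  fold
}

binary_metrics <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(accuracy = mean(pred == truth), precision = precision,
    recall = recall, f1 = f1)
}

# Fit one classifier and predict labels for `newx`. The "dummy" baseline
# draws labels at random from the training class frequencies.
fit_predict <- function(classifier, x, y, newx, seed) {
  y <- factor(y)
  with_seed(seed, switch(
    classifier,
    dummy = {
      prior <- table(y) / length(y)
      factor(sample(names(prior), nrow(newx), replace = TRUE, prob = prior),
             levels = levels(y))
    },
    svm = predict(e1071::svm(x, y), newx),
    knn = predict(e1071::gknn(x, y, k = 5), newx, type = "class"),
    rf = predict(randomForest::randomForest(x, y), newx),
    mlp = {
      fit <- nnet::nnet(x, nnet::class.ind(y), size = 32, decay = 0.01,
                        maxit = 200, softmax = TRUE, trace = FALSE,
                        MaxNWts = 5000)
      factor(levels(y)[apply(predict(fit, newx), 1, which.max)],
             levels = levels(y))
    },
    abort(sprintf("unknown classifier '%s'", classifier))
  ))
}

#' Cross-validate a classifier ensemble on composition features
#'
#' Runs stratified k-fold cross-validation of the random baseline (dummy)
#' and the SVM, MLP ("DNN"), KNN and RF classifiers on identical folds,
#' reporting accuracy, precision, recall and F1 per fold. Fold assignment
#' is a function of the labels and the seed only, so results are
#' classifier-order invariant and deterministic.
#'
#' @param x Feature matrix (rows = examples), e.g. from [aac()].
#' @param y Label vector (two classes, both present).
#' @param classifiers Subset of `c("dummy", "svm", "mlp", "knn", "rf")`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @param positive Label treated as the positive class for
#'   precision/recall/F1; default `"positive"` if present, else the first
#'   label alphabetically.
#' @return A tibble of class `qs_cv` with columns `classifier`, `fold`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
crossvalidate <- function(x, y, classifiers = c("dummy", "svm", "mlp", "knn", "rf"),
                          k = 5, seed = 1, positive = NULL) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) abort("both classes must be present in `y`")
  positive <- positive %||%
    (if ("positive" %in% y) "positive" else sort(unique(y))[1])
  fold <- stratified_folds(y, k, seed)
  res <- purrr::map(classifiers, function(cl) {
    purrr::map(seq_len(k), function(f) {
      tr <- fold != f
      pred <- fit_predict(cl, x[tr, , drop = FALSE], y[tr],
                          x[!tr, , drop = FALSE],
                          seed = derive_seed(seed, paste(cl, f)))
      m <- binary_metrics(y[!tr], as.character(pred), positive)
      tibble(classifier = cl, fold = f, accuracy = m["accuracy"],
             precision = m["precision"], recall = m["recall"], f1 = m["f1"])
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(res))
  class(out) <- c("qs_cv", class(out))
  attr(out, "k") <- k
  attr(out, "positive") <- positive
  out
}

#' Friedman rank test over a blocks-by-classifiers score matrix
#'
#' Within each block (row; e.g. a cross-validation fold) the classifiers
#' are ranked (ties mid-ranked); the statistic is
#' `chi2 = 12 N / (k (k + 1)) * (sum(Rbar_j^2) - k (k + 1)^2 / 4)` with
#' average ranks `Rbar_j` over `N` blocks, compared to a chi-squared
#' distribution with `k - 1` degrees of freedom.
#'
#' @param scores Numeric matrix: one row per block, one named column per
#'   classifier (higher = better).
#' @return A list with `statistic`, `p_value`, `mean_ranks` (1 = best),
#'   `n_blocks`, `k`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  n <- nrow(scores)
  if (k < 3) abort("need >= 3 classifiers (columns)")
  if (n < 2) abort("need >= 2 blocks (rows)")
  # rank 1 = best within each block
  ranks <- t(apply(-scores, 1L, rank))
  rbar <- colMeans(ranks)
  stat <- 12 * n / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
  p <- if (stat <= 0) 1 else pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p, mean_ranks = rbar, n_blocks = n, k = k)
}

# Nemenyi critical-difference constants: studentized-range quantiles
# divided by sqrt(2), for k = 2..10 classifiers.
nemenyi_q <- function(k, alpha) {
  if (k < 2 || k > 10) abort("Nemenyi quantiles tabulated for k in 2..10")
  q05 <- c(1.960, 2.343, 2.569, 2.728, 2.850, 2.949, 3.031, 3.102, 3.164)
  q10 <- c(1.645, 2.052, 2.291, 2.459, 2.589, 2.693, 2.780, 2.855, 2.920)
  if (isTRUE(all.equal(alpha, 0.05))) return(q05[k - 1])
  if (isTRUE(all.equal(alpha, 0.10))) return(q10[k - 1])
  abort("`alpha` must be 0.05 or 0.10")
}

#' Post hoc Nemenyi selection of classifiers against a baseline
#'
#' After a significant Friedman test, a classifier is selected iff its
#' average rank differs from the baseline's by at least the critical
#' difference `CD = q_alpha * sqrt(k (k + 1) / (6 N))` and its mean score
#' exceeds the baseline's. If the Friedman test is not significant at
#' `alpha`, nothing is selected and the result is flagged.
#'
#' @param scores Blocks-by-classifiers score matrix (named columns).
#' @param alpha Significance level (0.05 or 0.10).
#' @param baseline Baseline classifier name (default `"dummy"`).
#' @return An object of class `qs_selection`: `friedman_stat`, `friedman_p`,
#'   `friedman_significant`, `cd`, `mean_ranks`, `pairs` (tibble of all
#'   classifier pairs with rank difference and significance), `selected`.
#' @export
nemenyi_select <- function(scores, alpha = 0.05, baseline = "dummy") {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) abort("`scores` must have classifier column names")
  if (!baseline %in% colnames(scores)) {
    abort(sprintf("unknown baseline '%s'", baseline))
  }
  fr <- friedman_test(scores)
  k <- fr$k
  n <- fr$n_blocks
  cd <- nemenyi_q(k, alpha) * sqrt(k * (k + 1) / (6 * n))
  cmb <- utils::combn(colnames(scores), 2)
  pairs <- tibble(
    classifier_a = cmb[1, ], classifier_b = cmb[2, ],
    rank_difference = abs(fr$mean_ranks[cmb[1, ]] - fr$mean_ranks[cmb[2, ]]),
    significant = .data$rank_difference >= cd
  )
  significant_fr <- fr$p_value <= alpha
  selected <- character()
  if (significant_fr) {
    means <- colMeans(scores)
    others <- setdiff(colnames(scores), baseline)
    selected <- others[
      abs(fr$mean_ranks[baseline] - fr$mean_ranks[others]) >= cd &
        means[others] > means[baseline]
    ]
  }
  structure(list(friedman_stat = fr$statistic, friedman_p = fr$p_value,
                 friedman_significant = significant_fr, cd = cd,
                 alpha = alpha, baseline = baseline,
                 mean_ranks = fr$mean_ranks, pairs = pairs,
                 selected = selected),
            class = "qs_selection")
}

#' @export
print.qs_selection <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$friedman_stat, x$friedman_p,
              if (x$friedman_significant) "" else "not ", x$alpha))
  cat(sprintf("Nemenyi critical difference = %.4g (baseline: %s)\n",
              x$cd, x$baseline))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Union of predicted positives over selected classifiers
#'
#' @param predictions Named list mapping classifier name to a character
#'   vector of predicted-positive ids.
#' @param selected Classifier names to combine (must be a subset of
#'   `names(predictions)`).
#' @return Character vector: the set union over the selected classifiers.
#' @export
union_positives <- function(predictions, selected) {
  if (!all(selected %in% names(predictions))) {
    abort("`selected` must be a subset of the prediction names")
  }
  if (!length(selected)) {
    warn("no classifiers selected; returning an empty positive set")
    return(character())
  }
  sort(unique(unlist(predictions[selected], use.names = FALSE)))
}

#' Partition positives into annotated and uncharacterized entries
#'
#' An entry is uncharacterized iff its annotation is empty/missing, or
#' mentions "uncharacterized" or "hypothetical", or consists of a bare
#' domain-of-unknown-function (DUF) identifier.
#'
#' @param ids Entry ids to partition.
#' @param annotations Tibble with `entry_id` and `annotation`.
#' @return A list with character vectors `annotated` and `uncharacterized`
#'   (exhaustive and disjoint over `ids`).
#' @export
partition_positives <- function(ids, annotations) {
  annotations <- as_tibble(annotations)
  assert_columns(annotations, c("entry_id", "annotation"), "annotations")
  ann <- annotations$annotation[match(ids, annotations$entry_id)]
  low <- tolower(trimws(ifelse(is.na(ann), "", ann)))
  unchar <- low == "" |
    stringr::str_detect(low, "uncharacterized|uncharacterised|hypothetical") |
    stringr::str_detect(low, "^duf[0-9]*( (domain|family)([- ]containing)?( protein)?)?$")
  list(annotated = ids[!unchar], uncharacterized = ids[unchar])
}

#' Default re-annotation rules for uncharacterized positives
#'
#' Priority-ordered substring rules assigning the protein-cluster labels
#' used to sort re-annotated entries: HTH-domain proteins, OmpR/PhoB family
#' regulators, histidine kinases, response regulators, transcriptional
#' activators, AgrB-like proteins, clearly non-QS housekeeping functions,
#' and a residual "other" class.
#'
#' @return A tibble with columns `label`, `patterns` (list column of
#'   substrings) and `priority` (unique integers; lower = applied first).
#' @export
default_cluster_rules <- function() {
  tibble(
    label = c("HTH-domain", "OmpR/PhoB family", "histidine kinase",
              "response regulator", "transcriptional activator",
              "AgrB-like", "no-QS-function"),
    patterns = list(
      c("helix-turn-helix", "hth"),
      c("ompr", "phob"),
      c("histidine kinase"),
      c("response regulator"),
      c("transcriptional activator"),
      c("agrb"),
      c("enolase", "ribosomal", "polymerase", "dehydrogenase", "isomerase",
        "synthetase", "elongation factor", "citrate synthase",
        "aminotransferase")
    ),
    priority = 1:7
  )
}

#' Assign protein-cluster labels by priority-ordered substring rules
#'
#' The first rule (by priority) with any matching pattern assigns its
#' label; entries matching no rule are labelled `"other"`.
#'
#' @param entries Tibble with `entry_id` and `annotation` columns.
#' @param rules Rule tibble as in [default_cluster_rules()].
#' @return A tibble with `entry_id` and `cluster` columns.
#' @export
rule_annotate <- function(entries, rules = default_cluster_rules()) {
  entries <- as_tibble(entries)
  assert_columns(entries, c("entry_id", "annotation"), "entries")
  rules <- as_tibble(rules)
  assert_columns(rules, c("label", "patterns", "priority"), "rules")
  if (anyDuplicated(rules$priority)) abort("rule priorities must be unique")
  rules <- dplyr::arrange(rules, .data$priority)
  low <- tolower(ifelse(is.na(entries$annotation), "", entries$annotation))
  label <- rep("other", nrow(entries))
  assigned <- logical(nrow(entries))
  for (i in seq_len(nrow(rules))) {
    hit <- Reduce(`|`, lapply(tolower(rules$patterns[[i]]), function(p) {
      stringr::str_detect(low, stringr::fixed(p))
    }))
    take <- hit & !assigned
    label[take] <- rules$label[i]
    assigned <- assigned | hit
  }
  tibble(entry_id = entries$entry_id, cluster = label)
}

#' Train selected classifiers and predict positives on new entries
#'
#' Fits each classifier on the labelled training features and returns, per
#' classifier, the ids of `new_ids` predicted positive. This is the
#' screening step applied to homology-expanded candidate entries.
#'
#' @param train_x,train_y Training features and labels.
#' @param new_x Feature matrix for candidate entries.
#' @param new_ids Ids for the rows of `new_x`.
#' @param classifiers Classifier names (see [crossvalidate()]).
#' @param seed Integer seed.
#' @param positive Positive-class label (default `"positive"`).
#' @return Named list mapping classifier to predicted-positive id vectors.
#' @export
screen_classify <- function(train_x, train_y, new_x, new_ids,
                            classifiers = c("svm", "mlp", "knn", "rf"),
                            seed = 1, positive = "positive") {
  train_x <- as.matrix(train_x)
  new_x <- as.matrix(new_x)
  stopifnot(nrow(new_x) == length(new_ids))
  preds <- purrr::map(classifiers, function(cl) {
    p <- fit_predict(cl, train_x, train_y, new_x,
                     seed = derive_seed(seed, paste("screen", cl)))
    new_ids[as.character(p) == positive]
  })
  setNames(preds, classifiers)
}
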