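#' Default pipeline configuration
#'
#' One configuration object drives a full run for provenance: paths derive
#' from `out`, every stochastic stage draws on `seed`, and all stage
#' parameters are explicit.
#'
#' @param out Output directory (created if needed).
#' @param seed Master integer seed.
#' @param ... Overrides for any default parameter.
#' @return A named list of class `qs_config`.
#' @export
default_config <- function(out, seed = 1, ...) {
  cfg <- list(
    out = out, seed = seed,
    n_species = 20, proteome_size = 200, mutation_rate = 0.1, n_neg = 200,
    n_otus = 60, n_samples = 200, block_strength = 0.9, n_core = 5,
    e_threshold = 1e-5, k_folds = 5, alpha = 0.05,
    rho_min = 0.58, p_max = 0.05, min_shared = 2, min_languages = 5,
    denominator = NULL,
    classifiers = c("dummy", "svm", "mlp", "knn", "rf"),
    union_over = c("svm", "mlp", "knn", "rf")
  )
  cfg <- modifyList(cfg, list(...))
  validate_config(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [default_config()].
#' @param out,seed Optional overrides of the file's values.
#' @return A validated `qs_config` list.
#' @export
read_config <- function(path, out = NULL, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(out)) cfg$out <- out
  if (!is.null(seed)) cfg$seed <- seed
  base <- default_config(out = cfg$out %||% tempfile("qsrun"),
                         seed = cfg$seed %||% 1)
  validate_config(modifyList(unclass(base), cfg))
}

validate_config <- function(cfg) {
  problems <- character()
  chk <- function(name, lower, upper = Inf) {
    v <- cfg[[name]]
    if (!is.null(v) && (!is.numeric(v) || v < lower || v > upper)) {
      problems <<- c(problems, sprintf("%s must be in [%s, %s]", name,
                                       format(lower), format(upper)))
    }
  }
  if (is.null(cfg$out)) problems <- c(problems, "out is required")
  if (is.null(cfg$seed)) problems <- c(problems, "seed is required for stochastic stages")
  chk("e_threshold", 1e-300, 10); chk("k_folds", 2); chk("alpha", 0.001, 0.5)
  chk("rho_min", 0, 1); chk("p_max", 0, 1); chk("min_shared", 1)
  chk("min_languages", 1); chk("mutation_rate", 0, 0.499)
  chk("block_strength", 0, 1)
  if (length(problems)) {
    abort(paste0("invalid config:\n", paste("-", problems, collapse = "\n")))
  }
  structure(cfg, class = c("qs_config", "list"))
}

qs_stages <- function() {
  c("simulate", "catalog", "expand", "screen", "qsnet", "phylo",
    "ecology", "compare")
}

# files each stage requires (named by the stage that produces them)
stage_requirements <- function() {
  list(
    simulate = character(),
    catalog = c(simulate = "simulate/seeds.tsv"),
    expand = c(simulate = "simulate/proteome.tsv", catalog = "catalog/catalog.tsv"),
    screen = c(simulate = "simulate/training_pos.tsv", expand = "expand/candidates.tsv"),
    qsnet = c(screen = "screen/union.tsv", expand = "expand/candidates.tsv"),
    phylo = c(catalog = "catalog/catalog.tsv"),
    ecology = c(simulate = "simulate/abundance.tsv"),
    compare = c(ecology = "ecology/cooc_edges.tsv", qsnet = "qsnet/incidence.tsv")
  )
}

check_upstream <- function(stage, cfg) {
  req <- stage_requirements()[[stage]]
  for (i in seq_along(req)) {
    if (!file.exists(file.path(cfg$out, req[i]))) {
      abort(sprintf("stage '%s' requires %s; run stage '%s' first",
                    stage, req[i], names(req)[i]))
    }
  }
}

stage_dir <- function(cfg, stage) {
  d <- file.path(cfg$out, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  path
}

update_manifest <- function(cfg, stage, files, params) {
  mf_path <- file.path(cfg$out, "manifest.json")
  manifest <- if (file.exists(mf_path)) {
    jsonlite::read_json(mf_path, simplifyVector = FALSE)
  } else list(stages = list())
  rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", cfg$out), "/?"),
             "", files)
  manifest$stages[[stage]] <- list(
    files = purrr::map2(rel, files, function(r, f) {
      list(path = r, md5 = unname(tools::md5sum(f)))
    }),
    params = params,
    package_version = as.character(utils::packageVersion("qsmine"))
  )
  write_json_out(manifest, mf_path)
  invisible(mf_path)
}

read_stage_tsv <- function(cfg, rel, ...) {
  readr::read_tsv(file.path(cfg$out, rel), show_col_types = FALSE,
                  progress = FALSE, ...)
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path, progress = FALSE)
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Orchestrates the analysis stages over a shared output directory:
#' `simulate` (synthetic inputs with ground truth), `catalog` (dedup and
#' classification of seed entries), `expand` (homology search and
#' subtraction of reported entries), `screen` (composition features,
#' cross-validated classifiers, Friedman/Nemenyi selection, union of
#' positives, rule re-annotation), `qsnet` (incidence matrix, prevalence,
#' multilingual clustering, intersections, bipartite graph export),
#' `phylo` (Poisson-corrected distances and NJ tree of the seed set),
#' `ecology` (core community, Spearman co-occurrence edges, RMT scan,
#' metabolite network) and `compare` (edge-explanation labels). Each stage
#' writes its outputs plus a manifest entry (file hashes, parameters,
#' package version); deterministic stages are byte-identical across runs
#' with the same seed.
#'
#' @param name Stage name or `"all"`.
#' @param config A `qs_config` from [default_config()] or [read_config()].
#' @return The manifest path, invisibly.
#' @export
run_stage <- function(name, config) {
  if (identical(name, "all")) {
    for (s in qs_stages()) run_stage(s, config)
    return(invisible(file.path(config$out, "manifest.json")))
  }
  if (!name %in% qs_stages()) {
    abort(sprintf("unknown stage '%s' (expected one of: %s, all)",
                  name, paste(qs_stages(), collapse = ", ")))
  }
  cfg <- validate_config(config)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  check_upstream(name, cfg)
  files <- switch(name,
    simulate = stage_simulate(cfg),
    catalog = stage_catalog(cfg),
    expand = stage_expand(cfg),
    screen = stage_screen(cfg),
    qsnet = stage_qsnet(cfg),
    phylo = stage_phylo(cfg),
    ecology = stage_ecology(cfg),
    compare = stage_compare(cfg))
  params <- cfg[setdiff(names(cfg), c("out"))]
  params$classifiers <- paste(cfg$classifiers, collapse = ",")
  params$union_over <- paste(cfg$union_over, collapse = ",")
  update_manifest(cfg, name, files, params)
}

stage_simulate <- function(cfg) {
  d <- stage_dir(cfg, "simulate")
  fx <- qs_demo_fixture(seed = cfg$seed, n_species = cfg$n_species,
                        proteome_size = cfg$proteome_size,
                        mutation_rate = cfg$mutation_rate, n_neg = cfg$n_neg,
                        n_otus = cfg$n_otus, n_samples = cfg$n_samples,
                        block_strength = cfg$block_strength,
                        n_core = cfg$n_core)
  files <- c(
    write_entries_fasta(fx$seeds, file.path(d, "seeds.fasta")),
    write_stage_tsv(fx$seeds, d, "seeds.tsv"),
    write_entries_fasta(fx$proteome, file.path(d, "proteome.fasta")),
    write_stage_tsv(fx$proteome, d, "proteome.tsv"),
    write_stage_tsv(fx$training$positives, d, "training_pos.tsv"),
    write_stage_tsv(fx$training$negatives, d, "training_neg.tsv"),
    write_stage_tsv(fx$abundance, d, "abundance.tsv"),
    write_stage_tsv(fx$metabolites, d, "metabolites.tsv"),
    write_stage_tsv(fx$otu_species_map, d, "otu_species_map.tsv"),
    write_json_out(list(
      homologs = fx$truth$homologs,
      core = fx$abundance_truth$core,
      blocks = fx$abundance_truth$blocks,
      train_plants = fx$train_plants,
      eval_plants = fx$eval_plants
    ), file.path(d, "truth.json")))
  files
}

stage_catalog <- function(cfg) {
  d <- stage_dir(cfg, "catalog")
  seeds <- read_stage_tsv(cfg, "simulate/seeds.tsv")
  catalog <- classify_seed(dedup_longest_members(seeds))
  summary <- qs_summarize(catalog)
  c(write_stage_tsv(catalog, d, "catalog.tsv"),
    write_json_out(unclass(summary), file.path(d, "summary.json")))
}

# family members share a gene name by design; catalog-level dedup keeps a
# per-entry table here (the longest-per-gene rule applies to redundant
# accession collections, exercised separately by dedup_longest())
dedup_longest_members <- function(seeds) {
  dplyr::distinct(seeds, .data$entry_id, .keep_all = TRUE)
}

stage_expand <- function(cfg) {
  d <- stage_dir(cfg, "expand")
  seeds <- read_stage_tsv(cfg, "catalog/catalog.tsv")
  proteome <- read_stage_tsv(cfg, "simulate/proteome.tsv")
  params <- search_params(e_threshold = cfg$e_threshold)
  hits <- expand_seeds(seeds, proteome, params)
  candidates <- subtract_reported(hits, seeds$entry_id)
  c(write_blast_tab(hits, file.path(d, "hits.tsv")),
    write_stage_tsv(candidates, d, "candidates.tsv"))
}

stage_screen <- function(cfg) {
  d <- stage_dir(cfg, "screen")
  pos <- read_stage_tsv(cfg, "simulate/training_pos.tsv")
  neg <- read_stage_tsv(cfg, "simulate/training_neg.tsv")
  proteome <- read_stage_tsv(cfg, "simulate/proteome.tsv")
  candidates <- read_stage_tsv(cfg, "expand/candidates.tsv")
  train <- dplyr::bind_rows(pos, neg)
  x <- aac(train$sequence)
  cv <- crossvalidate(x, train$label, classifiers = cfg$classifiers,
                      k = cfg$k_folds, seed = derive_seed(cfg$seed, "cv"))
  acc <- as_tibble(cv) |>
    dplyr::select("classifier", "fold", "accuracy") |>
    tidyr::pivot_wider(names_from = "classifier", values_from = "accuracy")
  scores <- as.matrix(acc[, cfg$classifiers])
  sel <- nemenyi_select(scores, alpha = cfg$alpha)
  cand_ids <- sort(unique(as.character(candidates$subject_id)))
  cls <- intersect(cfg$union_over, cfg$classifiers)
  preds <- if (length(cand_ids)) {
    cand_seq <- proteome$sequence[match(cand_ids, proteome$entry_id)]
    screen_classify(x, train$label, aac(cand_seq), cand_ids,
                    classifiers = cls, seed = derive_seed(cfg$seed, "screen"))
  } else {
    setNames(rep(list(character()), length(cls)), cls)
  }
  union <- union_positives(preds, names(preds))
  part <- partition_positives(
    union, proteome[, c("entry_id", "annotation")])
  clusters <- rule_annotate(
    dplyr::filter(proteome, .data$entry_id %in% union))
  c(write_stage_tsv(as_tibble(cv), d, "cv_results.tsv"),
    write_json_out(list(
      friedman_stat = sel$friedman_stat, friedman_p = sel$friedman_p,
      friedman_significant = sel$friedman_significant, cd = sel$cd,
      mean_ranks = as.list(sel$mean_ranks), selected = sel$selected),
      file.path(d, "selection.json")),
    write_json_out(preds, file.path(d, "predictions.json")),
    write_stage_tsv(tibble(entry_id = union,
                           partition = ifelse(union %in% part$annotated,
                                              "annotated", "uncharacterized")),
                    d, "union.tsv"),
    write_stage_tsv(clusters, d, "clusters.tsv"))
}

stage_qsnet <- function(cfg) {
  d <- stage_dir(cfg, "qsnet")
  union <- read_stage_tsv(cfg, "screen/union.tsv")
  candidates <- read_stage_tsv(cfg, "expand/candidates.tsv")
  extended <- candidates |>
    dplyr::filter(.data$subject_id %in% union$entry_id) |>
    dplyr::distinct(.data$subject_id, .data$species_id, .data$role,
                    .data$language)
  catalog <- tibble(entry_id = extended$subject_id,
                    species_id = extended$species_id,
                    role = extended$role, language = extended$language)
  incidence <- build_incidence(catalog)
  denom <- cfg$denominator %||% cfg$n_species
  prev <- prevalence(incidence, denominator = denom)
  multi <- multilingual_matrix(incidence, min_languages = cfg$min_languages)
  inter <- language_intersections(incidence)
  files <- c(
    write_stage_tsv(as_tibble(incidence), d, "incidence.tsv"),
    write_stage_tsv(prev, d, "prevalence.tsv"),
    write_stage_tsv(as_tibble(multi), d, "multilingual.tsv"),
    write_stage_tsv(inter, d, "intersections.tsv"),
    write_stage_tsv(incidence_edges(incidence), d, "qsnet_edges.tsv"),
    write_graphml(as_bipartite_graph(incidence), file.path(d, "qsnet.graphml")))
  if (nrow(multi) >= 2) {
    dend <- cluster_species(multi)
    files <- c(files, {
      write_newick(dend$tree, file.path(d, "dendrogram.nwk"))
      file.path(d, "dendrogram.nwk")
    })
  }
  files
}

stage_phylo <- function(cfg) {
  d <- stage_dir(cfg, "phylo")
  catalog <- read_stage_tsv(cfg, "catalog/catalog.tsv")
  lens <- nchar(catalog$sequence)
  aligned <- catalog[lens == max(lens), ]
  if (length(unique(nchar(aligned$sequence))) != 1 || nrow(aligned) < 3) {
    abort("phylo stage needs >= 3 equal-length (aligned) catalog sequences")
  }
  dm <- poisson_dist_matrix(aligned)
  tree <- neighbor_joining(dm)
  dm_tbl <- as_tibble(dm, rownames = "entry_id")
  c(write_stage_tsv(dm_tbl, d, "seed_distances.tsv"),
    {
      write_newick(tree, file.path(d, "seed_tree.nwk"))
      file.path(d, "seed_tree.nwk")
    })
}

stage_ecology <- function(cfg) {
  d <- stage_dir(cfg, "ecology")
  abundance <- read_stage_tsv(cfg, "simulate/abundance.tsv")
  metab <- read_stage_tsv(cfg, "simulate/metabolites.tsv")
  core <- core_community(abundance)
  cooc <- spearman_edges(abundance, rho_min = cfg$rho_min, p_max = cfg$p_max)
  m <- abundance_matrix(abundance)
  rho <- cor(t(m), method = "spearman")
  rmt <- rmt_threshold(rho)
  min_edges <- build_min(metab, min_shared = cfg$min_shared)
  c(write_stage_tsv(tibble(otu_id = core), d, "core.tsv"),
    write_stage_tsv(as_tibble(cooc), d, "cooc_edges.tsv"),
    write_stage_tsv(rmt$scan, d, "rmt_scan.tsv"),
    write_json_out(list(threshold = rmt$threshold, converged = rmt$converged),
                   file.path(d, "rmt.json")),
    write_stage_tsv(min_edges, d, "min_edges.tsv"))
}

stage_compare <- function(cfg) {
  d <- stage_dir(cfg, "compare")
  cooc <- read_stage_tsv(cfg, "ecology/cooc_edges.tsv")
  min_edges <- read_stage_tsv(cfg, "ecology/min_edges.tsv")
  incidence_tbl <- read_stage_tsv(cfg, "qsnet/incidence.tsv")
  mapping <- read_stage_tsv(cfg, "simulate/otu_species_map.tsv")
  incidence <- incidence_tbl
  class(incidence) <- c("qs_incidence", class(incidence))
  explained <- explain_edges(cooc, min_edges, incidence, mapping = mapping)
  counts <- attr(explained, "counts")
  c(write_stage_tsv(as_tibble(explained), d, "explained.tsv"),
    write_json_out(c(as.list(counts),
                     list(no_data = sum(explained$label == "no-data"),
                          total_labelled = sum(counts))),
                   file.path(d, "comparison.json")))
}
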