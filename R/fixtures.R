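#' Standard seeded demonstration fixture
#'
#' Builds the full synthetic study used throughout the documentation and
#' tests: seed families for the eight languages (fixed 120-residue
#' sequences, so the seed set is alignment-compatible), species proteomes
#' with planted mutated homologs (two copies per planted species-language
#' pair; the first copy is used for training, the second held out for
#' recovery evaluation), labelled training sets, a compositional abundance
#' table with planted co-occurring blocks and a planted core, a metabolite
#' table, and an OTU-to-species mapping for the block OTUs.
#'
#' @param seed Master integer seed; every component derives its own
#'   sub-seed from it.
#' @param n_species,proteome_size Proteome dimensions.
#' @param mutation_rate Per-site substitution rate of planted homologs.
#' @param n_neg Negative training examples.
#' @param n_otus,n_samples Abundance-table dimensions.
#' @param block_strength Planted co-occurrence strength.
#' @param n_core Planted core OTUs.
#' @return A list with `seeds`, `seed_truth`, `proteome`, `truth`,
#'   `train_plants`, `eval_plants`, `training`, `abundance`, `metabolites`,
#'   `otu_species_map`, and the `plant_plan` used.
#' @export
qs_demo_fixture <- function(seed = 1, n_species = 20, proteome_size = 200,
                            mutation_rate = 0.1, n_neg = 200,
                            n_otus = 60, n_samples = 200,
                            block_strength = 0.9, n_core = 5) {
  specs <- default_seed_specs(n_members = 2, min_length = 120, max_length = 120)
  fam <- make_seed_families(specs, seed = derive_seed(seed, "seeds"))
  species <- sprintf("SP_%03d", seq_len(n_species))
  langs <- setdiff(qs_languages(), "AIP")  # AIP synthases are low-confidence
  plant_plan <- with_seed(derive_seed(seed, "plan"), {
    dplyr::bind_rows(purrr::map(species, function(sp) {
      k <- sample(2:6, 1)
      tibble(species_id = sp, language = sample(langs, k),
             mutation_rate = mutation_rate, n_copies = 2L)
    }))
  })
  prot <- make_proteomes(n_species, proteome_size, plant_plan, fam$entries,
                         seed = derive_seed(seed, "proteomes"),
                         length_range = c(150L, 350L))
  train_plants <- prot$truth$homologs$protein_id[
    grepl("_01$", prot$truth$homologs$protein_id)]
  eval_plants <- setdiff(prot$truth$homologs$protein_id, train_plants)
  training <- make_training_sets(fam$entries, prot$proteome, prot$truth,
                                 n_neg = n_neg,
                                 seed = derive_seed(seed, "training"),
                                 positive_ids = train_plants)
  # block OTUs are mapped 1:1 onto species, so their number is capped by
  # both the table size and the species count; undersized chunks are
  # dropped (a block needs at least two members)
  n_block_otus <- min(15L, n_otus - n_core, n_species)
  block_ids <- sprintf("OTU_%03d", n_core + seq_len(n_block_otus))
  blocks <- unname(split(block_ids, ceiling(seq_along(block_ids) / 5)))
  blocks <- blocks[lengths(blocks) >= 2]
  block_ids <- unlist(blocks)
  abund <- make_abundance(n_otus, n_samples, blocks = blocks,
                          block_strength = block_strength, n_core = n_core,
                          seed = derive_seed(seed, "abundance"))
  otu_species_map <- tibble(otu_id = block_ids,
                            species_id = species[seq_along(block_ids)])
  # one metabolite-sharing pair per block (>= 2 shared metabolites)
  overlap_plan <- dplyr::bind_rows(purrr::map(blocks, function(b) {
    sp <- otu_species_map$species_id[match(b[1:2], otu_species_map$otu_id)]
    tibble(species_a = sp[1], species_b = sp[2], shared = 3L)
  }))
  metab <- make_metabolite_table(species, n_metabolites = 65,
                                 overlap_plan = overlap_plan,
                                 seed = derive_seed(seed, "metabolites"))
  list(seeds = fam$entries, seed_truth = fam$truth,
       proteome = prot$proteome, truth = prot$truth,
       plant_plan = plant_plan, train_plants = train_plants,
       eval_plants = eval_plants, training = training,
       abundance = abund$table, abundance_truth = abund$truth,
       metabolites = metab$table, metabolite_truth = metab$truth,
       otu_species_map = otu_species_map)
}

#' Planted edge-explanation fixture
#'
#' A small self-contained instance with a known explanation label for each
#' co-occurrence edge: metabolite overlaps and shared languages are planted
#' so that [explain_edges()] must reproduce the intended map exactly.
#'
#' @param seed Integer seed (affects only private metabolite assignment).
#' @return A list with `cooc`, `metab_table`, `incidence`, and `expected`
#'   (a tibble of edges with their planted `label`).
#' @export
make_explained_fixture <- function(seed = 1) {
  species <- LETTERS[1:8]
  # planted labels: (A,B) both, (A,C) metabolite, (B,D) qs, (C,D)
  # unexplained, (E,F) metabolite, (G,H) qs
  plan <- tibble(species_a = c("A", "A", "E"),
                 species_b = c("B", "C", "F"),
                 shared = c(3L, 2L, 4L))
  metab <- make_metabolite_table(species, n_metabolites = 20,
                                 overlap_plan = plan, seed = seed)
  catalog <- tibble(
    species_id = c("A", "B", "B", "C", "D", "G", "H"),
    gene_name = c("luxI", "luxI", "rpfF", "cqsA", "rpfF", "tnaA", "tnaA"),
    entry_id = sprintf("E%02d", 1:7),
    sequence = strrep("ACDEF", 10)
  )
  incidence <- build_incidence(classify_seed(catalog))
  cooc <- tibble(
    otu_a = c("A", "A", "B", "C", "E", "G"),
    otu_b = c("B", "C", "D", "D", "F", "H"),
    rho = c(0.9, 0.8, 0.7, 0.75, 0.85, 0.65),
    p = rep(1e-4, 6), sign = "positive"
  )
  expected <- dplyr::mutate(cooc[, c("otu_a", "otu_b")],
                            label = c("both", "metabolite", "qs",
                                      "unexplained", "metabolite", "qs"))
  list(cooc = cooc, metab_table = metab$table, incidence = incidence,
       expected = expected)
}
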