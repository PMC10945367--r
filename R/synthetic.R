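#' Generate motif-bearing quorum-sensing seed families
#'
#' Builds synthetic seed entries (the stand-in for curated synthase/receptor
#' collections) in which every member of a family carries the family motif
#' verbatim, embedded at a random position inside random background sequence.
#' The motif gives each family a distinctive amino-acid composition, which is
#' what the downstream composition-based classifiers exploit.
#'
#' @param specs A data frame with one row per family and columns
#'   `family` (unique name), `language` (one of [qs_languages()]),
#'   `role` (`"synthase"` or `"receptor"`), `motif` (8-20 standard residues),
#'   `n_members` (>= 1), `min_length`, `max_length` (residues, motif included).
#' @param seed Integer seed; output is a pure function of `specs` and `seed`.
#' @param background_freqs Optional named vector of residue frequencies for
#'   the non-motif positions; default uniform over the 20 standard residues.
#'
#' @return A list with `entries`, a tibble of protein entries
#'   (`entry_id`, `species_id`, `gene_name`, `sequence`, `annotation`,
#'   `source`, `role`, `language`), and `truth`, a tibble recording each
#'   entry's family and motif start position.
#' @export
#' @examples
#' sp <- tibble::tibble(family = "luxI", language = "AHL", role = "synthase",
#'                      motif = "WCWHMYFQWCWHMY", n_members = 3,
#'                      min_length = 80, max_length = 120)
#' fam <- make_seed_families(sp, seed = 1)
#' fam$entries
make_seed_families <- function(specs, seed, background_freqs = NULL) {
  specs <- as_tibble(specs)
  assert_columns(specs, c("family", "language", "role", "motif", "n_members",
                          "min_length", "max_length"), "specs")
  if (nrow(specs) == 0L) abort("`specs` must have at least one row")
  if (anyDuplicated(specs$family)) abort("overlapping family names in `specs`")
  bad_lang <- setdiff(specs$language, qs_languages())
  if (length(bad_lang)) {
    abort(sprintf("unknown language(s): %s", paste(bad_lang, collapse = ", ")))
  }
  if (!all(specs$role %in% c("synthase", "receptor"))) {
    abort("`role` must be 'synthase' or 'receptor'")
  }
  aa_re <- sprintf("^[%s]+$", paste(aa_standard(), collapse = ""))
  if (!all(grepl(aa_re, specs$motif))) {
    abort("motifs must use only the 20 standard residues")
  }
  if (any(nchar(specs$motif) < 8L | nchar(specs$motif) > 20L)) {
    abort("motifs must be 8-20 residues long")
  }
  if (any(specs$n_members < 1L)) abort("`n_members` must be >= 1")
  if (any(specs$min_length < nchar(specs$motif)) ||
      any(specs$max_length < specs$min_length)) {
    abort("length range must admit the motif")
  }
  # distinct families must differ in >= 50% of motif positions (checked on
  # the overlap of equal-length motif pairs)
  for (i in seq_len(nrow(specs))) {
    for (j in seq_len(i - 1L)) {
      a <- specs$motif[i]; b <- specs$motif[j]
      if (nchar(a) == nchar(b) && hamming(a, b) < ceiling(nchar(a) / 2)) {
        abort(sprintf("motifs of families '%s' and '%s' differ in < 50%% of positions",
                      specs$family[i], specs$family[j]))
      }
    }
  }

  with_seed(seed, {
    rows <- purrr::pmap(specs, function(family, language, role, motif,
                                        n_members, min_length, max_length, ...) {
      purrr::map(seq_len(n_members), function(m) {
        len <- if (min_length == max_length) min_length else
          sample(seq(min_length, max_length), 1L)
        n_bg <- len - nchar(motif)
        bg <- if (n_bg > 0) random_protein(n_bg, background_freqs) else ""
        pos <- sample.int(n_bg + 1L, 1L)  # motif start (1-based)
        seq <- paste0(substr(bg, 1L, pos - 1L), motif,
                      substr(bg, pos, n_bg))
        tibble(
          entry_id = sprintf("SEED_%s_%02d", family, m),
          species_id = NA_character_,
          gene_name = family,
          sequence = seq,
          annotation = sprintf("%s family autoinducer %s (%s system)",
                               family, role, language),
          source = "reported",
          role = role,
          language = language,
          motif_start = pos
        )
      })
    })
    entries <- dplyr::bind_rows(rows)
    truth <- dplyr::select(entries, "entry_id", family = "gene_name",
                           "language", "role", "motif_start")
    entries$motif_start <- NULL
    list(entries = entries, truth = truth)
  })
}

#' Default seed-family specifications for the eight signal languages
#'
#' One synthase family per language, with motifs skewed towards rare residues
#' (W, C, M, H, Y, F) so that planted homologs are separable from uniform
#' background in amino-acid-composition space.
#'
#' @param n_members Members per family.
#' @param min_length,max_length Sequence length range in residues. Equal
#'   values yield fixed-length (alignment-compatible) families.
#' @return A specification tibble suitable for [make_seed_families()].
#' @export
default_seed_specs <- function(n_members = 2, min_length = 120,
                               max_length = 120) {
  motifs <- c(
    AHL      = "WCWHMYFQWCWHMYFQWCWH",
    `AI-2`   = "CMYWFHQCMYWFHQCMYWFH",
    `CAI-1`  = "HYMCWFPQHYMCWFPQHYMC",
    DAR      = "FWHYCMQPFWHYCMQPFWHY",
    HAQ      = "MHCFYWPQMHCFYWPQMHCF",
    DSF      = "YFWMHCQPYFWMHCQPYFWM",
    indole   = "WMYCHFQPWMYCHFQPWMYC",
    AIP      = "CYHWFMPQCYHWFMPQCYHW"
  )
  genes <- c(AHL = "luxI", `AI-2` = "luxS", `CAI-1` = "cqsA", DAR = "darB",
             HAQ = "pqsA", DSF = "rpfF", indole = "tnaA", AIP = "agrB")
  tibble(
    family = unname(genes[qs_languages()]),
    language = qs_languages(),
    role = "synthase",
    motif = unname(motifs[qs_languages()]),
    n_members = n_members,
    min_length = min_length,
    max_length = max_length
  )
}

#' Generate species proteomes with planted mutated homologs
#'
#' Each species receives `proteome_size` background proteins drawn i.i.d.
#' from `background_freqs` plus, for every row of `plant_plan`, copies of a
#' randomly chosen seed of the requested language with independent
#' Bernoulli(`mutation_rate`) per-site substitutions (a substitution always
#' changes the residue, so the Hamming distance to the seed is exactly
#' Binomial(L, rate)-distributed).
#'
#' @param n_species Number of species (`SP_001`, ...).
#' @param proteome_size Background proteins per species.
#' @param plant_plan Data frame with columns `species_id`, `language`,
#'   `mutation_rate` (0 <= rate < 0.5) and optionally `n_copies` (default 1).
#' @param seeds Seed entries from [make_seed_families()] (`$entries`).
#' @param seed Integer seed.
#' @param background_freqs Residue frequencies for background proteins.
#' @param length_range Length range (residues) of background proteins.
#'
#' @return A list with `proteome`, a tibble of proteins (`entry_id`,
#'   `species_id`, `sequence`, `annotation`), and `truth`, whose `homologs`
#'   tibble lists every plant (`protein_id`, `species_id`, `source_entry`,
#'   `source_family`, `language`, `n_mutations`).
#' @export
make_proteomes <- function(n_species, proteome_size, plant_plan, seeds, seed,
                           background_freqs = NULL,
                           length_range = c(80L, 200L)) {
  assert_scalar_number(n_species, "n_species", lower = 1)
  assert_scalar_number(proteome_size, "proteome_size", lower = 0)
  seeds <- as_tibble(seeds)
  assert_columns(seeds, c("entry_id", "gene_name", "sequence", "language"),
                 "seeds")
  species <- sprintf("SP_%03d", seq_len(n_species))
  plant_plan <- as_tibble(plant_plan)
  if (nrow(plant_plan)) {
    assert_columns(plant_plan, c("species_id", "language", "mutation_rate"),
                   "plant_plan")
    if (!all(plant_plan$species_id %in% species)) {
      abort("`plant_plan` references unknown species")
    }
    if (!all(plant_plan$language %in% seeds$language)) {
      abort("`plant_plan` requests a language absent from `seeds`")
    }
    if (any(plant_plan$mutation_rate < 0 | plant_plan$mutation_rate >= 0.5)) {
      abort("`mutation_rate` must satisfy 0 <= rate < 0.5")
    }
    if (anyDuplicated(plant_plan[c("species_id", "language")])) {
      abort("`plant_plan` must have one row per (species, language) pair")
    }
    if (!"n_copies" %in% names(plant_plan)) plant_plan$n_copies <- 1L
  }

  aa <- aa_standard()
  mutate_seq <- function(s, rate) {
    res <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(res)) < rate)
    for (i in hit) res[i] <- sample(setdiff(aa, res[i]), 1L)
    list(seq = paste(res, collapse = ""), n_mut = length(hit))
  }

  bg_annotations <- c(
    "enolase", "ribosomal protein L1", "DNA polymerase III subunit",
    "elongation factor Tu", "citrate synthase", "triosephosphate isomerase",
    "aminotransferase class I", "glyceraldehyde-3-phosphate dehydrogenase"
  )

  with_seed(seed, {
    bg <- purrr::map(species, function(sp) {
      if (proteome_size == 0) return(NULL)
      lens <- sample(seq(length_range[1], length_range[2]),
                     proteome_size, replace = TRUE)
      tibble(
        entry_id = sprintf("%s_P%04d", sp, seq_len(proteome_size)),
        species_id = sp,
        sequence = purrr::map_chr(lens, random_protein, freqs = background_freqs),
        annotation = sample(bg_annotations, proteome_size, replace = TRUE)
      )
    })
    plants <- NULL
    truth_homologs <- tibble(protein_id = character(), species_id = character(),
                             source_entry = character(), source_family = character(),
                             language = character(), n_mutations = integer())
    if (nrow(plant_plan)) {
      plant_rows <- tidyr::uncount(plant_plan, weights = .data$n_copies,
                                   .id = "copy")
      planted <- purrr::pmap(plant_rows, function(species_id, language,
                                                  mutation_rate, copy, ...) {
        cand <- seeds[seeds$language == language, ]
        src <- cand[sample.int(nrow(cand), 1L), ]
        mut <- mutate_seq(src$sequence, mutation_rate)
        list(
          protein = tibble(
            entry_id = sprintf("%s_H%s_%02d", species_id,
                               gsub("[^A-Za-z0-9]", "", language), copy),
            species_id = species_id,
            sequence = mut$seq,
            annotation = "uncharacterized protein"
          ),
          truth = tibble(
            protein_id = sprintf("%s_H%s_%02d", species_id,
                                 gsub("[^A-Za-z0-9]", "", language), copy),
            species_id = species_id,
            source_entry = src$entry_id,
            source_family = src$gene_name,
            language = language,
            n_mutations = mut$n_mut
          )
        )
      })
      plants <- dplyr::bind_rows(purrr::map(planted, "protein"))
      truth_homologs <- dplyr::bind_rows(purrr::map(planted, "truth"))
    }
    proteome <- dplyr::bind_rows(c(bg, list(plants)))
    list(proteome = proteome,
         truth = list(homologs = truth_homologs, species = species))
  })
}

#' Assemble labelled training sets from seeds and planted homologs
#'
#' Positives are the seed entries plus (optionally a subset of) the planted
#' homologs; negatives are sampled from background proteins only. The two
#' sets are disjoint by entry id.
#'
#' @param seeds Seed entry tibble.
#' @param proteome Proteome tibble from [make_proteomes()].
#' @param truth Truth list from [make_proteomes()].
#' @param n_neg Number of negative examples to sample.
#' @param seed Integer seed.
#' @param positive_ids Optional subset of planted homolog ids to use as
#'   positives (default: all plants).
#' @return A list with tibbles `positives` and `negatives`, each carrying a
#'   `label` column.
#' @export
make_training_sets <- function(seeds, proteome, truth, n_neg, seed,
                               positive_ids = NULL) {
  assert_scalar_number(n_neg, "n_neg", lower = 1)
  plants <- truth$homologs$protein_id
  if (!is.null(positive_ids)) plants <- intersect(plants, positive_ids)
  pos <- dplyr::bind_rows(
    dplyr::select(as_tibble(seeds), "entry_id", "sequence"),
    dplyr::select(dplyr::filter(as_tibble(proteome),
                                .data$entry_id %in% plants),
                  "entry_id", "sequence")
  )
  background <- dplyr::filter(as_tibble(proteome),
                              !.data$entry_id %in% truth$homologs$protein_id)
  if (nrow(background) < n_neg) {
    abort(sprintf("insufficient background proteins: %d available, %d requested",
                  nrow(background), n_neg))
  }
  with_seed(seed, {
    neg <- background[sample.int(nrow(background), n_neg), c("entry_id", "sequence")]
    list(positives = dplyr::mutate(pos, label = "positive"),
         negatives = dplyr::mutate(neg, label = "negative"))
  })
}

#' Generate a compositional OTU abundance table with planted structure
#'
#' Emulates three kinds of taxa on a shared log-normal scale. The first
#' `n_core` OTUs are planted core taxa: dominant (`core_share` of the total
#' mass) and present in every sample, so they pass the joint
#' abundance/prevalence/read-coverage core criteria. OTUs listed in
#' `blocks` are rare-but-persistent correlated guilds: members of a block
#' share a latent Gaussian factor (loading `1.2 * block_strength` on the
#' log scale, giving within-block log-correlation around 0.7 at the 0.9
#' default), and their mean relative abundance is kept well below the core
#' abundance floor. All remaining ("filler") OTUs are prevalent background
#' taxa subject to per-sample dropout, so they fail the prevalence screen.
#' Columns are renormalised to sum to one (relative abundances).
#'
#' @param n_otus,n_samples Table dimensions.
#' @param blocks List of disjoint OTU-id character vectors (ids `OTU_###`);
#'   block members may not be core OTUs.
#' @param block_strength Correlation strength in `[0, 1]`.
#' @param n_core Number of planted core OTUs (must be <= `n_otus`).
#' @param seed Integer seed.
#' @param core_share Total relative abundance of the core set.
#' @param block_share Total relative abundance of all block OTUs together.
#' @param dropout Per-sample zero probability for filler OTUs.
#' @param sigma Log-scale residual noise standard deviation.
#' @return A list with `table` (tibble: `otu_id` plus one numeric column per
#'   sample) and `truth` (`core` ids and `blocks`).
#' @export
make_abundance <- function(n_otus, n_samples, blocks = list(),
                           block_strength = 0.9, n_core = 0, seed,
                           core_share = 0.75, block_share = 0.006,
                           dropout = 0.35, sigma = 0.7) {
  assert_scalar_number(n_otus, "n_otus", lower = 2)
  assert_scalar_number(n_samples, "n_samples", lower = 2)
  assert_scalar_number(block_strength, "block_strength", 0, 1)
  if (n_core > n_otus) abort("`n_core` must be <= `n_otus`")
  otus <- sprintf("OTU_%03d", seq_len(n_otus))
  core <- utils::head(otus, n_core)
  if (length(blocks)) {
    all_block <- unlist(blocks)
    if (anyDuplicated(all_block)) abort("`blocks` must be disjoint")
    if (!all(all_block %in% otus)) abort("`blocks` reference unknown OTU ids")
    if (any(all_block %in% core)) abort("block OTUs may not be core OTUs")
  }
  with_seed(seed, {
    block_of <- rep(NA_integer_, n_otus)
    for (b in seq_along(blocks)) block_of[match(blocks[[b]], otus)] <- b
    in_block <- !is.na(block_of)
    is_core <- otus %in% core
    filler <- !is_core & !in_block
    loading <- 1.2 * block_strength
    # baseline log-abundance by group; the block baseline subtracts the
    # factor-variance inflation so the realised mean matches its target
    mu <- rep(log(1 / n_otus), n_otus)
    if (n_core > 0 || any(in_block)) {
      share_core <- if (n_core > 0) core_share else 0
      share_block <- if (any(in_block)) block_share else 0
      share_fill <- 1 - share_core - share_block
      if (n_core > 0) mu[is_core] <- log(share_core / n_core)
      if (any(in_block)) {
        mu[in_block] <- log(share_block / sum(in_block)) - loading^2 / 2
      }
      if (any(filler)) mu[filler] <- log(share_fill / sum(filler))
    }
    fac <- matrix(stats::rnorm(max(1, length(blocks)) * n_samples),
                  ncol = n_samples)
    eps <- matrix(stats::rnorm(n_otus * n_samples, sd = sigma),
                  ncol = n_samples)
    logx <- mu + eps
    if (any(in_block) && block_strength > 0) {
      logx[in_block, ] <- logx[in_block, ] +
        loading * fac[block_of[in_block], , drop = FALSE]
    }
    x <- exp(logx)
    if (any(filler) && dropout > 0) {
      drop <- matrix(stats::runif(sum(filler) * n_samples) < dropout,
                     nrow = sum(filler))
      x[filler, ][drop] <- 0
    }
    x <- sweep(x, 2L, colSums(x), "/")
    tab <- dplyr::bind_cols(tibble(otu_id = otus),
                            as_tibble(x, .name_repair = "minimal") |>
                              setNames(sprintf("S%03d", seq_len(n_samples))))
    list(table = tab, truth = list(core = core, blocks = blocks))
  })
}

#' Generate a binary species-by-metabolite utilization table
#'
#' Each planned species pair shares exactly its planned number of dedicated
#' metabolites; remaining metabolites are assigned privately, so unplanned
#' pairs share nothing by construction.
#'
#' @param species Character vector of species ids.
#' @param n_metabolites Total number of metabolite columns.
#' @param overlap_plan Data frame with columns `species_a`, `species_b`,
#'   `shared` (counts), or `NULL` for a fully disjoint assignment.
#' @param seed Integer seed (controls private-metabolite assignment order).
#' @return A list with `table` (tibble: `species_id` plus 0/1 metabolite
#'   columns `M###`) and `truth` (the plan).
#' @export
make_metabolite_table <- function(species, n_metabolites, overlap_plan = NULL,
                                  seed = 1) {
  if (!length(species)) abort("`species` must be non-empty")
  assert_scalar_number(n_metabolites, "n_metabolites", lower = 1)
  plan <- if (is.null(overlap_plan)) {
    tibble(species_a = character(), species_b = character(), shared = integer())
  } else {
    as_tibble(overlap_plan)
  }
  if (nrow(plan)) {
    assert_columns(plan, c("species_a", "species_b", "shared"), "overlap_plan")
    if (!all(c(plan$species_a, plan$species_b) %in% species)) {
      abort("`overlap_plan` references unknown species")
    }
    if (any(plan$shared > n_metabolites)) {
      abort("`shared` cannot exceed `n_metabolites`")
    }
  }
  need <- sum(plan$shared)
  if (need > n_metabolites) {
    abort(sprintf("infeasible overlap plan: %d shared metabolites needed, %d available",
                  need, n_metabolites))
  }
  m <- matrix(0L, nrow = length(species), ncol = n_metabolites,
              dimnames = list(species, sprintf("M%03d", seq_len(n_metabolites))))
  nxt <- 1L
  for (i in seq_len(nrow(plan))) {
    cols <- seq(nxt, length.out = plan$shared[i])
    m[plan$species_a[i], cols] <- 1L
    m[plan$species_b[i], cols] <- 1L
    nxt <- nxt + plan$shared[i]
  }
  # distribute remaining metabolites privately, round-robin over species
  if (nxt <= n_metabolites) {
    rest <- seq(nxt, n_metabolites)
    owner <- with_seed(seed, {
      rep_len(sample(seq_along(species)), length(rest))
    })
    for (j in seq_along(rest)) m[owner[j], rest[j]] <- 1L
  }
  tab <- dplyr::bind_cols(tibble(species_id = species),
                          as_tibble(m, .name_repair = "minimal"))
  list(table = tab, truth = list(plan = plan))
}
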