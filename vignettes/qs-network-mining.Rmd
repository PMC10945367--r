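---
title: "Mining quorum-sensing genes and comparing community networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining quorum-sensing genes and comparing community networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(qsmine)
library(dplyr)
```

## The scientific problem

Bacteria coordinate group behaviour by secreting and detecting
autoinducer molecules — quorum sensing (QS). In engineered ecosystems such
as activated sludge, many species and many signal classes coexist, and a
community-level picture of "who can speak which chemical language" helps
explain why certain taxa co-occur. qsmine implements a complete,
testable desk-scale version of that analysis:

1. **Catalog**: curate seed synthase/receptor entries, deduplicate by gene
   name (longest sequence wins), classify them into eight signal languages
   (AHL, AI-2, CAI-1, DAR, HAQ, DSF, indole, AIP).
2. **Homology expansion**: find candidate QS proteins in species proteomes
   by Smith–Waterman local alignment gated on a Karlin–Altschul
   expectation value (`E = K m n e^{-lambda S}`, default cutoff `1e-5`).
3. **Screening**: represent candidates by amino-acid composition (AAC,
   the 20-vector of residue frequencies), cross-validate an ensemble
   (dummy baseline, SVM, MLP, KNN, RF), compare classifiers with the
   Friedman rank test and post hoc Nemenyi critical differences, and take
   the union of predicted positives.
4. **QS network**: build the bipartite species-by-language incidence from
   synthase ownership, with prevalence statistics, multilingual-species
   clustering and language-set intersection counts.
5. **Phylogeny**: Poisson-corrected distances (`d = -ln(1 - p)`) and
   Neighbor-Joining trees of entry sets.
6. **Ecology**: identify the core community of an OTU abundance table,
   build the Spearman co-occurrence network (`|rho| > 0.58`, `P < .05`),
   scan correlation cutoffs with the generalized-Brody/RMT criterion,
   build the metabolite-interchange network (MIN), and label each
   co-occurrence edge as metabolite-explained, QS-plausible, both, or
   unexplained.

Real inputs at survey scale (reference proteome databases, amplicon
surveys, metabolite registries) are external; the package therefore ships
a first-class synthetic-data generator that plants known structure at
every level, so each stage can be tested against ground truth offline.

## The synthetic study and what it does (not) emulate

`qs_demo_fixture()` assembles the standard study used in the tests and in
`scripts/acceptance.R`:

* **Seed families.** One synthase family per language, two members each,
  fixed length 120 residues, carrying a 20-residue family motif skewed
  towards rare residues (W, C, M, H, Y, F). Fixed length makes the seed
  set alignment-compatible for the phylogeny stage; the rare-residue skew
  gives positives a composition signal, mirroring the fact that real QS
  protein families differ compositionally from the proteome background.
* **Proteomes.** 20 species with 200 background proteins each
  (i.i.d. uniform over the 20 residues, lengths 150–350 — typical
  bacterial protein lengths) plus planted homologs: per species, 2–6
  languages, two copies per language, each a seed copy with independent
  per-site substitutions at rate 0.1. A substitution always changes the
  residue, so the Hamming distance to the seed is exactly
  Binomial(120, 0.1), which the tests verify. The first copy of each
  plant joins the training positives; the second is held out to measure
  recovery, emulating the reported-versus-extended split of a real
  expansion.
* **Training sets.** Positives are seeds plus training plants; 200
  negatives are sampled from background proteins only.
* **Abundance table.** 60 OTUs by 200 samples with three strata on a
  shared log-normal scale: 5 dominant planted core OTUs (75% of the mass,
  always detected), 15 rare-but-persistent OTUs in three correlated
  blocks of five (shared latent factor, within-block log-correlation
  about 0.7 at the default `block_strength = 0.9`, total mass 0.6%), and
  prevalent filler OTUs with 35% per-sample dropout. Each stratum fails a
  different core criterion on purpose: fillers fail the prevalence
  screen, block OTUs fail the mean-abundance floor, so exactly the
  planted core passes all three.
* **Metabolite table.** 65 metabolites; each planted species pair shares
  exactly its planned number (3 by default for one pair per block),
  everything else is private, so the MIN ground truth is exact.

What the generator does **not** emulate: phylogenetic signal or codon
usage in the sequences, realistic taxonomies, compositional effects of
real amplicon pipelines, or the long-tailed abundance distributions of
real sludge surveys. Passing the planted-recovery tests therefore shows
the *algorithms* are correct and well-calibrated on their stated
assumptions — not that real-data results at survey scale are reproduced.
The published survey-scale headline numbers depend on external databases
and are deliberately out of scope; the published core-species
co-occurrence edge list ships only as a documentation fixture
(`inst/extdata/asia_core_edges.tsv`).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `e_threshold` | `1e-5` | expectation-value gate for homolog expansion (the standard homology-search cutoff) |
| `K`, `lambda` | 0.041, 0.267 | Karlin–Altschul constants for BLOSUM62 with gap open 11 / extend 1 |
| `k_folds` | 5 | stratified cross-validation folds |
| `alpha` | 0.05 | Friedman/Nemenyi significance level (0.05 or 0.10 tabulated) |
| `rho_min`, `p_max` | 0.58, 0.05 | co-occurrence filter: `abs(rho) > 0.58` and two-sided `P < .05` (t approximation), no multiple-testing correction by default (a Benjamini–Hochberg switch exists) |
| `abund_frac`, `prev_frac`, `top_reads_frac`, `top_reads_sample_frac` | 0.001, 0.80, 0.80, 0.50 | the three joint core-community criteria |
| `min_shared` | 2 | minimum shared metabolites for a MIN edge |
| `min_languages` | 5 | multilingual-species filter (row sum at least 5, inclusive) |
| `beta_poisson_tol` | 0.1 | Brody beta level accepted as Poisson-like in the RMT scan |

The prevalence **denominator is always an explicit argument**, never
inferred from the matrix: the set of surveyed species is a modelling
choice (catalogued species, species with any entry, species with
proteomes) and printed percentages are only meaningful relative to a
stated denominator. "Top 0.1% mean relative abundance" is read as an
absolute fraction (mean relative abundance at least 0.001), the
interpretation under which the three criteria are complementary; a
rank-percentile reading can be obtained by passing a quantile as
`abund_frac`.

## Numerical and design choices

* **Alignment.** Full Smith–Waterman with affine gaps (a gap of length L
  costs `open + L * extend`), BLOSUM62, executed by Biostrings; no
  heuristic seeding or X-drop, which is acceptable at desk scale. Tests
  compare scores against an independently written brute-force dynamic
  program, exactly. Non-standard residues are mapped to X before
  aligning. The database length `n` is the total residue count of the
  searched proteomes; no composition-based statistics. An adapter for an
  external BLAST+ binary (`run_blastp()`, outfmt-6 parser) produces the
  same hit shape but is never required.
* **Classifiers.** The "DNN" is realised as a single-hidden-layer
  perceptron (nnet, 32 units, weight decay 0.01) — R's standard MLP; KNN
  uses k = 5 (the conventional default in the comparable Python
  machine-learning stack; the e1071 default of k = 1 is noticeably more
  variance-prone). All other hyperparameters are library defaults with a
  recorded seed. The dummy baseline predicts labels drawn from the
  training class frequencies, so its expected accuracy is the sum of
  squared class priors. Fold assignment is a deterministic function of
  the labels and seed only, making results classifier-order invariant.
* **Friedman/Nemenyi.** The Friedman statistic is computed from
  mid-ranked average ranks over blocks (cross-validation folds of the
  accuracy metric by default; the other metrics are reported alongside);
  Nemenyi critical differences use studentized-range quantiles tabulated
  for k = 2..10 at alpha 0.05/0.10. A classifier is selected only when
  the Friedman test is significant, its rank beats the baseline by at
  least the critical difference, *and* its mean metric exceeds the
  baseline's. Whether the positive union is taken over the significant
  classifiers or all four ML classifiers is exposed as a parameter
  (`selected` in `union_positives()`, `union_over` in the pipeline
  config); the pipeline default unions all four, the more inclusive
  reading, with the Nemenyi selection reported alongside.
* **Neighbor-Joining.** Saitou–Nei with Q-criterion
  `Q(i,j) = (n-2) d(i,j) - r_i - r_j`, ties broken by the smallest label
  pair, negative branch lengths clamped to zero with the count recorded
  in the `negative_branches` attribute (a display convention; the
  original values are recoverable from the distances). On additive
  matrices the path-length matrix is reproduced exactly (tested on random
  trees up to 8 taxa, and cross-checked topologically against ape's NJ).
  Gap handling in p-distances is pairwise deletion by default, with
  complete deletion as an option. Saturated pairs (p-distance 1, where
  the Poisson correction diverges) are capped at `p = 1 - 1/L` by
  `poisson_dist_matrix()`; `poisson_correct()` itself rejects `p >= 1`.
* **RMT threshold.** Eigenvalues of the thresholded correlation matrix
  are unfolded by a smoothing-spline fit to the empirical spectral CDF
  (exact degeneracies collapsed first — zero spacings carry no
  level-repulsion information), the nearest-neighbour spacing histogram
  uses 30 bins on [0, 3] mean-spacing units, and the Brody parameter is
  fitted by least squares; the threshold is the smallest cutoff with
  fitted beta at or below 0.1. These unfolding/binning constants are
  declared package defaults: the upstream method leaves them open, and
  they are exposed as arguments. If the grid is exhausted the scan
  returns the argmin-beta cutoff, flagged `converged = FALSE`.
* **Determinism.** Every generator and stochastic stage takes a seed and
  restores the caller's RNG state; sub-seeds are derived per stage so
  independent components never share an RNG stream. Two pipeline runs
  with the same seed are byte-identical, which the tests assert
  file-by-file.

## Worked example

```{r example, eval = FALSE}
fx <- qs_demo_fixture(seed = 1)
hits <- expand_seeds(classify_seed(fx$seeds), fx$proteome)
mean(fx$truth$homologs$protein_id %in% hits$subject_id)  # homolog recall

train <- rbind(fx$training$positives, fx$training$negatives)
cv <- crossvalidate(aac(train$sequence), train$label, k = 5, seed = 1)
glance(cv)
autoplot(cv)

core_community(fx$abundance)          # the five planted core OTUs
ed <- spearman_edges(fx$abundance)    # the 30 planted block edges
```

The same computations, at the same problem sizes (20 species of 200
proteins, 60 OTUs by 200 samples, 5000 simulated spacings for the Brody
endpoints), are what `scripts/acceptance.R` re-runs from scratch; the
sizes were chosen so planted-structure recovery is statistically
comfortable for the effect sizes above while the whole study remains a
desk-scale computation.

## Known limitations

* The internal aligner is exact but quadratic; survey-scale expansion
  should use the BLAST+ adapter.
* AAC is a deliberately simple feature map; classifiers that exploit
  order or domain structure are out of scope, as is structure-template
  re-annotation (treated as literature input).
* The incidence matrix encodes *potential* communication (synthase
  ownership, with production implying reception); signal intensities and
  receptor-only links are recorded but not part of the graph.
* OTU-to-species reconciliation is a user-supplied mapping and is
  acknowledged to be imperfect in real surveys; unmapped edges are
  flagged `no-data` and excluded from explanation counts rather than
  guessed.
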