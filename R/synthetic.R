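# Per-class SMILES cores and the decoration fragment pool for the drug
# grammar.  Every concatenation prefix + core + suffix is syntactically
# valid: fragments are linear chains (with simple branches/carbonyls) and
# each core uses ring-bond label 1 only.
.drug_cores <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCOC1",
                 "C1CCNCC1", "C1CCSC1")
.drug_fragments <- c("C", "CC", "CCC", "CO", "CCO", "CN", "CCN", "CS",
                     "C(C)", "CC(C)", "C(=O)", "COC", "CNC")

#' Configuration of the synthetic drug-target benchmark generator
#'
#' Defines a planted drug-class / target-family affinity structure:
#' sequences of a family share an enriched hydrophobicity group, drugs of a
#' class share a core substructure, and each (class, family) cell of the
#' affinity matrix gives the mean log10(Ki / nM), perturbed by Gaussian
#' noise.
#'
#' @param n_target_families,targets_per_family Target layout (default 4 x 5).
#' @param sequence_length_range Min/max protein length (default 200-400).
#' @param group_bias Strength of family-specific residue-group enrichment
#'   in \[0, 1\] (default 0.5).
#' @param n_drug_classes,drugs_per_class Drug layout (default 4 x 15).
#' @param affinity_matrix Mean log10(Ki nM) per (class, family); default:
#'   2 for matched class/family (tight binding, ~100 nM), 5 otherwise
#'   (~100 uM).
#' @param noise_sd SD of log10(Ki) noise (default 0.5).
#' @param replicates Ki records per pair (default 1; > 1 exercises median
#'   aggregation).
#' @param species_fraction Fraction of records annotated with a non-human
#'   species keyword (default 0; exercises [filter_species()]).
#' @param seed Master seed; the generator is a pure function of the config.
#' @return Named list of class `dti_sim_config`.
#' @export
dti_sim_config <- function(n_target_families = 4L, targets_per_family = 5L,
                           sequence_length_range = c(200L, 400L),
                           group_bias = 0.5,
                           n_drug_classes = 4L, drugs_per_class = 15L,
                           affinity_matrix = NULL, noise_sd = 0.5,
                           replicates = 1L, species_fraction = 0,
                           seed = 1L) {
  stopifnot(n_target_families >= 1L, targets_per_family >= 1L,
            n_drug_classes >= 1L, drugs_per_class >= 1L,
            length(sequence_length_range) == 2L,
            sequence_length_range[1] >= 2L,
            sequence_length_range[1] <= sequence_length_range[2],
            group_bias >= 0, group_bias <= 1, noise_sd >= 0,
            replicates >= 1L, species_fraction >= 0, species_fraction <= 1)
  if (n_drug_classes > length(.drug_cores))
    stop("at most ", length(.drug_cores), " drug classes supported",
         call. = FALSE)
  if (is.null(affinity_matrix)) {
    affinity_matrix <- matrix(5, n_drug_classes, n_target_families)
    diag_n <- min(n_drug_classes, n_target_families)
    affinity_matrix[cbind(1:diag_n, 1:diag_n)] <- 2
  }
  stopifnot(nrow(affinity_matrix) == n_drug_classes,
            ncol(affinity_matrix) == n_target_families,
            all(is.finite(affinity_matrix)))
  structure(list(n_target_families = as.integer(n_target_families),
                 targets_per_family = as.integer(targets_per_family),
                 sequence_length_range = as.integer(sequence_length_range),
                 group_bias = group_bias,
                 n_drug_classes = as.integer(n_drug_classes),
                 drugs_per_class = as.integer(drugs_per_class),
                 affinity_matrix = affinity_matrix, noise_sd = noise_sd,
                 replicates = as.integer(replicates),
                 species_fraction = species_fraction,
                 seed = as.integer(seed)),
            class = "dti_sim_config")
}

#' Generate synthetic protein sequences with family-specific composition
#'
#' Residues are drawn i.i.d.; with probability `group_bias` a residue is
#' drawn uniformly from the family's enriched hydrophobicity group,
#' otherwise uniformly from all 20 amino acids.  Family f is enriched for
#' hydrophobicity group `((f - 1) mod 3) + 1`.
#'
#' @param config A `dti_sim_config`.
#' @return Named character vector of sequences (ids `T<family>_<i>`), with
#'   attribute `family` (integer vector, same names).
#' @export
generate_proteins <- function(config) {
  stopifnot(inherits(config, "dti_sim_config"))
  hyd <- property_alphabets()$hydrophobicity
  groups <- lapply(1:3, function(g) names(hyd)[hyd == g])
  .with_seed(derive_seed(config$seed, "proteins"), {
    ids <- character(0); fam <- integer(0); seqs <- character(0)
    for (f in seq_len(config$n_target_families)) {
      pool <- groups[[((f - 1L) %% 3L) + 1L]]
      rng <- config$sequence_length_range
      for (i in seq_len(config$targets_per_family)) {
        len <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
        from_pool <- stats::runif(len) < config$group_bias
        res <- ifelse(from_pool,
                      sample(pool, len, replace = TRUE),
                      sample(AMINO_ACIDS, len, replace = TRUE))
        ids <- c(ids, sprintf("T%d_%d", f, i))
        fam <- c(fam, f)
        seqs <- c(seqs, paste(res, collapse = ""))
      }
    }
    out <- stats::setNames(seqs, ids)
    attr(out, "family") <- stats::setNames(fam, ids)
    out
  })
}

#' Generate synthetic drug SMILES with class-specific substructures
#'
#' Each class shares a core ring fragment; drugs are composed as
#' `prefix + core + suffix` from a fragment grammar that only produces
#' syntactically valid SMILES, so every record parses.
#'
#' @param config A `dti_sim_config`.
#' @return Named character vector of SMILES (ids `D<class>_<i>`), with
#'   attribute `drug_class` (integer vector).
#' @export
generate_drugs <- function(config) {
  stopifnot(inherits(config, "dti_sim_config"))
  .with_seed(derive_seed(config$seed, "drugs"), {
    ids <- character(0); cls <- integer(0); smi <- character(0)
    for (cc in seq_len(config$n_drug_classes)) {
      core <- .drug_cores[cc]
      for (i in seq_len(config$drugs_per_class)) {
        pre <- paste(sample(.drug_fragments, sample(0:2, 1L),
                            replace = TRUE), collapse = "")
        suf <- paste(sample(.drug_fragments, sample(1:3, 1L),
                            replace = TRUE), collapse = "")
        ids <- c(ids, sprintf("D%d_%d", cc, i))
        cls <- c(cls, cc)
        smi <- c(smi, paste0(pre, core, suf))
      }
    }
    out <- stats::setNames(smi, ids)
    attr(out, "drug_class") <- stats::setNames(cls, ids)
    out
  })
}

#' Generate the synthetic Ki interaction table
#'
#' For every drug x target pair, `log10(Ki_nM) = affinity_matrix[class,
#' family] + Normal(0, noise_sd)`, with optional replicate records per pair
#' and optional non-human species annotations.
#'
#' @param config A `dti_sim_config`.
#' @param proteins Output of [generate_proteins()].
#' @param drugs Output of [generate_drugs()].
#' @return Data frame: `drug_id`, `target_id`, `ki_nM`, `species`,
#'   `source`.
#' @export
generate_ki <- function(config, proteins, drugs) {
  stopifnot(inherits(config, "dti_sim_config"))
  fam <- attr(proteins, "family"); cls <- attr(drugs, "drug_class")
  if (is.null(fam) || is.null(cls))
    stop("proteins/drugs must carry family/class labels", call. = FALSE)
  grid <- expand.grid(drug_id = names(drugs), target_id = names(proteins),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[rep(seq_len(nrow(grid)), each = config$replicates), ,
               drop = FALSE]
  mu <- config$affinity_matrix[cbind(cls[grid$drug_id],
                                     fam[grid$target_id])]
  .with_seed(derive_seed(config$seed, "ki"), {
    grid$ki_nM <- 10^(mu + stats::rnorm(nrow(grid), 0, config$noise_sd))
    grid$species <- "human"
    if (config$species_fraction > 0) {
      contam <- stats::runif(nrow(grid)) < config$species_fraction
      grid$species[contam] <- sample(SPECIES_EXCLUDE, sum(contam),
                                     replace = TRUE)
    }
  })
  grid$source <- "synthetic"
  rownames(grid) <- NULL
  grid
}

#' Generate a complete synthetic benchmark bundle
#'
#' End-to-end bundle of proteins, drugs, Ki table and ground-truth labels.
#' Two presets: `"strong"` plants a matched-pair affinity signal (mean
#' log10 Ki 2 for matched class/family, 5 otherwise, noise SD 0.5; 4
#' families x 5 targets, 4 classes x 15 drugs), `"null"` uses a uniform
#' affinity matrix (mean 3.5) so labels are independent of the features.
#'
#' @param preset `"strong"` or `"null"`; ignored when `config` is given.
#' @param seed Master seed.
#' @param config Optional explicit `dti_sim_config`.
#' @param truth_threshold_nM Ki threshold defining ground-truth labels
#'   (default 10000 = 10 uM).
#' @return Object of class `dti_benchmark`: list with `proteins`, `drugs`,
#'   `interactions`, `truth` (noise-free labels per pair from the affinity
#'   matrix), `config`.
#' @export
make_benchmark <- function(preset = c("strong", "null"), seed = 1L,
                           config = NULL, truth_threshold_nM = 10000) {
  if (is.null(config)) {
    preset <- match.arg(preset)
    config <- switch(preset,
      strong = dti_sim_config(seed = seed),
      null = dti_sim_config(
        affinity_matrix = matrix(3.5, 4, 4), seed = seed))
  }
  proteins <- generate_proteins(config)
  drugs <- generate_drugs(config)
  interactions <- generate_ki(config, proteins, drugs)
  fam <- attr(proteins, "family"); cls <- attr(drugs, "drug_class")
  key <- unique(interactions[, c("drug_id", "target_id")])
  truth <- data.frame(
    drug_id = key$drug_id, target_id = key$target_id,
    true_label = as.integer(
      config$affinity_matrix[cbind(cls[key$drug_id], fam[key$target_id])] <
        log10(truth_threshold_nM)),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  structure(list(proteins = proteins, drugs = drugs,
                 interactions = interactions, truth = truth,
                 config = config),
            class = "dti_benchmark")
}

#' @export
print.dti_benchmark <- function(x, ...) {
  cat("<dti_benchmark> ", length(x$drugs), " drugs x ",
      length(x$proteins), " targets; ", nrow(x$interactions),
      " Ki records; ", sum(x$truth$true_label), " true interactions\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic benchmark to disk
#'
#' Writes FASTA (targets), .smi (drugs), interactions CSV, ground-truth
#' CSV and the generator config as YAML.
#'
#' @param bench A `dti_benchmark`.
#' @param dir Output directory.
#' @return Invisibly, the named vector of paths.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "dti_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "targets.fasta"),
             smiles = file.path(dir, "drugs.smi"),
             interactions = file.path(dir, "interactions.csv"),
             truth = file.path(dir, "truth.csv"),
             config = file.path(dir, "config.yaml"))
  write_fasta(bench$proteins, paths["fasta"])
  writeLines(paste(bench$drugs, names(bench$drugs)), paths["smiles"])
  utils::write.csv(bench$interactions, paths["interactions"],
                   row.names = FALSE)
  utils::write.csv(bench$truth, paths["truth"], row.names = FALSE)
  cfg <- unclass(bench$config)
  cfg$affinity_matrix <- apply(cfg$affinity_matrix, 1L, as.numeric,
                               simplify = FALSE)
  write_run_config(cfg, paths["config"])
  invisible(paths)
}
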