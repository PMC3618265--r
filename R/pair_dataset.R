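#' Default species-exclusion keywords
#'
#' Non-human species annotations removed by [filter_species()]; matching is
#' case-insensitive substring.
#' @export
SPECIES_EXCLUDE <- c("rat", "rabbit", "bovine", "sheep", "calf", "pig",
                     "mouse", "guinea pig", "dog", "undefined")

#' Filter interaction records to human-specific pairs
#'
#' Removes records whose free-text species annotation contains (case
#' insensitively) any of the exclusion keywords.  Records with a missing or
#' empty species field are kept.
#'
#' @param records Data frame with at least `drug_id`, `target_id`, `ki_nM`;
#'   optional `species`.
#' @param exclude Character vector of keywords (default [SPECIES_EXCLUDE]).
#' @param verbose Log each exclusion with `message()`.
#' @return The filtered data frame, with attribute `n_excluded`.
#' @export
filter_species <- function(records, exclude = SPECIES_EXCLUDE,
                           verbose = FALSE) {
  if (is.null(records$species)) {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  sp <- tolower(ifelse(is.na(records$species), "", records$species))
  hit <- rep(FALSE, nrow(records))
  for (kw in tolower(exclude)) hit <- hit | grepl(kw, sp, fixed = TRUE)
  if (verbose && any(hit))
    message(sum(hit), " record(s) excluded by species filter: ",
            paste(unique(records$species[hit]), collapse = ", "))
  out <- records[!hit, , drop = FALSE]
  attr(out, "n_excluded") <- sum(hit)
  out
}

#' Aggregate replicate Ki measurements by the median
#'
#' Databases often report several Ki values for one drug-target pair; the
#' median is used as the reference Ki (mean of the two central values for
#' even counts).
#'
#' @param records Data frame with `drug_id`, `target_id`, `ki_nM` (> 0).
#' @return Data frame with one row per (drug_id, target_id) and columns
#'   `drug_id`, `target_id`, `median_ki_nM`, `n_records`.
#' @export
aggregate_ki <- function(records) {
  need <- c("drug_id", "target_id", "ki_nM")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L)
    stop("no interaction records to aggregate", call. = FALSE)
  if (any(!is.finite(records$ki_nM)) || any(records$ki_nM <= 0))
    stop("ki_nM must be positive and finite", call. = FALSE)
  key <- interaction(records$drug_id, records$target_id, drop = TRUE,
                     sep = "\r")
  med <- tapply(records$ki_nM, key, stats::median)
  cnt <- tapply(records$ki_nM, key, length)
  parts <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(
    drug_id = vapply(parts, `[[`, "", 1L),
    target_id = vapply(parts, `[[`, "", 2L),
    median_ki_nM = as.numeric(med),
    n_records = as.integer(cnt),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$drug_id, out$target_id), , drop = FALSE]
}

#' Label drug-target pairs by a Ki threshold
#'
#' A pair is a positive interaction when its (median) Ki is strictly below
#' the threshold; pairs with Ki greater than or equal to the threshold are
#' negatives.  The conventional threshold is 10 uM = 10,000 nM.
#'
#' @param pairs Data frame with `median_ki_nM` (e.g. from [aggregate_ki()]).
#' @param threshold_nM Positive Ki threshold in nM (default 10000).
#' @return `pairs` with an added integer `label` column (1 = interaction).
#' @export
label_pairs <- function(pairs, threshold_nM = 10000) {
  if (!is.numeric(threshold_nM) || length(threshold_nM) != 1L ||
      !is.finite(threshold_nM) || threshold_nM <= 0)
    stop("threshold_nM must be a positive number", call. = FALSE)
  if (is.null(pairs$median_ki_nM))
    stop("pairs must carry a median_ki_nM column", call. = FALSE)
  pairs$label <- as.integer(pairs$median_ki_nM < threshold_nM)
  pairs
}

#' Concatenate drug and protein features into one pair vector
#'
#' Drug fingerprint bits first, protein descriptors second; with the default
#' 1024-bit fingerprint and 167 protein descriptors the result has 1191
#' dimensions.
#'
#' @param fp Fingerprint bit vector (drug block).
#' @param pf Protein descriptor vector (protein block).
#' @return Numeric vector of `length(fp) + length(pf)` values.
#' @export
assemble_features <- function(fp, pf) {
  if (is.null(fp) || is.null(pf))
    stop("both drug and protein features are required", call. = FALSE)
  c(as.numeric(fp), as.numeric(pf))
}

#' Build the labelled pair feature dataset
#'
#' End-to-end assembly: species filtering, median Ki aggregation, threshold
#' labelling, and concatenation of per-drug fingerprints with per-target
#' protein descriptors into the pair feature matrix.
#'
#' @param interactions Data frame of Ki records (`drug_id`, `target_id`,
#'   `ki_nM`, optional `species`).
#' @param fingerprints Integer matrix from [fingerprint_matrix()], rownames
#'   = drug ids.
#' @param protein_feats Numeric matrix from [protein_feature_matrix()],
#'   rownames = target ids.
#' @param threshold_nM Ki labelling threshold in nM (default 10000 = 10 uM).
#' @param species_exclude Keywords for [filter_species()]; `NULL` disables
#'   the filter.
#' @return List of class `pair_dataset`: `x` (pair feature matrix, one row
#'   per pair), `y` (integer labels), `pairs` (the labelled pair table).
#' @export
build_pair_dataset <- function(interactions, fingerprints, protein_feats,
                               threshold_nM = 10000,
                               species_exclude = SPECIES_EXCLUDE) {
  if (!is.null(species_exclude))
    interactions <- filter_species(interactions, species_exclude)
  pairs <- label_pairs(aggregate_ki(interactions), threshold_nM)
  miss_d <- setdiff(unique(pairs$drug_id), rownames(fingerprints))
  if (length(miss_d))
    stop("no fingerprint for drug id(s): ",
         paste(utils::head(miss_d, 5L), collapse = ", "), call. = FALSE)
  miss_t <- setdiff(unique(pairs$target_id), rownames(protein_feats))
  if (length(miss_t))
    stop("no protein features for target id(s): ",
         paste(utils::head(miss_t, 5L), collapse = ", "), call. = FALSE)
  x <- cbind(fingerprints[pairs$drug_id, , drop = FALSE],
             protein_feats[pairs$target_id, , drop = FALSE])
  rownames(x) <- paste(pairs$drug_id, pairs$target_id, sep = "|")
  structure(list(x = x, y = pairs$label, pairs = pairs,
                 threshold_nM = threshold_nM),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat("<pair_dataset> ", nrow(x$x), " pairs x ", ncol(x$x), " features; ",
      sum(x$y == 1L), " positive / ", sum(x$y == 0L),
      " negative at Ki < ", x$threshold_nM, " nM\n", sep = "")
  invisible(x)
}
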