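#' Screen all drug x target combinations
#'
#' Predicts the interaction probability of every (drug, target) cell by
#' assembling the pair feature vector (drug fingerprint block, then protein
#' descriptor block) and applying the fitted model; identical to one-at-a-time
#' pairwise prediction.
#'
#' @param model A fitted `dti_rf` (or any model with a `predict` method
#'   returning probabilities).
#' @param fingerprints Fingerprint matrix (rownames = drug ids).
#' @param protein_feats Protein descriptor matrix (rownames = target ids).
#' @param chunk_rows Pairs predicted per block (memory control).
#' @return Numeric matrix of probabilities, drugs x targets.
#' @export
screen_matrix <- function(model, fingerprints, protein_feats,
                          chunk_rows = 20000L) {
  drugs <- rownames(fingerprints); targets <- rownames(protein_feats)
  if (is.null(drugs) || is.null(targets))
    stop("fingerprints and protein_feats need rownames", call. = FALSE)
  nd <- length(drugs); nt <- length(targets)
  out <- matrix(NA_real_, nd, nt, dimnames = list(drugs, targets))
  cells <- expand.grid(d = seq_len(nd), t = seq_len(nt),
                       KEEP.OUT.ATTRS = FALSE)
  for (start in seq(1L, nrow(cells), by = chunk_rows)) {
    idx <- start:min(start + chunk_rows - 1L, nrow(cells))
    xx <- cbind(fingerprints[cells$d[idx], , drop = FALSE],
                protein_feats[cells$t[idx], , drop = FALSE])
    out[cbind(cells$d[idx], cells$t[idx])] <- stats::predict(model, xx)
  }
  out
}

#' Calibrate probability cutoffs to target false-discovery rates
#'
#' From pooled cross-validation predictions, finds for each requested FDR
#' level the smallest probability threshold whose empirical
#' FDR = FP/(FP+TP) does not exceed the level (the smallest qualifying
#' threshold maximizes recall).  All unique scores are enumerated.
#'
#' @param scores Pooled out-of-fold probabilities (or a `cv_result`).
#' @param labels Binary labels (ignored when `scores` is a `cv_result`).
#' @param fdr_levels Target FDR levels (default `c(0.003, 0.005, 0.01,
#'   0.05)`).
#' @return Data frame: `fdr`, `recall`, `threshold`, `n_predicted`,
#'   `ratio` (predicted positives / all pairs), `attainable`.  Levels no
#'   threshold can satisfy get `attainable = FALSE` and NA statistics.
#' @export
fdr_calibration <- function(scores, labels = NULL,
                            fdr_levels = c(0.003, 0.005, 0.01, 0.05)) {
  if (inherits(scores, "cv_result")) {
    labels <- scores$y
    scores <- scores$prob
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (any(fdr_levels < 0 | fdr_levels > 1))
    stop("FDR levels must lie in [0, 1]", call. = FALSE)
  n <- length(scores)
  P <- sum(labels == 1L)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), 0L)
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), 0L)
  fdr <- fp / (fp + tp)
  rows <- lapply(fdr_levels, function(lev) {
    ok <- which(fdr <= lev)
    if (!length(ok))
      return(data.frame(fdr = lev, recall = NA_real_,
                        threshold = NA_real_, n_predicted = NA_integer_,
                        ratio = NA_real_, attainable = FALSE))
    i <- max(ok)  # smallest qualifying threshold
    data.frame(fdr = lev, recall = tp[i] / P, threshold = thr[i],
               n_predicted = tp[i] + fp[i],
               ratio = (tp[i] + fp[i]) / n, attainable = TRUE)
  })
  do.call(rbind, rows)
}

#' Extract high-confidence edges from a screening matrix
#'
#' All cells with probability at or above the cutoff, sorted by descending
#' probability.  Pairs present in the training set are flagged
#' (`is_novel = FALSE`) and, with `novel_only = TRUE`, removed.
#'
#' @param matrix Screening matrix from [screen_matrix()].
#' @param cutoff Probability cutoff in \[0, 1\] (e.g. a calibrated
#'   threshold from [fdr_calibration()]).
#' @param training_pairs Optional data frame with `drug_id`, `target_id`
#'   of pairs used in training.
#' @param novel_only Drop training pairs (default `TRUE` when
#'   `training_pairs` given).
#' @return Data frame: `drug_id`, `target_id`, `probability`, `is_novel`.
#' @export
novel_edges <- function(matrix, cutoff, training_pairs = NULL,
                        novel_only = !is.null(training_pairs)) {
  if (cutoff < 0 || cutoff > 1)
    stop("cutoff must lie in [0, 1]", call. = FALSE)
  hit <- which(matrix >= cutoff, arr.ind = TRUE)
  edges <- data.frame(
    drug_id = rownames(matrix)[hit[, 1]],
    target_id = colnames(matrix)[hit[, 2]],
    probability = matrix[hit],
    stringsAsFactors = FALSE)
  edges$is_novel <- rep(TRUE, nrow(edges))
  if (!is.null(training_pairs) && nrow(edges)) {
    key <- paste(edges$drug_id, edges$target_id, sep = "\r")
    tkey <- paste(training_pairs$drug_id, training_pairs$target_id,
                  sep = "\r")
    edges$is_novel <- !key %in% tkey
    if (novel_only) edges <- edges[edges$is_novel, , drop = FALSE]
  }
  edges <- edges[order(-edges$probability, edges$drug_id,
                       edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Export the predicted interaction network
#'
#' Writes the bipartite drug-target network as a SIF edge file, a GraphML
#' graph with a `type` node attribute (drug/target), a CSV edge table with
#' probabilities, and a node degree summary CSV.
#'
#' @param edges Edge data frame from [novel_edges()] (may be empty).
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default "network").
#' @return Invisibly, the named vector of written paths.
#' @export
export_network <- function(edges, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sif = file.path(dir, paste0(prefix, ".sif")),
             graphml = file.path(dir, paste0(prefix, ".graphml")),
             edges = file.path(dir, paste0(prefix, "_edges.csv")),
             degrees = file.path(dir, paste0(prefix, "_degrees.csv")))
  writeLines(if (nrow(edges))
    paste(edges$drug_id, "interacts", edges$target_id, sep = "\t")
    else character(0), paths["sif"])
  utils::write.csv(edges, paths["edges"], row.names = FALSE)
  drugs <- unique(edges$drug_id); targets <- unique(edges$target_id)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(drugs) + length(targets),
                            name = c(drugs, targets),
                            type = c(rep("drug", length(drugs)),
                                     rep("target", length(targets))))
  if (nrow(edges))
    g <- igraph::add_edges(
      g, rbind(match(edges$drug_id, c(drugs, targets)),
               match(edges$target_id, c(drugs, targets))),
      probability = edges$probability)
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  deg <- data.frame(node = c(drugs, targets),
                    type = c(rep("drug", length(drugs)),
                             rep("target", length(targets))),
                    degree = igraph::degree(g),
                    stringsAsFactors = FALSE)
  deg <- deg[order(-deg$degree, deg$node), , drop = FALSE]
  utils::write.csv(deg, paths["degrees"], row.names = FALSE)
  invisible(paths)
}
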