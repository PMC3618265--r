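# The published hand-worked CTD example: a 20-residue peptide whose
# hydrophobicity group encoding and all 21 descriptors are known.
worked <- list(
  sequence = "MTEITAAMVKELRESTGAGA",
  encoding = "32132223311311222222",
  C = c(25.00, 50.00, 25.00),
  T = c(10.53, 21.05, 15.79),           # 2-decimal rounded
  D1 = c(15.0, 15.0, 50.0, 55.0, 70.0),
  D2 = c(10.0, 25.0, 75.0, 85.0, 100.0),
  D3 = c(5.0, 5.0, 20.0, 40.0, 60.0)
)

# Independent single-pass counting oracle for C/T/D on an encoded string.
# Deliberately naive: explicit loops, no shared code with the package.
naive_ctd <- function(symbols) {
  n <- length(symbols)
  cnt <- c(0, 0, 0)
  for (s in symbols) cnt[s] <- cnt[s] + 1
  C <- cnt * 100 / n
  tr <- c(0, 0, 0)  # 12, 13, 23
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      a <- symbols[i]; b <- symbols[i + 1]
      if (a != b) {
        pair <- sort(c(a, b))
        if (all(pair == c(1, 2))) tr[1] <- tr[1] + 1
        if (all(pair == c(1, 3))) tr[2] <- tr[2] + 1
        if (all(pair == c(2, 3))) tr[3] <- tr[3] + 1
      }
    }
  }
  T <- tr * 100 / (n - 1)
  D <- numeric(15)
  for (g in 1:3) {
    pos <- c()
    for (i in seq_len(n)) if (symbols[i] == g) pos <- c(pos, i)
    ng <- length(pos)
    if (ng > 0) {
      ks <- c(1,
              max(1, floor(0.25 * ng)),
              max(1, floor(0.50 * ng)),
              max(1, floor(0.75 * ng)),
              ng)
      for (j in 1:5) D[(g - 1) * 5 + j] <- pos[ks[j]] * 100 / n
    }
  }
  list(C = C, T = T, D = D)
}

# Brute-force auROC: fraction of (positive, negative) score pairs that are
# concordant, ties counted one half.
brute_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Exhaustive FDR calibration: try every unique score as cutoff, keep those
# with FDR <= level, return the smallest qualifying cutoff and its recall.
brute_fdr <- function(scores, labels, level) {
  best <- NULL
  for (t in sort(unique(scores), decreasing = TRUE)) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    if (fp / (fp + tp) <= level)
      best <- list(threshold = t, recall = tp / sum(labels == 1),
                   n_predicted = tp + fp)
  }
  best
}

# Small planted-signal classification problem: label is an indicator of a
# single feature, the rest is noise.
planted_data <- function(n = 500, p = 20, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", seq_len(p))
  y <- as.integer(x[, 1] > 0)
  list(x = x, y = y)
}

# Tiny benchmark config keeping RF-based unit tests fast.
small_config <- function(seed = 1, ...) {
  dti_sim_config(n_target_families = 2, targets_per_family = 3,
                 sequence_length_range = c(60, 100),
                 n_drug_classes = 2, drugs_per_class = 6, seed = seed, ...)
}
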