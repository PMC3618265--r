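.check_sequence <- function(residues, strip = FALSE) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("sequence must be a single non-empty string", call. = FALSE)
  residues <- toupper(residues)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AMINO_ACIDS)
  if (length(bad)) {
    if (strip) {
      chars <- chars[-bad]
      if (!length(chars))
        stop("sequence contains no standard residues after stripping",
             call. = FALSE)
      attr(chars, "n_stripped") <- length(bad)
    } else {
      stop(sprintf("non-standard residue '%s' at position %d",
                   chars[bad[1]], bad[1]), call. = FALSE)
    }
  }
  chars
}

#' Encode a protein sequence over a three-group property alphabet
#'
#' Replaces every residue by its property-group index ('1', '2' or '3'),
#' e.g. MTEITAAMVKELRESTGAGA under hydrophobicity becomes
#' 32132223311311222222.
#'
#' @param residues Protein sequence (single string of one-letter codes).
#' @param alphabet A named integer vector mapping amino acids to groups 1-3,
#'   one element of [property_alphabets()], or the name of a property.
#' @return Object of class `group_encoding`: list with `symbols` (integer
#'   vector over 1:3), `counts` (n1, n2, n3) and `n` (sequence length).
#' @examples
#' enc <- encode_property("MTEITAAMVKELRESTGAGA", "hydrophobicity")
#' paste(enc$symbols, collapse = "")
#' @export
encode_property <- function(residues, alphabet) {
  if (is.character(alphabet) && length(alphabet) == 1L) {
    ab <- property_alphabets()
    if (!alphabet %in% names(ab))
      stop("unknown property '", alphabet, "'", call. = FALSE)
    alphabet <- ab[[alphabet]]
  }
  chars <- .check_sequence(residues)
  sym <- unname(alphabet[chars])
  if (anyNA(sym)) {
    i <- which(is.na(sym))[1]
    stop(sprintf("residue '%s' at position %d is not mapped by the alphabet",
                 chars[i], i), call. = FALSE)
  }
  counts <- tabulate(sym, nbins = 3L)
  structure(list(symbols = as.integer(sym),
                 counts = counts, n = length(sym)),
            class = "group_encoding")
}

.as_encoding <- function(enc) {
  if (inherits(enc, "group_encoding")) return(enc)
  if (is.character(enc) && length(enc) == 1L) {
    sym <- as.integer(strsplit(enc, "", fixed = TRUE)[[1]])
    if (anyNA(sym) || any(sym < 1L | sym > 3L))
      stop("encoding string must contain only '1', '2', '3'", call. = FALSE)
    return(structure(list(symbols = sym, counts = tabulate(sym, 3L),
                          n = length(sym)), class = "group_encoding"))
  }
  stop("expected a group_encoding or an encoding string", call. = FALSE)
}

#' Composition descriptors (C) of a group encoding
#'
#' Percentage of positions in each of the three property groups:
#' `n_g * 100 / N`.
#'
#' @param enc A `group_encoding` from [encode_property()], or an encoding
#'   string such as "32132223311311222222".
#' @return Numeric vector of 3 percentages (sums to 100).
#' @export
ctd_composition <- function(enc) {
  enc <- .as_encoding(enc)
  if (enc$n < 1L) stop("empty encoding", call. = FALSE)
  out <- enc$counts * 100 / enc$n
  names(out) <- paste0("C.", 1:3)
  out
}

#' Transition descriptors (T) of a group encoding
#'
#' Percent frequency with which a residue of one group is adjacent to a
#' residue of a different group: for the unordered pair \{x,y\},
#' `T_xy = (# adjacent xy or yx) * 100 / (N - 1)`.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector (T.1-2, T.1-3, T.2-3).
#' @export
ctd_transition <- function(enc) {
  enc <- .as_encoding(enc)
  if (enc$n < 2L)
    stop("transition requires a sequence of length >= 2", call. = FALSE)
  a <- enc$symbols[-enc$n]
  b <- enc$symbols[-1L]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- c(sum(lo == 1L & hi == 2L),
           sum(lo == 1L & hi == 3L),
           sum(lo == 2L & hi == 3L)) * 100 / (enc$n - 1L)
  names(out) <- c("T.1-2", "T.1-3", "T.2-3")
  out
}

#' Distribution descriptors (D) of a group encoding
#'
#' For each group, the sequence positions (as percent of chain length) of
#' the first, 25%, 50%, 75% and 100% occurrences of that group.  The k-th
#' occurrence used for fraction f is `max(1, floor(f * n_g))` (k = 1 for
#' "first"); a group absent from the sequence contributes five zeros.
#'
#' @inheritParams ctd_composition
#' @return Numeric vector of 15 percentages, groups 1..3 by 5 fractions.
#' @export
ctd_distribution <- function(enc) {
  enc <- .as_encoding(enc)
  if (enc$n < 1L) stop("empty encoding", call. = FALSE)
  fr <- c(0, 0.25, 0.50, 0.75, 1)
  out <- numeric(15)
  for (g in 1:3) {
    pos <- which(enc$symbols == g)
    ng <- length(pos)
    if (ng > 0L) {
      k <- pmax(1L, floor(fr * ng))
      out[(g - 1L) * 5L + 1:5] <- pos[k] * 100 / enc$n
    }
  }
  names(out) <- paste0("D.", rep(1:3, each = 5), ".",
                       rep(c("first", "25", "50", "75", "100"), 3))
  out
}

#' The 21 CTD descriptors of one property
#'
#' @inheritParams encode_property
#' @return Numeric vector of 21 values: C (3), T (3), D (15).
#' @export
ctd_property <- function(residues, alphabet) {
  enc <- encode_property(residues, alphabet)
  c(ctd_composition(enc), ctd_transition(enc), ctd_distribution(enc))
}

#' The 147 CTD descriptors over all seven property alphabets
#'
#' @param residues Protein sequence (single string).
#' @return Named numeric vector of length 147 (7 properties x 21 values),
#'   properties in the fixed order of [property_names()].
#' @export
ctd_vector <- function(residues) {
  ab <- property_alphabets()
  out <- unlist(lapply(names(ab), function(p) {
    v <- ctd_property(residues, ab[[p]])
    names(v) <- paste0(p, ".", names(v))
    v
  }))
  stopifnot(length(out) == 147L)
  out
}

#' Amino acid composition (AAC) descriptors
#'
#' Percentage of each of the 20 standard amino acids in the sequence,
#' alphabetical one-letter order; sums to 100.
#'
#' @param residues Protein sequence (single string).
#' @return Named numeric vector of length 20.
#' @export
aac_vector <- function(residues) {
  chars <- .check_sequence(residues)
  counts <- table(factor(chars, levels = AMINO_ACIDS))
  out <- as.numeric(counts) * 100 / length(chars)
  names(out) <- paste0("AAC.", AMINO_ACIDS)
  out
}

#' Index map of the 167-descriptor protein feature vector
#'
#' Named list of integer index slices, one per property's 21-column CTD
#' block plus the 20-column AAC block; slices are disjoint and cover 1:167.
#' Used by [ablate_property()] for per-property omission studies.
#' @return Named list of 8 integer vectors.
#' @export
protein_index_map <- function() {
  props <- property_names()
  m <- lapply(seq_along(props), function(i) ((i - 1L) * 21L + 1L):(i * 21L))
  names(m) <- props
  m$AAC <- 148:167
  m
}

#' Full 167-descriptor protein feature vector
#'
#' Concatenates the 147 CTD descriptors (7 properties x 21) with the 20
#' amino-acid composition descriptors.
#'
#' @param residues Protein sequence (single string of one-letter codes).
#' @param on_nonstandard Policy for residues outside the 20 standard codes:
#'   `"reject"` (default) stops with the offending character and position;
#'   `"strip"` removes them before featurization.
#' @return Named numeric vector of length 167, with attribute `index_map`
#'   (see [protein_index_map()]).
#' @examples
#' length(protein_features("MTEITAAMVKELRESTGAGA"))  # 167
#' @export
protein_features <- function(residues, on_nonstandard = c("reject", "strip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (on_nonstandard == "strip") {
    chars <- .check_sequence(residues, strip = TRUE)
    residues <- paste(chars, collapse = "")
  }
  out <- c(ctd_vector(residues), aac_vector(residues))
  stopifnot(length(out) == 167L)
  attr(out, "index_map") <- protein_index_map()
  out
}

#' Featurize many protein sequences into a matrix
#'
#' @param sequences Named character vector of sequences (names = ids).
#' @param on_nonstandard Passed to [protein_features()].
#' @return Numeric matrix, one row per sequence, 167 named columns.
#' @export
protein_feature_matrix <- function(sequences,
                                   on_nonstandard = c("reject", "strip")) {
  on_nonstandard <- match.arg(on_nonstandard)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names", call. = FALSE)
  rows <- lapply(sequences, protein_features, on_nonstandard = on_nonstandard)
  out <- do.call(rbind, lapply(rows, as.numeric))
  colnames(out) <- names(rows[[1]])
  rownames(out) <- names(sequences)
  out
}
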