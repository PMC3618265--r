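#' Parse a SMILES string into a molecular graph
#'
#' Parses with OpenBabel (via ChemmineR/ChemmineOB) and extracts the heavy-atom
#' connectivity used by [path_fingerprint()].  Aromatic rings are re-perceived
#' on the parsed structure so that downstream path typing does not depend on
#' the kekulized bond orders OpenBabel assigns (which vary with input atom
#' order).
#'
#' @param smiles A single SMILES string.
#' @param id Optional record id (defaults to the SMILES itself).
#' @return Object of class `drug_record`: list with `id`, `smiles`,
#'   `atoms` (element symbols), `bonds` (matrix: from, to, order) and
#'   `aromatic` (logical per atom).
#' @examples
#' \donttest{
#' mol <- parse_molecule("CCO")
#' mol$atoms
#' }
#' @export
parse_molecule <- function(smiles, id = smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("smiles must be a single non-empty string", call. = FALSE)
  sdf <- suppressWarnings(try(ChemmineR::smiles2sdf(smiles), silent = TRUE))
  ok <- !inherits(sdf, "try-error") && length(sdf) == 1L
  if (ok) {
    one <- sdf[[1]]
    ab <- ChemmineR::atomblock(one)
    ok <- is.matrix(ab) && nrow(ab) >= 1L && !anyNA(ab)
  }
  if (!ok)
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  atoms <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(one)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L)
  if (ncol(bb) >= 3L) {
    bonds <- matrix(as.integer(bb[, 1:3, drop = FALSE]), ncol = 3L)
  } else {
    bonds <- matrix(integer(0), ncol = 3L)
  }
  colnames(bonds) <- c("from", "to", "order")
  # single-atom SDFs carry a dummy zero bond row
  bonds <- bonds[bonds[, 1] > 0L & bonds[, 2] > 0L &
                   bonds[, 1] <= length(atoms) &
                   bonds[, 2] <= length(atoms), , drop = FALSE]
  aromatic <- rep(FALSE, length(atoms))
  if (nrow(bonds) > 0L && length(atoms) >= 3L) {
    rng <- try(suppressWarnings(
      ChemmineR::rings(one, type = "all", arom = TRUE, inner = FALSE)),
      silent = TRUE)
    if (!inherits(rng, "try-error") && length(rng$RINGS)) {
      for (i in seq_along(rng$RINGS)) {
        if (isTRUE(rng$AROMATIC[[i]])) {
          idx <- as.integer(sub("^.*_", "", rng$RINGS[[i]]))
          aromatic[idx] <- TRUE
        }
      }
    }
  }
  structure(list(id = id, smiles = smiles, atoms = atoms, bonds = bonds,
                 aromatic = aromatic),
            class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat("<drug_record> ", x$id, ": ", x$smiles, " (", length(x$atoms),
      " heavy atoms, ", nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

# Deterministic polynomial string hash (mod the Mersenne prime 2^31 - 1),
# folded to [0, nbits).  Plain-double arithmetic keeps every intermediate
# below 2^53, so the hash is identical across platforms.
.hash_string <- function(s, nbits) {
  codes <- utf8ToInt(s)
  h <- 5381
  for (cd in codes) h <- (h * 131 + cd) %% 2147483647
  as.integer(h %% nbits) + 1L
}

# Enumerate canonical linear atom paths with min_path..max_path atoms.
# Paths never revisit an atom; each path is typed as an alternating
# atom/bond string and canonicalized as min(forward, reverse).
.enumerate_paths <- function(mol, min_path, max_path,
                             bond_typing = c("aromatic", "kekule", "none")) {
  bond_typing <- match.arg(bond_typing)
  n <- length(mol$atoms)
  if (n < 2L || nrow(mol$bonds) == 0L) return(character(0))
  sym <- mol$atoms
  if (bond_typing == "aromatic") sym[mol$aromatic] <- tolower(sym[mol$aromatic])
  adj <- vector("list", n)
  blab <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds[i, 1]; b <- mol$bonds[i, 2]; o <- mol$bonds[i, 3]
    lab <- switch(bond_typing,
                  none = "-",
                  kekule = as.character(o),
                  aromatic = if (mol$aromatic[a] && mol$aromatic[b]) "a"
                             else as.character(o))
    adj[[a]] <- c(adj[[a]], b); blab[[a]] <- c(blab[[a]], lab)
    adj[[b]] <- c(adj[[b]], a); blab[[b]] <- c(blab[[b]], lab)
  }
  paths <- character(0)
  visited <- logical(n)
  walk <- function(atom, natoms, fwd) {
    if (natoms >= min_path) {
      rev_s <- paste(rev(strsplit(fwd, "\001", fixed = TRUE)[[1]]),
                     collapse = "\001")
      paths[[length(paths) + 1L]] <<- if (fwd <= rev_s) fwd else rev_s
    }
    if (natoms == max_path) return()
    for (j in seq_along(adj[[atom]])) {
      nb <- adj[[atom]][j]
      if (!visited[nb]) {
        visited[nb] <<- TRUE
        walk(nb, natoms + 1L,
             paste(fwd, blab[[atom]][j], sym[nb], sep = "\001"))
        visited[nb] <<- FALSE
      }
    }
  }
  for (start in seq_len(n)) {
    visited[start] <- TRUE
    walk(start, 1L, sym[start])
    visited[start] <- FALSE
  }
  unique(paths)
}

#' Hashed linear-path fingerprint of a molecule
#'
#' Enumerates all linear (non-revisiting) atom-bond paths of `min_path` to
#' `max_path` atoms and hashes each canonical path into a fixed-length bit
#' array.  Canonical paths are atom-order invariant (each path is read in
#' its lexicographically smaller direction), so the fingerprint is a
#' function of the molecular graph only.
#'
#' @param mol A `drug_record` from [parse_molecule()], or a SMILES string.
#' @param nbits Bit-array length (default 1024).
#' @param min_path,max_path Path length bounds, in atoms (defaults 2 and 7).
#' @param bond_typing How bonds enter path canonicalization: `"aromatic"`
#'   (default; aromatic-ring bonds typed 'a', others by order), `"kekule"`
#'   (raw kekulized orders) or `"none"` (element sequence only).
#' @return Integer 0/1 vector of length `nbits`, class `fingerprint`, with
#'   attributes `popcount`, `n_paths` and `params`.
#' @examples
#' \donttest{
#' fp <- path_fingerprint("CCO")
#' attr(fp, "popcount")
#' }
#' @export
path_fingerprint <- function(mol, nbits = 1024L, min_path = 2L,
                             max_path = 7L,
                             bond_typing = c("aromatic", "kekule", "none")) {
  bond_typing <- match.arg(bond_typing)
  if (nbits <= 0L) stop("nbits must be positive", call. = FALSE)
  if (min_path > max_path)
    stop("min_path must not exceed max_path", call. = FALSE)
  if (min_path < 1L) stop("min_path must be >= 1", call. = FALSE)
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(inherits(mol, "drug_record"))
  paths <- .enumerate_paths(mol, min_path, max_path, bond_typing)
  bits <- integer(nbits)
  for (p in paths) bits[.hash_string(p, nbits)] <- 1L
  structure(bits, class = "fingerprint",
            popcount = sum(bits), n_paths = length(paths),
            params = list(nbits = nbits, min_path = min_path,
                          max_path = max_path, bond_typing = bond_typing,
                          toolkit = "dtiscreen path hash v1 (OpenBabel parse)"))
}

#' @export
print.fingerprint <- function(x, ...) {
  p <- attr(x, "params")
  cat("<fingerprint> ", p$nbits, " bits, popcount ", attr(x, "popcount"),
      " (paths ", p$min_path, "-", p$max_path, " atoms, ",
      attr(x, "n_paths"), " distinct)\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity of two bit fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both fingerprints are all-zero.
#'
#' @param a,b Equal-length 0/1 vectors (e.g. from [path_fingerprint()]).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    stop("fingerprint lengths differ", call. = FALSE)
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' Fingerprint many drugs into a bit matrix
#'
#' @param smiles Named character vector of SMILES strings (names = ids).
#' @param ... Passed to [path_fingerprint()].
#' @return Integer matrix of 0/1, one row per drug, `nbits` columns named
#'   FP.1..FP.nbits.
#' @export
fingerprint_matrix <- function(smiles, ...) {
  if (is.null(names(smiles)) || anyDuplicated(names(smiles)))
    stop("smiles must have unique names", call. = FALSE)
  rows <- lapply(seq_along(smiles), function(i)
    as.integer(path_fingerprint(parse_molecule(smiles[[i]],
                                               id = names(smiles)[i]), ...)))
  out <- do.call(rbind, rows)
  colnames(out) <- paste0("FP.", seq_len(ncol(out)))
  rownames(out) <- names(smiles)
  out
}
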