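#' Read protein sequences from FASTA
#'
#' Multi-record FASTA with wrapped lines; record ids are the first
#' whitespace-delimited token of each header.  Duplicate ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- try(Biostrings::readAAStringSet(path), silent = TRUE)
  if (inherits(set, "try-error"))
    stop("malformed FASTA file: ", path, call. = FALSE)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  stats::setNames(as.character(set), ids)
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read drug SMILES records
#'
#' Accepts `.smi` files (one record per line: `SMILES id`, whitespace
#' separated, id optional) and CSV files with `id` and `smiles` columns;
#' the dialect is auto-detected from the header line.  Each SMILES is
#' validated with [parse_molecule()].
#'
#' @param path Input path.
#' @param strict If `TRUE`, any invalid SMILES aborts; if `FALSE`
#'   (default), invalid records are dropped and reported via the
#'   `errors` attribute (line number + offending string).
#' @return Named character vector of valid SMILES (names = ids), with
#'   attribute `errors` (data frame, possibly empty).
#' @export
read_smiles <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  first <- if (length(lines)) tolower(lines[1]) else ""
  is_csv <- grepl(",", first) & grepl("smiles", first)
  if (is_csv) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    if (!all(c("id", "smiles") %in% names(tab)))
      stop("CSV SMILES file needs 'id' and 'smiles' columns", call. = FALSE)
    ids <- as.character(tab$id); smi <- as.character(tab$smiles)
    lineno <- seq_len(nrow(tab)) + 1L
  } else {
    keep <- nzchar(trimws(lines))
    toks <- strsplit(trimws(lines[keep]), "\\s+")
    smi <- vapply(toks, `[[`, "", 1L)
    ids <- vapply(seq_along(toks), function(i)
      if (length(toks[[i]]) > 1L) toks[[i]][2L] else paste0("drug", i), "")
    lineno <- which(keep)
  }
  valid <- logical(length(smi))
  for (i in seq_along(smi))
    valid[i] <- !inherits(try(parse_molecule(smi[i]), silent = TRUE),
                          "try-error")
  errors <- data.frame(line = lineno[!valid], smiles = smi[!valid],
                       stringsAsFactors = FALSE)
  if (strict && nrow(errors))
    stop("invalid SMILES at line(s) ",
         paste(errors$line, collapse = ", "), call. = FALSE)
  if (!any(valid) && length(smi))
    stop("no valid SMILES records in ", path, call. = FALSE)
  out <- stats::setNames(smi[valid], ids[valid])
  if (anyDuplicated(names(out)))
    stop("duplicate drug id: ", names(out)[duplicated(names(out))][1],
         call. = FALSE)
  attr(out, "errors") <- errors
  out
}

#' Read a drug-target Ki interaction table
#'
#' CSV or TSV (auto-detected) with required columns `drug_id`, `target_id`
#' and either `ki_nM` or a `ki` column paired with a `unit` column
#' (`nM`, `uM`/`µM` or `M`, converted explicitly to nM).  Optional columns
#' `species` and `source` are carried through.
#'
#' @param path Input path.
#' @return Data frame of Ki records with `ki_nM` in nanomolar.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("drug_id", "target_id")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(tab$ki_nM)) {
    if (is.null(tab$ki) || is.null(tab$unit))
      stop("need a 'ki_nM' column, or 'ki' plus 'unit'", call. = FALSE)
    mult <- c(nm = 1, um = 1e3, "µm" = 1e3, m = 1e9)
    u <- tolower(trimws(tab$unit))
    if (any(!u %in% names(mult)))
      stop("unknown Ki unit(s): ",
           paste(unique(tab$unit[!u %in% names(mult)]), collapse = ", "),
           call. = FALSE)
    tab$ki_nM <- as.numeric(tab$ki) * unname(mult[u])
  }
  bad <- which(!is.finite(tab$ki_nM) | tab$ki_nM <= 0)
  if (length(bad))
    stop("non-positive Ki at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  tab$drug_id <- as.character(tab$drug_id)
  tab$target_id <- as.character(tab$target_id)
  tab
}

#' Write a feature matrix as CSV
#'
#' One row per record (rowname as first `id` column), named feature columns;
#' an optional label vector is appended as a final `label` column.  Read
#' back with [read_feature_csv()].
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param labels Optional vector of labels, same length as `nrow(x)`.
#' @export
write_feature_csv <- function(x, path, labels = NULL) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_csv()]
#'
#' @param path Input path.
#' @return Numeric matrix (rownames = ids); a `label` column, if present,
#'   is returned as the `labels` attribute.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df$id
  df$id <- NULL
  labels <- NULL
  if (!is.null(df$label)) { labels <- df$label; df$label <- NULL }
  m <- as.matrix(df)
  rownames(m) <- ids
  attr(m, "labels") <- labels
  m
}

#' Read / write a pipeline run configuration (YAML)
#'
#' Round-trips the full parameter list losslessly; [write_run_config()]
#' adds a provenance block (package version, timestamp).
#'
#' @param config Named list of parameters.
#' @param path YAML path.
#' @return `read_run_config()` returns the named list.
#' @export
write_run_config <- function(config, path) {
  config$provenance <- list(
    tool = "dtiscreen",
    version = as.character(utils::packageVersion("dtiscreen")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
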