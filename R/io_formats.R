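#' Read and canonicalize a FASTA file
#'
#' Sequences are uppercased; for nucleotide input `U` is mapped to `T`
#' (RNA transcripts are handled transparently); any character outside the
#' declared alphabet is removed with a warning stating how many characters
#' were dropped. Multi-line records are supported.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"NUCLEOTIDE"` or `"PROTEIN"`.
#' @return A `data.frame` with columns `id` and `sequence`, one row per
#'   record, with attribute `alphabet` set. Ids are the first whitespace
#'   token of each header.
#' @export
read_fasta <- function(path, alphabet = c("NUCLEOTIDE", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a valid FASTA file: ", path))
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- canonicalize_sequences(as.character(set), alphabet)
  empty <- ids[nchar(seqs) == 0]
  if (length(empty) > 0) {
    stop("sequence empty after canonicalization: ",
         paste(empty, collapse = ", "))
  }
  sequence_records(ids, seqs, alphabet)
}

#' Construct a set of sequence records
#'
#' @param ids Character vector of unique, non-empty identifiers.
#' @param sequences Character vector of canonical sequences.
#' @param alphabet `"NUCLEOTIDE"` or `"PROTEIN"`.
#' @return A `data.frame` with columns `id`, `sequence` and an `alphabet`
#'   attribute; the container used throughout the package.
#' @export
sequence_records <- function(ids, sequences,
                             alphabet = c("NUCLEOTIDE", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  stopifnot(length(ids) == length(sequences))
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  letters_ok <- alphabet_letters(alphabet)
  bad <- !vapply(strsplit(sequences, ""),
                 function(ch) all(ch %in% letters_ok), logical(1))
  if (any(bad)) {
    stop("non-canonical characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- data.frame(id = as.character(ids), sequence = as.character(sequences),
                    stringsAsFactors = FALSE)
  attr(out, "alphabet") <- alphabet
  out
}

canonicalize_sequences <- function(seqs, alphabet) {
  seqs <- toupper(seqs)
  if (alphabet == "NUCLEOTIDE") seqs <- chartr("U", "T", seqs)
  letters_ok <- alphabet_letters(alphabet)
  pattern <- paste0("[^", paste(letters_ok, collapse = ""), "]")
  n_before <- sum(nchar(seqs))
  seqs <- gsub(pattern, "", seqs)
  dropped <- n_before - sum(nchar(seqs))
  if (dropped > 0) {
    warning(sprintf("removed %d character(s) outside the %s alphabet",
                    dropped, alphabet))
  }
  seqs
}

#' Write sequence records as FASTA
#'
#' @param records Output of [read_fasta()] or [sequence_records()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a binary interaction matrix
#'
#' The bipartite adjacency matrix Y with lncRNAs as rows and proteins as
#' columns; `Y[i, j] = 1` records an observed interaction.
#'
#' @param Y Numeric 0/1 matrix.
#' @param lnc_ids,prot_ids Row and column identifiers; taken from `dimnames`
#'   when omitted.
#' @return An integer 0/1 matrix with row/column names set.
#' @export
interaction_matrix <- function(Y, lnc_ids = rownames(Y), prot_ids = colnames(Y)) {
  Y <- as.matrix(Y)
  if (is.null(lnc_ids) || is.null(prot_ids)) {
    stop("lnc_ids and prot_ids are required when Y is unnamed")
  }
  if (length(lnc_ids) != nrow(Y) || length(prot_ids) != ncol(Y)) {
    stop("id lengths do not match matrix dimensions")
  }
  if (anyDuplicated(lnc_ids) || anyDuplicated(prot_ids)) {
    stop("interaction matrix ids must be unique")
  }
  if (!all(Y %in% c(0, 1))) stop("interaction matrix entries must be 0 or 1")
  storage.mode(Y) <- "integer"
  dimnames(Y) <- list(as.character(lnc_ids), as.character(prot_ids))
  Y
}

#' Read an interaction network
#'
#' Two on-disk representations are supported: a two-column tab-separated
#' edge list (`lnc_id  prot_id`, one positive interaction per line, no
#' header) and a dense 0/1 matrix whose first row holds protein ids and
#' first column lncRNA ids.
#'
#' @param path Path to the network file.
#' @param lnc_ids,prot_ids Ordered identifiers defining the matrix axes.
#' @param format `"auto"` (default; a first line with more than two fields
#'   is treated as a dense matrix), `"edgelist"` or `"matrix"`.
#' @return An interaction matrix (see [interaction_matrix()]).
#' @export
read_network <- function(path, lnc_ids, prot_ids,
                         format = c("auto", "edgelist", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lnc_ids <- as.character(lnc_ids)
  prot_ids <- as.character(prot_ids)
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    nf <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
    format <- if (length(first) > 0 && nf > 2) "matrix" else "edgelist"
  }
  Y <- matrix(0L, length(lnc_ids), length(prot_ids),
              dimnames = list(lnc_ids, prot_ids))
  if (format == "edgelist") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(fields) != 2) stop("malformed edge-list line: ", ln)
      if (!fields[1] %in% lnc_ids) stop("unknown lncRNA id: ", fields[1])
      if (!fields[2] %in% prot_ids) stop("unknown protein id: ", fields[2])
      Y[fields[1], fields[2]] <- 1L
    }
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE)
    M <- as.matrix(tab)
    if (!all(rownames(M) %in% lnc_ids)) {
      stop("unknown lncRNA id: ",
           paste(setdiff(rownames(M), lnc_ids), collapse = ", "))
    }
    if (!all(colnames(M) %in% prot_ids)) {
      stop("unknown protein id: ",
           paste(setdiff(colnames(M), prot_ids), collapse = ", "))
    }
    if (!all(M %in% c(0, 1))) stop("non-binary entry in matrix-mode network")
    Y[rownames(M), colnames(M)] <- M
  }
  interaction_matrix(Y)
}

#' Write an interaction network
#'
#' @param Y Interaction matrix.
#' @param path Output path.
#' @param format `"matrix"` (dense TSV, round-trips through [read_network()])
#'   or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(Y, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  if (format == "matrix") {
    df <- data.frame(lnc_id = rownames(Y), Y, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(Y == 1L, arr.ind = TRUE)
    df <- data.frame(lnc_id = rownames(Y)[idx[, 1]],
                     prot_id = colnames(Y)[idx[, 2]])
    df <- df[order(df$lnc_id, df$prot_id), , drop = FALSE]
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write ranked pair predictions
#'
#' Pairs are ranked by score (descending); ties are broken by the
#' lexicographic order of `(lnc_id, prot_id)` so output is deterministic.
#'
#' @param pairs `data.frame` with columns `lnc_id`, `prot_id`, `score` and
#'   optionally `known` (0/1 flag for interactions already in the network).
#' @param path Output path for the 5-column TSV
#'   (`rank, lnc_id, prot_id, score, known`).
#' @return The ranked `data.frame`, invisibly.
#' @export
write_predictions <- function(pairs, path) {
  stopifnot(all(c("lnc_id", "prot_id", "score") %in% names(pairs)))
  if (any(!is.finite(pairs$score))) stop("scores must be finite")
  if (is.null(pairs$known)) pairs$known <- 0L
  o <- order(-pairs$score, pairs$lnc_id, pairs$prot_id)
  out <- data.frame(rank = seq_along(o),
                    lnc_id = pairs$lnc_id[o],
                    prot_id = pairs$prot_id[o],
                    score = pairs$score[o],
                    known = as.integer(pairs$known[o]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a feature matrix as TSV
#'
#' @param X Numeric matrix with sample ids as row names and feature names as
#'   column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path Input path.
#' @return Numeric matrix with row and column names.
#' @export
read_feature_matrix <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- tab[[1]]
  X
}

flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_config(v, key))
    } else {
      out[[key]] <- paste(v, collapse = ",")
    }
  }
  out
}

#' Write a run configuration as a flat key-value file
#'
#' Nested configuration lists (see [default_config()]) are flattened with
#' dotted keys, one `key = value` per line.
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- flatten_config(config)
  writeLines(paste(names(flat), unlist(flat), sep = " = "), path)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' @param path Input path.
#' @return Nested configuration list; numeric-looking values are converted,
#'   comma-separated values become vectors.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    vals <- trimws(strsplit(trimws(kv[2]), ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    v <- if (!any(is.na(num))) num else vals
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      out[[parts]] <- v
    } else {
      node <- out[[parts[1]]]
      if (is.null(node)) node <- list()
      node[[paste(parts[-1], collapse = ".")]] <- v
      out[[parts[1]]] <- node
    }
  }
  out
}
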