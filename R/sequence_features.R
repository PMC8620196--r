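#' Descriptor configuration
#'
#' @param kGap Maximum gap length for the k-gap composition families.
#' @param kTuple Maximum k-mer length for the pseudo k-tuple composition.
#' @return A list with class `descriptor_config`.
#' @export
descriptor_config <- function(kGap = 5L, kTuple = 3L) {
  kGap <- as.integer(kGap)
  kTuple <- as.integer(kTuple)
  stopifnot(kGap >= 1L, kTuple >= 1L)
  structure(list(kGap = kGap, kTuple = kTuple), class = "descriptor_config")
}

# integer codes 0..m-1 per residue
seq_to_int <- function(seq, letters_vec) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  codes <- match(ch, letters_vec) - 1L
  if (anyNA(codes)) stop("sequence contains non-canonical characters")
  codes
}

# codes of all k-mer windows (first residue most significant)
kmer_codes <- function(s_int, k, m) {
  L <- length(s_int)
  n <- L - k + 1L
  if (n < 1L) return(integer(0))
  code <- integer(n)
  for (j in seq_len(k)) code <- code * m + s_int[j:(j + n - 1L)]
  code
}

# all k-mers over `letters_vec` in lexicographic order (matches kmer_codes)
all_kmers <- function(letters_vec, k) {
  g <- expand.grid(rep(list(letters_vec), k), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_len(k)), drop = FALSE]
  do.call(paste0, g)
}

#' Scalar nucleotide composition descriptors
#'
#' Seven whole-sequence composition summaries: the three z-curve components
#' (purine-pyrimidine, amino-keto and weak-strong base differences on letter
#' totals), GC content, AT/GC ratio, and the cumulative GC and AT skews.
#' Any 0/0 ratio is defined as 0 so degenerate compositions never produce
#' NaN.
#'
#' @param seq A canonical nucleotide sequence.
#' @return Named numeric vector of length 7 in the order
#'   `zCurve.x, zCurve.y, zCurve.z, gcContent, atgcRatio,
#'   cumulativeSkew.gc, cumulativeSkew.at`.
#' @export
encode_scalar_descriptors <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  s <- seq_to_int(seq, NUCLEOTIDE_LETTERS)
  counts <- tabulate(s + 1L, nbins = 4L)
  nA <- counts[1]; nC <- counts[2]; nG <- counts[3]; nT <- counts[4]
  len <- length(s)
  safe_ratio <- function(num, den) if (den == 0) 0 else num / den
  c(zCurve.x = (nA + nG) - (nC + nT),
    zCurve.y = (nA + nC) - (nG + nT),
    zCurve.z = (nA + nT) - (nG + nC),
    gcContent = (nG + nC) / len,
    atgcRatio = safe_ratio(nA + nT, nG + nC),
    cumulativeSkew.gc = safe_ratio(nG - nC, nG + nC),
    cumulativeSkew.at = safe_ratio(nA - nT, nA + nT))
}

#' Pseudo k-tuple composition (pseudoKNC)
#'
#' Occurrence counts of every t-mer for t = 1..kTuple, overlaps included.
#' Canonical column order: ascending t, then lexicographic within each t.
#' Dimension is `sum(m^t)` over t, e.g. 84 for nucleotides and 8420 for
#' proteins at kTuple = 3.
#'
#' @param seq Canonical sequence.
#' @param alphabet `"NUCLEOTIDE"` or `"PROTEIN"`.
#' @param kTuple Maximum t-mer length.
#' @return Named numeric count vector.
#' @export
encode_pseudoknc <- function(seq, alphabet = c("NUCLEOTIDE", "PROTEIN"),
                             kTuple = 3L) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(seq)) stop("empty sequence")
  letters_vec <- alphabet_letters(alphabet)
  m <- length(letters_vec)
  s <- seq_to_int(seq, letters_vec)
  blocks <- lapply(seq_len(kTuple), function(t) {
    v <- tabulate(kmer_codes(s, t, m) + 1L, nbins = m^t)
    names(v) <- all_kmers(letters_vec, t)
    v
  })
  unlist(blocks)
}

#' Gapped k-mer pair composition
#'
#' Counts of a fixed head a-mer followed, after exactly g wildcard
#' positions, by a fixed tail b-mer, for g = 1..K. Windows running past the
#' sequence end contribute nothing; counts are raw (no normalization).
#' Canonical order: g ascending, then head lexicographic, then tail
#' lexicographic. Dimension is `m^(a+b) * K`.
#'
#' @param seq Canonical sequence.
#' @param alphabet `"NUCLEOTIDE"` or `"PROTEIN"`.
#' @param a,b Head and tail k-mer lengths.
#' @param K Maximum gap.
#' @return Named numeric count vector; names are `g<g>.<head>.<tail>`.
#' @export
encode_kgap <- function(seq, alphabet = c("NUCLEOTIDE", "PROTEIN"),
                        a, b, K) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(seq)) stop("empty sequence")
  a <- as.integer(a); b <- as.integer(b); K <- as.integer(K)
  stopifnot(a >= 1L, b >= 1L, K >= 1L)
  letters_vec <- alphabet_letters(alphabet)
  m <- length(letters_vec)
  s <- seq_to_int(seq, letters_vec)
  L <- length(s)
  dim_g <- m^(a + b)
  heads <- kmer_codes(s, a, m)
  tails <- kmer_codes(s, b, m)
  head_names <- all_kmers(letters_vec, a)
  tail_names <- all_kmers(letters_vec, b)
  nm_g <- as.vector(t(outer(head_names, tail_names,
                            function(h, t) paste(h, t, sep = "."))))
  out <- numeric(dim_g * K)
  nms <- character(dim_g * K)
  for (g in seq_len(K)) {
    n_win <- L - (a + g + b) + 1L
    block <- numeric(dim_g)
    if (n_win >= 1L) {
      i <- seq_len(n_win)
      pair <- heads[i] * m^b + tails[i + a + g]
      block <- tabulate(pair + 1L, nbins = dim_g)
    }
    idx <- (g - 1L) * dim_g + seq_len(dim_g)
    out[idx] <- block
    nms[idx] <- paste0("g", g, ".", nm_g)
  }
  names(out) <- nms
  out
}

LNC_KGAP_FAMILIES <- list(
  diDiKGap = c(2L, 2L), diMonoKGap = c(2L, 1L), diTriKGap = c(2L, 3L),
  monoDiKGap = c(1L, 2L), monoMonoKGap = c(1L, 1L), monoTriKGap = c(1L, 3L),
  triMonoKGap = c(3L, 1L), triDiKGap = c(3L, 2L))

# fixed family order of the lncRNA descriptor suite
LNC_FAMILY_ORDER <- c("atgcRatio", "cumulativeSkew", "diDiKGap", "diMonoKGap",
                      "diTriKGap", "gcContent", "monoDiKGap", "monoMonoKGap",
                      "monoTriKGap", "pseudoKNC", "triMonoKGap", "triDiKGap",
                      "zCurve")

#' Encode a lncRNA sequence into the full 13-family descriptor vector
#'
#' Concatenates, in a fixed family order, the scalar composition
#' descriptors, eight gapped k-mer pair families (head/tail lengths 1-3,
#' gaps 1..kGap) and the pseudo k-tuple counts. At the defaults
#' (kGap = 5, kTuple = 3) the vector has 14,891 entries.
#'
#' @param seq Canonical nucleotide sequence.
#' @param config A [descriptor_config()].
#' @return Named numeric vector; names carry the `lnc.<family>.` prefix.
#' @export
encode_lncrna <- function(seq, config = descriptor_config()) {
  if (!nzchar(seq)) stop("empty sequence")
  scal <- encode_scalar_descriptors(seq)
  blocks <- list(
    atgcRatio = scal["atgcRatio"],
    cumulativeSkew = scal[c("cumulativeSkew.gc", "cumulativeSkew.at")],
    gcContent = scal["gcContent"],
    zCurve = scal[c("zCurve.x", "zCurve.y", "zCurve.z")],
    pseudoKNC = encode_pseudoknc(seq, "NUCLEOTIDE", config$kTuple))
  for (fam in names(LNC_KGAP_FAMILIES)) {
    ab <- LNC_KGAP_FAMILIES[[fam]]
    blocks[[fam]] <- encode_kgap(seq, "NUCLEOTIDE", ab[1], ab[2], config$kGap)
  }
  out <- lapply(LNC_FAMILY_ORDER, function(fam) {
    v <- blocks[[fam]]
    if (fam %in% c("atgcRatio", "gcContent")) {
      names(v) <- paste0("lnc.", fam)
    } else {
      names(v) <- paste0("lnc.", fam, ".",
                         sub(paste0("^", fam, "\\."), "", names(v)))
    }
    v
  })
  unlist(out, use.names = TRUE)
}

#' Encode a protein sequence into the full 2-family descriptor vector
#'
#' Pseudo k-tuple composition (kTuple = 3 by default; 8420 entries) followed
#' by the mono-mono gapped pair composition (gaps 1..kGap; 2000 entries),
#' giving 10,420 entries at the defaults.
#'
#' @param seq Canonical protein sequence.
#' @param config A [descriptor_config()].
#' @return Named numeric vector; names carry the `prot.<family>.` prefix.
#' @export
encode_protein <- function(seq, config = descriptor_config()) {
  if (!nzchar(seq)) stop("empty sequence")
  knc <- encode_pseudoknc(seq, "PROTEIN", config$kTuple)
  names(knc) <- paste0("prot.pseudoKNC.", names(knc))
  kg <- encode_kgap(seq, "PROTEIN", 1L, 1L, config$kGap)
  names(kg) <- paste0("prot.monoMonoKGap.", names(kg))
  c(knc, kg)
}

#' Encode a set of sequence records into a feature matrix
#'
#' @param records Output of [read_fasta()] or [sequence_records()]; the
#'   alphabet attribute decides between the lncRNA and protein encoders.
#' @param config A [descriptor_config()].
#' @return Numeric matrix, one row per record (row names = ids), columns in
#'   canonical descriptor order.
#' @export
encode_records <- function(records, config = descriptor_config()) {
  alphabet <- attr(records, "alphabet")
  if (is.null(alphabet)) stop("records are missing the alphabet attribute")
  enc <- if (alphabet == "NUCLEOTIDE") encode_lncrna else encode_protein
  rows <- lapply(records$sequence, enc, config = config)
  X <- do.call(rbind, rows)
  rownames(X) <- records$id
  X
}

#' Build the concatenated per-pair feature matrix
#'
#' Each candidate pair is represented by its lncRNA descriptor block
#' followed by its protein descriptor block; the pair sample id is
#' `"lnc_id|prot_id"`.
#'
#' @param lnc_features,prot_features Feature matrices from
#'   [encode_records()] (rows = entity ids).
#' @param pairs `data.frame` with columns `lnc_id` and `prot_id`.
#' @return Numeric matrix with one row per pair.
#' @export
build_pair_matrix <- function(lnc_features, prot_features, pairs) {
  miss_l <- setdiff(unique(pairs$lnc_id), rownames(lnc_features))
  if (length(miss_l) > 0) stop("unknown lncRNA id: ", paste(miss_l, collapse = ", "))
  miss_p <- setdiff(unique(pairs$prot_id), rownames(prot_features))
  if (length(miss_p) > 0) stop("unknown protein id: ", paste(miss_p, collapse = ", "))
  X <- cbind(lnc_features[as.character(pairs$lnc_id), , drop = FALSE],
             prot_features[as.character(pairs$prot_id), , drop = FALSE])
  rownames(X) <- paste(pairs$lnc_id, pairs$prot_id, sep = "|")
  X
}

#' Min-max normalization learned on a training matrix
#'
#' Maps each column through `(x - min) / (max - min)` with the column
#' extrema of `X`; constant columns map to 0. The learned parameters are
#' returned so test data can be transformed with the training statistics
#' (no clipping is applied, so unseen data may fall outside `[0, 1]`).
#'
#' @param X Non-empty numeric matrix.
#' @return List with elements `X` (normalized matrix) and `params`
#'   (list of per-column `min` and `max`).
#' @export
min_max_normalize <- function(X) {
  if (nrow(X) == 0) stop("cannot fit normalization on an empty matrix")
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  params <- list(min = mins, max = maxs)
  list(X = apply_normalization(params, X), params = params)
}

#' Apply previously learned min-max parameters
#'
#' @param params `params` element returned by [min_max_normalize()].
#' @param X Matrix with the same columns as the fitting matrix.
#' @return Normalized matrix.
#' @export
apply_normalization <- function(params, X) {
  if (ncol(X) != length(params$min)) stop("column mismatch with normalization parameters")
  rng <- params$max - params$min
  rng[rng == 0] <- Inf  # constant columns -> 0
  out <- sweep(X, 2, params$min, "-")
  out <- sweep(out, 2, rng, "/")
  dimnames(out) <- dimnames(X)
  out
}
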