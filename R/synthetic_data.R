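#' Specification of a motif-planted synthetic LPI dataset
#'
#' The generator emulates the structure of a real LPI study at desk scale:
#' two sequence sets plus a bipartite 0/1 interaction matrix whose positive
#' entries are driven by planted sequence motifs. Each interaction rule
#' pairs a nucleotide motif with a peptide motif; a lncRNA and a protein
#' interact when, for some rule, the lncRNA carries the nucleotide motif
#' and the protein carries the peptide motif. Independent label flips at
#' `noise_rate` emulate annotation noise.
#'
#' @param n_lnc,n_prot Numbers of lncRNAs and proteins.
#' @param lnc_len,prot_len Sequence lengths (uniform background
#'   composition; motifs overwrite in place so lengths are fixed).
#' @param motif_pairs List of `c(nucleotide_motif, peptide_motif)` rules.
#' @param carrier_fraction Fraction of each entity set that carries a
#'   (randomly assigned) rule motif.
#' @param noise_rate Independent flip probability per matrix entry.
#' @param seed Integer seed; generation is fully reproducible.
#' @return List with class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lnc = 60L, n_prot = 30L,
                           lnc_len = 200L, prot_len = 150L,
                           motif_pairs = list(c("ACGACGACGACG", "MKVLHW"),
                                              c("TCCTCCTCCTCC", "QERTYS")),
                           carrier_fraction = 0.75, noise_rate = 0.05,
                           seed = 101L) {
  stopifnot(n_lnc >= 2, n_prot >= 2, carrier_fraction > 0,
            carrier_fraction < 1, noise_rate >= 0, noise_rate < 1)
  for (mp in motif_pairs) {
    stopifnot(length(mp) == 2, nzchar(mp[1]), nzchar(mp[2]))
    if (!all(strsplit(mp[1], "")[[1]] %in% NUCLEOTIDE_LETTERS)) {
      stop("nucleotide motif has non-canonical characters: ", mp[1])
    }
    if (!all(strsplit(mp[2], "")[[1]] %in% PROTEIN_LETTERS)) {
      stop("peptide motif has non-canonical characters: ", mp[2])
    }
    if (nchar(mp[1]) > lnc_len) stop("nucleotide motif longer than lnc_len")
    if (nchar(mp[2]) > prot_len) stop("peptide motif longer than prot_len")
  }
  structure(list(n_lnc = as.integer(n_lnc), n_prot = as.integer(n_prot),
                 lnc_len = as.integer(lnc_len), prot_len = as.integer(prot_len),
                 motif_pairs = motif_pairs,
                 carrier_fraction = carrier_fraction,
                 noise_rate = noise_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

random_sequences <- function(n, len, letters_vec) {
  vapply(seq_len(n), function(i) {
    paste(sample(letters_vec, len, replace = TRUE), collapse = "")
  }, character(1))
}

embed_motif <- function(seq, motif) {
  pos <- sample.int(nchar(seq) - nchar(motif) + 1L, 1L)
  paste0(substr(seq, 1, pos - 1L), motif,
         substr(seq, pos + nchar(motif), nchar(seq)))
}

#' Generate a synthetic LPI dataset with known ground truth
#'
#' Sequences are uniform random over their alphabet; a `carrier_fraction`
#' of each entity set receives the motif of a randomly assigned rule,
#' overwritten at a random position. `Y[i, j] = 1` iff some rule has its
#' nucleotide motif occurring in lncRNA i and its peptide motif in protein
#' j (occurrences are re-scanned, so chance background hits also count),
#' after which every entry is flipped independently with probability
#' `noise_rate`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `lnc` and `prot` (sequence records), `Y` (interaction
#'   matrix) and `truth` (carrier assignments and flipped cells).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    lnc_ids <- sprintf("lnc%03d", seq_len(spec$n_lnc))
    prot_ids <- sprintf("prot%03d", seq_len(spec$n_prot))
    lnc_seq <- random_sequences(spec$n_lnc, spec$lnc_len, NUCLEOTIDE_LETTERS)
    prot_seq <- random_sequences(spec$n_prot, spec$prot_len, PROTEIN_LETTERS)
    n_rule <- length(spec$motif_pairs)
    assign_carriers <- function(n, frac) {
      carriers <- sample.int(n, round(frac * n))
      rules <- if (n_rule > 0) sample.int(n_rule, length(carriers), replace = TRUE) else integer(0)
      list(idx = carriers, rule = rules)
    }
    lc <- assign_carriers(spec$n_lnc, spec$carrier_fraction)
    pc <- assign_carriers(spec$n_prot, spec$carrier_fraction)
    for (i in seq_along(lc$idx)) {
      lnc_seq[lc$idx[i]] <- embed_motif(lnc_seq[lc$idx[i]],
                                        spec$motif_pairs[[lc$rule[i]]][1])
    }
    for (i in seq_along(pc$idx)) {
      prot_seq[pc$idx[i]] <- embed_motif(prot_seq[pc$idx[i]],
                                         spec$motif_pairs[[pc$rule[i]]][2])
    }
    # interaction rule from actual motif occurrence, then noise flips
    Y <- matrix(0L, spec$n_lnc, spec$n_prot,
                dimnames = list(lnc_ids, prot_ids))
    for (r in seq_len(n_rule)) {
      has_l <- grepl(spec$motif_pairs[[r]][1], lnc_seq, fixed = TRUE)
      has_p <- grepl(spec$motif_pairs[[r]][2], prot_seq, fixed = TRUE)
      Y[has_l, has_p] <- 1L
    }
    flips <- matrix(runif(length(Y)) < spec$noise_rate, nrow(Y))
    Y_noisy <- Y
    Y_noisy[flips] <- 1L - Y_noisy[flips]
    flip_idx <- which(flips, arr.ind = TRUE)
    truth <- list(
      lnc_carriers = data.frame(id = lnc_ids[lc$idx], rule = lc$rule,
                                stringsAsFactors = FALSE),
      prot_carriers = data.frame(id = prot_ids[pc$idx], rule = pc$rule,
                                 stringsAsFactors = FALSE),
      flips = data.frame(lnc_id = lnc_ids[flip_idx[, 1]],
                         prot_id = prot_ids[flip_idx[, 2]],
                         stringsAsFactors = FALSE),
      Y_clean = interaction_matrix(Y))
    list(lnc = sequence_records(lnc_ids, lnc_seq, "NUCLEOTIDE"),
         prot = sequence_records(prot_ids, prot_seq, "PROTEIN"),
         Y = interaction_matrix(Y_noisy), truth = truth)
  })
}

#' Canonical feature names elevated by the planted motifs
#'
#' Decomposes each rule motif into its sliding t-mers (t = 1..kTuple) and
#' returns the corresponding pseudo k-tuple feature names of the pair
#' matrix, i.e. the columns whose counts are elevated in motif carriers.
#' Used by the selection-recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param config A [descriptor_config()].
#' @return Character vector of canonical feature names (`lnc.pseudoKNC.*`
#'   and `prot.pseudoKNC.*`).
#' @export
planted_feature_names <- function(spec, config = descriptor_config()) {
  out <- character(0)
  sliding <- function(motif, t) {
    if (nchar(motif) < t) return(character(0))
    starts <- seq_len(nchar(motif) - t + 1L)
    unique(substring(motif, starts, starts + t - 1L))
  }
  for (mp in spec$motif_pairs) {
    for (t in seq_len(config$kTuple)) {
      out <- c(out,
               paste0("lnc.pseudoKNC.", sliding(mp[1], t)),
               paste0("prot.pseudoKNC.", sliding(mp[2], t)))
    }
  }
  unique(out)
}
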