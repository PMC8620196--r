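# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals.

# gapped pair counts by exhaustive enumeration of (start, gap) index pairs
oracle_kgap <- function(seq, letters_vec, a, b, K) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  head_mers <- all_mers(letters_vec, a)
  tail_mers <- all_mers(letters_vec, b)
  out <- numeric(0)
  for (g in seq_len(K)) {
    counts <- matrix(0, length(head_mers), length(tail_mers),
                     dimnames = list(head_mers, tail_mers))
    if (L >= a + g + b) {
      for (i in seq_len(L - (a + g + b) + 1)) {
        h <- paste(ch[i:(i + a - 1)], collapse = "")
        t <- paste(ch[(i + a + g):(i + a + g + b - 1)], collapse = "")
        counts[h, t] <- counts[h, t] + 1
      }
    }
    block <- as.vector(t(counts))
    names(block) <- paste0("g", g, ".",
                           as.vector(t(outer(head_mers, tail_mers, paste, sep = "."))))
    out <- c(out, block)
  }
  out
}

# lexicographically ordered k-mers (first letter most significant)
all_mers <- function(letters_vec, k) {
  out <- letters_vec
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      out <- as.vector(t(outer(out, letters_vec, paste0)))
    }
  }
  out
}

# exhaustive weighted-stump search over every midpoint/sentinel threshold
# and both polarities; ties to smaller threshold, then polarity +1
oracle_stump <- function(column, y, D) {
  xs <- sort(unique(column))
  thresholds <- c(-Inf, if (length(xs) > 1) (xs[-1] + xs[-length(xs)]) / 2, Inf)
  best <- list(eps = Inf, thr = NA, pol = NA)
  for (thr in thresholds) {
    for (pol in c(1, -1)) {
      pred <- ifelse(column <= thr, pol, -pol)
      eps <- sum(D[pred != y])
      if (eps < best$eps - 1e-12) best <- list(eps = eps, thr = thr, pol = pol)
    }
  }
  best
}

# AUC by O(n^2) pairwise comparison, ties counted 1/2
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

random_seq <- function(len, letters_vec) {
  paste(sample(letters_vec, len, replace = TRUE), collapse = "")
}

# small fast synthetic spec for pipeline-shape tests
tiny_spec <- function(seed = 7L, noise_rate = 0.05) {
  synthetic_spec(n_lnc = 20L, n_prot = 12L, lnc_len = 80L, prot_len = 60L,
                 noise_rate = noise_rate, seed = seed)
}
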