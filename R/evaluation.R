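#' Positive pairs of an interaction matrix
#'
#' @param Y Interaction matrix.
#' @return `data.frame` with columns `lnc_id`, `prot_id`, `label` (= 1).
#' @export
positive_pairs <- function(Y) {
  idx <- which(Y == 1L, arr.ind = TRUE)
  df <- data.frame(lnc_id = rownames(Y)[idx[, 1]],
                   prot_id = colnames(Y)[idx[, 2]],
                   label = 1L, stringsAsFactors = FALSE)
  df[order(df$lnc_id, df$prot_id), , drop = FALSE]
}

#' Sample presumed non-interacting pairs
#'
#' Negatives are drawn uniformly without replacement from the zero entries
#' of Y, at `round(ratio * positives)` pairs.
#'
#' @param Y Interaction matrix.
#' @param ratio Negatives per positive (default 1, the balanced setting).
#' @param seed Integer seed; the draw is reproducible.
#' @return `data.frame` with columns `lnc_id`, `prot_id`, `label` (= 0).
#' @export
sample_negatives <- function(Y, ratio = 1.0, seed = 1L) {
  zeros <- which(Y == 0L, arr.ind = TRUE)
  n_neg <- round(ratio * sum(Y == 1L))
  if (n_neg > nrow(zeros)) {
    stop("not enough zero entries to sample ", n_neg, " negatives")
  }
  pick <- with_seed(seed, sample.int(nrow(zeros), n_neg))
  data.frame(lnc_id = rownames(Y)[zeros[pick, 1]],
             prot_id = colnames(Y)[zeros[pick, 2]],
             label = 0L, stringsAsFactors = FALSE)
}

# shuffled near-equal fold assignment for a set of entities
fold_assignment <- function(ids, n_folds) {
  if (length(ids) < n_folds) {
    stop("fewer entities (", length(ids), ") than folds (", n_folds, ")")
  }
  split(sample(ids), rep_len(seq_len(n_folds), length(ids)))
}

#' Build cross-validation splits under one of four schemes
#'
#' * `CV_LP`: the labeled pair list is partitioned into folds (warm start).
#' * `CV_L`: lncRNA ids are partitioned; a fold tests every pair whose
#'   lncRNA is held out (lncRNA cold start).
#' * `CV_P`: symmetric over proteins.
#' * `CV_IND`: per fold, 1/n_folds of the lncRNAs and of the proteins are
#'   drawn as test nodes; training keeps only pairs with both endpoints in
#'   the train nodes, testing keeps only pairs with both endpoints in the
#'   test nodes, and cross pairs (one endpoint on each side) are discarded
#'   from both. Folds redraw their node sets independently, so `CV_IND`
#'   folds do not partition the pair list.
#'
#' @param scheme One of `"CV_LP"`, `"CV_L"`, `"CV_P"`, `"CV_IND"`.
#' @param Y Interaction matrix (defines the entity universes).
#' @param pairs Labeled pair `data.frame` (`lnc_id`, `prot_id`, `label`).
#' @param n_folds Number of folds (default 5, i.e. 80%/20%).
#' @param seed Integer seed.
#' @return List of `cv_split` objects, each with elements `scheme`, `fold`,
#'   `train` and `test` (labeled pair `data.frame`s).
#' @export
make_splits <- function(scheme = c("CV_LP", "CV_L", "CV_P", "CV_IND"),
                        Y, pairs, n_folds = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  n_folds <- as.integer(n_folds)
  with_seed(seed, {
    splits <- vector("list", n_folds)
    if (scheme == "CV_LP") {
      fold_of <- sample(rep_len(seq_len(n_folds), nrow(pairs)))
      for (f in seq_len(n_folds)) {
        splits[[f]] <- list(train = pairs[fold_of != f, , drop = FALSE],
                            test = pairs[fold_of == f, , drop = FALSE])
      }
    } else if (scheme %in% c("CV_L", "CV_P")) {
      ids <- if (scheme == "CV_L") rownames(Y) else colnames(Y)
      key <- if (scheme == "CV_L") "lnc_id" else "prot_id"
      folds <- fold_assignment(ids, n_folds)
      for (f in seq_len(n_folds)) {
        held <- pairs[[key]] %in% folds[[f]]
        splits[[f]] <- list(train = pairs[!held, , drop = FALSE],
                            test = pairs[held, , drop = FALSE])
      }
    } else { # CV_IND: independent redraw of test nodes per fold
      lncs <- rownames(Y); prots <- colnames(Y)
      n_test_l <- max(1L, round(length(lncs) / n_folds))
      n_test_p <- max(1L, round(length(prots) / n_folds))
      if (n_test_l >= length(lncs) || n_test_p >= length(prots)) {
        stop("too few entities for CV_IND with ", n_folds, " folds")
      }
      for (f in seq_len(n_folds)) {
        test_l <- sample(lncs, n_test_l)
        test_p <- sample(prots, n_test_p)
        in_test <- pairs$lnc_id %in% test_l & pairs$prot_id %in% test_p
        in_train <- !(pairs$lnc_id %in% test_l) & !(pairs$prot_id %in% test_p)
        splits[[f]] <- list(train = pairs[in_train, , drop = FALSE],
                            test = pairs[in_test, , drop = FALSE])
      }
    }
    lapply(seq_len(n_folds), function(f) {
      structure(list(scheme = scheme, fold = f,
                     train = splits[[f]]$train, test = splits[[f]]$test),
                class = "cv_split")
    })
  })
}

#' The six evaluation metrics for one scored test set
#'
#' Precision, recall, accuracy and F1 are computed from hard labels
#' (label 1 iff score > threshold; precision and F1 are 0 when nothing is
#' predicted positive). AUC is the probability that a random positive
#' outranks a random negative, ties counted 1/2 (rank formulation). AUPR
#' is the trapezoidal area of the precision-recall curve over recall, with
#' tied scores grouped at a single cutoff and the curve anchored at recall
#' 0 with the precision of the top cutoff.
#'
#' @param y_true Labels in `{0, 1}`; both classes required.
#' @param scores Numeric scores.
#' @param threshold Decision threshold (default 0.5).
#' @return List with class `metrics_report`: `precision`, `recall`,
#'   `accuracy`, `f1`, `auc`, `aupr`.
#' @export
compute_metrics <- function(y_true, scores, threshold = 0.5) {
  y_true <- to_01(y_true)
  if (length(y_true) != length(scores)) stop("y_true and scores lengths differ")
  n_pos <- sum(y_true == 1); n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC/AUPR are undefined when y_true has a single class")
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  accuracy <- mean(pred == y_true)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  # AUC via mean ranks; midranks give the ties-count-1/2 convention
  r <- rank(scores)
  auc <- (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # AUPR: group tied scores, walk cutoffs from high to low
  o <- order(-scores)
  ys <- y_true[o]; ss <- scores[o]
  cut_end <- which(!duplicated(ss, fromLast = TRUE) | seq_along(ss) == length(ss))
  cum_tp <- cumsum(ys)[cut_end]
  n_at <- cut_end
  prec_c <- cum_tp / n_at
  rec_c <- cum_tp / n_pos
  rec_pts <- c(0, rec_c)
  prec_pts <- c(prec_c[1], prec_c)
  aupr <- sum(diff(rec_pts) * (head(prec_pts, -1) + prec_pts[-1]) / 2)
  structure(list(precision = precision, recall = recall, accuracy = accuracy,
                 f1 = f1, auc = auc, aupr = aupr),
            class = "metrics_report")
}

# encode both entity sets once; reused across folds and repeats
encode_dataset <- function(dataset, config = descriptor_config()) {
  list(lnc = encode_records(dataset$lnc, config),
       prot = encode_records(dataset$prot, config))
}

# selection -> normalization -> three classifiers -> combined test scores
fit_score_fold <- function(Xtr, ytr, Xte, k_features, config, seed) {
  sel <- select_features(Xtr, ytr, k_features)
  Xtr_k <- reduce_matrix(Xtr, sel$selected)
  nrm <- min_max_normalize(Xtr_k)
  Xte_k <- apply_normalization(nrm$params, reduce_matrix(Xte, sel$selected))
  dnn <- train_dnn(nrm$X, ytr, config$dnn, derive_seed(seed, 11))
  gbt <- train_gbt(nrm$X, ytr, config$gbt, derive_seed(seed, 12))
  svm <- train_csvm(nrm$X, ytr, config$svm, derive_seed(seed, 13))
  w <- ensemble_weights(config$ensemble$alpha, config$ensemble$beta,
                        config$ensemble$theta)
  scores <- combine_scores(score_model(dnn, Xte_k), score_model(gbt, Xte_k),
                           score_model(svm, Xte_k), w)
  list(scores = scores, selection = sel, models = list(dnn = dnn, gbt = gbt, svm = svm),
       normalization = nrm$params, weights = w)
}

#' Run the full repeated cross-validation experiment
#'
#' Per repeat: negatives are sampled 1:1 from the zero entries, the labeled
#' pairs are split under the chosen scheme, and per fold the pipeline runs
#' end to end (pair encoding, AdaBoost selection on the training fold,
#' min-max normalization with training statistics, the three base
#' classifiers, the weighted ensemble) before the six metrics are measured
#' on the test fold. All stage seeds derive deterministically from the
#' master seed. Folds whose training or test part degenerates to a single
#' class (possible under the cold-start schemes on small data) are recorded
#' as `NA` and excluded from the averages.
#'
#' @param dataset List with `lnc`, `prot` (sequence records) and `Y`
#'   (interaction matrix), e.g. from [generate_dataset()].
#' @param scheme Cross-validation scheme (see [make_splits()]).
#' @param k_features Number of features kept by AdaBoost selection.
#' @param config Pipeline configuration (see [default_config()]).
#' @param n_repeats Number of repeats (negatives and folds are redrawn
#'   each repeat).
#' @param n_folds Folds per repeat.
#' @param seed Master seed.
#' @return List with `summary` (mean/sd per metric over repeat x fold),
#'   `per_fold` (one row per repeat and fold) and `per_repeat` (fold-
#'   averaged rows, the coarser averaging granularity).
#' @export
run_experiment <- function(dataset, scheme = "CV_LP", k_features = 50L,
                           config = default_config(), n_repeats = 20L,
                           n_folds = 5L, seed = 1L) {
  feats <- encode_dataset(dataset, do.call(descriptor_config,
                                           as.list(config$descriptors)))
  metric_names <- c("precision", "recall", "accuracy", "f1", "auc", "aupr")
  rows <- list()
  for (r in seq_len(n_repeats)) {
    neg <- sample_negatives(dataset$Y, 1.0, derive_seed(seed, r, 1))
    pairs <- rbind(positive_pairs(dataset$Y), neg)
    splits <- make_splits(scheme, dataset$Y, pairs, n_folds,
                          derive_seed(seed, r, 2))
    for (sp in splits) {
      vals <- rep(NA_real_, length(metric_names))
      ok <- length(unique(sp$train$label)) == 2 &&
        nrow(sp$test) > 0 && length(unique(sp$test$label)) == 2
      if (ok) {
        Xtr <- build_pair_matrix(feats$lnc, feats$prot, sp$train)
        Xte <- build_pair_matrix(feats$lnc, feats$prot, sp$test)
        fold_seed <- derive_seed(seed, r, sp$fold, 3)
        fit <- fit_score_fold(Xtr, sp$train$label, Xte, k_features, config,
                              fold_seed)
        m <- compute_metrics(sp$test$label, fit$scores,
                             config$ensemble$threshold)
        vals <- unlist(m[metric_names])
        rm(Xtr, Xte, fit)
        gc(verbose = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        c(list(repeat_ = r, fold = sp$fold, scheme = scheme),
          as.list(stats::setNames(vals, metric_names)))
    }
  }
  per_fold <- do.call(rbind, lapply(rows, as.data.frame))
  names(per_fold)[1] <- "repeat"
  mvals <- per_fold[, metric_names, drop = FALSE]
  summary <- data.frame(metric = metric_names,
                        mean = vapply(mvals, mean, numeric(1), na.rm = TRUE),
                        sd = vapply(mvals, sd, numeric(1), na.rm = TRUE),
                        row.names = NULL)
  per_repeat <- do.call(rbind, lapply(split(per_fold, per_fold[["repeat"]]),
    function(d) {
      out <- data.frame(repeat_ = d[["repeat"]][1])
      for (mn in metric_names) out[[mn]] <- mean(d[[mn]], na.rm = TRUE)
      names(out)[1] <- "repeat"
      out
    }))
  rownames(per_repeat) <- NULL
  list(summary = summary, per_fold = per_fold, per_repeat = per_repeat)
}

#' Rank candidate partners for one query entity
#'
#' Emulates the cold-start case study: all known edges of the query entity
#' are hidden, the pipeline is trained on the remaining pairs (plus
#' sampled negatives avoiding the query), and every candidate partner is
#' scored and ranked. Known interactions of the query are flagged so the
#' ranking can be inspected against the hidden truth.
#'
#' @param dataset List with `lnc`, `prot`, `Y`.
#' @param entity_id Query lncRNA or protein id.
#' @param mode `"proteins_for_lncRNA"` or `"lncRNAs_for_protein"`.
#' @param k_features Number of selected features.
#' @param config Pipeline configuration.
#' @param seed Master seed.
#' @return Ranked `data.frame` (`rank`, `lnc_id`, `prot_id`, `score`,
#'   `known`), ready for [write_predictions()].
#' @export
rank_for_entity <- function(dataset, entity_id,
                            mode = c("proteins_for_lncRNA", "lncRNAs_for_protein"),
                            k_features = 50L, config = default_config(),
                            seed = 1L) {
  mode <- match.arg(mode)
  Y <- dataset$Y
  is_lnc <- mode == "proteins_for_lncRNA"
  universe <- if (is_lnc) rownames(Y) else colnames(Y)
  if (!entity_id %in% universe) stop("unknown entity id: ", entity_id)
  candidates <- if (is_lnc) colnames(Y) else rownames(Y)
  if (length(candidates) == 0) {
    return(data.frame(rank = integer(0), lnc_id = character(0),
                      prot_id = character(0), score = numeric(0),
                      known = integer(0)))
  }
  # hide the query's row/column entirely while training
  Y_train <- Y
  if (is_lnc) Y_train[entity_id, ] <- 0L else Y_train[, entity_id] <- 0L
  pos <- positive_pairs(Y_train)
  neg <- sample_negatives(Y_train, 1.0, derive_seed(seed, 1))
  drop_entity <- if (is_lnc) neg$lnc_id == entity_id else neg$prot_id == entity_id
  neg <- neg[!drop_entity, , drop = FALSE]
  train <- rbind(pos, neg)
  feats <- encode_dataset(dataset, do.call(descriptor_config,
                                           as.list(config$descriptors)))
  test <- if (is_lnc) {
    data.frame(lnc_id = entity_id, prot_id = candidates, stringsAsFactors = FALSE)
  } else {
    data.frame(lnc_id = candidates, prot_id = entity_id, stringsAsFactors = FALSE)
  }
  Xtr <- build_pair_matrix(feats$lnc, feats$prot, train)
  Xte <- build_pair_matrix(feats$lnc, feats$prot, test)
  fit <- fit_score_fold(Xtr, train$label, Xte, k_features, config,
                        derive_seed(seed, 2))
  known <- if (is_lnc) Y[entity_id, candidates] else Y[candidates, entity_id]
  out <- data.frame(lnc_id = test$lnc_id, prot_id = test$prot_id,
                    score = fit$scores, known = as.integer(known),
                    stringsAsFactors = FALSE)
  o <- order(-out$score, out$lnc_id, out$prot_id)
  out <- out[o, , drop = FALSE]
  data.frame(rank = seq_len(nrow(out)), out, row.names = NULL)
}
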