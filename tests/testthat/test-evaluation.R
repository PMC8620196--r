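# scheme invariant audit used by several tests
audit_split <- function(sp) {
  train <- sp$train; test <- sp$test
  key <- function(d) paste(d$lnc_id, d$prot_id)
  expect_length(intersect(key(train), key(test)), 0)
  if (sp$scheme %in% c("CV_L", "CV_IND")) {
    expect_length(intersect(train$lnc_id, test$lnc_id), 0)
  }
  if (sp$scheme %in% c("CV_P", "CV_IND")) {
    expect_length(intersect(train$prot_id, test$prot_id), 0)
  }
}

random_instance <- function(seed) {
  withr::with_seed(seed, {
    nl <- sample(6:12, 1); np <- sample(6:12, 1)
    Y <- matrix(as.integer(runif(nl * np) < 0.3), nl, np,
                dimnames = list(sprintf("l%02d", 1:nl), sprintf("p%02d", 1:np)))
    if (sum(Y) < 2) Y[1:2, 1] <- 1L
    Y <- interaction_matrix(Y)
    neg <- sample_negatives(Y, 1, seed)
    list(Y = Y, pairs = rbind(positive_pairs(Y), neg))
  })
}

test_that("negative sampling draws the requested count, disjoint from positives", {
  Y <- interaction_matrix(matrix(as.integer(runif(100) < 0.1), 10, 10,
                                 dimnames = list(paste0("l", 1:10), paste0("p", 1:10))))
  n_pos <- sum(Y)
  neg <- sample_negatives(Y, 1, seed = 9)
  expect_equal(nrow(neg), n_pos)
  expect_true(all(Y[cbind(neg$lnc_id, neg$prot_id)] == 0))
  expect_identical(neg, sample_negatives(Y, 1, seed = 9))
  expect_equal(nrow(sample_negatives(Y, 0.5, seed = 9)), round(0.5 * n_pos))
  expect_error(sample_negatives(Y, 1e6, seed = 9), "not enough")
})

test_that("negative sampling is uniform over the zero cells", {
  Y <- interaction_matrix(matrix(c(1L, rep(0L, 8)), 3, 3,
                                 dimnames = list(paste0("l", 1:3), paste0("p", 1:3))))
  draws <- table(unlist(lapply(1:1000, function(s) {
    neg <- sample_negatives(Y, 1, seed = s)
    paste(neg$lnc_id, neg$prot_id)
  })))
  expect_length(draws, 8)
  expect_true(all(abs(draws / 1000 - 0.125) < 0.04))
})

test_that("CV_L folds partition the lncRNAs and never leak entities", {
  inst <- random_instance(90)
  Y10 <- interaction_matrix(matrix(0L, 10, 4,
                                   dimnames = list(paste0("l", 1:10), paste0("p", 1:4))))
  Y10[cbind(1:10, rep(1:4, length.out = 10))] <- 1L
  pairs <- rbind(positive_pairs(Y10), sample_negatives(Y10, 1, 1))
  splits <- make_splits("CV_L", Y10, pairs, 5, seed = 2)
  held <- lapply(splits, function(sp) unique(sp$test$lnc_id))
  expect_true(all(lengths(held) == 2))
  expect_setequal(unlist(held), rownames(Y10))
  expect_equal(sum(lengths(held)), 10) # pairwise disjoint
  for (sp in splits) audit_split(sp)
})

test_that("CV_LP folds partition the pair list exactly", {
  inst <- random_instance(91)
  splits <- make_splits("CV_LP", inst$Y, inst$pairs, 5, seed = 3)
  key <- function(d) paste(d$lnc_id, d$prot_id, d$label)
  test_keys <- unlist(lapply(splits, function(sp) key(sp$test)))
  expect_setequal(test_keys, key(inst$pairs))
  expect_equal(length(test_keys), nrow(inst$pairs))
  for (sp in splits) {
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(inst$pairs))
  }
})

test_that("CV_IND keeps only within-train and within-test pairs, dropping cross edges", {
  # complete bipartite 5x5 with 1 test lncRNA and 1 test protein:
  # 16 train pairs, 1 test pair, 8 discarded cross pairs
  Y <- interaction_matrix(matrix(1L, 5, 5,
                                 dimnames = list(paste0("l", 1:5), paste0("p", 1:5))))
  pairs <- positive_pairs(Y)
  splits <- make_splits("CV_IND", Y, pairs, n_folds = 5, seed = 4)
  for (sp in splits) {
    expect_equal(nrow(sp$train), 16)
    expect_equal(nrow(sp$test), 1)
    expect_equal(nrow(pairs) - nrow(sp$train) - nrow(sp$test), 8)
    audit_split(sp)
  }
})

test_that("every scheme passes the leakage audit on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(200 + seed)
    for (scheme in c("CV_L", "CV_P", "CV_LP", "CV_IND")) {
      for (sp in make_splits(scheme, inst$Y, inst$pairs, 5, seed = seed)) {
        audit_split(sp)
      }
    }
  }
  expect_error(make_splits("CV_L", random_instance(1)$Y[1:3, ],
                           random_instance(1)$pairs, 5, 1), "fewer entities")
})

test_that("threshold metrics and AUC/AUPR match their definitions", {
  m <- compute_metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(m$auc, 0.75)
  expect_equal(m$precision, 0.5) # predictions (1,1,0,0): one true, one false positive
  expect_equal(m$recall, 0.5)
  expect_equal(m$accuracy, 0.5)
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)
  # all scores tied: AUC 0.5 by the ties convention
  expect_equal(compute_metrics(c(1, 0, 1, 0), rep(0.3, 4))$auc, 0.5)
  # empty positive-prediction set: precision and F1 defined as 0
  m <- compute_metrics(c(1, 0), c(0.2, 0.1))
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("AUC agrees with the O(n^2) pairwise oracle, with and without ties", {
  withr::with_seed(92, {
    for (rep in 1:20) {
      n <- sample(10:200, 1)
      y <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      s <- round(runif(n), sample(c(1, 2, 6), 1)) # coarse rounding forces ties
      expect_equal(compute_metrics(y, s)$auc, oracle_auc(y, s),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC and AUPR agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(93, {
    y <- sample(c(0, 1), 80, replace = TRUE)
    y[1:2] <- c(0, 1)
    s <- runif(80)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(compute_metrics(y, s)$auc, ref, tolerance = 1e-10)
  })
})

test_that("repeated experiments are reproducible and converge with repeats", {
  d <- generate_dataset(tiny_spec())
  cfg <- default_config()
  cfg$dnn$hidden_sizes <- c(16L, 8L)
  r1 <- run_experiment(d, "CV_LP", k_features = 10, config = cfg,
                       n_repeats = 2, seed = 5)
  r2 <- run_experiment(d, "CV_LP", k_features = 10, config = cfg,
                       n_repeats = 2, seed = 5)
  expect_equal(r1$per_fold, r2$per_fold)
  expect_equal(nrow(r1$per_fold), 10)
  expect_equal(nrow(r1$per_repeat), 2)
  # standard error of the fold mean shrinks with more folds aggregated
  auc <- r1$per_fold$auc
  se2 <- sd(auc[1:5]) / sqrt(5)
  se10 <- sd(auc) / sqrt(10)
  expect_true(is.finite(se10) && is.finite(se2))
  expect_lte(se10, se2 * 1.5 + 1e-9)
})

test_that("entity ranking hides the query and flags its known partners", {
  d <- generate_dataset(tiny_spec(seed = 8))
  # pick a lncRNA with at least two known partners
  deg <- rowSums(d$Y)
  q <- names(which(deg >= 2))[1]
  cfg <- default_config()
  cfg$dnn$hidden_sizes <- c(16L, 8L)
  rk <- rank_for_entity(d, q, "proteins_for_lncRNA", k_features = 10,
                        config = cfg, seed = 6)
  expect_equal(nrow(rk), ncol(d$Y))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_setequal(rk$prot_id, colnames(d$Y))
  expect_equal(sum(rk$known), sum(d$Y[q, ]))
  expect_error(rank_for_entity(d, "nope", "proteins_for_lncRNA"), "unknown entity")
})
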