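# well-separated 2-D Gaussian blobs; linearly separable with margin
make_blobs <- function(seed, n_per = 100, dist = 2.5, sd = 0.5) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(2 * n_per, -dist, sd), ncol = 2),
               matrix(rnorm(2 * n_per, dist, sd), ncol = 2))
    colnames(X) <- c("x1", "x2")
    list(X = X, y = rep(c(0L, 1L), each = n_per))
  })
}

blob_dnn_config <- function() {
  cfg <- default_config()$dnn
  cfg$hidden_sizes <- c(32L, 16L)
  cfg$learning_rate <- 0.01
  cfg$epochs <- 300L
  cfg
}

test_that("DNN trains to the early-stop accuracy on separable blobs", {
  d <- make_blobs(70)
  m <- train_dnn(d$X, d$y, blob_dnn_config(), seed = 1)
  expect_gte(m$train_accuracy, 0.99)
  expect_lt(m$epochs_run, 300) # early stop triggered
  s <- score_model(m, d$X)
  expect_true(all(s > 0 & s < 1))
  expect_gte(compute_metrics(d$y, s)$auc, 0.99)
})

test_that("DNN scoring is deterministic, bounded and dimension-checked", {
  d <- make_blobs(71, n_per = 40)
  m <- train_dnn(d$X, d$y, blob_dnn_config(), seed = 2)
  s1 <- score_dnn(m, d$X)
  s2 <- score_dnn(m, d$X)
  expect_identical(s1, s2)
  expect_identical(s1[1], s1[1 + 0]) # duplicated row scores identically
  dup <- rbind(d$X[1, ], d$X[1, ])
  sdup <- score_dnn(m, dup)
  expect_equal(sdup[1], sdup[2])
  expect_error(score_dnn(m, d$X[, 1, drop = FALSE]), "dimension")
  # retraining with the same seed reproduces the model exactly
  m2 <- train_dnn(d$X, d$y, blob_dnn_config(), seed = 2)
  expect_identical(score_dnn(m2, d$X), s1)
})

test_that("DNN training loss is non-increasing overall on the separable benchmark", {
  ok <- 0
  for (seed in 1:10) {
    d <- make_blobs(100 + seed, n_per = 50)
    cfg <- blob_dnn_config()
    cfg$epochs <- 30L
    cfg$early_stop_accuracy <- 1.01 # run all epochs
    bce <- function(m) {
      p <- score_dnn(m, d$X)
      -mean(d$y * log(p) + (1 - d$y) * log(1 - p))
    }
    cfg1 <- cfg; cfg1$epochs <- 5L
    cfg2 <- cfg
    l_early <- bce(train_dnn(d$X, d$y, cfg1, seed = seed))
    l_late <- bce(train_dnn(d$X, d$y, cfg2, seed = seed))
    if (l_late <= l_early) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("boosting leaf weight matches its closed form", {
  expect_equal(gbt_leaf_weight(c(1, 1), c(1, 1), 1), -2 / 3)
  expect_equal(gbt_leaf_weight(c(0, 0, 0), c(1, 2, 3), 0.5), 0)
  g <- c(0.3, -1.2, 0.8)
  h <- c(0.2, 0.9, 0.4)
  expect_equal(gbt_leaf_weight(3 * g, h, 0.7), 3 * gbt_leaf_weight(g, h, 0.7))
  # with lambda = 0 this is the Newton step -sum(g)/sum(h)
  expect_equal(gbt_leaf_weight(g, h, 0), -sum(g) / sum(h))
  expect_error(gbt_leaf_weight(c(1), c(1, 2), 1), "lengths")
})

test_that("split gain matches direct evaluation and its structural properties", {
  expect_equal(gbt_split_gain(3, 2, -3, 2, lambda = 1, gamma = 0), 3)
  # proportional split of a homogeneous leaf gains nothing
  expect_equal(gbt_split_gain(2, 3, 2, 3, lambda = 0, gamma = 0), 0)
  # additive penalty: strictly decreasing in gamma
  gains <- vapply(c(0, 0.5, 1, 2), function(gm)
    gbt_split_gain(3, 2, -1, 4, 1, gm), numeric(1))
  expect_true(all(diff(gains) < 0))
  withr::with_seed(72, {
    for (rep in 1:50) {
      GL <- rnorm(1); GR <- rnorm(1)
      HL <- runif(1, 0.1, 3); HR <- runif(1, 0.1, 3)
      lam <- runif(1, 0, 2); gam <- runif(1, 0, 1)
      direct <- 0.5 * (GL^2 / (HL + lam) + GR^2 / (HR + lam) -
                         (GL + GR)^2 / (HL + HR + lam)) - gam
      expect_equal(gbt_split_gain(GL, HL, GR, HR, lam, gam), direct,
                   tolerance = 1e-12)
      gsamp <- rnorm(4); hsamp <- runif(4, 0.1, 1)
      expect_equal(gbt_leaf_weight(gsamp, hsamp, lam),
                   -sum(gsamp) / (sum(hsamp) + lam), tolerance = 1e-12)
    }
  })
})

test_that("GBT separates a single-feature rule and a planted threshold rule", {
  withr::with_seed(73, {
    X <- matrix(runif(500 * 2), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
    y <- as.integer(X[, 1] > 0.5)
    tr <- sample(500, 400)
    m <- train_gbt(X[tr, ], y[tr], seed = 3)
    expect_gte(compute_metrics(y[tr], score_model(m, X[tr, ]))$auc, 0.999)
    expect_gte(compute_metrics(y[-tr], score_model(m, X[-tr, ]))$auc, 0.95)
    s <- score_model(m, X)
    expect_true(all(s >= 0 & s <= 1))
  })
})

test_that("C-SVM separates the two-point problem and standardizes columns", {
  # two-point separable problem: the sign-form decision rule is exact
  X <- matrix(c(0, 10), 2, 1, dimnames = list(NULL, "x"))
  m <- train_csvm(X, c(0, 1), seed = 4)
  Xs <- sweep(sweep(X, 2, m$center, "-"), 2, m$scale, "/")
  expect_equal(as.character(predict(m$svm, Xs)), c("neg", "pos"))
  # dual box constraint: |y_i alpha_i| <= C
  expect_true(all(abs(m$svm$coefs) <= m$config$C + 1e-8))

  d <- make_blobs(74, n_per = 30)
  m <- train_csvm(d$X, d$y, seed = 5)
  Xs <- sweep(sweep(d$X, 2, m$center, "-"), 2, m$scale, "/")
  expect_true(all(abs(colMeans(Xs)) < 1e-8))
  expect_true(all(abs(apply(Xs, 2, sd) - 1) < 1e-8))
  expect_gte(compute_metrics(d$y, score_model(m, d$X))$auc, 0.99)
  # zero-variance columns standardize to 0 rather than NaN
  X2 <- cbind(d$X, const = 1)
  m2 <- train_csvm(X2, d$y, seed = 5)
  Xs2 <- sweep(sweep(X2, 2, m2$center, "-"), 2, m2$scale, "/")
  expect_true(all(Xs2[, "const"] == 0))
})

test_that("all three classifiers hit AUC >= 0.95 on the separable benchmark", {
  d <- make_blobs(75)
  models <- list(train_dnn(d$X, d$y, blob_dnn_config(), seed = 6),
                 train_gbt(d$X, d$y, seed = 6),
                 train_csvm(d$X, d$y, seed = 6))
  for (m in models) {
    s <- score_model(m, d$X)
    expect_true(all(s >= 0 & s <= 1))
    expect_identical(score_model(m, d$X), s) # repeated call identical
    expect_length(score_model(m, d$X[0, , drop = FALSE]), 0)
    expect_gte(compute_metrics(d$y, s)$auc, 0.95)
  }
  expect_error(train_gbt(d$X, rep(1, nrow(d$X))), "both classes")
  expect_error(train_dnn(d$X, rep(0, nrow(d$X))), "both classes")
})
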