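#' Default pipeline configuration
#'
#' Hyperparameter defaults for the three base classifiers, the ensemble
#' weights, the feature-selection size and the descriptor parameters.
#' DNN: Adam at learning rate 1e-4, batch size 128, 100 epochs, dropout
#' 0.25, early stop once training accuracy reaches 0.99, two hidden ReLU
#' layers (256, 64). GBT: learning rate 0.1, 100 trees, depth 6, logistic
#' objective, column subsample 0.8, early stopping on a held-out 10%
#' validation split. SVM: RBF kernel, C = 1, automatic gamma (1/n_features),
#' probability outputs.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    dnn = list(hidden_sizes = c(256L, 64L), learning_rate = 1e-4,
               batch_size = 128L, epochs = 100L, dropout = 0.25,
               early_stop_accuracy = 0.99),
    gbt = list(learning_rate = 0.1, n_estimators = 100L, max_depth = 6L,
               objective = "binary:logistic", colsample = 0.8,
               validation_fraction = 0.1, early_stopping_rounds = 10L),
    svm = list(kernel = "radial", C = 1, gamma_mode = "auto",
               probability = TRUE),
    ensemble = list(alpha = 0.4, beta = 0.3, theta = 0.3, threshold = 0.5),
    selection = list(k = 500L),
    descriptors = list(kGap = 5L, kTuple = 3L)
  )
}

relu <- function(z) pmax(z, 0)

dnn_forward <- function(W, b, X) {
  nh <- length(W) - 1L
  a <- X
  for (l in seq_len(nh)) a <- relu(sweep(a %*% W[[l]], 2, b[[l]], "+"))
  z <- drop(a %*% W[[nh + 1L]] + b[[nh + 1L]])
  plogis(z)
}

#' Train the feed-forward neural network classifier
#'
#' A fully connected network with ReLU hidden layers and a single sigmoid
#' output unit, trained by minimizing binary cross-entropy with the Adam
#' optimizer. Inverted dropout is applied to hidden activations during
#' training. Training halts early once full-training-set accuracy (at the
#' 0.5 decision threshold) reaches `early_stop_accuracy`.
#'
#' @param X Numeric feature matrix (normalize first; see
#'   [min_max_normalize()]).
#' @param y Labels in `{0, 1}`; both classes required.
#' @param config DNN configuration (see [default_config()]`$dnn`).
#' @param seed Integer seed; initialization, shuffling and dropout are
#'   reproducible given the seed.
#' @return A `TrainedModel` list (`kind = "DNN"`) usable with
#'   [score_model()].
#' @export
train_dnn <- function(X, y, config = default_config()$dnn, seed = 1L) {
  y <- to_01(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (nrow(X) != length(y)) stop("X and y dimensions differ")
  storage.mode(X) <- "double"
  sizes <- c(ncol(X), config$hidden_sizes, 1L)
  nl <- length(sizes) - 1L
  keep <- 1 - config$dropout
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  lr <- config$learning_rate
  model <- with_seed(seed, {
    W <- lapply(seq_len(nl), function(l) {
      matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    step <- 0L
    n <- nrow(X)
    epochs_run <- 0L
    train_acc <- NA_real_
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        batch <- idx[s:min(s + config$batch_size - 1L, n)]
        Xb <- X[batch, , drop = FALSE]
        yb <- y[batch]
        B <- length(batch)
        # forward with inverted dropout on hidden activations
        act <- vector("list", nl)  # layer inputs (post-dropout)
        mask <- vector("list", nl - 1L)
        a <- Xb
        for (l in seq_len(nl - 1L)) {
          act[[l]] <- a
          h <- relu(sweep(a %*% W[[l]], 2, b[[l]], "+"))
          m <- matrix((runif(length(h)) < keep) / keep, nrow(h), ncol(h))
          mask[[l]] <- m * (h > 0) # combined relu/dropout gate for backprop
          a <- h * m
        }
        act[[nl]] <- a
        p <- plogis(drop(a %*% W[[nl]] + b[[nl]]))
        # backprop of mean binary cross-entropy
        delta <- matrix((p - yb) / B, B, 1)
        gW <- vector("list", nl); gb <- vector("list", nl)
        for (l in rev(seq_len(nl))) {
          gW[[l]] <- crossprod(act[[l]], delta)
          gb[[l]] <- colSums(delta)
          if (l > 1L) delta <- (delta %*% t(W[[l]])) * mask[[l - 1L]]
        }
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (l in seq_len(nl)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
          W[[l]] <- W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + adam_eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
          b[[l]] <- b[[l]] - lr * corr * mb[[l]] / (sqrt(vb[[l]]) + adam_eps)
        }
      }
      epochs_run <- epoch
      train_acc <- mean((dnn_forward(W, b, X) > 0.5) == (y == 1))
      if (train_acc >= config$early_stop_accuracy) break
    }
    list(W = W, b = b, epochs_run = epochs_run, train_accuracy = train_acc)
  })
  structure(list(kind = "DNN", W = model$W, b = model$b,
                 input_dim = ncol(X), config = config, seed = seed,
                 epochs_run = model$epochs_run,
                 train_accuracy = model$train_accuracy),
            class = "lpi_model")
}

#' Score new samples with a trained DNN
#'
#' @param model A DNN `TrainedModel`.
#' @param X Matrix with `model$input_dim` columns.
#' @return Sigmoid outputs in (0, 1), one per row.
#' @export
score_dnn <- function(model, X) {
  if (model$kind != "DNN") stop("not a DNN model")
  if (ncol(X) != model$input_dim) stop("input dimension mismatch")
  if (nrow(X) == 0) return(numeric(0))
  p <- dnn_forward(model$W, model$b, X)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Optimal leaf weight of the second-order boosting objective
#'
#' For the samples routed to one leaf, the weight minimizing the
#' regularized second-order approximation of the loss is
#' `-(sum g) / (sum h + lambda)`.
#'
#' @param g_values First-order gradients of the samples in the leaf.
#' @param h_values Second-order gradients (Hessians), same length.
#' @param lambda L2 regularization on leaf weights.
#' @return The optimal leaf weight.
#' @export
gbt_leaf_weight <- function(g_values, h_values, lambda) {
  if (length(g_values) != length(h_values)) stop("g and h lengths differ")
  den <- sum(h_values) + lambda
  if (den == 0) stop("sum(h) + lambda must be nonzero")
  -sum(g_values) / den
}

#' Loss reduction of a candidate split
#'
#' `gain = 1/2 [ G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda)
#'               - (G_L+G_R)^2/(H_L+H_R+lambda) ] - gamma`,
#' the structure score improvement of splitting one leaf into two, minus
#' the complexity penalty for the extra leaf.
#'
#' @param G_L,H_L Gradient/Hessian sums on the left child.
#' @param G_R,H_R Gradient/Hessian sums on the right child.
#' @param lambda L2 regularization on leaf weights.
#' @param gamma Per-leaf complexity penalty.
#' @return The split gain.
#' @export
gbt_split_gain <- function(G_L, H_L, G_R, H_R, lambda, gamma) {
  if (H_L + lambda <= 0 || H_R + lambda <= 0 || H_L + H_R + lambda <= 0) {
    stop("Hessian sums plus lambda must be positive")
  }
  0.5 * (G_L^2 / (H_L + lambda) + G_R^2 / (H_R + lambda) -
           (G_L + G_R)^2 / (H_L + H_R + lambda)) - gamma
}

#' Train the gradient-boosted tree classifier
#'
#' An additive tree ensemble under the logistic objective, delegated to
#' xgboost with the configured hyperparameters (learning rate, tree count,
#' depth, column subsampling). A seeded 10% validation split of the
#' training rows drives early stopping; if the split would leave either
#' part single-class the model trains for the full round budget instead.
#'
#' @param X Numeric feature matrix.
#' @param y Labels in `{0, 1}`; both classes required.
#' @param config GBT configuration (see [default_config()]`$gbt`).
#' @param seed Integer seed for the validation split and tree growing.
#' @return A `TrainedModel` list (`kind = "GBT"`).
#' @export
train_gbt <- function(X, y, config = default_config()$gbt, seed = 1L) {
  y <- to_01(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  storage.mode(X) <- "double"
  n <- nrow(X)
  n_val <- floor(config$validation_fraction * n)
  val_idx <- if (n_val >= 1) with_seed(derive_seed(seed, 1), sample.int(n, n_val)) else integer(0)
  use_val <- length(val_idx) >= 1 &&
    length(unique(y[val_idx])) == 2 && length(unique(y[-val_idx])) == 2
  params <- list(objective = config$objective, eta = config$learning_rate,
                 max_depth = config$max_depth,
                 colsample_bytree = config$colsample,
                 nthread = 1L, seed = seed)
  fit <- if (use_val) {
    dtrain <- xgboost::xgb.DMatrix(X[-val_idx, , drop = FALSE],
                                   label = y[-val_idx])
    dval <- xgboost::xgb.DMatrix(X[val_idx, , drop = FALSE],
                                 label = y[val_idx])
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = config$n_estimators,
                       evals = list(val = dval),
                       early_stopping_rounds = config$early_stopping_rounds,
                       verbose = 0)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    xgboost::xgb.train(params = params, data = dtrain,
                       nrounds = config$n_estimators, verbose = 0)
  }
  structure(list(kind = "GBT", booster = fit, input_dim = ncol(X),
                 config = config, seed = seed),
            class = "lpi_model")
}

#' Train the soft-margin RBF C-SVM classifier
#'
#' Columns are standardized to zero mean and unit variance with training
#' statistics (stored in the model and re-applied at scoring time;
#' zero-variance columns map to 0). The dual problem is solved by the
#' libsvm backend with Platt-style probability calibration so the model
#' returns interaction probabilities for the ensemble.
#'
#' @param X Numeric feature matrix.
#' @param y Labels in `{0, 1}` (internally mapped to `{-1, +1}`).
#' @param config SVM configuration (see [default_config()]`$svm`);
#'   `gamma_mode = "auto"` uses `1 / ncol(X)`.
#' @param seed Integer seed for the probability-calibration folds.
#' @return A `TrainedModel` list (`kind = "SVM"`).
#' @export
train_csvm <- function(X, y, config = default_config()$svm, seed = 1L) {
  y <- to_01(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  storage.mode(X) <- "double"
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma == 0] <- Inf # zero-variance columns standardize to 0
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sigma, "/")
  gamma <- if (identical(config$gamma_mode, "auto")) 1 / ncol(X) else as.numeric(config$gamma_mode)
  yf <- factor(ifelse(y == 1, "pos", "neg"), levels = c("neg", "pos"))
  fit <- with_seed(seed, e1071::svm(Xs, yf, type = "C-classification",
                                    kernel = config$kernel, cost = config$C,
                                    gamma = gamma,
                                    probability = isTRUE(config$probability),
                                    scale = FALSE))
  structure(list(kind = "SVM", svm = fit, center = mu, scale = sigma,
                 input_dim = ncol(X), config = config, seed = seed),
            class = "lpi_model")
}

#' Score samples with any trained base classifier
#'
#' Uniform scoring facade: applies the model's stored preprocessing (SVM
#' standardization) and returns interaction probabilities in `[0, 1]`.
#'
#' @param model A `TrainedModel` from [train_dnn()], [train_gbt()] or
#'   [train_csvm()].
#' @param X Matrix with `model$input_dim` columns.
#' @return Numeric score vector, one entry per row of `X`.
#' @export
score_model <- function(model, X) {
  if (!inherits(model, "lpi_model")) stop("not a fitted model")
  if (ncol(X) != model$input_dim) stop("input dimension mismatch")
  if (nrow(X) == 0) return(numeric(0))
  storage.mode(X) <- "double"
  switch(model$kind,
    DNN = score_dnn(model, X),
    GBT = {
      p <- predict(model$booster, xgboost::xgb.DMatrix(X))
      as.numeric(p)
    },
    SVM = {
      Xs <- sweep(sweep(X, 2, model$center, "-"), 2, model$scale, "/")
      pred <- predict(model$svm, Xs, probability = TRUE)
      as.numeric(attr(pred, "probabilities")[, "pos"])
    },
    stop("unknown model kind: ", model$kind))
}
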