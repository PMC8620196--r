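#' Initialize AdaBoost sample weights
#'
#' @param n Number of samples (>= 1).
#' @return Numeric vector of length `n`, all entries `1/n`.
#' @export
init_weights <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  rep(1 / n, n)
}

#' Fit a weighted decision stump on one feature
#'
#' The weak learner of the selection loop: a depth-1 threshold classifier.
#' Polarity +1 predicts +1 where `x <= threshold` and -1 elsewhere;
#' polarity -1 flips both sides. Candidate thresholds are the midpoints
#' between consecutive distinct sorted values plus `-Inf`/`+Inf` sentinels.
#' The stump minimizing the weighted misclassification is returned; ties go
#' to the smaller threshold, then polarity +1.
#'
#' @param column Numeric feature values.
#' @param y Labels in `{-1, +1}` (or `{0, 1}`, converted).
#' @param D Sample weights summing to 1.
#' @return List with class `stump`: `threshold`, `polarity`,
#'   `weighted_error`, and `feature_name` (NA here; set by
#'   [select_features()]).
#' @export
fit_stump <- function(column, y, D = init_weights(length(y))) {
  y <- to_pm1(y)
  n <- length(column)
  if (length(y) != n || length(D) != n) stop("column, y and D lengths differ")
  o <- order(column)
  xs <- column[o]
  delta <- ifelse(y[o] > 0, -D[o], D[o])
  wpos <- sum(D[y > 0])
  # err[s+1] = weighted error of polarity +1 with the first s sorted points
  # on the <= side; sequential cumsum mirrors the compiled scan exactly
  err <- wpos + c(0, cumsum(delta))
  thr <- c(-Inf, (xs[-1] + xs[-n]) / 2, Inf)
  valid <- c(TRUE, xs[-1] > xs[-n], TRUE)
  best <- list(eps = Inf, thr = -Inf, pol = 1L)
  for (s in which(valid)) {
    if (err[s] < best$eps) best <- list(eps = err[s], thr = thr[s], pol = 1L)
    if (1 - err[s] < best$eps) best <- list(eps = 1 - err[s], thr = thr[s], pol = -1L)
  }
  structure(list(feature_name = NA_character_, threshold = best$thr,
                 polarity = best$pol, weighted_error = best$eps),
            class = "stump")
}

#' Predict with a fitted stump
#'
#' @param object A `stump`.
#' @param column Feature values.
#' @param ... Unused.
#' @return Predictions in `{-1, +1}`.
#' @export
predict.stump <- function(object, column, ...) {
  if (object$threshold == Inf) return(rep(object$polarity, length(column)))
  if (object$threshold == -Inf) return(rep(-object$polarity, length(column)))
  ifelse(column <= object$threshold, object$polarity, -object$polarity)
}

#' Weak-classifier weight from its weighted error
#'
#' `beta = 0.5 * log((1 - eps) / eps)`, with `eps` clamped away from 0 and
#' 1 so a perfect stump never produces an infinite weight.
#'
#' @param eps Weighted error in `[0, 1]`.
#' @param clamp Clamping bound (default `1e-10`).
#' @return The classifier weight.
#' @export
compute_beta <- function(eps, clamp = 1e-10) {
  eps <- pmin(pmax(eps, clamp), 1 - clamp)
  0.5 * log((1 - eps) / eps)
}

#' AdaBoost sample-weight update
#'
#' Correctly classified samples are down-weighted by `exp(-beta)` and
#' misclassified samples up-weighted by `exp(beta)`; the result is
#' renormalized to sum to 1.
#'
#' @param D Current weights (summing to 1).
#' @param predictions Stump predictions in `{-1, +1}`.
#' @param y True labels in `{-1, +1}` (or `{0, 1}`).
#' @param beta Classifier weight from [compute_beta()].
#' @return Updated weight vector summing to 1.
#' @export
update_weights <- function(D, predictions, y, beta) {
  y <- to_pm1(y)
  predictions <- to_pm1(predictions)
  Dn <- D * ifelse(predictions == y, exp(-beta), exp(beta))
  Dn / sum(Dn)
}

#' AdaBoost forward feature selection
#'
#' Runs `k` boosting rounds over the candidate columns of `X`. Each round
#' fits one threshold stump per remaining feature under the current sample
#' weights, moves the minimum-error feature into the selected set (ties
#' broken by the lowest canonical column index), computes the classifier
#' weight and reweights samples with the winning stump's predictions.
#' Sample weights persist across rounds. The procedure is deterministic
#' given its inputs.
#'
#' @param X Numeric feature matrix (samples x features, named columns).
#' @param y Binary labels (`{0,1}` or `{-1,+1}`); both classes required.
#' @param k Number of features to select (`<= ncol(X)`).
#' @return List with class `selection_state`: `selected` (ordered feature
#'   names), `remaining`, `weights` (final sample weights), and `history`
#'   (`data.frame` of round, feature, epsilon, beta, threshold, polarity).
#' @export
select_features <- function(X, y, k) {
  y <- to_pm1(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  k <- as.integer(k)
  if (k > ncol(X)) stop("k exceeds the number of candidate features")
  if (k < 1L) stop("k must be >= 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  ORD <- apply(X, 2, order) - 1L # 0-based, stable; shared with the C++ scan
  if (!is.matrix(ORD)) ORD <- matrix(ORD, ncol = ncol(X))
  res <- select_core_cpp(X, ORD, as.integer(y), init_weights(nrow(X)),
                         k, 1e-10)
  selected <- colnames(X)[res$feature]
  history <- data.frame(round = seq_len(k), feature = selected,
                        epsilon = res$epsilon, beta = res$beta,
                        threshold = res$threshold, polarity = res$polarity,
                        stringsAsFactors = FALSE)
  structure(list(selected = selected,
                 remaining = setdiff(colnames(X), selected),
                 weights = res$D, history = history),
            class = "selection_state")
}

#' Persist a selection state as TSV
#'
#' @param state A `selection_state`.
#' @param path Output path; columns round, feature_name, epsilon, beta.
#' @return `path`, invisibly.
#' @export
write_selection <- function(state, path) {
  df <- data.frame(round = state$history$round,
                   feature_name = state$history$feature,
                   epsilon = state$history$epsilon,
                   beta = state$history$beta)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a feature matrix to selected columns
#'
#' @param X Feature matrix.
#' @param features Feature names, kept in the given (selection) order.
#' @return The column-restricted matrix.
#' @export
reduce_matrix <- function(X, features) {
  missing_f <- setdiff(features, colnames(X))
  if (length(missing_f) > 0) {
    stop("unknown feature name(s): ", paste(head(missing_f, 5), collapse = ", "))
  }
  X[, features, drop = FALSE]
}
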