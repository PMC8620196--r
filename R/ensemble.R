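#' Ensemble weights
#'
#' @param alpha Weight of the DNN score (default 0.4).
#' @param beta Weight of the GBT score (default 0.3).
#' @param theta Weight of the SVM score (default 0.3).
#' @return List with class `ensemble_weights`. All weights must be
#'   non-negative; the defaults sum to 1 so the combined score stays in
#'   `[0, 1]`.
#' @export
ensemble_weights <- function(alpha = 0.4, beta = 0.3, theta = 0.3) {
  if (any(c(alpha, beta, theta) < 0)) stop("ensemble weights must be >= 0")
  structure(list(alpha = alpha, beta = beta, theta = theta),
            class = "ensemble_weights")
}

#' Combine base-classifier scores into the hybrid interaction score
#'
#' `Score = alpha * p_dnn + beta * p_gbt + theta * p_svm`, elementwise.
#'
#' @param p_dnn,p_gbt,p_svm Score vectors of equal length with entries in
#'   `[0, 1]`.
#' @param w An [ensemble_weights()] object.
#' @return Combined score vector.
#' @export
combine_scores <- function(p_dnn, p_gbt, p_svm, w = ensemble_weights()) {
  if (length(p_gbt) != length(p_dnn) || length(p_svm) != length(p_dnn)) {
    stop("score vectors must have equal length")
  }
  rng <- range(c(p_dnn, p_gbt, p_svm, 0, 1))
  if (rng[1] < 0 || rng[2] > 1) stop("scores must lie in [0, 1]")
  w$alpha * p_dnn + w$beta * p_gbt + w$theta * p_svm
}

#' Hard interaction labels from scores
#'
#' Label 1 iff the score strictly exceeds the threshold (a score exactly at
#' the threshold is labeled 0).
#'
#' @param scores Finite score vector.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer labels in `{0, 1}`.
#' @export
decide <- function(scores, threshold = 0.5) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  as.integer(scores > threshold)
}
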