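# F1 with the +1 class as positive, from hard +1/-1 predictions
f1_score <- function(y_true, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == -1 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == -1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Choose the PLS component count by leave-one-out F1
#'
#' For each candidate component count up to `max_components`, a
#' leave-one-out cross-validation over the training samples fits a
#' PLS-DA (scaling recomputed per fold from the retained samples) and
#' predicts the held-out sample; the F1 score (positive class = +1) is
#' computed over the LOO predictions, and the smallest count achieving the
#' maximal F1 is returned.
#'
#' @param x_train Raw training matrix, samples x features.
#' @param y_train Class-coded +1 / -1 vector (both classes present).
#' @param max_components Upper bound on the component count (default 8).
#' @param scale Column scaling method (default `"pareto"`).
#' @return Integer component count in `[1, max_components]`.
#' @export
choose_n_components <- function(x_train, y_train, max_components = 8L,
                                scale = "pareto") {
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  if (n < 3L) abort("need >= 3 training samples")
  if (length(unique(y_train)) < 2L) abort("both classes must be present")
  kmax <- min(max_components, n - 2L, ncol(x_train))
  pred <- matrix(NA_real_, n, kmax)
  for (i in seq_len(n)) {
    sc <- scale_train(x_train[-i, , drop = FALSE], scale)
    if (stats::sd(y_train[-i]) == 0) next   # fold lost a whole class
    fit <- nipals_pls_fit(sc$x, y_train[-i], kmax)
    xi <- apply_scaling(x_train[i, , drop = FALSE], sc)
    for (k in seq_len(fit$n_components))
      pred[i, k] <- pls_predict(fit, xi, k)$y_hat
  }
  f1 <- vapply(seq_len(kmax), function(k) {
    ok <- !is.na(pred[, k])
    if (!any(ok)) return(0)
    f1_score(y_train[ok], ifelse(pred[ok, k] >= 0, 1, -1))
  }, numeric(1))
  which.max(f1)                             # ties go to fewer components
}

# stratified train/test split indices; >= 1 test sample per class
stratified_split <- function(y, test_fraction) {
  test <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_test <- max(1L, round(test_fraction * length(idx)))
    n_test <- min(n_test, length(idx) - 1L)
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

# one double-CV repeat: split, inner LOO component choice, final OPLS-DA,
# test-set Q2 and F1
double_cv_repeat <- function(x, y, test_fraction, max_components, scale,
                             prediction = "both") {
  test <- stratified_split(y, test_fraction)
  xtr <- x[-test, , drop = FALSE]; ytr <- y[-test]
  xte <- x[test, , drop = FALSE]; yte <- y[test]
  k <- choose_n_components(xtr, ytr, max_components, scale)
  model <- fit_final_opls_da(xtr, ytr, k, scale)
  pr <- predict_opls(model, xte, components = prediction)
  c(k = k, q2 = q2_score(yte, pr$y_hat, mean(ytr)),
    f1 = f1_score(yte, pr$class))
}

#' Double cross-validation for OPLS-DA
#'
#' The outer loop draws a stratified random 75/25 train/test split
#' (test-set class counts proportional to the class sizes, at least one
#' test sample per class); centering/scaling statistics come from the
#' training samples only. The inner loop picks the component count by
#' leave-one-out F1 ([choose_n_components()]); the final model is the
#' OPLS-filtered 2-component PLS-DA ([fit_final_opls_da()]); predictive
#' ability is the test-set Q2 with the training-mean denominator. The
#' procedure is repeated `n_repeats` times (2,000 by default) with fresh
#' random splits.
#'
#' @param x Raw feature matrix, samples x features.
#' @param y Class-coded +1 / -1 vector (each class >= 2 samples).
#' @param n_repeats Number of outer repeats (default 2000).
#' @param test_fraction Held-out fraction (default 0.25).
#' @param max_components Inner-loop bound (default 8).
#' @param seed Integer seed.
#' @param scale Column scaling method (default `"pareto"`).
#' @param prediction `"both"` components (default) or `"predictive"` only.
#' @return List of class `"double_cv_result"`: `repeats` (data frame with
#'   `k`, `q2`, `f1` per repeat), `q2_mean`, `q2_median`, `f1_mean`.
#' @export
double_cv <- function(x, y, n_repeats = 2000L, test_fraction = 0.25,
                      max_components = 8L, seed = 1L, scale = "pareto",
                      prediction = "both") {
  x <- as.matrix(x); y <- as.numeric(y)
  if (any(table(y) < 2L)) abort("each class needs >= 2 samples")
  set.seed(derive_seed(seed, "double_cv"))
  reps <- t(vapply(seq_len(n_repeats), function(i)
    double_cv_repeat(x, y, test_fraction, max_components, scale, prediction),
    numeric(3)))
  reps <- as.data.frame(reps)
  structure(list(repeats = reps, q2_mean = mean(reps$q2),
                 q2_median = stats::median(reps$q2),
                 f1_mean = mean(reps$f1)),
            class = "double_cv_result")
}

#' Permuted-label reference distribution for Q2
#'
#' Repeats the full double-CV procedure with class labels randomly
#' permuted before each repeat, giving the reference distribution against
#' which an observed Q2 is judged.
#'
#' @inheritParams double_cv
#' @return List with `q2` (per-repeat reference values), `q2_mean` and
#'   `q2_median`.
#' @export
permuted_reference_q2 <- function(x, y, n_repeats = 2000L,
                                  test_fraction = 0.25, max_components = 8L,
                                  seed = 1L, scale = "pareto",
                                  prediction = "both") {
  x <- as.matrix(x); y <- as.numeric(y)
  if (any(table(y) < 2L)) abort("each class needs >= 2 samples")
  set.seed(derive_seed(seed, "permuted_q2"))
  q2 <- vapply(seq_len(n_repeats), function(i) {
    yp <- sample(y)
    double_cv_repeat(x, yp, test_fraction, max_components, scale,
                     prediction)[["q2"]]
  }, numeric(1))
  list(q2 = q2, q2_mean = mean(q2), q2_median = stats::median(q2))
}
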