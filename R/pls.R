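# internal: column scaling for a training block
# method: "pareto" (sqrt sd), "unit" (sd), "none" (center only)
scale_train <- function(x, method = c("pareto", "unit", "none")) {
  method <- match.arg(method)
  ctr <- colMeans(x)
  scl <- rep(1, ncol(x))
  if (method != "none") {
    sds <- apply(x, 2, stats::sd)
    sds[sds <= 0] <- 1
    scl <- if (method == "pareto") sqrt(sds) else sds
  }
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl,
       method = method)
}

apply_scaling <- function(x_new, sc) {
  sweep(sweep(x_new, 2, sc$center), 2, sc$scale, "/")
}

#' Fit a PLS1 regression by the NIPALS algorithm
#'
#' Extracts components sequentially: weight `w = X'y` (normalized), score
#' `t = Xw`, y-loading `q = t'y / t't`, x-loading `p = X't / t't`, then
#' deflation of both blocks. With a single response the NIPALS inner loop
#' converges in one pass, so each component is closed-form. Successive
#' score vectors are mutually orthogonal.
#'
#' @param x Centered (and scaled) predictor matrix, samples x features.
#' @param y Response vector, conventionally class-coded +1 / -1.
#' @param n_components Number of components (bounded by `min(n - 1, p)`).
#' @return List of class `"pls_model"` with `weights` W, `loadings` P,
#'   `scores` T, `y_loadings` q, `coefficients` B (for each component
#'   count up to `n_components`) and the component count actually
#'   extracted.
#' @export
nipals_pls_fit <- function(x, y, n_components) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (stats::sd(y) == 0) abort("response has zero variance")
  n <- nrow(x); p <- ncol(x)
  n_components <- min(n_components, n - 1L, p)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0); Tm <- matrix(0, n, 0)
  qv <- numeric(0)
  xr <- x; yr <- y
  for (a in seq_len(n_components)) {
    w <- crossprod(xr, yr)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- as.numeric(xr %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-12) break
    qa <- sum(tt * yr) / t2
    pa <- crossprod(xr, tt) / t2
    xr <- xr - tcrossprod(tt, pa)
    yr <- yr - tt * qa
    W <- cbind(W, w); P <- cbind(P, pa); Tm <- cbind(Tm, tt)
    qv <- c(qv, qa)
  }
  if (ncol(W) == 0L) abort("no PLS component could be extracted")
  structure(list(weights = W, loadings = P, scores = Tm, y_loadings = qv,
                 n_components = ncol(W)),
            class = "pls_model")
}

# regression coefficients using the first k components: B = W (P'W)^-1 q
pls_coefficients <- function(model, k = model$n_components) {
  W <- model$weights[, seq_len(k), drop = FALSE]
  P <- model$loadings[, seq_len(k), drop = FALSE]
  q <- model$y_loadings[seq_len(k)]
  W %*% solve(crossprod(P, W), q)
}

#' Predict from a fitted PLS model
#'
#' Continuous prediction `y_hat = X_new B` from the regression-coefficient
#' form of the model (the new data must already be centered/scaled with the
#' training statistics). The hard class is `sign(y_hat)` under +1/-1
#' coding, with the tie `y_hat = 0` assigned to class +1.
#'
#' @param model A [nipals_pls_fit()] model.
#' @param x_new Matrix of new observations (training feature space).
#' @param k Number of components to use (default: all fitted).
#' @return List with `y_hat` (numeric) and `class` (+1 / -1).
#' @export
pls_predict <- function(model, x_new, k = model$n_components) {
  x_new <- as.matrix(x_new)
  if (ncol(x_new) != nrow(model$weights))
    abort("x_new has %d features; model was trained on %d",
          ncol(x_new), nrow(model$weights))
  y_hat <- as.numeric(x_new %*% pls_coefficients(model, k))
  list(y_hat = y_hat, class = ifelse(y_hat >= 0, 1, -1))
}

#' Predictive ability Q-squared
#'
#' `Q2 = 1 - sum((y - y_hat)^2) / sum((y - y_train_mean)^2)`: the
#' fraction of held-out response variance (about the training mean)
#' explained by the predictions. At most 1; near or below 0 for
#' uninformative models.
#'
#' @param y_true Observed responses (class-coded).
#' @param y_hat Continuous predictions.
#' @param y_train_mean Mean of the training-set responses.
#' @return Scalar Q2.
#' @export
q2_score <- function(y_true, y_hat, y_train_mean) {
  stopifnot(length(y_true) == length(y_hat))
  denom <- sum((y_true - y_train_mean)^2)
  if (denom <= 0)
    abort("test set has no response variance about the training mean; stratify the split")
  1 - sum((y_true - y_hat)^2) / denom
}
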