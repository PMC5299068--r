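#' Orthogonal signal correction filter (OPLS)
#'
#' Iteratively removes variation orthogonal to the response: at each pass
#' the PLS weight `w` and loading `p` are computed, the orthogonal weight
#' is the part of `p` not collinear with `w`
#' (`w_orth = p - (w'p) w`, normalized), and the component
#' `t_orth = X w_orth`, `p_orth = X' t_orth / t_orth' t_orth` is deflated
#' from X. Orthogonal scores are uncorrelated with `y` by construction.
#' Stops early (recording the actual count) if no orthogonal variation
#' remains.
#'
#' @param x Centered/scaled matrix, samples x features.
#' @param y Class-coded response.
#' @param n_orthogonal Number of filter components (0 = identity).
#' @return List with `x_filtered`, `w_orth`, `p_orth`, `t_orth` (matrices
#'   with one column per extracted component) and `n_orthogonal` actually
#'   removed.
#' @export
opls_filter <- function(x, y, n_orthogonal) {
  x <- as.matrix(x); y <- as.numeric(y)
  p_dim <- ncol(x)
  W <- matrix(0, p_dim, 0); P <- matrix(0, p_dim, 0)
  Tm <- matrix(0, nrow(x), 0)
  xr <- x
  n_done <- 0L
  while (n_done < n_orthogonal) {
    w <- crossprod(xr, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- as.numeric(xr %*% w)
    p <- crossprod(xr, tt) / sum(tt^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    nw_o <- sqrt(sum(w_o^2))
    if (nw_o < 1e-10) break                 # no orthogonal variation left
    w_o <- w_o / nw_o
    t_o <- as.numeric(xr %*% w_o)
    t2 <- sum(t_o^2)
    if (t2 < 1e-12) break
    p_o <- crossprod(xr, t_o) / t2
    xr <- xr - tcrossprod(t_o, p_o)
    W <- cbind(W, w_o); P <- cbind(P, p_o); Tm <- cbind(Tm, t_o)
    n_done <- n_done + 1L
  }
  list(x_filtered = xr, w_orth = W, p_orth = P, t_orth = Tm,
       n_orthogonal = n_done)
}

#' Fit the final OPLS-DA model for a chosen component count
#'
#' Implements the published rule: the chosen number of components minus one
#' is used as an OPLS filter, and a two-component NIPALS PLS-DA is fitted
#' on the filtered data, yielding one predictive and one within-model
#' orthogonal component (with `k_chosen = 1` the filter is the identity).
#' Prediction applies the training centering/scaling, removes the
#' orthogonal components from the new data, and uses the 2-component
#' regression. The predictive component is sign-fixed so that a positive
#' back-scaled loading means elevated in the +1 class.
#'
#' @param x_train Raw (unscaled) training matrix, samples x features.
#' @param y_train Class-coded +1 / -1 response.
#' @param k_chosen Component count from [choose_n_components()] (>= 1).
#' @param scale Column scaling: `"pareto"` (default), `"unit"`, `"none"`.
#' @return List of class `"opls_model"`: scaling statistics, the filter,
#'   the embedded [nipals_pls_fit()] model, and `y_train_mean`.
#' @export
fit_final_opls_da <- function(x_train, y_train, k_chosen,
                              scale = "pareto") {
  if (k_chosen < 1L) abort("k_chosen must be >= 1")
  sc <- scale_train(as.matrix(x_train), scale)
  filt <- opls_filter(sc$x, y_train, k_chosen - 1L)
  pls <- nipals_pls_fit(filt$x_filtered, y_train,
                        min(2L, nrow(sc$x) - 1L, ncol(sc$x)))
  if (pls$y_loadings[1L] < 0) {             # sign convention on component 1
    pls$weights[, 1L] <- -pls$weights[, 1L]
    pls$loadings[, 1L] <- -pls$loadings[, 1L]
    pls$scores[, 1L] <- -pls$scores[, 1L]
    pls$y_loadings[1L] <- -pls$y_loadings[1L]
  }
  structure(list(scaling = sc, filter = filt, pls = pls,
                 k_chosen = as.integer(k_chosen),
                 y_train_mean = mean(y_train)),
            class = "opls_model")
}

#' Predict from a fitted OPLS-DA model
#'
#' @param model An [fit_final_opls_da()] model.
#' @param x_new Raw matrix of new observations.
#' @param components `"both"` (default; the 2-component regression) or
#'   `"predictive"` (component 1 only).
#' @return List with `y_hat`, `class`, and the new orthogonal scores.
#' @export
predict_opls <- function(model, x_new, components = c("both", "predictive")) {
  components <- match.arg(components)
  xs <- apply_scaling(as.matrix(x_new), model$scaling)
  t_orth_new <- NULL
  if (model$filter$n_orthogonal > 0L) {
    for (j in seq_len(model$filter$n_orthogonal)) {
      t_o <- as.numeric(xs %*% model$filter$w_orth[, j])
      xs <- xs - tcrossprod(t_o, model$filter$p_orth[, j])
      t_orth_new <- cbind(t_orth_new, t_o)
    }
  }
  k <- if (components == "predictive") 1L else model$pls$n_components
  pred <- pls_predict(model$pls, xs, k)
  c(pred, list(t_orth = t_orth_new))
}

#' Back-scaled predictive loadings
#'
#' Multiplies the predictive-component loading vector elementwise by the
#' stored scaling factors so peak weights are interpretable on the
#' original intensity scale. Positive values mark features elevated in the
#' +1 class.
#'
#' @param model An [fit_final_opls_da()] model.
#' @param scale_factors Optional override of the stored factors.
#' @return Named numeric vector, one entry per feature.
#' @export
backscaled_loadings <- function(model, scale_factors = NULL) {
  scl <- scale_factors %||% model$scaling$scale
  if (is.null(scl)) abort("no scale factors stored in the model")
  load1 <- model$pls$loadings[, 1L]
  stats::setNames(load1 * scl, rownames(model$pls$loadings) %||%
                    names(model$scaling$center))
}
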