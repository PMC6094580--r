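# PLS1 regression (NIPALS) with autoscaling and Monte-Carlo-resampling
# selection of the number of components.

#' Center and scale a predictor matrix (and optionally a response)
#'
#' Each column is centered to mean 0 and scaled to unit variance (SD with
#' denominator n - 1). The parameters are returned so the same transform can
#' be applied to new data.
#'
#' @param X Numeric matrix, n x p.
#' @param y Optional numeric response vector.
#' @return List with `X`, `y` (scaled copies) and `params`, a `scaling_params`
#'   object holding `x_center`, `x_scale`, `y_center`, `y_scale`.
#' @export
autoscale <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  bad <- which(scl == 0)
  if (length(bad))
    stop("zero-variance column(s): ",
         paste(if (is.null(colnames(X))) bad else colnames(X)[bad],
               collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- ysc <- NULL
  ys <- NULL
  if (!is.null(y)) {
    yc <- mean(y); ysc <- stats::sd(y)
    if (ysc == 0) stop("zero-variance response")
    ys <- (y - yc) / ysc
  }
  params <- structure(list(x_center = ctr, x_scale = scl,
                           y_center = yc, y_scale = ysc),
                      class = "scaling_params")
  list(X = Xs, y = ys, params = params)
}

apply_scaling <- function(params, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$x_center))
    stop("column count mismatch: model expects ", length(params$x_center),
         " variables")
  sweep(sweep(X, 2, params$x_center), 2, params$x_scale, "/")
}

#' Fit a single-response PLS (PLS1) regression model
#'
#' NIPALS recursion with X-deflation: at each step the weight vector is the
#' normalized covariance direction `X'y`, scores are `t = Xw`, loadings
#' `p = X't/(t't)`, `q = y't/(t't)`, and X (and y) are deflated by the rank-1
#' score contribution. The regression vector on the standardized scale is
#' `b = W (P'W)^{-1} q`. If the residual covariance vanishes before `ncomp`
#' components, the model stops early with a status flag.
#'
#' @param X Predictor matrix (original units unless `scale = FALSE`).
#' @param y Response vector.
#' @param ncomp Number of latent components A (1 <= A <= min(n-1, p)).
#' @param scale If `TRUE` (default) autoscale X and y internally; set to
#'   `FALSE` when X and y are already centered/scaled (identity scaling is
#'   then stored).
#' @return Object of class `pls1`: weights `W` (p x A), X-loadings `P`,
#'   y-loadings `q`, scores `T`, per-component-count coefficient matrix `B`
#'   (column A holds the regression vector using components 1..A), regression
#'   vector `b = B[, ncomp]`, cumulative training `r2`, `scaling`, and the
#'   scaled training data `Xs`, `ys`.
#' @export
fit_pls1 <- function(X, y, ncomp, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be in 1..min(n-1, p)")
  if (scale) {
    sc <- autoscale(X, y)
    Xs <- sc$X; ys <- sc$y; params <- sc$params
  } else {
    Xs <- X; ys <- as.numeric(y)
    params <- structure(list(x_center = rep(0, p), x_scale = rep(1, p),
                             y_center = 0, y_scale = 1),
                        class = "scaling_params")
  }
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  qv <- numeric(ncomp)
  r2 <- numeric(ncomp)
  Xa <- Xs; ya <- ys
  sst <- sum(ys^2)
  converged <- TRUE
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    wv <- crossprod(Xa, ya)
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12 * max(1, sst)) { converged <- FALSE; break }
    wv <- wv / nw
    tv <- Xa %*% wv
    tt <- sum(tv^2)
    pv <- crossprod(Xa, tv) / tt
    qa <- sum(ya * tv) / tt
    Xa <- Xa - tcrossprod(tv, pv)
    ya <- ya - qa * tv
    W[, a] <- wv; P[, a] <- pv; Tm[, a] <- tv; qv[a] <- qa
    r2[a] <- 1 - sum(ya^2) / sst
    a_done <- a
  }
  if (a_done == 0L) stop("X'y is zero: no covariance to model")
  W <- W[, 1:a_done, drop = FALSE]; P <- P[, 1:a_done, drop = FALSE]
  Tm <- Tm[, 1:a_done, drop = FALSE]; qv <- qv[1:a_done]; r2 <- r2[1:a_done]
  # regression vectors for every cumulative component count
  B <- matrix(0, p, a_done)
  for (a in 1:a_done) {
    Wa <- W[, 1:a, drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(P[, 1:a, drop = FALSE], Wa), qv[1:a])
  }
  dimnames(B) <- list(colnames(X), NULL)
  structure(
    list(ncomp = a_done, requested_ncomp = ncomp, converged = converged,
         W = W, P = P, q = qv, T = Tm, B = B, b = B[, a_done],
         r2 = r2, scaling = params, Xs = Xs, ys = ys,
         var_names = colnames(X)),
    class = "pls1")
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("<pls1> %d component(s), p = %d, n = %d; training R2 = %s\n",
              x$ncomp, nrow(x$B), nrow(x$Xs),
              paste(sprintf("%.3f", x$r2), collapse = " ")))
  invisible(x)
}

#' Predict from a fitted PLS1 model
#'
#' @param object A `pls1` model.
#' @param newdata Matrix with the same columns as the training X.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Predictions on the original response scale.
#' @export
predict.pls1 <- function(object, newdata, ncomp = object$ncomp, ...) {
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  Xs <- apply_scaling(object$scaling, newdata)
  yhat_s <- drop(Xs %*% object$B[, ncomp])
  object$scaling$y_center + object$scaling$y_scale * yhat_s
}

#' Select the number of PLS components by Monte-Carlo resampling
#'
#' Repeatedly splits the subjects at random into a training half and an
#' external validation half, fits PLS1 models with 1..`a_max` components on
#' the training half (scaling re-estimated there each time), and records the
#' root-mean-squared error of prediction (RMSEP) on the validation half. The
#' selected component count minimizes the across-repetition median RMSEP;
#' ties go to the smaller count. A model whose best median RMSEP is no better
#' than the mean-only (zero-component) predictor is flagged as having no
#' predictive value.
#'
#' @param X Predictor matrix (original units).
#' @param y Response vector.
#' @param repetitions Number of random splits (default 100).
#' @param holdout_fraction Fraction held out for validation (default 0.5).
#' @param a_max Maximum component count examined (default 10, capped by the
#'   training-half size and p); exceeding the feasible cap is an error.
#' @param seed Integer seed making the split sequence reproducible.
#' @return Object of class `pls_selection`: `a` (chosen count), `medians`
#'   (median RMSEP per count), `errors` (repetitions x a_max RMSEP matrix),
#'   `rmsep0` (mean-only RMSEP per repetition), `no_model` (logical), `seed`.
#' @export
select_components <- function(X, y, repetitions = 100,
                              holdout_fraction = 0.5, a_max = 10,
                              seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("need at least 10 subjects")
  n_val <- floor(n * holdout_fraction)
  n_train <- n - n_val
  if (a_max > min(n_train - 1, p))
    stop("a_max exceeds feasible maximum min(n_train - 1, p) = ",
         min(n_train - 1, p))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  errors <- matrix(NA_real_, repetitions, a_max)
  rmsep0 <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    val <- sample.int(n, n_val)
    fit <- fit_pls1(X[-val, , drop = FALSE], y[-val], a_max)
    Xs_val <- apply_scaling(fit$scaling, X[val, , drop = FALSE])
    pred_s <- Xs_val %*% fit$B                       # n_val x ncomp
    pred <- fit$scaling$y_center + fit$scaling$y_scale * pred_s
    res2 <- (pred - y[val])^2
    errors[r, seq_len(fit$ncomp)] <- sqrt(colMeans(res2))
    if (fit$ncomp < a_max)                            # early stop: carry last
      errors[r, (fit$ncomp + 1):a_max] <- errors[r, fit$ncomp]
    rmsep0[r] <- sqrt(mean((mean(y[-val]) - y[val])^2))
  }
  medians <- apply(errors, 2, stats::median)
  a <- which.min(medians)                             # ties -> smallest count
  structure(
    list(a = a, medians = medians, errors = errors, rmsep0 = rmsep0,
         no_model = medians[a] >= stats::median(rmsep0),
         repetitions = repetitions, holdout_fraction = holdout_fraction,
         a_max = a_max, seed = seed),
    class = "pls_selection")
}

#' @export
print.pls_selection <- function(x, ...) {
  cat(sprintf("<pls_selection> A* = %d (median RMSEP %.4f over %d reps)%s\n",
              x$a, x$medians[x$a], x$repetitions,
              if (x$no_model) " [no predictive model]" else ""))
  invisible(x)
}

#' Serialize a PLS1 model to JSON
#'
#' @param model A `pls1` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
pls_to_json <- function(model, path) {
  obj <- list(
    ncomp = model$ncomp,
    var_names = model$var_names,
    scaling = list(x_center = unname(model$scaling$x_center),
                   x_scale = unname(model$scaling$x_scale),
                   y_center = model$scaling$y_center,
                   y_scale = model$scaling$y_scale),
    W = unname(model$W), P = unname(model$P), q = model$q,
    b = unname(model$b), r2 = model$r2)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
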