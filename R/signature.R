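# Target projection, signed selectivity ratios with resampling confidence
# intervals, loading-pattern comparisons, and sensitivity analyses.

#' Collapse a PLS1 model to its single predictive component
#'
#' Target projection rotates a multi-component PLS model onto the one
#' direction spanned by its regression vector: `w_tp = b / ||b||`, scores
#' `t_tp = Xs w_tp`, loadings `p_tp = Xs' t_tp / (t_tp' t_tp)`. All the
#' predictive variance is concentrated in this single component — the rank-1
#' model reproduces the full model's fitted values exactly. Per-variable
#' explained and residual variances decompose the standardized X variance.
#'
#' @param model A fitted [fit_pls1()] model (A >= 1).
#' @return Object of class `target_projection`: `w_tp`, `t_tp`, `p_tp`,
#'   `v_expl`, `v_res` (per-variable variances, n-1 denominator), and the
#'   score-to-response slope `q_tp`.
#' @export
target_projection <- function(model) {
  b <- model$b
  nb <- sqrt(sum(b^2))
  if (nb < 1e-300) stop("null model: regression vector is zero")
  w_tp <- b / nb
  Xs <- model$Xs
  t_tp <- drop(Xs %*% w_tp)
  tt <- sum(t_tp^2)
  p_tp <- drop(crossprod(Xs, t_tp)) / tt
  E <- Xs - tcrossprod(t_tp, p_tp)
  n <- nrow(Xs)
  structure(
    list(w_tp = w_tp, t_tp = t_tp, p_tp = p_tp,
         v_expl = p_tp^2 * tt / (n - 1),
         v_res = colSums(E^2) / (n - 1),
         q_tp = sum(model$ys * t_tp) / tt,
         var_names = model$var_names, n = n),
    class = "target_projection")
}

#' Signed selectivity ratios
#'
#' For each variable, the ratio of variance explained by the target-projected
#' component to the residual variance, signed by the corresponding TP loading.
#' Large |SR| marks variables important for predicting the response; the sign
#' gives the direction of association.
#'
#' @param tp A [target_projection()] object.
#' @param inf_tol Residual variances below this are flagged as infinite SR.
#' @return Numeric vector of signed SRs (named when variable names exist);
#'   attribute `infinite` marks flagged variables.
#' @export
selectivity_ratios <- function(tp, inf_tol = 1e-12) {
  inf <- tp$v_res < inf_tol
  sr <- ifelse(inf, Inf, tp$v_expl / tp$v_res) * sign(tp$p_tp)
  names(sr) <- tp$var_names
  attr(sr, "infinite") <- inf
  sr
}

#' Resampling confidence intervals for selectivity ratios
#'
#' Recomputes the signed SR profile on each Monte-Carlo training half (the
#' same split machinery used for component selection, with the component
#' count held fixed). Intervals are either percentile intervals of the
#' resampled SRs (`method = "percentile"`, the default) or symmetric
#' normal-theory intervals around the full-sample point estimate using the
#' resampling standard deviation (`method = "normal"`, the jackknife-style
#' interval chemometrics software typically reports). A variable is deemed
#' significant when its interval excludes zero.
#'
#' @param X Predictor matrix (original units).
#' @param y Response vector.
#' @param ncomp Fixed component count (typically the selected A*).
#' @param repetitions Number of random half-splits (default 100).
#' @param holdout_fraction Fraction excluded from each refit (default 0.5).
#' @param level Confidence level (default 0.95).
#' @param method Interval construction; see Details.
#' @param seed Integer seed.
#' @return Data frame: `variable`, `sr` (full-sample point estimate), `lower`,
#'   `upper`, `significant`; attribute `draws` holds the repetitions x p SR
#'   matrix.
#' @export
sr_confidence_intervals <- function(X, y, ncomp, repetitions = 100,
                                    holdout_fraction = 0.5, level = 0.95,
                                    method = c("percentile", "normal"),
                                    seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  n_out <- floor(n * holdout_fraction)
  if (ncomp > min(n - n_out - 1, p)) stop("ncomp infeasible for split size")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  draws <- matrix(NA_real_, repetitions, p)
  for (r in seq_len(repetitions)) {
    keep <- sample.int(n, n - n_out)
    fit <- fit_pls1(X[keep, , drop = FALSE], y[keep], ncomp)
    draws[r, ] <- selectivity_ratios(target_projection(fit))
  }
  alpha <- (1 - level) / 2
  point <- selectivity_ratios(target_projection(fit_pls1(X, y, ncomp)))
  if (method == "percentile") {
    ci <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    lower <- ci[1, ]; upper <- ci[2, ]
  } else {
    z <- stats::qnorm(1 - alpha)
    sds <- apply(draws, 2, stats::sd, na.rm = TRUE)
    lower <- as.numeric(point) - z * sds
    upper <- as.numeric(point) + z * sds
  }
  out <- data.frame(
    variable = if (is.null(colnames(X))) paste0("V", 1:p) else colnames(X),
    sr = as.numeric(point), lower = lower, upper = upper)
  out$significant <- out$lower > 0 | out$upper < 0
  attr(out, "draws") <- draws
  out
}

#' SD-weighted target-projection loadings
#'
#' Multiplying each TP loading by the original-scale SD of its variable gives
#' the covariance between that variable and the predictive component — the
#' importance of a fixed change in minutes/day at each intensity. The
#' unweighted loadings (importance per SD) are returned alongside.
#'
#' @param tp A [target_projection()] object.
#' @param scaling The `scaling_params` stored in the fitted model.
#' @return Data frame: `variable`, `loading` (unweighted `p_tp`), `sd`
#'   (min/day), `weighted` (`p_tp * sd`).
#' @export
weighted_loadings <- function(tp, scaling) {
  if (length(scaling$x_scale) != length(tp$p_tp))
    stop("scaling and target projection have different variable counts")
  data.frame(
    variable = if (is.null(tp$var_names)) seq_along(tp$p_tp) else tp$var_names,
    loading = unname(tp$p_tp),
    sd = unname(scaling$x_scale),
    weighted = unname(tp$p_tp * scaling$x_scale))
}

#' Pearson correlation between two loading patterns
#'
#' Used e.g. to quantify agreement between sex-stratified signatures.
#'
#' @param loadings_a,loadings_b Numeric vectors of equal length >= 3.
#' @return Pearson's r.
#' @export
compare_patterns <- function(loadings_a, loadings_b) {
  stopifnot(length(loadings_a) == length(loadings_b), length(loadings_a) >= 3)
  if (stats::sd(loadings_a) == 0 || stats::sd(loadings_b) == 0)
    stop("zero-variance loading vector: correlation undefined")
  stats::cor(loadings_a, loadings_b)
}

#' Critical |r| for a two-sided Pearson correlation test
#'
#' The boundary value solving `t = r sqrt((n-2)/(1-r^2))` at the two-sided
#' alpha quantile of the t distribution with n - 2 degrees of freedom.
#'
#' @param n Sample size.
#' @param alpha Significance level (default 0.05).
#' @return The critical absolute correlation.
#' @export
r_significance_threshold <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(n - 2 + tc^2)
}

#' Univariate correlation profile of bins against adjusted outcomes
#'
#' Pearson correlations of each intensity bin with each (age/sex-adjusted)
#' outcome, with two-sided p-values from the t transform and a significance
#' flag at alpha = 0.05 (no multiplicity adjustment).
#'
#' @param X Bin matrix (n x p).
#' @param outcomes Matrix or data frame of adjusted outcome vectors.
#' @param alpha Significance level for flags.
#' @return A list with matrices `r`, `p` (bins x outcomes) and `significant`.
#' @export
univariate_profile <- function(X, outcomes, alpha = 0.05) {
  X <- as.matrix(X); Y <- as.matrix(outcomes)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  r <- stats::cor(X, Y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, significant = p < alpha, n = n)
}

#' Sensitivity of the sedentary-bin SR to its upper cut point
#'
#' Rebuilds the intensity spectrum from epoch-level data with alternative
#' upper edges for the first (sedentary) bin, keeping a contiguous partition
#' (default-scheme edges above the alternative edge are retained), refits the
#' model, and reports the sedentary bin's |SR| for each variant.
#'
#' @param streams List of [epoch_stream()] objects.
#' @param y Named response vector (names = subject ids); subjects lacking
#'   valid wear data are dropped with a message.
#' @param criteria A [wear_criteria()].
#' @param base_edges Lower edges of the reference scheme.
#' @param alt_first_edges Alternative upper edges for the sedentary bin.
#' @param ncomp Fixed component count; if `NULL`, selected per variant by
#'   [select_components()].
#' @param repetitions,a_max,seed Passed to [select_components()].
#' @return Data frame: `sed_upper`, `n_bins`, `a`, `sr_sed`, `abs_sr_sed`.
#' @export
sed_sensitivity <- function(streams, y, criteria = wear_criteria(),
                            base_edges = default_bin_edges(),
                            alt_first_edges = c(50, 100, 150, 250),
                            ncomp = NULL, repetitions = 100, a_max = 10,
                            seed = 1) {
  stopifnot(!is.null(names(y)))
  out <- vector("list", length(alt_first_edges))
  for (i in seq_along(alt_first_edges)) {
    e <- alt_first_edges[i]
    if (e <= 0 || e >= max(base_edges))
      stop("alternative sedentary edge must lie inside the base scheme")
    edges <- sort(unique(c(0, e, base_edges[base_edges > e])))
    scheme <- bin_scheme(edges)
    processed <- lapply(streams, process_stream, criteria = criteria,
                        scheme = scheme)
    sm <- spectrum_matrix(processed)
    ids <- intersect(rownames(sm$X), names(y))
    if (length(ids) < nrow(sm$X) || length(ids) < length(y))
      message("sed_sensitivity: ", length(ids), " subjects with both wear ",
              "and outcome data")
    Xv <- sm$X[ids, , drop = FALSE]
    yv <- y[ids]
    a <- if (is.null(ncomp)) {
      select_components(Xv, yv, repetitions = repetitions, a_max = a_max,
                        seed = seed)$a
    } else ncomp
    sr <- selectivity_ratios(target_projection(fit_pls1(Xv, yv, a)))
    out[[i]] <- data.frame(sed_upper = e, n_bins = ncol(Xv), a = a,
                           sr_sed = sr[1], abs_sr_sed = abs(sr[1]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full signature analysis for one outcome
#'
#' Convenience wrapper: selects the component count, fits the final model,
#' target-projects it, and returns the SR profile with confidence intervals
#' and SD-weighted loadings. If the minimum-median RMSEP does not beat the
#' mean-only predictor, the signature is flagged `no_model` and SR results
#' are still returned for inspection.
#'
#' @param X Bin matrix.
#' @param y Response vector.
#' @param repetitions,holdout_fraction,a_max,seed As in [select_components()].
#' @return Object of class `signature_profile`: `selection`, `model`, `tp`,
#'   `profile` (data frame with SR, CI, loadings), `no_model`.
#' @export
fit_signature <- function(X, y, repetitions = 100, holdout_fraction = 0.5,
                          a_max = 10, seed = 1) {
  sel <- select_components(X, y, repetitions = repetitions,
                           holdout_fraction = holdout_fraction,
                           a_max = a_max, seed = seed)
  model <- fit_pls1(X, y, sel$a)
  tp <- target_projection(model)
  ci <- sr_confidence_intervals(X, y, sel$a, repetitions = repetitions,
                                holdout_fraction = holdout_fraction,
                                seed = if (is.null(seed)) NULL else seed + 1L)
  wl <- weighted_loadings(tp, model$scaling)
  profile <- cbind(ci, loading = wl$loading, weighted_loading = wl$weighted)
  structure(
    list(selection = sel, model = model, tp = tp, profile = profile,
         no_model = sel$no_model, r2 = model$r2[model$ncomp]),
    class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat(sprintf("<signature_profile> A* = %d, training R2 = %.3f%s\n",
              x$selection$a, x$r2,
              if (x$no_model) " [no predictive model]" else ""))
  print(x$profile[, c("variable", "sr", "lower", "upper", "significant")],
        digits = 3)
  invisible(x)
}
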