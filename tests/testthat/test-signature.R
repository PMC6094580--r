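# Target projection, selectivity ratios, pattern comparison, sensitivity.

fit_demo <- function(n = 60, p = 6, ncomp = 3, seed = 71) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("b", 1:p)))
  beta <- c(1, -0.5, rep(0, p - 2))
  y <- drop(X %*% beta) + rnorm(n, sd = 0.8)
  fit_pls1(X, y, ncomp)
}

test_that("target projection reproduces full-model predictions exactly", {
  fit <- fit_demo()
  tp <- target_projection(fit)
  expect_equal(sum(tp$w_tp^2), 1)
  expect_equal(tp$t_tp, drop(fit$Xs %*% tp$w_tp))
  # rank-1 model: yhat = t_tp q_tp equals Xs b
  expect_equal(tp$t_tp * tp$q_tp * sqrt(sum(fit$b^2)) / sqrt(sum(fit$b^2)),
               tp$t_tp * tp$q_tp)
  yhat_tp <- tp$t_tp * sum(fit$ys * tp$t_tp) / sum(tp$t_tp^2)
  expect_equal(yhat_tp, drop(fit$Xs %*% fit$b), tolerance = 1e-10)
})

test_that("variance bookkeeping decomposes standardized X exactly", {
  fit <- fit_demo(n = 80, p = 8, ncomp = 4)
  tp <- target_projection(fit)
  v_tot <- apply(fit$Xs, 2, var)
  expect_equal(tp$v_expl + tp$v_res, v_tot, tolerance = 1e-8,
               ignore_attr = TRUE)
  # total explained share equals the variance captured by the TP component
  lhs <- sum(tp$v_expl) / sum(tp$v_expl + tp$v_res)
  recon <- tcrossprod(tp$t_tp, tp$p_tp)
  expect_equal(lhs, sum(apply(recon, 2, var)) / sum(v_tot))
})

test_that("A = 1 target projection equals the first component", {
  fit <- fit_demo(ncomp = 1)
  tp <- target_projection(fit)
  alignment <- abs(cor(tp$t_tp, fit$T[, 1]))
  expect_equal(alignment, 1, tolerance = 1e-10)
})

test_that("TP slope reproduces the regression of y on the TP score", {
  fit <- fit_demo(n = 70, p = 5)
  tp <- target_projection(fit)
  slope <- unname(coef(lm(fit$ys ~ tp$t_tp))[2])
  expect_equal(tp$q_tp, slope, tolerance = 1e-10)
})

test_that("orthogonal designs make p_tp proportional to w_tp", {
  set.seed(73)
  X0 <- scale(matrix(rnorm(50 * 5), 50, 5), scale = FALSE)
  Xs <- svd(X0)$u * sqrt(49)       # centered, orthogonal, unit-variance
  y <- drop(Xs %*% c(2, 1, 0, -1, 0)) + rnorm(50, sd = 0.4)
  ys <- (y - mean(y)) / sd(y)
  fit <- fit_pls1(Xs, ys, 3, scale = FALSE)
  tp <- target_projection(fit)
  ratio <- tp$p_tp / tp$w_tp
  expect_lt(diff(range(ratio)), 1e-8 * max(abs(ratio)))
})

test_that("selectivity ratios match brute-force column regressions on t_tp", {
  fit <- fit_demo(n = 40, p = 3, ncomp = 2, seed = 77)
  tp <- target_projection(fit)
  sr <- selectivity_ratios(tp)
  for (j in 1:3) {
    m <- lm(fit$Xs[, j] ~ tp$t_tp - 1)   # columns are centered
    ss_expl <- sum(fitted(m)^2)
    ss_res <- sum(resid(m)^2)
    expect_equal(abs(sr[j]), ss_expl / ss_res, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sign(sr[j]), sign(tp$p_tp[j]), ignore_attr = TRUE)
  }
})

test_that("SR edge cases: orthogonal and collinear variables", {
  set.seed(79)
  n <- 400
  t <- rnorm(n)
  X <- cbind(on = t + rnorm(n, sd = 1e-8),    # ~ proportional to the score
             off = rnorm(n))                  # ~ orthogonal noise
  y <- t + rnorm(n, sd = 0.5)
  fit <- fit_pls1(X, y, 1)
  sr <- selectivity_ratios(target_projection(fit))
  expect_gt(abs(sr["on"]), 1e3)               # explodes toward infinity
  expect_lt(abs(sr["off"]), 0.05)
  tp <- target_projection(fit)
  tp$v_res[1] <- 0
  flagged <- selectivity_ratios(tp)
  expect_true(is.infinite(flagged[1]))
  expect_true(attr(flagged, "infinite")[1])
})

test_that("SR confidence intervals: determinism, methods, significance", {
  pr <- rank1_problem(n = 150, p = 6, seed = 83)
  ci1 <- sr_confidence_intervals(pr$X, pr$y, 1, repetitions = 40, seed = 5)
  ci2 <- sr_confidence_intervals(pr$X, pr$y, 1, repetitions = 40, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower <= ci1$upper))
  expect_true(all(ci1$significant))        # every column loads on the factor

  cin <- sr_confidence_intervals(pr$X, pr$y, 1, repetitions = 40, seed = 5,
                                 method = "normal")
  expect_equal(cin$sr, ci1$sr)
  expect_equal(cin$upper - cin$sr, cin$sr - cin$lower, tolerance = 1e-10)

  # independent null column's interval straddles zero
  set.seed(84)
  Xn <- cbind(pr$X, null = rnorm(150))
  cin2 <- sr_confidence_intervals(Xn, pr$y, 1, repetitions = 40, seed = 6)
  expect_false(cin2$significant[7])
})

test_that("weighted loadings scale with the original-unit SDs", {
  fit <- fit_demo()
  tp <- target_projection(fit)
  fake_scaling <- fit$scaling
  fake_scaling$x_scale <- rep(c(10, 20), length.out = length(tp$p_tp))
  wl <- weighted_loadings(tp, fake_scaling)
  expect_equal(wl$weighted, wl$loading * wl$sd)
  # equal loadings with SDs 10 vs 20 -> importances in ratio 1:2
  tp2 <- tp; tp2$p_tp <- rep(0.3, length(tp$p_tp))
  wl2 <- weighted_loadings(tp2, fake_scaling)
  expect_equal(wl2$weighted[2] / wl2$weighted[1], 2)
  # all-equal SDs: weighted profile proportional to unweighted
  flat <- fit$scaling; flat$x_scale <- rep(3, length(tp$p_tp))
  wl3 <- weighted_loadings(tp, flat)
  expect_equal(wl3$weighted, 3 * wl3$loading)
})

test_that("pattern comparison is plain Pearson correlation", {
  a <- c(0.1, -0.4, 0.8, 0.2)
  expect_equal(compare_patterns(a, a), 1)
  expect_equal(compare_patterns(a, -a), -1)
  b <- c(0.3, -0.2, 0.5, 0.0)
  # manual covariance/SD arithmetic oracle
  r_manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(compare_patterns(a, b), r_manual)
  expect_error(compare_patterns(a, rep(1, 4)), "zero-variance")
  expect_error(compare_patterns(a[1:2], b[1:2]), "length")
})

test_that("univariate profile matches cor.test and the analytic threshold", {
  set.seed(87)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("b1", "b2", "b3")))
  y1 <- scale(X[, 1])                      # outcome equals standardized bin 1
  y2 <- rnorm(n)
  up <- univariate_profile(X, cbind(o1 = drop(y1), o2 = y2))
  expect_equal(up$r["b1", "o1"], 1)
  expect_lt(abs(up$r["b2", "o2"]), 0.3)
  # p-values agree with cor.test (independent implementation)
  ct <- cor.test(X[, 2], y2)
  expect_equal(up$p["b2", "o2"], ct$p.value, tolerance = 1e-10)
  expect_equal(up$significant["b2", "o2"], ct$p.value < 0.05)
})

test_that("SED sensitivity rebuilds the spectrum per cut-point variant", {
  streams <- lapply(1:14, function(i)
    simulate_epochs(epoch_sim_spec(subject_id = sprintf("s%02d", i)),
                    seed = 100 + i))
  names(streams) <- vapply(streams, `[[`, "", "subject_id")
  set.seed(91)
  y <- rnorm(14)
  names(y) <- names(streams)
  res <- sed_sensitivity(streams, y, alt_first_edges = c(50, 100, 250),
                         ncomp = 1)
  expect_equal(res$sed_upper, c(50, 100, 250))
  expect_equal(res$n_bins, c(17, 16, 15))
  expect_equal(res$abs_sr_sed, abs(res$sr_sed))

  # alt edge 100 reproduces the base pipeline exactly
  processed <- lapply(streams, process_stream)
  sm <- spectrum_matrix(processed)
  base_sr <- selectivity_ratios(target_projection(
    fit_pls1(sm$X, y[rownames(sm$X)], 1)))
  expect_equal(res$abs_sr_sed[2], abs(base_sr[1]), ignore_attr = TRUE)

  # partition property: total minutes conserved for every variant
  scheme17 <- bin_scheme(sort(unique(c(0, 50, default_bin_edges()))))
  p17 <- process_stream(streams[[1]], scheme = scheme17)
  expect_equal(sum(p17$spectrum$minutes_per_day),
               p17$spectrum$mean_wear_minutes)

  expect_error(sed_sensitivity(streams, y, alt_first_edges = 9000,
                               ncomp = 1), "inside the base scheme")
})
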