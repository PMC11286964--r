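# IPCW concordance, forecasting MSE, LOCF baseline, grid evaluation and
# model comparison statistics.

test_that("concordance is 1 for perfectly ordered scores and ~0.5 for noise", {
  y <- c(1, 2, 3, 4, 5)
  d <- rep(1, 5)
  expect_equal(cindex_ipcw(rev(y), y, d), 1)   # higher score = earlier event
  expect_equal(cindex_ipcw(y, y, d), 0)
  set.seed(40)
  n <- 1500
  time <- stats::rexp(n, 0.1)
  status <- rep(1, n)
  sc <- stats::rnorm(n)
  expect_equal(cindex_ipcw(sc, time, status), 0.5, tolerance = 0.03)
})

test_that("concordance equals the all-pairs enumeration oracle without censoring", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    y <- sample(seq_len(20), n)
    sc <- stats::rnorm(n)
    expect_equal(cindex_ipcw(sc, y, rep(1, n), eval_time = max(y)),
                 oracle_cindex(sc, y), tolerance = 1e-12)
  }
  # tied scores contribute half
  expect_equal(cindex_ipcw(c(1, 1, 0), c(1, 2, 3), c(1, 1, 1)),
               oracle_cindex(c(1, 1, 0), c(1, 2, 3)), tolerance = 1e-12)
})

test_that("IPCW weighting agrees with the survival package's Uno estimator", {
  set.seed(42)
  n <- 400
  time <- stats::rexp(n, 0.1)
  cens <- stats::runif(n, 0, 25)
  y <- pmin(time, cens)
  d <- as.integer(time <= cens)
  sc <- -time + stats::rnorm(n, 0, 3)   # informative but noisy
  ours <- cindex_ipcw(sc, y, d, eval_time = max(y) + 1)
  ref <- survival::concordance(survival::Surv(y, d) ~ sc, reverse = TRUE,
                               timewt = "n/G2")$concordance
  expect_equal(ours, ref, tolerance = 0.01)
})

test_that("truncation restricts the usable pairs", {
  y <- c(1, 2, 3, 4)
  d <- rep(1, 4)
  sc <- c(4, 1, 2, 3)
  # only events at time <= 1 are usable: patient 1 vs the rest, all concordant
  expect_equal(cindex_ipcw(sc, y, d, eval_time = 1), 1)
  expect_error(cindex_ipcw(sc, y, d, eval_time = 0.5), "comparable")
})

test_that("averaged concordance is the mean over quantile times", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  d <- rep(1, 8)
  sc <- rev(y)
  expect_equal(averaged_cindex(sc, y, d), 1)   # identical value at all times
  # hand check against per-time values at the linear-interpolation quantiles
  set.seed(43)
  sc2 <- stats::rnorm(8)
  qs <- stats::quantile(y, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  manual <- mean(vapply(qs, function(q) cindex_ipcw(sc2, y, d, q),
                        numeric(1)))
  expect_equal(averaged_cindex(sc2, y, d), manual, tolerance = 1e-12)
  expect_equal(mean(c(0.6, 0.7, 0.8)), 0.7)  # the aggregation rule
  expect_error(averaged_cindex(sc, y, d, quantiles = c(0.5, 0.25, 0.75)),
               "increasing")
})

test_that("forecast MSE is the masked mean and ignores masked entries", {
  X <- array(stats::rnorm(24), c(2, 3, 4))
  M <- array(stats::rbinom(24, 1, 0.7), c(2, 3, 4))
  M[1, 1, 1] <- 1
  expect_equal(forecast_mse(X, X, M), 0)
  expect_equal(forecast_mse(X + 0.5, X, M), 0.25, tolerance = 1e-12)
  X2 <- X
  X2[M == 0] <- 1e6
  expect_equal(forecast_mse(X + 0.5, X2, M), 0.25, tolerance = 1e-12)
  # explicit sum on a 2-patient, 3-period toy
  Xh <- X + array(stats::rnorm(24, 0, 0.3), dim(X))
  manual <- sum(M * (X - Xh)^2) / sum(M)
  expect_equal(forecast_mse(Xh, X, M), manual, tolerance = 1e-12)
  expect_error(forecast_mse(X, X, array(0, dim(X))), "zero observed")
})

test_that("LOCF carries the last observed value through the horizon", {
  prep <- small_prep(n = 6, Tt = 8, seed = 44, missingness = 0)
  # variable constant over history -> forecast equals that constant
  prep$X[1, , 1] <- 1.2
  lf <- locf_forecast(prep, t_cond = 4, horizon = 3)
  expect_equal(unname(lf[1, , 1]), rep(1.2, 3))
  # last observed value at an earlier period is carried when later are masked
  prep$M[2, 3:4, 1] <- 0
  prep$X[2, 2, 1] <- 0.7
  lf2 <- locf_forecast(prep, t_cond = 4, horizon = 2)
  expect_equal(unname(lf2[2, , 1]), rep(0.7, 2))
})

test_that("grid evaluation has the right cells and zero spread for identical models", {
  fx <- trained_fixture()
  ens <- structure(list(models = list(fx$model, fx$model),
                        config = fx$model$config, events = "pfs",
                        t_cond = 1, seed = 1),
                   class = "cf_ensemble")
  g <- eval_grid(t_cond = c(1, 3), t_horizon = 4, var_groups = list(
    all = NULL, igs = c("m_protein", "kappa_flc")))
  res <- evaluate_grid(ens, fx$cohort, test_idx = 1:60, grid = g)
  # 2 t_cond x (1 cindex + 2 mse groups) cells, subgroup "all"
  expect_equal(nrow(res), 2 * 3)
  expect_true(all(res$sd[res$n_models == 2] < 1e-12))
  expect_true(all(res$subgroup == "all"))
  g1 <- eval_grid(t_cond = 1, t_horizon = 4, var_groups = list(all = NULL))
  res1 <- evaluate_grid(ens, fx$cohort, test_idx = 1:60, grid = g1)
  expect_equal(nrow(res1), 2)
  # subtype stratification marks small cells missing rather than zero
  g2 <- eval_grid(t_cond = 1, t_horizon = 4, by_subtype = TRUE)
  res2 <- evaluate_grid(ens, fx$cohort, test_idx = 1:40, grid = g2,
                        min_subgroup = 5)
  rare <- res2[res2$n_patients < 5, ]
  if (nrow(rare)) expect_true(all(is.na(rare$mean)))
})

test_that("model comparison reproduces textbook t statistics and Bonferroni", {
  a <- c(0.6, 0.6, 0.6, 0.6, 0.6)
  out0 <- compare_models(rbind(a), rbind(a))
  expect_equal(out0$per_cell$t, 0)
  expect_equal(out0$per_cell$p, 1)
  set.seed(45)
  b <- c(0.5, 0.5, 0.5, 0.5, 0.5) + stats::rnorm(5, 0, 0.01)
  out <- compare_models(rbind(a), rbind(b))
  d <- a - b
  t_manual <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(out$per_cell$t, t_manual, tolerance = 1e-12)
  expect_equal(out$per_cell$df, 4)
  p_manual <- 2 * stats::pt(-abs(t_manual), df = 4)
  expect_equal(out$per_cell$p, p_manual, tolerance = 1e-12)
  out3 <- compare_models(rbind(a), rbind(b), n_pairs = 3)
  expect_equal(out3$per_cell$p_bonferroni, min(3 * p_manual, 1))
  # constant non-zero paired difference: infinitely strong evidence
  out_big <- compare_models(rbind(a), rbind(rep(0.9, 5)), n_pairs = 3)
  expect_equal(out_big$per_cell$t, -Inf)
  expect_equal(out_big$per_cell$p_bonferroni, 0)
  expect_error(compare_models(rbind(a), rbind(b[1:4])), "replicate")
})

test_that("two-way ANOVA without interaction reports a method effect", {
  set.seed(46)
  ma <- matrix(0.6 + stats::rnorm(10, 0, 0.01), 2, 5)
  mb <- matrix(0.5 + stats::rnorm(10, 0, 0.01), 2, 5)
  out <- compare_models(ma, mb)
  expect_lt(out$anova$p, 0.001)
  # the ANOVA matches a direct aov fit on the same long layout
  long <- data.frame(
    value = c(as.vector(t(ma)), as.vector(t(mb))),
    method = rep(c("a", "b"), each = 10),
    cell = factor(rep(rep(1:2, each = 5), 2)))
  ref <- summary(stats::aov(value ~ method + cell, long))[[1]]
  expect_equal(out$anova$F, ref["method", "F value"], tolerance = 1e-10)
})

test_that("stronger burden signal yields higher concordance (monotone signal)", {
  # burden-driven hazards: discrimination grows with burden heterogeneity
  cis <- vapply(c(0.05, 0.9), function(sdl) {
    cfg <- sim_config(n_patients = 1200, n_periods = 12, seed = 47,
                      dynamics = list(burden_sd_log = sdl), missingness = 0)
    co <- generate_cohort(cfg)
    ol <- co$outcomes[co$outcomes$event == "pfs", ]
    averaged_cindex(co$truth$burden[, 1], ol$time, ol$status)
  }, numeric(1))
  expect_gt(cis[2], cis[1] + 0.05)
})
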