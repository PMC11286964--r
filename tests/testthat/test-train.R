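# Losses, pre-training, fine-tuning, bagging and the tuning grid.

test_that("masked forecasting loss matches hand evaluation", {
  X <- array(c(1, 2), c(1, 2, 1))
  Xh <- array(0, c(1, 2, 1))
  M <- array(c(1, 0), c(1, 2, 1))
  expect_equal(forecast_loss(X, Xh, M), 1.0)   # only the observed entry
  expect_equal(forecast_loss(X, X, array(1, dim(X))), 0)
  # flipping a masked value changes nothing
  X2 <- X; X2[1, 2, 1] <- 99
  expect_equal(forecast_loss(X2, Xh, M), 1.0)
  # per-patient normalization then patient average
  X3 <- array(c(1, 1, 2, 2), c(2, 2, 1))
  M3 <- array(c(1, 1, 1, 0), c(2, 2, 1))
  Xh3 <- array(0, c(2, 2, 1))
  # patient 1: (1 + 4)/2; patient 2: 1/1 -> mean 1.75
  expect_equal(forecast_loss(X3, Xh3, M3), mean(c(2.5, 1)))
  M4 <- M3; M4[2, , 1] <- 0
  expect_warning(l4 <- forecast_loss(X3, Xh3, M4), "excluded")
  expect_equal(l4, 2.5)
})

test_that("Cox loss matches hand-computed partial likelihoods", {
  expect_equal(cox_event_loss(c(0, 0), c(1, 2), c(1, 1)), log(2))
  expect_equal(cox_event_loss(0.7, 3, 1), 0)   # own risk set only
  s <- c(0.3, -1, 2, 0.1)
  y <- c(2, 1, 4, 3); d <- c(1, 0, 1, 1)
  expect_equal(cox_event_loss(s + 5, y, d), cox_event_loss(s, y, d),
               tolerance = 1e-10)
  expect_error(cox_event_loss(c(1, 2), c(1, 2), c(0, 0)), "event")
  expect_error(cox_event_loss(c(NA, 1), c(1, 2), c(1, 1)), "finite")
})

test_that("Cox loss equals the enumeration oracle on all orderings of 4 patients", {
  perms <- rbind(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
                 c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
                 c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
                 c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                 c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  set.seed(20)
  s <- stats::rnorm(4)
  for (r in seq_len(nrow(perms))) {
    y <- perms[r, ]
    for (d in list(c(1,1,1,1), c(1,0,1,0), c(0,1,1,1))) {
      expect_equal(cox_event_loss(s, y, d), oracle_cox_loss(s, y, d),
                   tolerance = 1e-12)
    }
  }
  # and with ties (Breslow risk sets)
  y_tie <- c(1, 2, 2, 3)
  expect_equal(cox_event_loss(s, y_tie, c(1, 1, 1, 1)),
               oracle_cox_loss(s, y_tie, c(1, 1, 1, 1)), tolerance = 1e-12)
})

test_that("Cox loss gradient matches finite differences on small instances", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    s <- stats::rnorm(n)
    y <- sample(seq_len(n + 2), n)
    d <- stats::rbinom(n, 1, 0.7)
    d[sample(n, 1)] <- 1
    for (lm in c(FALSE, TRUE)) {
      g <- coxformer:::cox_loss_grad(s, y, d, landmark = lm)
      fd <- vapply(seq_len(n), function(i) {
        e <- 1e-6
        sp <- s; sp[i] <- s[i] + e
        sm <- s; sm[i] <- s[i] - e
        (cox_event_loss(sp, y, d, landmark = lm) -
           cox_event_loss(sm, y, d, landmark = lm)) / (2 * e)
      }, numeric(1))
      expect_equal(g, fd, tolerance = 1e-4)
    }
  }
})

test_that("landmark-weighted loss reduces to repeated partial likelihoods", {
  s <- c(0.5, -0.2, 1.1, 0)
  y <- c(1, 2, 3, 4); d <- c(1, 1, 0, 1)
  # explicit sum over landmark times of renormalized event sums
  Tm <- 4
  manual <- 0
  for (t in 1:Tm) {
    dt <- sum(d == 1 & y <= t)
    if (dt == 0) next
    term <- 0
    for (i in which(d == 1 & y <= t)) {
      term <- term + (s[i] - log(sum(exp(s[y >= y[i]]))))
    }
    manual <- manual - term / dt
  }
  expect_equal(cox_event_loss(s, y, d, landmark = TRUE, T_max = Tm), manual,
               tolerance = 1e-12)
})

test_that("encoder gradient matches finite differences", {
  prep <- small_prep(n = 8, Tt = 5, seed = 22)
  m <- tiny_model(prep, d_z = 6, tau = 4, seed = 23)
  fg <- coxformer:::forecast_grad(m, prep, train = FALSE)
  probe <- list(list(c("input", "W"), 5),
                list(c("layers", "1", "Wq"), 3),
                list(c("layers", "2", "Wv"), 7),
                list(c("layers", "1", "W1"), 11),
                list(c("layers", "2", "ln2_g"), 2),
                list(c("pred", "W2"), 4))
  get_leaf <- function(p, pl) {
    for (k in pl) p <- if (grepl("^[0-9]+$", k)) p[[as.integer(k)]] else
      p[[k]]
    p
  }
  for (pr in probe) {
    path <- pr[[1]]; i <- pr[[2]]
    eps <- 1e-6
    bump <- function(delta) {
      m2 <- m
      leaf_path <- path
      # walk down, modify, rebuild
      modify <- function(p, pl) {
        k <- pl[[1]]
        kk <- if (grepl("^[0-9]+$", k)) as.integer(k) else k
        if (length(pl) == 1) {
          p[[kk]][i] <- p[[kk]][i] + delta
        } else {
          p[[kk]] <- modify(p[[kk]], pl[-1])
        }
        p
      }
      m2$params <- modify(m$params, as.list(leaf_path))
      coxformer:::forecast_grad(m2, prep, train = FALSE)$loss
    }
    fd <- (bump(eps) - bump(-eps)) / (2 * eps)
    an <- get_leaf(fg$grads, path)[i]
    expect_equal(an, fd, tolerance = 1e-4)
  }
})

test_that("pretraining is deterministic, improves the loss, and zero epochs is a no-op", {
  prep <- small_prep(n = 25, Tt = 6, seed = 24)
  m <- tiny_model(prep, dropout = 0.1, seed = 25)
  m0 <- pretrain(m, prep, epochs = 0, seed = 1)
  expect_identical(m0$params, m$params)
  a <- pretrain(m, prep, epochs = 8, lr = 3e-3, seed = 2)
  b <- pretrain(m, prep, epochs = 8, lr = 3e-3, seed = 2)
  expect_identical(a$params, b$params)
  expect_equal(a$loss_curve, b$loss_curve)
  expect_lt(utils::tail(a$loss_curve$train, 1), a$loss_curve$train[1])
})

test_that("pretraining converges on noise-free dynamics and validation is logged", {
  co <- small_cohort(n = 50, Tt = 8, seed = 26, noise_sd = 0,
                     missingness = 0,
                     dynamics = list(process_sd = 0))
  prep <- preprocess_cohort(co, train_idx = 1:40)
  m <- tiny_model(prep, d_z = 12, tau = 6, seed = 27)
  m <- pretrain(m, prep, idx = 1:40, val_idx = 41:50, epochs = 120,
                lr = 5e-3, seed = 28)
  expect_true(all(is.finite(m$loss_curve$val)))
  expect_lt(utils::tail(m$loss_curve$train, 1), 0.02)
  # one-step error near zero on the noise-free dynamics
  p <- forecast_next(m, prep, t_cond = 4)
  expect_lt(mean((p - prep$X[, 5, ])^2), 0.02)
})

test_that("fine-tuning trains only the selected head and leaves forecasts unchanged", {
  fx <- trained_fixture()
  m <- fx$model
  before <- serialize(m$params[c("input", "layers", "pred")], NULL)
  ro_before <- rollout(m, fx$cohort, 1, 4)$X_pred
  m2 <- finetune_heads(m, fx$cohort, "os", t_cond = 1, epochs = 30,
                       lr = 1e-2, seed = 3)
  after <- serialize(m2$params[c("input", "layers", "pred")], NULL)
  expect_identical(before, after)   # backbone byte-identical
  expect_identical(m2$params$heads$pfs, m$params$heads$pfs)
  expect_false(identical(m2$params$heads$os, m$params$heads$os))
  expect_identical(rollout(m2, fx$cohort, 1, 4)$X_pred, ro_before)
})

test_that("fine-tuned head recovers signal: validation concordance above 0.5", {
  fx <- trained_fixture()
  ol <- coxformer:::outcomes_for(fx$cohort, "pfs")
  sc <- event_score(fx$model, fx$cohort, 1, "pfs")
  expect_gt(averaged_cindex(sc, ol$time, ol$status), 0.55)
})

test_that("AE fine-tuning trains a 12-output head", {
  fx <- trained_fixture()
  m <- finetune_heads(fx$model, fx$cohort, "ae", t_cond = 1, epochs = 20,
                      lr = 1e-2, seed = 4)
  S <- event_score(m, fx$cohort, 1, "ae")
  expect_equal(ncol(S), 12)
  expect_true(all(is.finite(S)))
})

test_that("bagging resamples at 1.5x and aggregates by the mean", {
  prep <- small_prep(n = 40, Tt = 5, seed = 30)
  expect_warning(
    ens <- fit_bagged_ensemble(prep, train_idx = 1:30,
                               config = encoder_config(d_z = 8, tau = 4),
                               n_bags = 1, pretrain_epochs = 2,
                               finetune_epochs = 5, seed = 2),
    "uncertainty")
  ens <- fit_bagged_ensemble(prep, train_idx = 1:30,
                             config = encoder_config(d_z = 8, tau = 4),
                             n_bags = 3, pretrain_epochs = 2,
                             finetune_epochs = 5, seed = 2)
  for (b in ens$bags) expect_length(b, round(1.5 * 30))
  pr <- predict_ensemble(ens, prep, 1, "pfs")
  expect_equal(pr$mean,
               (pr$per_model[[1]] + pr$per_model[[2]] + pr$per_model[[3]]) / 3,
               tolerance = 1e-12)
  # identical models -> zero spread, aggregate equals any member
  ens2 <- ens
  ens2$models <- list(ens$models[[1]], ens$models[[1]], ens$models[[1]])
  pr2 <- predict_ensemble(ens2, prep, 1, "pfs")
  expect_equal(max(abs(pr2$sd)), 0)
  expect_equal(pr2$mean, pr2$per_model[[1]])
})

test_that("hyperparameter tuning selects by mean validation loss", {
  expect_equal(nrow(default_grid()), 16)
  expect_equal(encoder_config()$K, 1L)   # default when tuning is skipped
  prep <- small_prep(n = 40, Tt = 5, seed = 33)
  sp <- split_cohort(40, seed = 3)
  grid1 <- data.frame(d_z = 8L, dropout = 0.1, K = 1L, n_layers = 1L,
                      nonlinear_head = TRUE)
  out1 <- tune_hyperparameters(prep, sp, grid1, pretrain_epochs = 2)
  expect_equal(out1$best_config$d_z, 8L)
  expect_equal(nrow(out1$results), 5)    # one row per fold
  grid2 <- rbind(grid1, data.frame(d_z = 4L, dropout = 0.2, K = 0L,
                                   n_layers = 1L, nonlinear_head = FALSE))
  out2 <- tune_hyperparameters(prep, sp, grid2, pretrain_epochs = 2)
  expect_equal(nrow(out2$results), 10)
  expect_true(out2$best_config$d_z %in% c(4L, 8L))
  expect_equal(out2$summary$val_loss[which.min(out2$summary$val_loss)],
               min(out2$summary$val_loss))
  expect_error(tune_hyperparameters(prep, sp, grid1[0, ]), "empty")
})
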