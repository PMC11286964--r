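# Encoder, heads and rollout mechanics.

test_that("time embedding matches its closed form", {
  E <- time_embedding(c(0, 1), tau = 6, T_max = 24)
  expect_equal(E[1, 1], 0)          # sin(0)
  expect_equal(E[1, 2], 1)          # cos(0)
  expect_equal(E[2, 1], sin(1))     # k = 0 exponent is 0, any T_max
  E2 <- time_embedding(1, tau = 6, T_max = 1000)
  expect_equal(E2[1, 1], sin(1))
  # general entries
  expect_equal(E[2, 3], sin(1 / 24^(2 / 6)))
  expect_equal(E[2, 4], cos(1 / 24^(3 / 6)))
  expect_error(time_embedding(0, tau = 5, T_max = 10), "even")
  expect_error(time_embedding(-1, tau = 4, T_max = 10), "non-negative")
})

test_that("input embedding is the stated affine map of the concatenation", {
  prep <- small_prep(n = 5, Tt = 3, seed = 1)
  m <- tiny_model(prep)
  # zero weights and bias give the zero embedding
  m0 <- m
  m0$params$input$W[] <- 0
  m0$params$input$b[] <- 0
  expect_equal(max(abs(embed_inputs(m0, prep))), 0)
  # non-zero bias shifts every state by the bias
  m0$params$input$b[] <- 1:8
  Z <- embed_inputs(m0, prep)
  expect_equal(Z[3, 2, ], as.numeric(1:8))
  # a masked-out value still changes the embedding (mask is an input channel,
  # values are imputed) - documented behavior
  prep2 <- prep
  prep2$M[1, 2, 1] <- 0
  prep2$X[1, 2, 1] <- prep$X[1, 2, 1] + 1
  expect_false(isTRUE(all.equal(embed_inputs(m, prep2)[1, 2, ],
                                embed_inputs(m, prep)[1, 2, ])))
})

test_that("attention with a single time step returns the value vector", {
  Zn <- matrix(stats::rnorm(8), 2, 4)  # 2 patients, T = 1, d_z = 4
  W <- diag(4)
  at <- coxformer:::attn_forward(Zn, n = 2, Tt = 1, n_heads = 1,
                                 Wq = W, Wk = W, Wv = W)
  expect_equal(at$O, Zn %*% W)     # softmax over one key is 1
  expect_equal(at$Aw[[1]][[1]], matrix(1, 2, 1))
})

test_that("attention rows sum to one over the allowed keys", {
  prep <- small_prep(n = 7, Tt = 5, seed = 2)
  m <- tiny_model(prep, n_heads = 2)
  U <- coxformer:::build_inputs(m, prep)
  Zn <- coxformer:::ln_forward(
    coxformer:::mat3(U) %*% m$params$input$W, rep(1, 8), rep(0, 8))$out
  lp <- m$params$layers[[1]]
  at <- coxformer:::attn_forward(Zn, 7, 5, 2, lp$Wq, lp$Wk, lp$Wv)
  for (h in 1:2) {
    for (t in 1:5) expect_equal(rowSums(at$Aw[[h]][[t]]), rep(1, 7))
  }
})

test_that("encoder equals an independent loop-based oracle", {
  prep <- small_prep(n = 4, Tt = 3, seed = 3)
  for (heads in c(1, 2)) {
    m <- tiny_model(prep, d_z = 4, tau = 2, n_heads = heads, seed = 11)
    U <- coxformer:::build_inputs(m, prep)
    Z_pkg <- encode(m, prep)
    Z_oracle <- oracle_encode(m, U)
    expect_equal(Z_pkg, Z_oracle, tolerance = 1e-6)
  }
})

test_that("causality: perturbing inputs after t leaves states and scores at t unchanged", {
  prep <- small_prep(n = 6, Tt = 6, seed = 4)
  m <- tiny_model(prep, K = 1, seed = 9)
  t_cut <- 3
  Z_before <- encode(m, prep)
  sc_before <- event_score(m, prep, t_cond = t_cut, type = "pfs")
  fc_before <- forecast_next(m, prep, t_cond = t_cut)
  ro_before <- rollout(m, prep, t_cond = t_cut, horizon = 2)
  prep2 <- prep
  prep2$X[, (t_cut + 1):6, ] <- stats::rnorm(length(prep2$X[, (t_cut + 1):6, ]))
  prep2$M[, (t_cut + 1):6, ] <- 1
  Z_after <- encode(m, prep2)
  expect_equal(Z_after[, 1:t_cut, ], Z_before[, 1:t_cut, ],
               tolerance = 1e-12)
  expect_equal(event_score(m, prep2, t_cond = t_cut, type = "pfs"),
               sc_before, tolerance = 1e-12)
  expect_equal(forecast_next(m, prep2, t_cond = t_cut), fc_before,
               tolerance = 1e-12)
  expect_equal(rollout(m, prep2, t_cond = t_cut, horizon = 2)$X_pred,
               ro_before$X_pred, tolerance = 1e-12)
})

test_that("forecast head is the stated map of the last state", {
  prep <- small_prep(n = 5, Tt = 4, seed = 5)
  m <- tiny_model(prep)
  m$params$pred$W1[] <- 0
  m$params$pred$b1[] <- 0
  m$params$pred$W2[] <- 0
  m$params$pred$b2[] <- 0
  expect_equal(max(abs(forecast_next(m, prep, 2))), 0)
  # affine contract: with ReLU disabled by a large positive bias shift the
  # head reduces to W2' relu(W1' z + b1) + b2; check against hand computation
  m2 <- tiny_model(prep, seed = 6)
  Z <- encode(m2, prep, T_use = 2)
  z_last <- matrix(Z[, 2, ], 5, 8)
  hand <- pmax(sweep(z_last %*% m2$params$pred$W1, 2, m2$params$pred$b1,
                     "+"), 0) %*% m2$params$pred$W2
  hand <- sweep(hand, 2, m2$params$pred$b2, "+")
  expect_equal(unname(forecast_next(m2, prep, 2)), unname(hand),
               tolerance = 1e-12)
})

test_that("rollout is consistent with one-step forecasting and hand unrolling", {
  prep <- small_prep(n = 4, Tt = 6, seed = 7)
  m <- tiny_model(prep, seed = 12)
  ro1 <- rollout(m, prep, t_cond = 2, horizon = 1)
  expect_equal(ro1$X_pred[, 1, ], forecast_next(m, prep, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  # hand-unrolled two-step computation with the same weights
  ro2 <- rollout(m, prep, t_cond = 2, horizon = 2)
  step1 <- forecast_next(m, prep, 2)
  prep_fed <- prep
  prep_fed$X[, 3, ] <- step1
  prep_fed$M[, 3, ] <- 1
  step2 <- forecast_next(m, prep_fed, 3)
  expect_equal(ro2$X_pred[, 1, ], step1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ro2$X_pred[, 2, ], step2, tolerance = 1e-12,
               ignore_attr = TRUE)
  # determinism at inference
  expect_identical(ro2$X_pred, rollout(m, prep, 2, 2)$X_pred)
  expect_error(rollout(m, prep, t_cond = 4, horizon = 4), "treatment plan")
})

test_that("event scores consume exactly K + 1 states", {
  prep <- small_prep(n = 5, Tt = 5, seed = 8)
  m0 <- tiny_model(prep, K = 0, seed = 13, nonlinear_head = FALSE)
  # K = 0: the head consumes only z_t; a hand dot product reproduces it
  Feat <- coxformer:::event_features(m0, prep, t_cond = 2)
  expect_equal(ncol(Feat), m0$config$d_z)
  head <- m0$params$heads$pfs
  hand <- drop(Feat %*% head$W + head$b)
  expect_equal(unname(event_score(m0, prep, 2, "pfs")), unname(hand),
               tolerance = 1e-12)
  m1 <- tiny_model(prep, K = 1, seed = 13, nonlinear_head = FALSE)
  Feat1 <- coxformer:::event_features(m1, prep, t_cond = 2)
  expect_equal(ncol(Feat1), 2 * m1$config$d_z)
  # hand-set linear head on the concatenated states
  head1 <- m1$params$heads$pfs
  head1$W[] <- stats::rnorm(length(head1$W))
  head1$b[] <- 0.3
  m1$params$heads$pfs <- head1
  expect_equal(unname(event_score(m1, prep, 2, "pfs")),
               unname(drop(Feat1 %*% head1$W + 0.3)), tolerance = 1e-12)
  # AE head returns one score per adverse-event type
  S <- event_score(m1, prep, 2, "ae")
  expect_equal(dim(S), c(5, 12))
  expect_identical(colnames(S), coxformer:::ae_types())
})

test_that("normalized risk is the clipped train-range map", {
  tr <- c(-2, 0, 2)
  expect_equal(normalized_risk(-2, tr), 0)
  expect_equal(normalized_risk(2, tr), 1)
  expect_equal(normalized_risk(0, tr), 0.5)
  expect_equal(normalized_risk(5, tr), 1)    # clipped
  expect_equal(normalized_risk(-5, tr), 0)
  expect_error(normalized_risk(1, c(3, 3)), "degenerate")
})

test_that("literal rollout flag reuses the previous period's treatments", {
  prep <- small_prep(n = 4, Tt = 6, seed = 14)
  # make treatments vary over time so the flag is observable
  prep$As[, 4, 1] <- 9
  m_adv <- tiny_model(prep, seed = 15)
  m_lit <- m_adv
  m_lit$config$literal_rollout <- TRUE
  a <- rollout(m_adv, prep, t_cond = 3, horizon = 3)$X_pred
  b <- rollout(m_lit, prep, t_cond = 3, horizon = 3)$X_pred
  expect_equal(a[, 1, ], b[, 1, ], tolerance = 1e-12)  # first step agrees
  expect_false(isTRUE(all.equal(a[, 2, ], b[, 2, ])))  # later steps diverge
})
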