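# Shared fixtures, all generated in code.

# Small preprocessed cohort for structural tests.
small_cohort <- function(n = 30, Tt = 8, seed = 42, noise_sd = 0.15,
                         missingness = 0.1, ...) {
  cfg <- sim_config(n_patients = n, n_periods = Tt, seed = seed,
                    noise_sd = noise_sd, missingness = missingness, ...)
  generate_cohort(cfg)
}

# Tiny cohorts routinely have constant one-hot columns; the zero-variance
# warning is expected there.
small_prep <- function(...) suppressWarnings(preprocess_cohort(small_cohort(...)))

tiny_model <- function(cohort, d_z = 8, tau = 4, dropout = 0, K = 1,
                       seed = 7, ...) {
  init_model(cohort, encoder_config(d_z = d_z, tau = tau, dropout = dropout,
                                    K = K, ...), seed = seed)
}

# One moderately trained model on a burden-driven cohort, fitted once per
# test run and cached (training is deterministic, so every test sees the
# same object).
trained_fixture_env <- new.env()
trained_fixture <- function() {
  if (!is.null(trained_fixture_env$fx)) return(trained_fixture_env$fx)
  cfg <- sim_config(n_patients = 250, n_periods = 10, seed = 31,
                    effect_log_hr = c(pfs = -0.8))
  cohort <- generate_cohort(cfg)
  prep <- preprocess_cohort(cohort)
  model <- init_model(prep, encoder_config(d_z = 12, tau = 6), seed = 5)
  model <- pretrain(model, prep, epochs = 80, lr = 3e-3, seed = 6)
  model <- finetune_heads(model, prep, "pfs", t_cond = 1, epochs = 200,
                          lr = 2e-2, seed = 8)
  trained_fixture_env$fx <- list(cohort = prep, model = model, config = cfg)
  trained_fixture_env$fx
}

# Independent loop-based attention encoder oracle: plain double/triple loops
# over patients, periods and dimensions, mirroring the pre-norm residual
# architecture but sharing no code with the package implementation.
oracle_encode <- function(model, U) {
  n <- dim(U)[1]; Tt <- dim(U)[2]
  cfg <- model$config
  ln <- function(z, g, b, eps = 1e-5) {
    mu <- mean(z); v <- mean((z - mu)^2)
    ((z - mu) / sqrt(v + eps)) * g + b
  }
  out <- array(0, c(n, Tt, cfg$d_z))
  for (i in seq_len(n)) {
    Z <- matrix(0, Tt, cfg$d_z)
    for (t in seq_len(Tt)) {
      Z[t, ] <- as.numeric(U[i, t, ] %*% model$params$input$W) +
        model$params$input$b
    }
    for (l in seq_len(cfg$n_layers)) {
      lp <- model$params$layers[[l]]
      Zn <- t(apply(Z, 1, ln, g = lp$ln1_g, b = lp$ln1_b))
      d_h <- cfg$d_z / cfg$n_heads
      O <- matrix(0, Tt, cfg$d_z)
      for (h in seq_len(cfg$n_heads)) {
        cols <- ((h - 1) * d_h + 1):(h * d_h)
        for (t in seq_len(Tt)) {
          q <- as.numeric(Zn[t, ] %*% lp$Wq)[cols]
          scores <- numeric(t)
          for (s in seq_len(t)) {
            k <- as.numeric(Zn[s, ] %*% lp$Wk)[cols]
            scores[s] <- sum(q * k) / sqrt(d_h)
          }
          w <- exp(scores - max(scores))
          w <- w / sum(w)
          acc <- numeric(d_h)
          for (s in seq_len(t)) {
            v <- as.numeric(Zn[s, ] %*% lp$Wv)[cols]
            acc <- acc + w[s] * v
          }
          O[t, cols] <- acc
        }
      }
      a <- Z + O
      An <- t(apply(a, 1, ln, g = lp$ln2_g, b = lp$ln2_b))
      H <- pmax(sweep(An %*% lp$W1, 2, lp$b1, "+"), 0)
      Ff <- sweep(H %*% lp$W2, 2, lp$b2, "+")
      Z <- a + Ff
    }
    out[i, , ] <- Z
  }
  out
}

# Brute-force Breslow negative partial log-likelihood with explicit risk-set
# loops.
oracle_cox_loss <- function(scores, time, status) {
  loss <- 0
  for (i in seq_along(scores)) {
    if (status[i] != 1) next
    denom <- 0
    for (j in seq_along(scores)) {
      if (time[j] >= time[i]) denom <- denom + exp(scores[j])
    }
    loss <- loss - (scores[i] - log(denom))
  }
  loss
}

# All-pairs concordance enumeration (no censoring, no truncation).
oracle_cindex <- function(scores, time) {
  num <- 0; den <- 0
  for (i in seq_along(time)) {
    for (j in seq_along(time)) {
      if (time[i] < time[j]) {
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}
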