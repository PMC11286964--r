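# Causal temporal self-attention encoder with forecasting and Cox event
# heads. The network is small (hidden dimension 16-32, 2 layers) and all
# forward/backward passes are written as dense matrix algebra, batched over
# patients; per-(t, s) attention terms are vectorized over the cohort.
#
# Time convention (used everywhere): treatment periods are 0-based integers;
# a conditioning window t_cond means periods 0 .. t_cond-1 are observed and
# predictions begin at period t_cond.

#' Encoder configuration
#'
#' @param d_z Hidden dimension of the transformer layers (grid: 16 or 32).
#' @param n_layers Number of transformer layers (default 2).
#' @param n_heads Attention heads; must divide `d_z` (default 1).
#' @param d_ff Feed-forward width (default `4 * d_z`).
#' @param dropout Dropout probability in the transformer layers (grid: 0.1
#'   or 0.2).
#' @param K Rollout window: number of future (rolled-out) hidden states fed to
#'   the event heads (grid: 0 or 1; 1 by default).
#' @param nonlinear_head Use a one-hidden-layer ReLU perceptron for the event
#'   heads instead of an affine map.
#' @param head_hidden Hidden width of nonlinear event heads.
#' @param pred_hidden Hidden width of the forecasting head MLP.
#' @param tau Time-embedding dimension (even).
#' @param literal_rollout Reuse the previous period's treatment and time
#'   embedding during rollout instead of advancing them (reproduces the
#'   literal one-step update; default FALSE, i.e. treatments and time advance
#'   with the rollout).
#' @return An object of class `cf_encoder_config`.
#' @export
encoder_config <- function(d_z = 16, n_layers = 2, n_heads = 1,
                           d_ff = 4 * d_z, dropout = 0.1, K = 1,
                           nonlinear_head = TRUE, head_hidden = 32,
                           pred_hidden = 2 * d_z, tau = 8,
                           literal_rollout = FALSE) {
  if (d_z %% n_heads != 0) stop("`d_z` must be divisible by `n_heads`",
                                call. = FALSE)
  if (n_layers < 1) stop("`n_layers` must be >= 1", call. = FALSE)
  if (K < 0) stop("`K` must be >= 0", call. = FALSE)
  if (tau %% 2 != 0) stop("`tau` must be even", call. = FALSE)
  structure(list(d_z = as.integer(d_z), n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads), d_ff = as.integer(d_ff),
                 dropout = dropout, K = as.integer(K),
                 nonlinear_head = isTRUE(nonlinear_head),
                 head_hidden = as.integer(head_hidden),
                 pred_hidden = as.integer(pred_hidden),
                 tau = as.integer(tau),
                 literal_rollout = isTRUE(literal_rollout)),
            class = "cf_encoder_config")
}

#' Sinusoidal time embedding
#'
#' `E_{2k}(t) = sin(t / T_max^{2k/tau})`, `E_{2k+1}(t) = cos(t /
#' T_max^{(2k+1)/tau})` for `k = 0 .. tau/2 - 1`.
#'
#' @param t Vector of 0-based periods (non-negative).
#' @param tau Embedding dimension (even).
#' @param T_max Horizon constant, at least the maximum follow-up.
#' @return `length(t) x tau` matrix.
#' @export
time_embedding <- function(t, tau, T_max) {
  if (tau %% 2 != 0) stop("`tau` must be even", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  E <- matrix(0, length(t), tau)
  for (k in 0:(tau / 2 - 1)) {
    E[, 2 * k + 1] <- sin(t / T_max^(2 * k / tau))
    E[, 2 * k + 2] <- cos(t / T_max^((2 * k + 1) / tau))
  }
  E
}

init_affine <- function(d_in, d_out) {
  list(W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / (d_in + d_out))),
                  d_in, d_out),
       b = numeric(d_out))
}

init_head <- function(d_in, d_out, config) {
  if (config$nonlinear_head) {
    h <- config$head_hidden
    list(W1 = matrix(stats::rnorm(d_in * h, 0, sqrt(2 / (d_in + h))), d_in, h),
         b1 = numeric(h),
         W2 = matrix(stats::rnorm(h * d_out, 0, sqrt(2 / (h + d_out))),
                     h, d_out),
         b2 = numeric(d_out))
  } else {
    a <- init_affine(d_in, d_out)
    list(W = a$W, b = a$b)
  }
}

#' Initialize a joint longitudinal-survival model for a cohort
#'
#' @param cohort A preprocessed `cf_cohort` (see [preprocess_cohort()]).
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @param T_max Horizon constant for the time embedding (default: the
#'   cohort's number of periods).
#' @return An object of class `cf_model` holding parameters, configuration
#'   and input metadata.
#' @export
init_model <- function(cohort, config = encoder_config(), seed = 1L,
                       T_max = NULL) {
  stopifnot(inherits(cohort, "cf_cohort"))
  if (is.null(cohort$Bmat) || is.null(cohort$As)) {
    stop("cohort must be preprocessed first (see `preprocess_cohort()`)",
         call. = FALSE)
  }
  vars <- dimnames(cohort$X)[[3]]
  J <- length(vars)
  p <- ncol(cohort$Bmat)
  q <- dim(cohort$As)[3]
  Tt <- dim(cohort$X)[2]
  T_max <- T_max %||% Tt
  d_in <- p + 2 * J + q + config$tau
  d_feat <- config$d_z * (config$K + 1)
  with_seed(seed, {
    params <- list(input = init_affine(d_in, config$d_z))
    params$layers <- lapply(seq_len(config$n_layers), function(l) {
      list(ln1_g = rep(1, config$d_z), ln1_b = numeric(config$d_z),
           Wq = init_affine(config$d_z, config$d_z)$W,
           Wk = init_affine(config$d_z, config$d_z)$W,
           Wv = init_affine(config$d_z, config$d_z)$W,
           ln2_g = rep(1, config$d_z), ln2_b = numeric(config$d_z),
           W1 = init_affine(config$d_z, config$d_ff)$W,
           b1 = numeric(config$d_ff),
           W2 = init_affine(config$d_ff, config$d_z)$W,
           b2 = numeric(config$d_z))
    })
    params$pred <- list(
      W1 = init_affine(config$d_z, config$pred_hidden)$W,
      b1 = numeric(config$pred_hidden),
      W2 = init_affine(config$pred_hidden, J)$W,
      b2 = numeric(J))
    params$heads <- list(
      pfs = init_head(d_feat, 1L, config),
      os = init_head(d_feat, 1L, config),
      ae = init_head(d_feat, length(ae_types()), config))
    structure(list(params = params, config = config,
                   meta = list(vars = vars, J = J, p = p, q = q,
                               d_in = d_in, T_max = T_max,
                               base_cols = colnames(cohort$Bmat),
                               a_cols = dimnames(cohort$As)[[3]]),
                   score_range = list()),
              class = "cf_model")
  })
}

#' @export
print.cf_model <- function(x, ...) {
  cfg <- x$config
  cat("<cf_model> causal self-attention encoder\n",
      "  d_z = ", cfg$d_z, ", layers = ", cfg$n_layers,
      ", heads = ", cfg$n_heads, ", K = ", cfg$K,
      ", nonlinear event heads = ", cfg$nonlinear_head, "\n",
      "  inputs: ", x$meta$p, " baseline + ", x$meta$J,
      " biomarkers (+mask) + ", x$meta$q, " treatments + tau=", cfg$tau,
      "\n", sep = "")
  invisible(x)
}

# Assemble the input array U (n x T_use x d_in) = [B, X(t), M(t), A(t), E(t)].
build_inputs <- function(model, cohort, T_use = NULL, X_work = NULL,
                         M_work = NULL, E_idx = NULL) {
  n <- nrow(cohort$Bmat)
  Tt <- dim(cohort$X)[2]
  T_use <- T_use %||% Tt
  X_work <- X_work %||% cohort$X
  M_work <- M_work %||% cohort$M
  E_idx <- E_idx %||% (0:(T_use - 1))
  E <- time_embedding(E_idx, model$config$tau, model$meta$T_max)
  d_in <- model$meta$d_in
  U <- array(0, c(n, T_use, d_in))
  p <- model$meta$p; J <- model$meta$J; q <- model$meta$q
  for (t in seq_len(T_use)) {
    U[, t, 1:p] <- cohort$Bmat
    U[, t, p + (1:J)] <- X_work[, t, ]
    U[, t, p + J + (1:J)] <- M_work[, t, ]
    U[, t, p + 2 * J + (1:q)] <- cohort$As[, t, ]
    U[, t, p + 2 * J + q + (1:model$config$tau)] <-
      matrix(E[t, ], n, model$config$tau, byrow = TRUE)
  }
  U
}

#' Input embedding
#'
#' Concatenates `[B, X(t), M(t), A(t), E(t)]` per period and applies the
#' learned affine map to dimension `d_z`. Note that masked-out biomarker
#' entries still enter through their imputed values: the mask is itself an
#' input channel, values are imputed.
#'
#' @param model A `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param T_use Number of leading periods to embed (default: all).
#' @return `n x T_use x d_z` array of layer-0 states.
#' @export
embed_inputs <- function(model, cohort, T_use = NULL) {
  U <- build_inputs(model, cohort, T_use = T_use)
  n <- dim(U)[1]; Tt <- dim(U)[2]
  Z0 <- mat3(U) %*% model$params$input$W
  Z0 <- sweep(Z0, 2, model$params$input$b, "+")
  arr3(Z0, n, Tt)
}

ln_forward <- function(Z, g, b, eps = 1e-5) {
  mu <- rowMeans(Z)
  Zc <- Z - mu
  v <- rowMeans(Zc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- Zc * inv_sd
  out <- sweep(xhat * rep(1, nrow(Z)) %o% g, 2, b, "+")
  list(out = out, xhat = xhat, inv_sd = inv_sd)
}

ln_backward <- function(dout, cache, g) {
  dxhat <- sweep(dout, 2, g, "*")
  xhat <- cache$xhat
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dZ <- cache$inv_sd * (dxhat - m1 - xhat * m2)
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  list(dZ = dZ, dg = dg, db = db)
}

# Causal multi-head attention over an (n*T) x d_z matrix of normalized
# states. Row block t holds all patients at period t-1. Attention at period t
# is restricted to keys at periods <= t (lower-triangular mask); rows of the
# attention weights sum to 1 over the allowed keys.
attn_forward <- function(Zn, n, Tt, n_heads, Wq, Wk, Wv) {
  d_z <- ncol(Wq)
  d_h <- d_z / n_heads
  Q <- Zn %*% Wq
  K <- Zn %*% Wk
  V <- Zn %*% Wv
  O <- matrix(0, n * Tt, d_z)
  Aw <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * d_h + 1):(h * d_h)
    A_h <- vector("list", Tt)
    for (t in seq_len(Tt)) {
      rows_t <- ((t - 1) * n + 1):(t * n)
      S <- matrix(0, n, t)
      for (s in seq_len(t)) {
        rows_s <- ((s - 1) * n + 1):(s * n)
        S[, s] <- rowSums(Q[rows_t, cols, drop = FALSE] *
                            K[rows_s, cols, drop = FALSE]) / sqrt(d_h)
      }
      S <- S - apply(S, 1, max)
      W <- exp(S)
      W <- W / rowSums(W)
      A_h[[t]] <- W
      Ot <- matrix(0, n, d_h)
      for (s in seq_len(t)) {
        rows_s <- ((s - 1) * n + 1):(s * n)
        Ot <- Ot + W[, s] * V[rows_s, cols, drop = FALSE]
      }
      O[rows_t, cols] <- Ot
    }
    Aw[[h]] <- A_h
  }
  list(O = O, Q = Q, K = K, V = V, Aw = Aw)
}

attn_backward <- function(dO, cache, Zn, n, Tt, n_heads, Wq, Wk, Wv) {
  d_z <- ncol(Wq)
  d_h <- d_z / n_heads
  dQ <- matrix(0, n * Tt, d_z)
  dK <- matrix(0, n * Tt, d_z)
  dV <- matrix(0, n * Tt, d_z)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * d_h + 1):(h * d_h)
    for (t in seq_len(Tt)) {
      rows_t <- ((t - 1) * n + 1):(t * n)
      dOt <- dO[rows_t, cols, drop = FALSE]
      W <- cache$Aw[[h]][[t]]
      dA <- matrix(0, n, t)
      for (s in seq_len(t)) {
        rows_s <- ((s - 1) * n + 1):(s * n)
        dA[, s] <- rowSums(dOt * cache$V[rows_s, cols, drop = FALSE])
      }
      dS <- W * (dA - rowSums(W * dA))
      for (s in seq_len(t)) {
        rows_s <- ((s - 1) * n + 1):(s * n)
        dV[rows_s, cols] <- dV[rows_s, cols] + W[, s] * dOt
        dQ[rows_t, cols] <- dQ[rows_t, cols] +
          dS[, s] * cache$K[rows_s, cols, drop = FALSE] / sqrt(d_h)
        dK[rows_s, cols] <- dK[rows_s, cols] +
          dS[, s] * cache$Q[rows_t, cols, drop = FALSE] / sqrt(d_h)
      }
    }
  }
  list(dZn = dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv),
       dWq = crossprod(Zn, dQ), dWk = crossprod(Zn, dK),
       dWv = crossprod(Zn, dV))
}

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1, 1 - p) / (1 - p), nr, nc)
}

# Full encoder forward. U: n x T x d_in. Returns the last-layer states as an
# (n*T) x d_z matrix plus (optionally) all caches needed for backprop.
# Dropout is active only when train = TRUE (draws from the current RNG
# stream).
encode_forward <- function(model, U, train = FALSE, keep_cache = FALSE) {
  n <- dim(U)[1]; Tt <- dim(U)[2]
  cfg <- model$config
  p_drop <- if (train) cfg$dropout else 0
  Uf <- mat3(U)
  Z <- sweep(Uf %*% model$params$input$W, 2, model$params$input$b, "+")
  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- model$params$layers[[l]]
    ln1 <- ln_forward(Z, lp$ln1_g, lp$ln1_b)
    at <- attn_forward(ln1$out, n, Tt, cfg$n_heads, lp$Wq, lp$Wk, lp$Wv)
    dm1 <- dropout_mask(nrow(at$O), ncol(at$O), p_drop)
    O <- if (is.null(dm1)) at$O else at$O * dm1
    a <- Z + O
    ln2 <- ln_forward(a, lp$ln2_g, lp$ln2_b)
    H_pre <- sweep(ln2$out %*% lp$W1, 2, lp$b1, "+")
    H <- pmax(H_pre, 0)
    Ff <- sweep(H %*% lp$W2, 2, lp$b2, "+")
    dm2 <- dropout_mask(nrow(Ff), ncol(Ff), p_drop)
    Fd <- if (is.null(dm2)) Ff else Ff * dm2
    Z_next <- a + Fd
    if (keep_cache) {
      caches[[l]] <- list(Z_in = Z, ln1 = ln1, attn = at, dm1 = dm1, a = a,
                          ln2 = ln2, H = H, dm2 = dm2)
    }
    Z <- Z_next
  }
  list(ZL = Z, n = n, Tt = Tt, Uf = if (keep_cache) Uf else NULL,
       caches = if (keep_cache) caches else NULL)
}

# Backward through the encoder given dL/dZL. Returns gradients for the input
# affine map and every layer.
encode_backward <- function(model, fwd, dZL) {
  cfg <- model$config
  n <- fwd$n; Tt <- fwd$Tt
  dZ <- dZL
  g_layers <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- model$params$layers[[l]]
    cc <- fwd$caches[[l]]
    dFd <- dZ
    da <- dZ
    dF <- if (is.null(cc$dm2)) dFd else dFd * cc$dm2
    dH <- dF %*% t(lp$W2)
    dW2 <- crossprod(cc$H, dF)
    db2 <- colSums(dF)
    dH_pre <- dH * (cc$H > 0)
    dln2_out <- dH_pre %*% t(lp$W1)
    dW1 <- crossprod(cc$ln2$out, dH_pre)
    db1 <- colSums(dH_pre)
    ln2b <- ln_backward(dln2_out, cc$ln2, lp$ln2_g)
    da <- da + ln2b$dZ
    dO <- if (is.null(cc$dm1)) da else da * cc$dm1
    ab <- attn_backward(dO, cc$attn, cc$ln1$out, n, Tt, cfg$n_heads,
                        lp$Wq, lp$Wk, lp$Wv)
    ln1b <- ln_backward(ab$dZn, cc$ln1, lp$ln1_g)
    dZ_in <- da + ln1b$dZ
    g_layers[[l]] <- list(ln1_g = ln1b$dg, ln1_b = ln1b$db,
                          Wq = ab$dWq, Wk = ab$dWk, Wv = ab$dWv,
                          ln2_g = ln2b$dg, ln2_b = ln2b$db,
                          W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
    dZ <- dZ_in
  }
  list(input = list(W = crossprod(fwd$Uf, dZ), b = colSums(dZ)),
       layers = g_layers)
}

pred_forward <- function(params_pred, Z, keep_cache = FALSE) {
  H_pre <- sweep(Z %*% params_pred$W1, 2, params_pred$b1, "+")
  H <- pmax(H_pre, 0)
  P <- sweep(H %*% params_pred$W2, 2, params_pred$b2, "+")
  if (keep_cache) list(P = P, H = H) else list(P = P)
}

pred_backward <- function(params_pred, Z, cache, dP) {
  dH <- (dP %*% t(params_pred$W2)) * (cache$H > 0)
  list(grads = list(W1 = crossprod(Z, dH), b1 = colSums(dH),
                    W2 = crossprod(cache$H, dP), b2 = colSums(dP)),
       dZ = dH %*% t(params_pred$W1))
}

head_forward <- function(head, Feat, nonlinear, keep_cache = FALSE) {
  if (nonlinear) {
    H <- pmax(sweep(Feat %*% head$W1, 2, head$b1, "+"), 0)
    S <- sweep(H %*% head$W2, 2, head$b2, "+")
    if (keep_cache) list(S = S, H = H) else list(S = S)
  } else {
    S <- sweep(Feat %*% head$W, 2, head$b, "+")
    list(S = S)
  }
}

head_backward <- function(head, Feat, cache, dS, nonlinear) {
  if (nonlinear) {
    dH <- (dS %*% t(head$W2)) * (cache$H > 0)
    list(W1 = crossprod(Feat, dH), b1 = colSums(dH),
         W2 = crossprod(cache$H, dS), b2 = colSums(dS))
  } else {
    list(W = crossprod(Feat, dS), b = colSums(dS))
  }
}

#' Encode a cohort into hidden-state trajectories
#'
#' Runs the causal self-attention stack over the first `T_use` periods and
#' returns the last-layer hidden states. States at period `t` depend only on
#' inputs at periods `<= t`.
#'
#' @param model A `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param T_use Number of leading periods to encode (default: all).
#' @return `n x T_use x d_z` array of last-layer states.
#' @export
encode <- function(model, cohort, T_use = NULL) {
  Tt <- dim(cohort$X)[2]
  T_use <- T_use %||% Tt
  if (T_use < 1) stop("at least one time step is required", call. = FALSE)
  U <- build_inputs(model, cohort, T_use = T_use)
  fwd <- encode_forward(model, U)
  arr3(fwd$ZL, dim(U)[1], T_use)
}

#' One-step-ahead biomarker forecast
#'
#' Applies the forecasting head to the last-layer state at period
#' `t_cond - 1`, predicting the (normalized-scale) biomarker vector at period
#' `t_cond`.
#'
#' @param model A `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param t_cond Conditioning window (periods `0 .. t_cond - 1` observed).
#' @return `n x J` matrix of predictions for period `t_cond`.
#' @export
forecast_next <- function(model, cohort, t_cond) {
  Z <- encode(model, cohort, T_use = t_cond)
  n <- dim(Z)[1]
  z_last <- matrix(Z[, t_cond, ], n, model$config$d_z)
  P <- pred_forward(model$params$pred, z_last)$P
  colnames(P) <- model$meta$vars
  P
}

#' Autoregressive multi-step rollout
#'
#' Iteratively feeds each one-step forecast back as the next period's input.
#' Observed biomarkers are used only up to `t_cond`; future treatments and
#' time embeddings are taken as given (advancing with the rollout unless the
#' model was configured with `literal_rollout`). The mask channel at rolled
#' positions is set to "observed", as predictions substitute for
#' measurements.
#'
#' @param model A `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param t_cond Conditioning window (>= 1).
#' @param horizon Number of future periods to predict (>= 1).
#' @return list with `X_pred` (`n x horizon x J`, periods `t_cond ..
#'   t_cond + horizon - 1`, normalized scale) and `states`
#'   (`n x horizon x d_z`; `states[, r, ]` is the last-layer state that
#'   produced prediction `r` — the first comes from observed data, the rest
#'   from rolled-out inputs).
#' @export
rollout <- function(model, cohort, t_cond, horizon) {
  Tt <- dim(cohort$X)[2]
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  if (t_cond < 1) stop("`t_cond` must be >= 1", call. = FALSE)
  if (t_cond + horizon - 1 > Tt) {
    stop("treatment plan covers ", Tt, " periods; t_cond + horizon - 1 = ",
         t_cond + horizon - 1, " required", call. = FALSE)
  }
  n <- dim(cohort$X)[1]; J <- model$meta$J
  X_work <- cohort$X
  M_work <- cohort$M
  X_pred <- array(0, c(n, horizon, J),
                  dimnames = list(dimnames(cohort$X)[[1]], NULL,
                                  model$meta$vars))
  states <- array(0, c(n, horizon, model$config$d_z))
  for (r in seq_len(horizon)) {
    T_use <- t_cond + r - 1
    E_idx <- 0:(T_use - 1)
    if (model$config$literal_rollout && r > 1) {
      # Rolled positions reuse the previous period's A(t) and E(t).
      roll_pos <- (t_cond + 1):T_use
      E_idx[roll_pos] <- E_idx[roll_pos] - 1
      A_work <- cohort$As
      A_work[, roll_pos, ] <- cohort$As[, roll_pos - 1, , drop = FALSE]
      cohort_step <- cohort
      cohort_step$As <- A_work
    } else {
      cohort_step <- cohort
    }
    U <- build_inputs(model, cohort_step, T_use = T_use, X_work = X_work,
                      M_work = M_work, E_idx = E_idx)
    fwd <- encode_forward(model, U)
    z_last <- fwd$ZL[((T_use - 1) * n + 1):(T_use * n), , drop = FALSE]
    states[, r, ] <- z_last
    xhat <- pred_forward(model$params$pred, z_last)$P
    X_pred[, r, ] <- xhat
    if (T_use + 1 <= Tt) {
      X_work[, T_use + 1, ] <- xhat
      M_work[, T_use + 1, ] <- 1
    }
  }
  list(X_pred = X_pred, states = states, t_cond = t_cond, horizon = horizon)
}

# Event-head input features at a conditioning time: the state computed from
# observed data at period t_cond - 1 concatenated with K rolled-out states.
event_features <- function(model, cohort, t_cond) {
  K <- model$config$K
  ro <- rollout(model, cohort, t_cond, horizon = K + 1)
  n <- dim(ro$states)[1]
  Feat <- do.call(cbind, lapply(seq_len(K + 1), function(r) {
    matrix(ro$states[, r, ], n, model$config$d_z)
  }))
  rownames(Feat) <- cohort$baseline$patient_id
  Feat
}

#' Event risk score at a conditioning time
#'
#' `y_hat_t = f_event([z_t, ..., z_{t+K}])` where the states beyond the
#' conditioning window are produced by rollout; the score at `t_cond` uses no
#' information after `t_cond`.
#'
#' @param model A `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param t_cond Conditioning window.
#' @param type `"pfs"`, `"os"` or `"ae"`.
#' @return For `"pfs"`/`"os"` a numeric vector (one score per patient); for
#'   `"ae"` an `n x 12` matrix (one column per adverse-event type).
#' @export
event_score <- function(model, cohort, t_cond, type = c("pfs", "os", "ae")) {
  type <- match.arg(type)
  Feat <- event_features(model, cohort, t_cond)
  S <- head_forward(model$params$heads[[type]], Feat,
                    model$config$nonlinear_head)$S
  if (type == "ae") {
    colnames(S) <- ae_types()
    S
  } else {
    stats::setNames(drop(S), rownames(Feat))
  }
}

#' Normalized (quantile-like) risk score
#'
#' Rescales a raw Cox-head score by the train-set extremes:
#' `(y - y_min) / (y_max - y_min)`, clipped to `[0, 1]`. A normalized risk of
#' 0.7 means 70% of the training cohort have a lower risk score.
#'
#' @param score Raw score(s).
#' @param train_scores Collection of raw scores over the training set
#'   (patients and, where applicable, times).
#' @return Normalized risk in `[0, 1]`.
#' @export
normalized_risk <- function(score, train_scores) {
  lo <- min(train_scores)
  hi <- max(train_scores)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
    stop("train scores are degenerate (max must exceed min)", call. = FALSE)
  }
  pmin(pmax((score - lo) / (hi - lo), 0), 1)
}
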