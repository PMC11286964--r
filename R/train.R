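# Two-stage optimization: autoregressive forecasting pre-training of the
# whole encoder, then event-head fine-tuning with a frozen backbone, plus
# bootstrap aggregation and hyperparameter grid search.

#' Masked forecasting loss
#'
#' Per patient, the squared forecast error summed over observed entries and
#' divided by that patient's number of observed entries, averaged over
#' patients. Masked entries contribute nothing. Patients with zero observed
#' entries are excluded with a warning.
#'
#' @param X `n x T x J` array of target values.
#' @param X_hat Array of predictions with the same shape.
#' @param M `n x T x J` observation mask (1 = observed).
#' @return Non-negative scalar.
#' @export
forecast_loss <- function(X, X_hat, M) {
  stopifnot(all(dim(X) == dim(X_hat)), all(dim(X) == dim(M)))
  n <- dim(X)[1]
  se <- M * (X - X_hat)^2
  num <- apply(se, 1, sum)
  den <- apply(M, 1, sum)
  keep <- den > 0
  if (!any(keep)) stop("no observed entries in the loss window",
                       call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " patient(s) with zero observed entries excluded ",
            "from the forecasting loss", call. = FALSE)
  }
  mean(num[keep] / den[keep])
}

# Forward + backward pass for the teacher-forced one-step forecasting
# objective on a (sub)cohort. States at period t predict targets at t+1.
# Returns the loss and gradients for the input map, layers and forecast head.
forecast_grad <- function(model, cohort, train = TRUE) {
  n <- dim(cohort$X)[1]; Tt <- dim(cohort$X)[2]; J <- model$meta$J
  U <- build_inputs(model, cohort)
  fwd <- encode_forward(model, U, train = train, keep_cache = TRUE)
  pf <- pred_forward(model$params$pred, fwd$ZL, keep_cache = TRUE)
  # Row block t of P predicts period t+1 (1-based); the last block is unused.
  X_hat <- array(0, c(n, Tt, J))
  P <- arr3(pf$P, n, Tt)
  if (Tt > 1) X_hat[, 2:Tt, ] <- P[, 1:(Tt - 1), ]
  M_loss <- cohort$M
  M_loss[, 1, ] <- 0  # the first period has no prediction
  den <- apply(M_loss, 1, sum)
  keep <- den > 0
  n_eff <- sum(keep)
  if (n_eff == 0) stop("no observed entries to train on", call. = FALSE)
  resid <- M_loss * (cohort$X - X_hat)
  loss <- mean(apply(resid * (cohort$X - X_hat), 1, sum)[keep] / den[keep])
  # dL/dX_hat, mapped back to prediction rows.
  w <- ifelse(keep, 1 / (den * n_eff), 0)
  dXhat <- -2 * resid * array(w, dim(resid))
  dP <- array(0, c(n, Tt, J))
  if (Tt > 1) dP[, 1:(Tt - 1), ] <- dXhat[, 2:Tt, ]
  dP <- mat3(dP)
  pb <- pred_backward(model$params$pred, fwd$ZL, pf, dP)
  enc <- encode_backward(model, fwd, pb$dZ)
  list(loss = loss,
       grads = list(input = enc$input, layers = enc$layers,
                    pred = pb$grads))
}

# Teacher-forced forecasting loss without gradient (no dropout), e.g. for
# validation curves.
forecast_eval_loss <- function(model, cohort) {
  n <- dim(cohort$X)[1]; Tt <- dim(cohort$X)[2]; J <- model$meta$J
  U <- build_inputs(model, cohort)
  fwd <- encode_forward(model, U)
  P <- arr3(pred_forward(model$params$pred, fwd$ZL)$P, n, Tt)
  X_hat <- array(0, c(n, Tt, J))
  if (Tt > 1) X_hat[, 2:Tt, ] <- P[, 1:(Tt - 1), ]
  M_loss <- cohort$M
  M_loss[, 1, ] <- 0
  suppressWarnings(forecast_loss(cohort$X, X_hat, M_loss))
}

#' Cox partial-likelihood event loss
#'
#' Negative Breslow partial log-likelihood of the risk scores:
#' `-sum_{i: event} w_i * (s_i - log sum_{j in R(y_i)} exp(s_j))` with risk
#' set `R(y) = {j : y_j >= y}` (Breslow tie handling). By default `w_i = 1`
#' (scores taken at the conditioning time); `landmark = TRUE` uses the
#' landmark-aggregated weighting `w_i = sum_{t >= y_i} 1 / d(t)` with `d(t)`
#' the number of events observed by `t`, which reduces the aggregate to a sum
#' of repeated partial likelihoods.
#'
#' @param scores Numeric vector of risk scores (one per patient).
#' @param time Event/censoring times (periods, > 0).
#' @param status Event indicators (1 = event, 0 = censored).
#' @param landmark Use the landmark-weighted form.
#' @param T_max Last landmark time (default: `max(time)`).
#' @return Scalar loss (lower is better). Shift-invariant in the scores.
#' @export
cox_event_loss <- function(scores, time, status, landmark = FALSE,
                           T_max = NULL) {
  if (!any(status == 1)) stop("at least one event is required", call. = FALSE)
  if (any(!is.finite(scores))) stop("non-finite risk score", call. = FALSE)
  w <- cox_event_weights(time, status, landmark, T_max)
  s <- scores - max(scores)
  loss <- 0
  for (i in which(status == 1)) {
    rs <- time >= time[i]
    loss <- loss - w[i] * (s[i] - log(sum(exp(s[rs]))))
  }
  loss
}

cox_event_weights <- function(time, status, landmark = FALSE, T_max = NULL) {
  w <- as.numeric(status == 1)
  if (landmark) {
    T_max <- T_max %||% max(time)
    lm_times <- seq_len(floor(T_max))
    d <- vapply(lm_times, function(t) sum(status == 1 & time <= t),
                numeric(1))
    for (i in which(status == 1)) {
      valid <- lm_times >= time[i] & d > 0
      w[i] <- sum(1 / d[valid])
    }
  }
  w
}

# Analytic gradient of cox_event_loss with respect to the scores.
cox_loss_grad <- function(scores, time, status, landmark = FALSE,
                          T_max = NULL) {
  w <- cox_event_weights(time, status, landmark, T_max)
  s <- scores - max(scores)
  es <- exp(s)
  g <- -w * (status == 1)
  for (i in which(status == 1)) {
    rs <- time >= time[i]
    g[rs] <- g[rs] + w[i] * es[rs] / sum(es[rs])
  }
  g
}

#' Pre-train the encoder on the forecasting objective
#'
#' Minimizes [forecast_loss()] with Adam under teacher forcing (observed
#' inputs at every step). Event heads are untouched. Training is
#' deterministic given the seed.
#'
#' @param model A `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param idx Patient indices to train on (default: all).
#' @param val_idx Optional validation indices; the validation loss is logged
#'   per epoch and used for early stopping.
#' @param epochs Number of full-batch epochs.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience on the validation loss.
#' @param seed Integer seed governing dropout draws.
#' @param verbose Print the loss every 10 epochs.
#' @return The trained model with a `loss_curve` data.frame attached.
#' @export
pretrain <- function(model, cohort, idx = NULL, val_idx = NULL, epochs = 100,
                     lr = 1e-3, patience = Inf, seed = 1L, verbose = FALSE) {
  n <- dim(cohort$X)[1]
  idx <- idx %||% seq_len(n)
  train_cohort <- if (length(idx) == n && all(idx == seq_len(n))) cohort else
    subset_cohort(cohort, idx)
  val_cohort <- if (!is.null(val_idx)) subset_cohort(cohort, val_idx)
  trainable <- model$params[c("input", "layers", "pred")]
  opt <- adam_init(trainable)
  curve <- data.frame(epoch = integer(0), train = numeric(0),
                      val = numeric(0))
  best_val <- Inf
  best_params <- trainable
  stall <- 0
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      fg <- forecast_grad(model, train_cohort)
      if (!is.finite(fg$loss)) {
        stop("forecasting loss diverged (non-finite) at epoch ", ep,
             "; reduce the learning rate", call. = FALSE)
      }
      st <- adam_step(trainable, fg$grads, opt, lr = lr)
      trainable <- st$params
      opt <- st$state
      model$params[c("input", "layers", "pred")] <- trainable
      val_loss <- if (!is.null(val_idx)) {
        forecast_eval_loss(model, val_cohort)
      } else NA_real_
      curve <- rbind(curve, data.frame(epoch = ep, train = fg$loss,
                                       val = val_loss))
      if (verbose && ep %% 10 == 0) {
        message(sprintf("epoch %d  train %.5f  val %.5f", ep, fg$loss,
                        val_loss))
      }
      if (!is.null(val_idx)) {
        if (val_loss < best_val - 1e-9) {
          best_val <- val_loss
          best_params <- trainable
          stall <- 0
        } else {
          stall <- stall + 1
          if (stall >= patience) break
        }
      }
    }
  })
  if (!is.null(val_idx) && is.finite(best_val)) {
    model$params[c("input", "layers", "pred")] <- best_params
  }
  model$loss_curve <- curve
  model
}

#' Fine-tune an event head with a frozen backbone
#'
#' Computes the event-head input features once (the backbone is frozen, so
#' they never change), then minimizes [cox_event_loss()] over the selected
#' head's parameters with Adam. For the adverse-event head the twelve
#' per-event losses are summed by default (`ae_joint = TRUE`); the per-event
#' alternative optimizes each output column in turn.
#'
#' @param model A pre-trained `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param event_type `"pfs"`, `"os"` or `"ae"`.
#' @param idx Patient indices to train on (default: all).
#' @param t_cond Conditioning time at which scores are taken (default 1).
#' @param epochs Adam steps.
#' @param lr Learning rate.
#' @param landmark Use the landmark-weighted Cox loss.
#' @param ae_joint Sum the twelve AE losses (default) instead of optimizing
#'   each column separately.
#' @param seed Integer seed.
#' @return The model with the selected head trained, the train-score range
#'   stored for [normalized_risk()], and a `finetune_curve` attached. All
#'   other parameters are byte-identical to the input model.
#' @export
finetune_heads <- function(model, cohort, event_type = c("pfs", "os", "ae"),
                           idx = NULL, t_cond = 1, epochs = 200, lr = 1e-2,
                           landmark = FALSE, ae_joint = TRUE, seed = 1L) {
  event_type <- match.arg(event_type)
  n <- dim(cohort$X)[1]
  idx <- idx %||% seq_len(n)
  train_cohort <- if (length(idx) == n && all(idx == seq_len(n))) cohort else
    subset_cohort(cohort, idx)
  Feat <- event_features(model, train_cohort, t_cond)
  events <- if (event_type == "ae") ae_types() else event_type
  out_list <- lapply(events, function(e) outcomes_for(train_cohort, e))
  for (ol in out_list) {
    if (!any(ol$status == 1)) {
      stop("no events of the requested type in the training fold",
           call. = FALSE)
    }
  }
  head <- model$params$heads[[event_type]]
  nl <- model$config$nonlinear_head
  opt <- adam_init(head)
  curve <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      hf <- head_forward(head, Feat, nl, keep_cache = TRUE)
      S <- hf$S
      dS <- matrix(0, nrow(S), ncol(S))
      loss <- 0
      active <- if (event_type == "ae" && !ae_joint) {
        1 + (ep - 1) %% length(events)   # cycle through the columns
      } else {
        seq_along(events)
      }
      for (k in active) {
        ol <- out_list[[k]]
        loss <- loss + cox_event_loss(S[, k], ol$time, ol$status,
                                      landmark = landmark)
        dS[, k] <- cox_loss_grad(S[, k], ol$time, ol$status,
                                 landmark = landmark)
      }
      grads <- head_backward(head, Feat, hf, dS / nrow(S), nl)
      st <- adam_step(head, grads, opt, lr = lr)
      head <- st$params
      opt <- st$state
      curve[ep] <- loss
    }
  })
  model$params$heads[[event_type]] <- head
  S_final <- head_forward(head, Feat, nl)$S
  model$score_range[[event_type]] <- list(min = min(S_final),
                                          max = max(S_final),
                                          t_cond = t_cond)
  model$finetune_curve <- curve
  model
}

#' Fit a bootstrap-aggregated ensemble
#'
#' Trains `n_bags` models, each on a with-replacement resample of the training
#' set of size `round(resample_factor * n_train)`, pre-training on the
#' forecasting objective and fine-tuning the requested event heads.
#' Predictions are aggregated by the mean; the between-model standard
#' deviation is the uncertainty estimate.
#'
#' @param cohort A preprocessed `cf_cohort`.
#' @param train_idx Training-fold patient indices.
#' @param config An [encoder_config()].
#' @param n_bags Number of bagged models (default 5).
#' @param resample_factor Resample size as a multiple of the training set
#'   (default 1.5).
#' @param pretrain_epochs,finetune_epochs,lr_pretrain,lr_finetune Training
#'   budget per bag.
#' @param events Event heads to fine-tune.
#' @param t_cond Conditioning time for fine-tuning.
#' @param seed Integer seed; per-bag seeds are derived from it.
#' @return An object of class `cf_ensemble`.
#' @export
fit_bagged_ensemble <- function(cohort, train_idx, config = encoder_config(),
                                n_bags = 5, resample_factor = 1.5,
                                pretrain_epochs = 60, finetune_epochs = 150,
                                lr_pretrain = 1e-3, lr_finetune = 1e-2,
                                events = "pfs", t_cond = 1, seed = 1L) {
  if (n_bags < 2) {
    warning("fewer than 2 bags: no between-model uncertainty", call. = FALSE)
  }
  models <- vector("list", n_bags)
  bags <- vector("list", n_bags)
  for (b in seq_len(n_bags)) {
    bag_seed <- derive_seed(seed, paste0("bag", b))
    bag_idx <- with_seed(bag_seed, {
      sample(train_idx, round(resample_factor * length(train_idx)),
             replace = TRUE)
    })
    bags[[b]] <- bag_idx
    m <- init_model(cohort, config, seed = derive_seed(bag_seed, "init"))
    m <- pretrain(m, cohort, idx = bag_idx, epochs = pretrain_epochs,
                  lr = lr_pretrain, seed = derive_seed(bag_seed, "pretrain"))
    for (e in events) {
      m <- finetune_heads(m, cohort, event_type = e, idx = bag_idx,
                          t_cond = t_cond, epochs = finetune_epochs,
                          lr = lr_finetune,
                          seed = derive_seed(bag_seed, paste0("ft_", e)))
    }
    models[[b]] <- m
  }
  structure(list(models = models, bags = bags, config = config,
                 events = events, t_cond = t_cond, seed = seed),
            class = "cf_ensemble")
}

#' Aggregate ensemble predictions
#'
#' @param ensemble A `cf_ensemble`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param t_cond Conditioning time.
#' @param type `"pfs"`, `"os"` or `"ae"` for event scores, or `"forecast"`
#'   for rolled-out biomarker trajectories (requires `horizon`).
#' @param horizon Forecast horizon when `type = "forecast"`.
#' @return list with `mean`, `sd` (between-model spread) and `per_model`.
#' @export
predict_ensemble <- function(ensemble, cohort, t_cond,
                             type = c("pfs", "os", "ae", "forecast"),
                             horizon = NULL) {
  type <- match.arg(type)
  per_model <- lapply(ensemble$models, function(m) {
    if (type == "forecast") {
      rollout(m, cohort, t_cond, horizon)$X_pred
    } else {
      event_score(m, cohort, t_cond, type)
    }
  })
  stack <- simplify2array(per_model)
  nd <- length(dim(stack))
  list(mean = apply(stack, seq_len(nd - 1), mean),
       sd = apply(stack, seq_len(nd - 1), stats::sd),
       per_model = per_model)
}

#' Default hyperparameter grid
#'
#' The tuned grid: hidden dimension 16 or 32, dropout 0.1 or 0.2, rollout
#' window 0 or 1, 2 layers, linear or non-linear event head — 16
#' configurations.
#' @return data.frame of configurations.
#' @export
default_grid <- function() {
  expand.grid(d_z = c(16L, 32L), dropout = c(0.1, 0.2), K = c(0L, 1L),
              n_layers = 2L, nonlinear_head = c(TRUE, FALSE))
}

#' Select encoder hyperparameters across validation folds
#'
#' Trains one model per (configuration, fold) pair and selects the
#' configuration with the best mean validation objective across the five
#' folds (validation forecasting loss by default).
#'
#' @param cohort A preprocessed `cf_cohort`.
#' @param split_plan A [split_cohort()] plan.
#' @param grid data.frame of configurations (default: [default_grid()]).
#' @param pretrain_epochs,lr Training budget per cell.
#' @param seed Integer seed.
#' @return list with `best_config` (an [encoder_config()]), `results`
#'   (the full grid-by-fold table) and `summary`.
#' @export
tune_hyperparameters <- function(cohort, split_plan, grid = default_grid(),
                                 pretrain_epochs = 30, lr = 1e-3, seed = 1L) {
  if (is.null(grid) || nrow(grid) == 0) stop("empty hyperparameter grid",
                                             call. = FALSE)
  results <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- encoder_config(d_z = grid$d_z[g], dropout = grid$dropout[g],
                          K = grid$K[g], n_layers = grid$n_layers[g],
                          nonlinear_head = grid$nonlinear_head[g])
    for (f in seq_along(split_plan$folds)) {
      fold <- split_plan$folds[[f]]
      m <- init_model(cohort, cfg, seed = derive_seed(seed, paste0(g, "i", f)))
      m <- pretrain(m, cohort, idx = fold$train, epochs = pretrain_epochs,
                    lr = lr, seed = derive_seed(seed, paste0(g, "p", f)))
      val_loss <- forecast_eval_loss(m, subset_cohort(cohort, fold$val))
      results[[length(results) + 1]] <-
        cbind(grid[g, , drop = FALSE],
              data.frame(fold = f, val_loss = val_loss))
    }
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL
  agg <- stats::aggregate(val_loss ~ d_z + dropout + K + n_layers +
                            nonlinear_head, data = results, FUN = mean)
  best <- agg[which.min(agg$val_loss), ]
  best_config <- encoder_config(d_z = best$d_z, dropout = best$dropout,
                                K = best$K, n_layers = best$n_layers,
                                nonlinear_head = best$nonlinear_head)
  list(best_config = best_config, results = results, summary = agg)
}
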