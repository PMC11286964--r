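# Evaluation protocol: truncated IPCW (Uno) concordance averaged over
# event-time quantiles, masked forecasting MSE over horizons, the LOCF
# baseline, and the statistical comparison machinery.

# Kaplan-Meier estimate of the censoring survival function G(t). Ties between
# events and censorings at the same time are resolved by letting events occur
# first: subjects with an event at t are not at risk of censoring at t.
censor_km <- function(time, status) {
  tu <- sort(unique(time))
  surv <- numeric(length(tu))
  g <- 1
  for (k in seq_along(tu)) {
    t <- tu[k]
    at_risk <- sum(time >= t) - sum(time == t & status == 1)
    n_cens <- sum(time == t & status == 0)
    if (at_risk > 0) g <- g * (1 - n_cens / at_risk)
    surv[k] <- g
  }
  # Left-continuous evaluation G(t-): survival just before t.
  function(t, left = TRUE) {
    vapply(t, function(tt) {
      idx <- if (left) which(tu < tt) else which(tu <= tt)
      if (!length(idx)) 1 else surv[max(idx)]
    }, numeric(1))
  }
}

#' IPCW (Uno) concordance index truncated at an evaluation time
#'
#' Fraction of usable pairs ranked concordantly by the risk scores, weighted
#' by the inverse squared Kaplan-Meier censoring survival at the earlier event
#' time. A pair (i, j) is usable when patient i has an observed event, with
#' `y_i < y_j` and `y_i <= eval_time`; tied scores count 1/2. Higher scores
#' must indicate higher risk (earlier events). Uninformative scores give 0.5;
#' with no censoring and `eval_time` beyond the last event this equals
#' Harrell's pairwise concordance.
#'
#' @param scores Risk scores (one per patient; higher = riskier).
#' @param time Observed times.
#' @param status Event indicators (1 = event, 0 = censored).
#' @param eval_time Truncation (landmark) time.
#' @return Concordance in `[0, 1]`.
#' @export
cindex_ipcw <- function(scores, time, status, eval_time = max(time)) {
  stopifnot(length(scores) == length(time), length(time) == length(status))
  G <- censor_km(time, status)
  ii <- which(status == 1 & time <= eval_time)
  num <- 0
  den <- 0
  for (i in ii) {
    cmp <- time > time[i]
    if (!any(cmp)) next
    g <- G(time[i])
    if (g <= 0) next
    w <- 1 / g^2
    num <- num + w * (sum(scores[i] > scores[cmp]) +
                        0.5 * sum(scores[i] == scores[cmp]))
    den <- den + w * sum(cmp)
  }
  if (den == 0) stop("no comparable pairs at eval_time = ", eval_time,
                     call. = FALSE)
  num / den
}

#' Concordance averaged over event-time quantiles
#'
#' Mean of [cindex_ipcw()] at the 25th/50th/75th (by default) quantiles of
#' the observed event times of the evaluation fold (linear-interpolation
#' quantile rule). Quantile times with no comparable pairs are dropped with a
#' warning.
#'
#' @param scores,time,status As in [cindex_ipcw()].
#' @param quantiles Strictly increasing probabilities in (0, 1).
#' @return Averaged concordance.
#' @export
averaged_cindex <- function(scores, time, status,
                            quantiles = c(0.25, 0.5, 0.75)) {
  if (any(diff(quantiles) <= 0) || any(quantiles <= 0) ||
      any(quantiles >= 1)) {
    stop("`quantiles` must be strictly increasing in (0, 1)", call. = FALSE)
  }
  ev_times <- time[status == 1]
  if (!length(ev_times)) stop("no observed events", call. = FALSE)
  qs <- stats::quantile(ev_times, quantiles, type = 7, names = FALSE)
  vals <- numeric(0)
  for (q in qs) {
    ci <- tryCatch(cindex_ipcw(scores, time, status, eval_time = q),
                   error = function(e) NA_real_)
    if (is.na(ci)) {
      warning("no comparable pairs at quantile time ", signif(q, 4),
              "; term dropped", call. = FALSE)
    } else {
      vals <- c(vals, ci)
    }
  }
  if (!length(vals)) stop("no evaluable quantile times", call. = FALSE)
  mean(vals)
}

#' Masked forecasting mean squared error
#'
#' Mean squared error over the observed entries of a forecasting window
#' (normalized scale), optionally restricted to a variable group.
#'
#' @param X_hat Predicted `n x h x J` array.
#' @param X True values, same shape.
#' @param M Observation mask, same shape.
#' @param vars Optional variable names to restrict to.
#' @return Scalar MSE; it is invariant to values at masked entries.
#' @export
forecast_mse <- function(X_hat, X, M, vars = NULL) {
  stopifnot(all(dim(X_hat) == dim(X)), all(dim(X) == dim(M)))
  if (!is.null(vars)) {
    X_hat <- X_hat[, , vars, drop = FALSE]
    X <- X[, , vars, drop = FALSE]
    M <- M[, , vars, drop = FALSE]
  }
  if (sum(M) == 0) stop("zero observed entries in the evaluation window",
                        call. = FALSE)
  sum(M * (X - X_hat)^2) / sum(M)
}

# Slice the true panel over a forecasting window (periods t_cond ..
# t_cond + horizon - 1, 0-based).
horizon_slice <- function(cohort, t_cond, horizon) {
  Tt <- dim(cohort$X)[2]
  if (t_cond + horizon > Tt) stop("window extends past follow-up",
                                  call. = FALSE)
  idx <- (t_cond + 1):(t_cond + horizon)
  list(X = cohort$X[, idx, , drop = FALSE],
       M = cohort$M[, idx, , drop = FALSE])
}

#' Last-observation-carried-forward forecast baseline
#'
#' Every horizon entry equals the last observed value at or before the
#' conditioning window (falling back to the imputed value at the last
#' conditioning period when a variable was never observed).
#'
#' @param cohort A preprocessed `cf_cohort`.
#' @param t_cond Conditioning window.
#' @param horizon Forecast horizon.
#' @return `n x horizon x J` array of predictions.
#' @export
locf_forecast <- function(cohort, t_cond, horizon) {
  n <- dim(cohort$X)[1]; J <- dim(cohort$X)[3]
  vars <- dimnames(cohort$X)[[3]]
  last_val <- matrix(0, n, J, dimnames = list(NULL, vars))
  for (j in seq_len(J)) {
    xv <- cohort$X[, seq_len(t_cond), j, drop = FALSE]
    mv <- cohort$M[, seq_len(t_cond), j, drop = FALSE]
    for (i in seq_len(n)) {
      obs <- which(mv[i, , 1] == 1)
      last_val[i, j] <- if (length(obs)) xv[i, max(obs), 1] else
        xv[i, t_cond, 1]
    }
  }
  X_hat <- array(0, c(n, horizon, J), dimnames = list(NULL, NULL, vars))
  for (r in seq_len(horizon)) X_hat[, r, ] <- last_val
  X_hat
}

#' Evaluation grid definition
#'
#' @param t_cond Conditioning windows (periods).
#' @param t_horizon Forecasting horizons (periods).
#' @param quantiles Event-time quantiles for concordance averaging.
#' @param var_groups Named list of variable groups for the forecasting MSE
#'   (`NULL` entry = all variables).
#' @param by_subtype Also stratify by Ig heavy-chain subtype.
#' @return An object of class `cf_eval_grid`.
#' @export
eval_grid <- function(t_cond = c(1, 6, 12), t_horizon = c(6, 12),
                      quantiles = c(0.25, 0.5, 0.75),
                      var_groups = list(all = NULL), by_subtype = FALSE) {
  if (any(t_cond <= 0) || any(t_horizon <= 0)) {
    stop("`t_cond` and `t_horizon` must be positive", call. = FALSE)
  }
  if (any(diff(quantiles) <= 0)) {
    stop("`quantiles` must be strictly increasing", call. = FALSE)
  }
  structure(list(t_cond = t_cond, t_horizon = t_horizon,
                 quantiles = quantiles, var_groups = var_groups,
                 by_subtype = by_subtype),
            class = "cf_eval_grid")
}

#' Evaluate a bagged ensemble over an evaluation grid
#'
#' For every (task, t_cond, t_horizon, subgroup) cell, reports the mean and
#' between-model standard deviation of the metric over the bagged models:
#' quantile-averaged IPCW concordance for the event tasks and masked MSE for
#' the forecasting tasks. Subgroups with fewer than `min_subgroup` evaluable
#' patients are reported as missing cells.
#'
#' @param ensemble A `cf_ensemble`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param test_idx Evaluation-fold patient indices.
#' @param grid An [eval_grid()].
#' @param events Event tasks to score (subset of the ensemble's fine-tuned
#'   heads).
#' @param min_subgroup Minimum evaluable patients per subgroup cell.
#' @return Tidy data.frame: task, t_cond, t_horizon, subgroup, mean, sd,
#'   n_models, n_patients.
#' @export
evaluate_grid <- function(ensemble, cohort, test_idx, grid = eval_grid(),
                          events = ensemble$events, min_subgroup = 5) {
  test <- subset_cohort(cohort, test_idx)
  subgroups <- list(all = seq_len(length(test_idx)))
  if (grid$by_subtype) {
    for (s in levels(droplevels(test$baseline$subtype))) {
      subgroups[[s]] <- which(test$baseline$subtype == s)
    }
  }
  rows <- list()
  add_row <- function(...) rows[[length(rows) + 1]] <<- data.frame(...)
  for (tc in grid$t_cond) {
    # Event tasks: concordance does not involve the horizon.
    for (e in events) {
      per_model <- lapply(ensemble$models, function(m) {
        event_score(m, test, tc, type = e)
      })
      for (sg in names(subgroups)) {
        sel <- subgroups[[sg]]
        ol <- outcomes_for(test, e)[sel, , drop = FALSE]
        if (length(sel) < min_subgroup || sum(ol$status) < 2) {
          add_row(task = paste0("cindex_", e), t_cond = tc,
                  t_horizon = NA_real_, subgroup = sg, mean = NA_real_,
                  sd = NA_real_, n_models = length(per_model),
                  n_patients = length(sel))
          next
        }
        vals <- vapply(per_model, function(s) {
          tryCatch(averaged_cindex(s[sel], ol$time, ol$status,
                                   grid$quantiles),
                   error = function(err) NA_real_)
        }, numeric(1))
        add_row(task = paste0("cindex_", e), t_cond = tc,
                t_horizon = NA_real_, subgroup = sg,
                mean = mean(vals, na.rm = TRUE),
                sd = stats::sd(vals, na.rm = TRUE),
                n_models = sum(!is.na(vals)), n_patients = length(sel))
      }
    }
    for (th in grid$t_horizon) {
      if (tc + th > dim(test$X)[2]) next
      truth <- horizon_slice(test, tc, th)
      per_model <- lapply(ensemble$models, function(m) {
        rollout(m, test, tc, th)$X_pred
      })
      for (gname in names(grid$var_groups)) {
        vg <- grid$var_groups[[gname]]
        for (sg in names(subgroups)) {
          sel <- subgroups[[sg]]
          if (length(sel) < min_subgroup) {
            add_row(task = paste0("mse_", gname), t_cond = tc,
                    t_horizon = th, subgroup = sg, mean = NA_real_,
                    sd = NA_real_, n_models = length(per_model),
                    n_patients = length(sel))
            next
          }
          vals <- vapply(per_model, function(xp) {
            tryCatch(forecast_mse(xp[sel, , , drop = FALSE],
                                  truth$X[sel, , , drop = FALSE],
                                  truth$M[sel, , , drop = FALSE], vars = vg),
                     error = function(err) NA_real_)
          }, numeric(1))
          add_row(task = paste0("mse_", gname), t_cond = tc, t_horizon = th,
                  subgroup = sg, mean = mean(vals, na.rm = TRUE),
                  sd = stats::sd(vals, na.rm = TRUE),
                  n_models = sum(!is.na(vals)), n_patients = length(sel))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two methods' per-model metrics
#'
#' Per evaluation cell: a paired t-test across the per-model replicates
#' (five bagged models give 4 degrees of freedom). Overall: a two-way ANOVA
#' without interaction (factor 1 = method, factor 2 = condition cell).
#' Bonferroni correction across method pairs is applied via `n_pairs`.
#'
#' @param metrics_a,metrics_b Numeric matrices, one row per evaluation cell
#'   and one column per bagged model (same shape).
#' @param n_pairs Number of method pairs compared in the study (Bonferroni
#'   multiplier).
#' @param paired Use the paired t-test (default, df = replicates - 1);
#'   `FALSE` gives Welch's two-sample test.
#' @return list with `per_cell` (data.frame: cell, t, df, p, p_bonferroni)
#'   and `anova` (method-effect F and p, with Bonferroni-corrected p).
#' @export
compare_models <- function(metrics_a, metrics_b, n_pairs = 1, paired = TRUE) {
  metrics_a <- rbind(metrics_a)
  metrics_b <- rbind(metrics_b)
  if (!all(dim(metrics_a) == dim(metrics_b))) {
    stop("replicate counts differ between the two methods", call. = FALSE)
  }
  cells <- nrow(metrics_a)
  per_cell <- data.frame(cell = seq_len(cells), t = NA_real_, df = NA_real_,
                         p = NA_real_)
  for (r in seq_len(cells)) {
    a <- metrics_a[r, ]
    b <- metrics_b[r, ]
    if (isTRUE(all.equal(a, b))) {
      per_cell$t[r] <- 0
      per_cell$df[r] <- length(a) - 1
      per_cell$p[r] <- 1
    } else if (paired && stats::sd(a - b) == 0) {
      # constant non-zero paired difference: infinitely strong evidence
      per_cell$t[r] <- sign(mean(a - b)) * Inf
      per_cell$df[r] <- length(a) - 1
      per_cell$p[r] <- 0
    } else {
      tt <- stats::t.test(a, b, paired = paired)
      per_cell$t[r] <- unname(tt$statistic)
      per_cell$df[r] <- unname(tt$parameter)
      per_cell$p[r] <- tt$p.value
    }
  }
  per_cell$p_bonferroni <- pmin(per_cell$p * n_pairs, 1)
  long <- data.frame(
    value = c(as.vector(t(metrics_a)), as.vector(t(metrics_b))),
    method = rep(c("a", "b"), each = length(metrics_a)),
    cell = factor(rep(rep(seq_len(cells), each = ncol(metrics_a)), 2))
  )
  an <- if (cells > 1) {
    fit <- stats::aov(value ~ method + cell, data = long)
    s <- summary(fit)[[1]]
    list(F = s["method", "F value"], p = s["method", "Pr(>F)"],
         p_bonferroni = min(s["method", "Pr(>F)"] * n_pairs, 1))
  } else {
    list(F = NA_real_, p = NA_real_, p_bonferroni = NA_real_)
  }
  list(per_cell = per_cell, anova = an)
}
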