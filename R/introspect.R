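# Hidden-state interpretation: Pearson correlation maps between encoder
# state dimensions and predicted risks / next-step biomarker predictions,
# patient-level narrative summaries, and a 2-D manifold-embedding hook.

#' Correlation map between hidden dimensions and model predictions
#'
#' Across patients, the Pearson correlation between each last-layer hidden
#' dimension and (a) the predicted event risk and (b) each selected
#' biomarker's next-step prediction, at a set of inspection times. Constant
#' dimensions yield an undefined correlation, which is flagged `NA` and
#' excluded from the display set rather than zeroed. Display filtering never
#' alters the stored values: dimensions without any `|rho| >= threshold` are
#' only dropped from `display_dims`.
#'
#' @param model A fine-tuned `cf_model`.
#' @param cohort A preprocessed `cf_cohort` (>= 3 patients).
#' @param biomarkers Biomarker names to inspect (default: all).
#' @param times Inspection times in periods (default 1, 3, 6, 9, 12; times
#'   beyond the follow-up are skipped).
#' @param event_type Risk head to correlate against.
#' @param threshold Display threshold on `|rho|` (default 0.4).
#' @return An object of class `cf_correlation_map`: list with `values`
#'   (tidy data.frame: dimension, time, target, rho), `display_dims` and
#'   `threshold`.
#' @export
hidden_correlation_map <- function(model, cohort, biomarkers = NULL,
                                   times = c(1, 3, 6, 9, 12),
                                   event_type = "pfs", threshold = 0.4) {
  n <- dim(cohort$X)[1]
  if (n < 3) stop("at least 3 patients are required", call. = FALSE)
  biomarkers <- biomarkers %||% model$meta$vars
  Tt <- dim(cohort$X)[2]
  times <- times[times >= 1 & times + model$config$K <= Tt]
  rows <- list()
  for (t in times) {
    Z <- encode(model, cohort, T_use = t)
    z_t <- matrix(Z[, t, ], n, model$config$d_z)
    risk <- event_score(model, cohort, t_cond = t, type = event_type)
    if (is.matrix(risk)) risk <- risk[, 1]
    xhat <- forecast_next(model, cohort, t_cond = t)
    for (d in seq_len(model$config$d_z)) {
      zd <- z_t[, d]
      safe_cor <- function(a, b) {
        if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
          stats::cor(a, b)
      }
      rows[[length(rows) + 1]] <- data.frame(
        dimension = d, time = t, target = paste0("risk_", event_type),
        rho = safe_cor(zd, risk), stringsAsFactors = FALSE)
      for (j in biomarkers) {
        rows[[length(rows) + 1]] <- data.frame(
          dimension = d, time = t, target = j,
          rho = safe_cor(zd, xhat[, j]), stringsAsFactors = FALSE)
      }
    }
  }
  values <- do.call(rbind, rows)
  keep <- tapply(abs(values$rho), values$dimension,
                 function(v) any(v >= threshold, na.rm = TRUE))
  display_dims <- as.integer(names(keep)[keep])
  structure(list(values = values, display_dims = display_dims,
                 threshold = threshold),
            class = "cf_correlation_map")
}

#' @export
print.cf_correlation_map <- function(x, ...) {
  cat("<cf_correlation_map> ", nrow(x$values), " correlations, ",
      length(x$display_dims), " dimension(s) past |rho| >= ", x$threshold,
      "\n", sep = "")
  invisible(x)
}

#' Tidy export of a correlation map
#'
#' @param x A `cf_correlation_map`.
#' @param display_only Restrict to the display dimension set.
#' @param ... Unused.
#' @return data.frame (dimension, time, target, rho).
#' @export
as.data.frame.cf_correlation_map <- function(x, display_only = FALSE, ...) {
  v <- x$values
  if (display_only) v <- v[v$dimension %in% x$display_dims, , drop = FALSE]
  v
}

trend_label <- function(y, tol = 0.01) {
  if (length(y) < 2) return("flat")
  slope <- stats::coef(stats::lm(y ~ seq_along(y)))[2]
  if (!is.finite(slope) || abs(slope) < tol) "flat"
  else if (slope > 0) "up" else "down"
}

#' Patient-level narrative summary
#'
#' For each conditioning time: the normalized risk (with its cohort-quantile
#' reading), the forecast trajectories de-normalized to clinical units, and a
#' trend label per biomarker (up/down/flat by the sign of the forecast
#' slope). Forecast values outside the invertible range of the squashing
#' transform are reported on the normalized scale and flagged.
#'
#' @param model A fine-tuned `cf_model` (its stored train-score range is used
#'   for risk normalization).
#' @param cohort A preprocessed `cf_cohort`.
#' @param patient Patient index or id.
#' @param t_conds Conditioning times.
#' @param horizon Forecast horizon from each conditioning time.
#' @param event_type Risk head to summarize.
#' @return An object of class `cf_patient_summary` (list, one record per
#'   conditioning time).
#' @export
patient_summary <- function(model, cohort, patient, t_conds = c(1, 6, 12),
                            horizon = 6, event_type = "pfs") {
  if (is.character(patient)) {
    patient <- match(patient, cohort$baseline$patient_id)
  }
  stopifnot(is.finite(patient), patient >= 1)
  sr <- model$score_range[[event_type]]
  if (is.null(sr)) {
    stop("model has no stored train-score range for '", event_type,
         "'; fine-tune the head first", call. = FALSE)
  }
  Tt <- dim(cohort$X)[2]
  ranges <- cohort$prep$normalization$ranges
  scale_raw <- cohort$prep$normalization$scale_raw
  records <- list()
  for (tc in t_conds) {
    h <- min(horizon, Tt - tc)
    if (tc + model$config$K > Tt || h < 1) next
    score <- event_score(model, cohort, t_cond = tc, type = event_type)
    nr <- normalized_risk(score[patient], c(sr$min, sr$max))
    ro <- rollout(model, cohort, t_cond = tc, horizon = h)
    fc <- list()
    for (j in model$meta$vars) {
      y_norm <- ro$X_pred[patient, , j]
      in_domain <- abs(y_norm) < 3.5
      y_clin <- rep(NA_real_, length(y_norm))
      if (any(in_domain)) {
        y_clin[in_domain] <- denormalize_values(y_norm[in_domain], j,
                                                ranges, scale_raw)
      }
      fc[[j]] <- list(normalized = y_norm, clinical = y_clin,
                      out_of_domain = !all(in_domain),
                      trend = trend_label(y_norm))
    }
    records[[as.character(tc)]] <- list(
      t_cond = tc, score = unname(score[patient]), normalized_risk = nr,
      risk_text = sprintf(
        "%.0f%% of patients in the cohort have a lower risk score",
        100 * nr),
      forecasts = fc)
  }
  structure(list(patient_id = cohort$baseline$patient_id[patient],
                 event_type = event_type, records = records),
            class = "cf_patient_summary")
}

#' @export
print.cf_patient_summary <- function(x, ...) {
  cat("<cf_patient_summary> patient ", x$patient_id, " (",
      x$event_type, ")\n", sep = "")
  for (r in x$records) {
    cat(sprintf("  t_cond = %d: normalized risk %.2f (%s)\n",
                r$t_cond, r$normalized_risk, r$risk_text))
    for (j in names(r$forecasts)) {
      cat(sprintf("    %-12s trend %s\n", j, r$forecasts[[j]]$trend))
    }
  }
  invisible(x)
}

#' 2-D embedding of baseline hidden states
#'
#' Thin hook delegating the manifold embedding of the first-period hidden
#' state to a configurable routine: classical multidimensional scaling
#' (default), PCA, or any user-supplied function taking the `n x d_z` state
#' matrix and returning an `n x 2` matrix. Output is labelled by Ig subtype
#' for plotting.
#'
#' @param model A `cf_model`.
#' @param cohort A preprocessed `cf_cohort` (>= 10 patients).
#' @param method `"mds"`, `"pca"`, or a function.
#' @param t_cond Conditioning time whose state is embedded (default 1).
#' @return data.frame with `dim1`, `dim2`, `subtype` and `patient_id`.
#' @export
embed_states_2d <- function(model, cohort, method = "mds", t_cond = 1) {
  n <- dim(cohort$X)[1]
  if (n < 10) stop("at least 10 patients are required", call. = FALSE)
  Z <- encode(model, cohort, T_use = t_cond)
  z <- matrix(Z[, t_cond, ], n, model$config$d_z)
  coords <- if (is.function(method)) {
    method(z)
  } else if (identical(method, "mds")) {
    stats::cmdscale(stats::dist(z), k = 2)
  } else if (identical(method, "pca")) {
    stats::prcomp(z, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  } else {
    stop("unknown embedding method", call. = FALSE)
  }
  if (!is.matrix(coords) || nrow(coords) != n || ncol(coords) != 2) {
    stop("embedding routine must return an n x 2 matrix", call. = FALSE)
  }
  data.frame(dim1 = coords[, 1], dim2 = coords[, 2],
             subtype = cohort$baseline$subtype,
             patient_id = cohort$baseline$patient_id,
             stringsAsFactors = FALSE)
}
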