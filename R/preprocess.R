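# Preprocessing: clinical normal-range normalization with an invertible
# squashing non-linearity, train-fold-only baseline standardization,
# imputation, missingness-based variable filtering, and data splitting.

#' Default normal-range table
#'
#' Per-variable clinical normal range (alpha, beta) plus an extra scale factor
#' (1/5 for variables whose values run far above the normal range, e.g. free
#' light chains). Shipped as an editable CSV resource; ranges are
#' configuration, not constants.
#'
#' @return data.frame with columns `variable`, `alpha`, `beta`, `extra_scale`.
#' @export
default_normal_ranges <- function() {
  path <- system.file("extdata", "normal_ranges.csv", package = "coxformer")
  read_normal_ranges(path)
}

#' Read a normal-range table from CSV
#'
#' @param path CSV with columns `variable`, `alpha`, `beta`, `extra_scale`.
#' @return Validated normal-range data.frame.
#' @export
read_normal_ranges <- function(path) {
  rg <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("variable", "alpha", "beta", "extra_scale")
  if (!all(required %in% names(rg))) {
    stop("normal-range table needs columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (any(rg$beta <= rg$alpha)) {
    stop("normal-range upper bound must exceed the lower bound for every ",
         "variable", call. = FALSE)
  }
  if (any(rg$extra_scale <= 0)) {
    stop("`extra_scale` must be positive", call. = FALSE)
  }
  rg
}

#' Normal-range normalization
#'
#' Maps a clinical value so that the normal range `[alpha, beta]` lands on
#' `[-2, 2]`: `4 * (x - alpha) / (beta - alpha) - 2`.
#'
#' @param x Clinical value(s).
#' @param alpha,beta Lower and upper bounds of the normal range; `beta` must
#'   exceed `alpha`.
#' @return Normalized value(s).
#' @export
normalize_range <- function(x, alpha, beta) {
  if (any(beta <= alpha)) stop("`beta` must exceed `alpha`", call. = FALSE)
  4 * (x - alpha) / (beta - alpha) - 2
}

inverse_normalize_range <- function(x_star, alpha, beta) {
  if (any(beta <= alpha)) stop("`beta` must exceed `alpha`", call. = FALSE)
  (x_star + 2) * (beta - alpha) / 4 + alpha
}

#' Invertible squashing non-linearity
#'
#' `7 / (1 + exp(-0.25 * x)) - 3.5`: strictly increasing, bounded in
#' `(-3.5, 3.5)`, with unit slope preserved near 0 so variability in the lower
#' ranges is retained.
#'
#' @param x_star Finite numeric input (range-normalized value).
#' @return Squashed value strictly inside `(-3.5, 3.5)`.
#' @export
squash <- function(x_star) {
  7 / (1 + exp(-0.25 * x_star)) - 3.5
}

#' Inverse of [squash()]
#'
#' @param x_dagger Value strictly inside `(-3.5, 3.5)`.
#' @return The unique `x` with `squash(x) == x_dagger`.
#' @export
inverse_squash <- function(x_dagger) {
  if (any(abs(x_dagger) >= 3.5)) {
    stop("`inverse_squash` is defined for |x| < 3.5 only", call. = FALSE)
  }
  -4 * log(7 / (x_dagger + 3.5) - 1)
}

#' Normalize the longitudinal panel of a cohort
#'
#' Applies, per variable: [normalize_range()], multiplication by the
#' configured extra scale factor, then [squash()]. Masks are untouched. By
#' default the extra scaling acts on the range-normalized value before the
#' squashing step; `scale_raw = TRUE` reproduces the alternative reading where
#' the raw value is scaled first.
#'
#' @param cohort A `cf_cohort`.
#' @param ranges Normal-range table; defaults to the table stored in the
#'   cohort or, failing that, [default_normal_ranges()].
#' @param scale_raw Apply the extra scale to the raw clinical value instead of
#'   the range-normalized one.
#' @return The cohort with `X` replaced by its normalized version (original
#'   values kept in `X_raw`) and a `normalization` record attached.
#' @export
normalize_longitudinal <- function(cohort, ranges = NULL, scale_raw = FALSE) {
  stopifnot(inherits(cohort, "cf_cohort"))
  ranges <- ranges %||% cohort$ranges %||% default_normal_ranges()
  vars <- dimnames(cohort$X)[[3]]
  missing_vars <- setdiff(vars, ranges$variable)
  if (length(missing_vars)) {
    stop("no normal range configured for variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  cohort$X_raw <- cohort$X
  for (v in vars) {
    r <- ranges[ranges$variable == v, ]
    x <- cohort$X[, , v]
    if (scale_raw) {
      xs <- normalize_range(r$extra_scale * x, r$alpha, r$beta)
    } else {
      xs <- r$extra_scale * normalize_range(x, r$alpha, r$beta)
    }
    cohort$X[, , v] <- squash(xs)
  }
  cohort$normalization <- list(ranges = ranges, scale_raw = scale_raw)
  cohort
}

#' Map normalized values back to clinical units
#'
#' Inverts [normalize_longitudinal()] for a matrix/array of normalized values
#' of one variable.
#'
#' @param x_dagger Normalized value(s) in `(-3.5, 3.5)`.
#' @param variable Variable name to look up in `ranges`.
#' @param ranges Normal-range table.
#' @param scale_raw Must match the setting used during normalization.
#' @return Values in clinical units.
#' @export
denormalize_values <- function(x_dagger, variable, ranges,
                               scale_raw = FALSE) {
  r <- ranges[ranges$variable == variable, ]
  if (nrow(r) != 1) stop("unknown variable: ", variable, call. = FALSE)
  xs <- inverse_squash(x_dagger)
  if (scale_raw) {
    inverse_normalize_range(xs, r$alpha, r$beta) / r$extra_scale
  } else {
    inverse_normalize_range(xs / r$extra_scale, r$alpha, r$beta)
  }
}

# One-hot encode factor/character columns of a baseline table; continuous
# columns pass through. Returns the matrix and the encoding map.
one_hot_baseline <- function(B, levels_map = NULL) {
  stopifnot(is.data.frame(B))
  cols <- setdiff(names(B), "patient_id")
  pieces <- list()
  if (is.null(levels_map)) {
    levels_map <- list()
    for (cn in cols) {
      if (is.factor(B[[cn]]) || is.character(B[[cn]])) {
        levels_map[[cn]] <- levels(factor(B[[cn]]))
      }
    }
  }
  for (cn in cols) {
    if (cn %in% names(levels_map)) {
      lv <- levels_map[[cn]]
      f <- factor(as.character(B[[cn]]), levels = lv)
      mm <- matrix(0, nrow(B), length(lv),
                   dimnames = list(NULL, paste0(cn, "_", lv)))
      mm[cbind(seq_len(nrow(B)), as.integer(f))] <- 1
      pieces[[cn]] <- mm
    } else {
      pieces[[cn]] <- matrix(as.numeric(B[[cn]]), ncol = 1,
                             dimnames = list(NULL, cn))
    }
  }
  list(mat = do.call(cbind, pieces), levels_map = levels_map)
}

#' Standardize baseline covariates using train-fold statistics only
#'
#' Continuous columns are centred and scaled with means/sds computed on
#' `stats_from` rows only; categorical columns are one-hot encoded.
#' Zero-variance train columns are scaled by 1 with a warning.
#'
#' @param B Baseline data.frame (a `patient_id` column is carried through).
#' @param stats_from Row indices used to fit the statistics (default: all).
#' @param stats A previously fitted statistics object; when supplied, `B` is
#'   transformed with it and nothing is re-fitted.
#' @return list with `mat` (numeric matrix) and `stats` (fitted statistics:
#'   one-hot level map, means, sds).
#' @export
standardize_baseline <- function(B, stats_from = seq_len(nrow(B)),
                                 stats = NULL) {
  if (is.null(stats)) {
    oh_fit <- one_hot_baseline(B[stats_from, , drop = FALSE])
    oh_all <- one_hot_baseline(B, levels_map = oh_fit$levels_map)
    train_mat <- oh_all$mat[stats_from, , drop = FALSE]
    mu <- colMeans(train_mat)
    sd <- apply(train_mat, 2, stats::sd)
    zero_var <- !is.finite(sd) | sd == 0
    if (any(zero_var)) {
      warning("zero-variance baseline column(s) scaled by 1: ",
              paste(colnames(train_mat)[zero_var], collapse = ", "),
              call. = FALSE)
      sd[zero_var] <- 1
    }
    stats <- list(levels_map = oh_fit$levels_map, mean = mu, sd = sd)
  } else {
    oh_all <- one_hot_baseline(B, levels_map = stats$levels_map)
  }
  mat <- sweep(sweep(oh_all$mat, 2, stats$mean, "-"), 2, stats$sd, "/")
  rownames(mat) <- B$patient_id
  list(mat = mat, stats = stats)
}

#' Impute missing baseline and longitudinal values
#'
#' Baseline categoricals take the most frequent value, baseline continuous
#' variables the mean. Longitudinal variables missing at the first period are
#' set to the train-fold mean at that period; later gaps are filled by last
#' observation carried forward.
#'
#' @param cohort A `cf_cohort` (mask `M` marks observed entries).
#' @param train_idx Patient indices whose statistics are used (default: all).
#' @param t0_means Optional previously fitted first-period means (named by
#'   variable), for transforming held-out data with train statistics.
#' @return The cohort with `X` fully filled (mask `M` unchanged) and the
#'   fitted `t0_means` attached as `imputation`.
#' @export
impute_cohort <- function(cohort, train_idx = NULL, t0_means = NULL) {
  stopifnot(inherits(cohort, "cf_cohort"))
  n <- dim(cohort$X)[1]; Tt <- dim(cohort$X)[2]
  train_idx <- train_idx %||% seq_len(n)
  vars <- dimnames(cohort$X)[[3]]

  # Baseline imputation.
  B <- cohort$baseline
  for (cn in setdiff(names(B), "patient_id")) {
    miss <- is.na(B[[cn]])
    if (!any(miss)) next
    if (is.factor(B[[cn]]) || is.character(B[[cn]])) {
      tab <- table(B[[cn]][!miss])
      B[[cn]][miss] <- names(tab)[which.max(tab)]
    } else {
      B[[cn]][miss] <- mean(B[[cn]][!miss])
    }
  }
  cohort$baseline <- B

  fitted_means <- t0_means
  if (is.null(fitted_means)) {
    fitted_means <- stats::setNames(numeric(length(vars)), vars)
    for (v in vars) {
      obs0 <- cohort$M[train_idx, 1, v] == 1
      if (!any(cohort$M[, , v] == 1)) {
        stop("variable never observed for any patient: ", v, call. = FALSE)
      }
      fitted_means[[v]] <- if (any(obs0)) {
        mean(cohort$X[train_idx, 1, v][obs0])
      } else {
        mean(cohort$X[train_idx, , v][cohort$M[train_idx, , v] == 1])
      }
    }
  }
  for (v in vars) {
    xv <- cohort$X[, , v]
    mv <- cohort$M[, , v]
    xv[mv == 0] <- NA
    xv[is.na(xv[, 1]), 1] <- fitted_means[[v]]
    if (Tt > 1) {
      for (t in 2:Tt) {
        gap <- is.na(xv[, t])
        xv[gap, t] <- xv[gap, t - 1]
      }
    }
    cohort$X[, , v] <- xv
  }
  cohort$imputation <- list(t0_means = fitted_means)
  cohort
}

#' Filter variables by missingness
#'
#' Drops baseline variables whose missing fraction exceeds `baseline_thresh`
#' and longitudinal variables whose missing fraction over the whole follow-up
#' exceeds `longitudinal_thresh`.
#'
#' @param cohort A `cf_cohort`.
#' @param baseline_thresh Maximum tolerated baseline missing fraction
#'   (default 0.15).
#' @param longitudinal_thresh Maximum tolerated longitudinal missing fraction
#'   (default 0.70).
#' @return The filtered cohort, with the retained variable names in
#'   `retained`.
#' @export
filter_variables <- function(cohort, baseline_thresh = 0.15,
                             longitudinal_thresh = 0.70) {
  stopifnot(inherits(cohort, "cf_cohort"))
  if (!is_prob(baseline_thresh) || !is_prob(longitudinal_thresh)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  B <- cohort$baseline
  base_cols <- setdiff(names(B), "patient_id")
  base_miss <- vapply(base_cols, function(cn) mean(is.na(B[[cn]])), numeric(1))
  keep_base <- base_cols[base_miss <= baseline_thresh]
  vars <- dimnames(cohort$X)[[3]]
  long_miss <- vapply(vars, function(v) mean(cohort$M[, , v] == 0), numeric(1))
  keep_long <- vars[long_miss <= longitudinal_thresh]
  if (!length(keep_base) && !length(keep_long)) {
    stop("all variables dropped by the missingness filter", call. = FALSE)
  }
  if (!length(keep_long)) {
    stop("all longitudinal variables dropped by the missingness filter",
         call. = FALSE)
  }
  cohort$baseline <- B[, c("patient_id", keep_base), drop = FALSE]
  cohort$X <- cohort$X[, , keep_long, drop = FALSE]
  cohort$M <- cohort$M[, , keep_long, drop = FALSE]
  if (!is.null(cohort$X_raw)) {
    cohort$X_raw <- cohort$X_raw[, , keep_long, drop = FALSE]
  }
  cohort$retained <- list(baseline = keep_base, longitudinal = keep_long,
                          baseline_missing = base_miss,
                          longitudinal_missing = long_miss)
  cohort
}

#' Train/test split plan with five validation resplits
#'
#' One random 80/20 train/test split, then five independent 75/25 resplits of
#' the 80% into (train, validation) pairs. The smaller partition size is
#' floored.
#'
#' @param n Number of patients (>= 10).
#' @param seed Integer seed; the plan is deterministic given `(n, seed)`.
#' @return An object of class `cf_split_plan` with elements `test`,
#'   `folds` (list of five `list(train, val)` index pairs) and `seed`.
#' @export
split_cohort <- function(n, seed = 1L) {
  if (!is_count(n) || n < 10) stop("`n` must be an integer >= 10",
                                   call. = FALSE)
  with_seed(seed, {
    n_test <- floor(0.2 * n)
    test <- sort(sample.int(n, n_test))
    trainval <- setdiff(seq_len(n), test)
    folds <- lapply(1:5, function(k) {
      n_val <- floor(0.25 * length(trainval))
      val <- sort(sample(trainval, n_val))
      list(train = setdiff(trainval, val), val = val)
    })
    structure(list(test = test, trainval = trainval, folds = folds,
                   seed = as.integer(seed), n = as.integer(n)),
              class = "cf_split_plan")
  })
}

#' Even 50/50 split for subgroup analysis
#'
#' A dedicated split mode used by the treatment-effect analysis: policy
#' learning on one half, survival assessment on the held-out half.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @return list with `train` and `test` index vectors.
#' @export
split_even <- function(n, seed = 1L) {
  if (!is_count(n) || n < 4) stop("`n` must be an integer >= 4", call. = FALSE)
  with_seed(seed, {
    train <- sort(sample.int(n, floor(n / 2)))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Subset a cohort to a set of patients
#'
#' @param cohort A `cf_cohort`.
#' @param idx Patient indices to keep.
#' @return The subsetted cohort.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "cf_cohort"))
  out <- cohort
  out$baseline <- cohort$baseline[idx, , drop = FALSE]
  out$X <- cohort$X[idx, , , drop = FALSE]
  out$M <- cohort$M[idx, , , drop = FALSE]
  out$A <- cohort$A[idx, , , drop = FALSE]
  if (!is.null(cohort$X_raw)) out$X_raw <- cohort$X_raw[idx, , , drop = FALSE]
  if (!is.null(cohort$Bmat)) out$Bmat <- cohort$Bmat[idx, , drop = FALSE]
  if (!is.null(cohort$As)) out$As <- cohort$As[idx, , , drop = FALSE]
  out$outcomes <- cohort$outcomes[
    cohort$outcomes$patient_id %in% out$baseline$patient_id, , drop = FALSE]
  if (!is.null(cohort$truth)) {
    out$truth$burden <- cohort$truth$burden[idx, , drop = FALSE]
    out$truth$cate <- cohort$truth$cate[idx]
  }
  out
}

#' Run the full preprocessing pipeline on a cohort
#'
#' Filters variables by missingness, imputes, normalizes the longitudinal
#' panel by the clinical normal ranges, standardizes the baseline table and
#' scales treatment dosages — all statistics fitted on `train_idx` only. The
#' fitted state is attached so held-out or future data can be transformed
#' identically (see `prep` element).
#'
#' @param cohort A `cf_cohort`.
#' @param train_idx Patient indices used to fit every statistic
#'   (default: all patients).
#' @param ranges Normal-range table (default: cohort's own or the packaged
#'   defaults).
#' @param prep Previously fitted preprocessing state; when given, the cohort
#'   is transformed with it instead of refitting.
#' @param filter Apply the missingness variable filter (default TRUE).
#' @return The preprocessed cohort with model-ready `Bmat`, normalized `X`,
#'   scaled `As`, and the fitted `prep` state.
#' @export
preprocess_cohort <- function(cohort, train_idx = NULL, ranges = NULL,
                              prep = NULL, filter = TRUE) {
  stopifnot(inherits(cohort, "cf_cohort"))
  n <- dim(cohort$X)[1]
  train_idx <- train_idx %||% seq_len(n)
  if (is.null(prep)) {
    if (filter) cohort <- filter_variables(cohort)
    cohort <- impute_cohort(cohort, train_idx = train_idx)
    cohort <- normalize_longitudinal(cohort, ranges = ranges)
    std <- standardize_baseline(cohort$baseline, stats_from = train_idx)
    a_scale <- apply(abs(mat3(cohort$A[train_idx, , , drop = FALSE])), 2, max)
    a_scale[a_scale == 0] <- 1
    cohort$prep <- list(
      retained = cohort$retained,
      t0_means = cohort$imputation$t0_means,
      normalization = cohort$normalization,
      baseline_stats = std$stats,
      a_scale = a_scale
    )
  } else {
    keep <- prep$retained
    if (!is.null(keep)) {
      cohort$baseline <- cohort$baseline[
        , c("patient_id", keep$baseline), drop = FALSE]
      cohort$X <- cohort$X[, , keep$longitudinal, drop = FALSE]
      cohort$M <- cohort$M[, , keep$longitudinal, drop = FALSE]
    }
    cohort <- impute_cohort(cohort, t0_means = prep$t0_means)
    cohort <- normalize_longitudinal(cohort,
                                     ranges = prep$normalization$ranges,
                                     scale_raw = prep$normalization$scale_raw)
    std <- standardize_baseline(cohort$baseline,
                                stats = prep$baseline_stats)
    cohort$prep <- prep
  }
  cohort$Bmat <- std$mat
  As <- cohort$A
  for (k in seq_len(dim(As)[3])) {
    As[, , k] <- As[, , k] / cohort$prep$a_scale[[k]]
  }
  cohort$As <- As
  cohort
}
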