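# Potential-outcome prediction under both arms, CATE computation,
# median-threshold policy learning, surrogate decision-tree extraction, and
# subgroup survival assessment.

#' Set the treatment arm of every patient in a cohort
#'
#' Rewrites the arm indicator in the baseline table and the drug dosages in
#' the treatment panel (the experimental arm adds ixazomib), then re-derives
#' the model-ready matrices with the cohort's previously fitted preprocessing
#' statistics — the fit/transform separation is preserved.
#'
#' @param cohort A preprocessed `cf_cohort`.
#' @param arm 0 (Rd) or 1 (IRd).
#' @return The modified cohort.
#' @export
set_arm <- function(cohort, arm) {
  stopifnot(inherits(cohort, "cf_cohort"), arm %in% c(0, 1))
  if (is.null(cohort$prep)) {
    stop("cohort must be preprocessed before setting a counterfactual arm",
         call. = FALSE)
  }
  cohort$baseline$arm <- arm
  cohort$A[, , "ixa_dose"] <- 4 * arm
  std <- standardize_baseline(cohort$baseline,
                              stats = cohort$prep$baseline_stats)
  cohort$Bmat <- std$mat
  As <- cohort$A
  for (k in seq_len(dim(As)[3])) {
    As[, , k] <- As[, , k] / cohort$prep$a_scale[[k]]
  }
  cohort$As <- As
  cohort
}

#' Predict potential outcomes under both treatment arms
#'
#' Runs the model twice from baseline — once with the treatment covariate and
#' dosages set to IRd, once to Rd — and returns both risk scores and both
#' rolled-out biomarker trajectories. Predictions are made at baseline only
#' (`t = 0` is the only time at which randomization holds); both calls share
#' the identical observed `X(0)`, only `B` and `A` differ.
#'
#' @param model A fine-tuned `cf_model`.
#' @param cohort A preprocessed `cf_cohort`.
#' @param event_type Event head used for the risk scores (default `"pfs"`).
#' @param horizon Rollout horizon for the potential trajectories (default:
#'   the remaining follow-up).
#' @param t Prediction time; must be 0.
#' @param normalized Express both risks (and hence the CATE) on the
#'   normalized `[0, 1]` scale via the model's stored train-score range
#'   instead of the raw Cox-score scale. The raw default is
#'   monotone-equivalent for threshold policies.
#' @return list with `y1`, `y0` (risk scores under IRd / Rd), `X1`, `X0`
#'   (potential trajectories) and `cate = y1 - y0`.
#' @export
predict_potential_outcomes <- function(model, cohort, event_type = "pfs",
                                       horizon = NULL, t = 0,
                                       normalized = FALSE) {
  if (t != 0) {
    stop("potential outcomes are predicted at baseline only ",
         "(randomization holds only at t = 0)", call. = FALSE)
  }
  horizon <- horizon %||% (dim(cohort$X)[2] - 1)
  c1 <- set_arm(cohort, 1)
  c0 <- set_arm(cohort, 0)
  y1 <- event_score(model, c1, t_cond = 1, type = event_type)
  y0 <- event_score(model, c0, t_cond = 1, type = event_type)
  if (normalized) {
    sr <- model$score_range[[event_type]]
    if (is.null(sr)) {
      stop("no stored train-score range for '", event_type,
           "'; fine-tune the head first or use normalized = FALSE",
           call. = FALSE)
    }
    y1 <- normalized_risk(y1, c(sr$min, sr$max))
    y0 <- normalized_risk(y0, c(sr$min, sr$max))
  }
  X1 <- rollout(model, c1, t_cond = 1, horizon = horizon)$X_pred
  X0 <- rollout(model, c0, t_cond = 1, horizon = horizon)$X_pred
  list(y1 = y1, y0 = y0, X1 = X1, X0 = X0, cate = compute_cate(y1, y0))
}

#' Conditional average treatment effect on predicted risk
#'
#' `CATE = y1 - y0` on the risk-score scale: a negative CATE means the
#' experimental arm (IRd) reduces the predicted progression risk, a positive
#' CATE flags a predicted harmful effect.
#'
#' @param y1 Predicted risk under IRd.
#' @param y0 Predicted risk under Rd.
#' @return CATE per patient.
#' @export
compute_cate <- function(y1, y0) {
  stopifnot(length(y1) == length(y0))
  y1 - y0
}

#' Median-threshold subgroup policy
#'
#' The subgroup threshold is the median CATE over the training patients;
#' patient i is assigned to the benefiting subgroup (`pi_star = 1`) when
#' `CATE_i <= delta`.
#'
#' @param train_cates CATE values on the training fold.
#' @return list with `delta` (the threshold) and `labels` (0/1 assignments
#'   for the training patients).
#' @export
learn_threshold_policy <- function(train_cates) {
  if (!length(train_cates)) stop("no CATE values supplied", call. = FALSE)
  delta <- stats::median(train_cates)
  list(delta = delta, labels = as.integer(train_cates <= delta))
}

#' Fit a shallow surrogate decision tree for a subgroup policy
#'
#' Trains an axis-aligned classification tree on baseline covariates only,
#' with the threshold-policy labels as targets, giving an interpretable
#' replication of the model-derived subgroup. Each node reports its sample
#' count and the label proportions P0 (not selected) and P1 (selected).
#'
#' @param B Baseline data.frame (`patient_id` and `arm` are excluded from the
#'   features).
#' @param labels 0/1 policy labels.
#' @param max_depth Tree depth (default 3, "shallow"); 0 yields the
#'   majority-vote policy.
#' @return An object of class `cf_policy_tree`.
#' @export
fit_surrogate_tree <- function(B, labels, max_depth = 3) {
  stopifnot(is.data.frame(B), length(labels) == nrow(B))
  feats <- B[, setdiff(names(B), c("patient_id", "arm")), drop = FALSE]
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    warning("single-class labels: returning a single-leaf tree",
            call. = FALSE)
    max_depth <- 0
  }
  if (max_depth == 0) {
    maj <- as.integer(mean(labels) >= 0.5)
    return(structure(list(fit = NULL, majority = maj,
                          p1 = mean(labels), n = length(labels)),
                     class = "cf_policy_tree"))
  }
  df <- cbind(data.frame(.label = factor(labels, levels = c(0, 1))), feats)
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = 0, minsplit = 10,
                        minbucket = 5, xval = 0))
  structure(list(fit = fit, majority = NULL, n = length(labels)),
            class = "cf_policy_tree")
}

#' Predict subgroup membership with a surrogate tree
#'
#' @param object A `cf_policy_tree`.
#' @param newdata Baseline data.frame.
#' @param ... Unused.
#' @return Integer 0/1 labels.
#' @export
predict.cf_policy_tree <- function(object, newdata, ...) {
  if (is.null(object$fit)) {
    return(rep(object$majority, nrow(newdata)))
  }
  as.integer(as.character(
    stats::predict(object$fit, newdata = newdata, type = "class")))
}

#' Human-readable description of a surrogate policy tree
#'
#' One row per node: the splitting rule path, the number of patients, and the
#' label proportions P0/P1.
#'
#' @param tree A `cf_policy_tree`.
#' @return data.frame with columns node, rule, n, P0, P1, leaf.
#' @export
describe_tree <- function(tree) {
  stopifnot(inherits(tree, "cf_policy_tree"))
  if (is.null(tree$fit)) {
    return(data.frame(node = 1, rule = "<majority vote>", n = tree$n,
                      P0 = 1 - tree$p1, P1 = tree$p1, leaf = TRUE,
                      stringsAsFactors = FALSE))
  }
  fr <- tree$fit$frame
  nodes <- as.integer(rownames(fr))
  rules <- vapply(seq_along(nodes), function(i) {
    if (nodes[i] == 1) return("<root>")
    paste(rpart::path.rpart(tree$fit, nodes[i], print.it = FALSE)[[1]][-1],
          collapse = " & ")
  }, character(1))
  data.frame(node = nodes, rule = rules, n = fr$n,
             P0 = fr$yval2[, 4], P1 = fr$yval2[, 5],
             leaf = fr$var == "<leaf>", stringsAsFactors = FALSE)
}

#' Survival assessment of a discovered subgroup
#'
#' Within the selected held-out subgroup: Kaplan-Meier curves by actual
#' randomized arm, a log-rank test, and a (optionally stratified)
#' proportional-hazards arm effect — with the same quantities on the full
#' held-out set for contrast. Policies must be learned on the training half
#' only; this function only consumes labels.
#'
#' @param cohort The held-out `cf_cohort`.
#' @param selected Logical/0-1 subgroup membership per held-out patient.
#' @param event_type Event to assess (default `"pfs"`).
#' @param strata Optional baseline column name(s) to stratify the Cox model
#'   on.
#' @return An object of class `cf_subgroup_report`: list with `subgroup` and
#'   `full`, each holding `km` (survfit), `logrank_p`, `cox` (arm log-HR,
#'   se, p) and `n`.
#' @export
evaluate_subgroup <- function(cohort, selected, event_type = "pfs",
                              strata = NULL) {
  stopifnot(inherits(cohort, "cf_cohort"))
  selected <- as.logical(selected)
  ol <- outcomes_for(cohort, event_type)
  df <- data.frame(time = ol$time, status = ol$status,
                   arm = cohort$baseline$arm)
  if (!is.null(strata)) {
    for (s in strata) df[[s]] <- cohort$baseline[[s]]
  }
  assess <- function(d) {
    if (min(table(factor(d$arm, levels = 0:1))) < 2) {
      stop("subgroup has fewer than 2 patients in an arm", call. = FALSE)
    }
    km <- survival::survfit(survival::Surv(time, status) ~ arm, data = d)
    lr <- survival::survdiff(survival::Surv(time, status) ~ arm, data = d)
    lr_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
    fml <- if (is.null(strata)) {
      survival::Surv(time, status) ~ arm
    } else {
      stats::as.formula(paste("survival::Surv(time, status) ~ arm +",
                              paste(sprintf("survival::strata(%s)", strata),
                                    collapse = " + ")))
    }
    cx <- survival::coxph(fml, data = d)
    sm <- summary(cx)$coefficients
    list(km = km, logrank_p = lr_p,
         cox = list(log_hr = sm["arm", "coef"], se = sm["arm", "se(coef)"],
                    p = sm["arm", "Pr(>|z|)"]),
         n = nrow(d))
  }
  structure(list(subgroup = assess(df[selected, , drop = FALSE]),
                 full = assess(df), event_type = event_type),
            class = "cf_subgroup_report")
}

#' @export
print.cf_subgroup_report <- function(x, ...) {
  cat("<cf_subgroup_report> event:", x$event_type, "\n")
  cat(sprintf("  subgroup (n=%d): arm log-HR %.3f (p=%.4f), log-rank p=%.4f\n",
              x$subgroup$n, x$subgroup$cox$log_hr, x$subgroup$cox$p,
              x$subgroup$logrank_p))
  cat(sprintf("  full set (n=%d): arm log-HR %.3f (p=%.4f), log-rank p=%.4f\n",
              x$full$n, x$full$cox$log_hr, x$full$cox$p, x$full$logrank_p))
  invisible(x)
}

#' End-to-end subgroup discovery on a 50/50 split
#'
#' Convenience pipeline: preprocess with statistics fitted on one half, train
#' (pre-train + fine-tune) on that half, compute baseline potential outcomes
#' and CATEs, learn the median-threshold policy and its surrogate tree on the
#' same half, then assess survival within the tree-selected subgroup on the
#' held-out half. Nothing derived from the held-out half influences the
#' policy: preprocessing statistics, model weights, the CATE threshold and
#' the tree all come from the training half alone.
#'
#' @param cohort A raw (not yet preprocessed) `cf_cohort`; preprocessing is
#'   fitted internally on the training half. A cohort that already carries a
#'   fitted preprocessing state is used as-is.
#' @param config An [encoder_config()].
#' @param seed Integer seed (controls the split and all training).
#' @param pretrain_epochs,finetune_epochs,lr_pretrain,lr_finetune Training
#'   budget.
#' @param max_depth Surrogate tree depth.
#' @return list with the split, model, CATEs, policy, tree, test labels and
#'   the subgroup report.
#' @export
discover_subgroup <- function(cohort, config = encoder_config(),
                              seed = 1L, pretrain_epochs = 30,
                              finetune_epochs = 150, lr_pretrain = 1e-3,
                              lr_finetune = 1e-2, max_depth = 3) {
  n <- dim(cohort$X)[1]
  sp <- split_even(n, seed = derive_seed(seed, "even_split"))
  if (is.null(cohort$prep)) {
    cohort <- preprocess_cohort(cohort, train_idx = sp$train)
  }
  model <- init_model(cohort, config, seed = derive_seed(seed, "init"))
  model <- pretrain(model, cohort, idx = sp$train, epochs = pretrain_epochs,
                    lr = lr_pretrain, seed = derive_seed(seed, "pretrain"))
  model <- finetune_heads(model, cohort, event_type = "pfs", idx = sp$train,
                          t_cond = 1, epochs = finetune_epochs,
                          lr = lr_finetune,
                          seed = derive_seed(seed, "finetune"))
  train_cohort <- subset_cohort(cohort, sp$train)
  po <- predict_potential_outcomes(model, train_cohort, horizon = 1)
  policy <- learn_threshold_policy(po$cate)
  tree <- fit_surrogate_tree(train_cohort$baseline, policy$labels,
                             max_depth = max_depth)
  test_cohort <- subset_cohort(cohort, sp$test)
  test_labels <- predict(tree, test_cohort$baseline)
  report <- evaluate_subgroup(test_cohort, test_labels == 1)
  list(split = sp, model = model, cate = po$cate, policy = policy,
       tree = tree, test_labels = test_labels, report = report)
}
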