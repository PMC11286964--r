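# Potential outcomes, CATE, policy learning, surrogate tree and subgroup
# survival assessment.

test_that("CATE is the risk difference with the documented sign convention", {
  expect_equal(compute_cate(0.2, 0.5), -0.3)   # IRd beneficial
  expect_equal(compute_cate(0.4, 0.4), 0)
  expect_gt(compute_cate(0.9, 0.1), 0)         # positive = harmful IRd
})

test_that("median-threshold policy assigns CATE <= delta to the subgroup", {
  out <- learn_threshold_policy(c(-1, 0, 1, 2))
  expect_equal(out$delta, 0.5)
  expect_equal(out$labels, as.integer(c(-1, 0, 1, 2) <= 0.5))
  expect_equal(out$labels, c(1L, 1L, 0L, 0L))
  all_same <- learn_threshold_policy(rep(0.3, 4))
  expect_equal(all_same$delta, 0.3)
  expect_equal(all_same$labels, rep(1L, 4))    # <= comparison
  single <- learn_threshold_policy(0.7)
  expect_equal(single$delta, 0.7)
  expect_equal(single$labels, 1L)
  expect_error(learn_threshold_policy(numeric(0)), "no CATE")
})

test_that("potential outcomes share X(0) and differ only through treatment", {
  prep <- small_prep(n = 12, Tt = 5, seed = 50)
  m <- tiny_model(prep, seed = 51)
  c1 <- set_arm(prep, 1)
  c0 <- set_arm(prep, 0)
  expect_identical(c1$X, c0$X)
  expect_identical(c1$M, c0$M)
  expect_true(all(c1$A[, , "ixa_dose"] == 4))
  expect_true(all(c0$A[, , "ixa_dose"] == 0))
  expect_error(predict_potential_outcomes(m, prep, t = 1), "baseline only")
  po <- predict_potential_outcomes(m, prep, horizon = 2)
  expect_length(po$y1, 12)
  expect_equal(po$cate, po$y1 - po$y0)
  expect_equal(dim(po$X1), c(12, 2, 6))
})

test_that("a model with zeroed treatment pathways predicts a null effect", {
  prep <- small_prep(n = 10, Tt = 4, seed = 52)
  m <- tiny_model(prep, seed = 53)
  # zero the input-embedding rows of the arm covariate and all dosage
  # channels: treatment information can then never reach the hidden state
  arm_row <- which(m$meta$base_cols == "arm")
  dose_rows <- m$meta$p + 2 * m$meta$J + seq_len(m$meta$q)
  m$params$input$W[c(arm_row, dose_rows), ] <- 0
  po <- predict_potential_outcomes(m, prep, horizon = 2)
  expect_equal(po$y1, po$y0, tolerance = 1e-12)
  expect_equal(po$X1, po$X0, tolerance = 1e-12)
  expect_equal(max(abs(po$cate)), 0, tolerance = 1e-12)
})

test_that("trained model recovers the sign of the configured arm effect", {
  fx <- trained_fixture()   # simulated with effect_log_hr pfs = -0.8
  po <- predict_potential_outcomes(fx$model, fx$cohort, horizon = 1)
  expect_lt(mean(po$cate), 0)
  # normalized scale: risks in [0, 1], policy ordering preserved
  pn <- predict_potential_outcomes(fx$model, fx$cohort, horizon = 1,
                                   normalized = TRUE)
  expect_true(all(pn$y1 >= 0 & pn$y1 <= 1))
  interior <- pn$y1 > 0 & pn$y1 < 1 & pn$y0 > 0 & pn$y0 < 1
  expect_gt(mean(interior), 0.5)
  expect_equal(sign(pn$cate[interior]), sign(po$cate[interior]))
  m_raw <- tiny_model(fx$cohort, seed = 1)
  expect_error(predict_potential_outcomes(m_raw, fx$cohort, horizon = 1,
                                          normalized = TRUE),
               "train-score range")
})

test_that("surrogate tree separates a single-covariate rule at depth 1", {
  set.seed(54)
  B <- data.frame(patient_id = sprintf("P%03d", 1:80),
                  age = c(stats::runif(40, 50, 60), stats::runif(40, 70, 80)),
                  iss = factor(sample(c("I", "II"), 80, TRUE)),
                  stringsAsFactors = FALSE)
  labels <- as.integer(B$age > 65)
  tree <- fit_surrogate_tree(B, labels, max_depth = 1)
  expect_equal(predict(tree, B), labels)
  desc <- describe_tree(tree)
  expect_true(any(grepl("age", desc$rule)))
  expect_equal(desc$n[desc$node == 1], 80)
  expect_equal(desc$P0 + desc$P1, rep(1, nrow(desc)), tolerance = 1e-12)
})

test_that("degenerate trees fall back to majority vote", {
  B <- data.frame(patient_id = c("a", "b", "c", "d"),
                  age = c(50, 60, 70, 80))
  maj <- fit_surrogate_tree(B, c(0, 1, 1, 1), max_depth = 0)
  expect_equal(predict(maj, B), rep(1L, 4))
  expect_warning(one <- fit_surrogate_tree(B, c(1, 1, 1, 1)), "single-class")
  expect_equal(predict(one, B), rep(1L, 4))
  expect_equal(describe_tree(one)$P1, 1)
})

test_that("policy and threshold agree definitionally on the training fold", {
  set.seed(55)
  cates <- stats::rnorm(60)
  pol <- learn_threshold_policy(cates)
  expect_equal(pol$labels, as.integer(cates <= pol$delta))
  B <- data.frame(patient_id = sprintf("P%03d", 1:60),
                  age = stats::rnorm(60, 70, 8),
                  x = stats::rnorm(60))
  tree <- fit_surrogate_tree(B, pol$labels, max_depth = 3)
  agreement <- mean(predict(tree, B) == pol$labels)
  # agreement rate equals the tree's training accuracy by definition
  acc <- mean(predict(tree, B) == pol$labels)
  expect_equal(agreement, acc)
  expect_gte(agreement, 0.5)
})

test_that("subgroup evaluation: identity policy reproduces the full-set report", {
  co <- small_cohort(n = 120, Tt = 10, seed = 56)
  rep_all <- evaluate_subgroup(co, rep(TRUE, 120))
  expect_equal(rep_all$subgroup$cox$log_hr, rep_all$full$cox$log_hr)
  expect_equal(rep_all$subgroup$logrank_p, rep_all$full$logrank_p)
  expect_equal(rep_all$subgroup$n, rep_all$full$n)
  sel <- rep(FALSE, 120)
  sel[co$baseline$arm == 1][1] <- TRUE  # one treated patient only
  expect_error(evaluate_subgroup(co, sel), "fewer than 2")
})

test_that("stratified Cox assessment accepts strata variables", {
  co <- small_cohort(n = 150, Tt = 10, seed = 57)
  rep_s <- evaluate_subgroup(co, rep(TRUE, 150), strata = "iss")
  expect_true(is.finite(rep_s$full$cox$log_hr))
  expect_true(rep_s$full$logrank_p >= 0 && rep_s$full$logrank_p <= 1)
})

test_that("discovery pipeline never touches the held-out half", {
  cfg <- sim_config(n_patients = 120, n_periods = 6, seed = 58)
  co <- generate_cohort(cfg)
  run <- function(cohort) {
    discover_subgroup(cohort, encoder_config(d_z = 8, tau = 4), seed = 4,
                      pretrain_epochs = 2, finetune_epochs = 10)
  }
  ds1 <- run(co)
  # plant sentinels in the held-out half: biomarkers and outcomes
  co2 <- co
  test_half <- ds1$split$test
  co2$X[test_half, , ] <- co2$X[test_half, , ] * 3 + 10
  ds2 <- run(co2)
  expect_identical(ds1$policy$delta, ds2$policy$delta)
  expect_identical(ds1$cate, ds2$cate)
  expect_identical(describe_tree(ds1$tree), describe_tree(ds2$tree))
})

test_that("null world: subgroup discovery does not manufacture arm effects", {
  # zero treatment effect everywhere; selection on train, evaluation on test
  rejections <- 0
  n_reps <- 6
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_patients = 160, n_periods = 8,
                      seed = 600 + r,
                      effect_log_hr = c(pfs = 0, os = 0),
                      dynamics = list(decay = c(rd = 0.92, ird = 0.92)))
    co <- generate_cohort(cfg)
    ds <- discover_subgroup(co, encoder_config(d_z = 8, tau = 4),
                            seed = 700 + r, pretrain_epochs = 3,
                            finetune_epochs = 30)
    if (ds$report$subgroup$logrank_p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)   # ~0.05 nominal rate; allow Monte-Carlo slack
})
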