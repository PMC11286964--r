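# Synthetic randomized two-arm trial simulator.
#
# The generator emulates the statistical structure the joint model assumes:
# a scalar latent disease-burden state per patient following a discrete-time
# linear update with arm-specific decay, biomarkers as affine emissions of the
# burden, discrete-time proportional-hazards event generation on the burden,
# right censoring, and MCAR missingness. One time unit is a 28-day treatment
# period.

#' Immunoglobulin heavy-chain subtype levels
#'
#' Levels used for the myeloma Ig-subtype baseline covariate, in the order of
#' the trial summary tables.
#' @return Character vector of subtype labels.
#' @export
ig_subtypes <- function() {
  c("IgG", "IgA", "IgD", "IgE", "IgM", "Biclonal", "NoHeavyChain")
}

#' Event types simulated and modelled
#'
#' Progression-free survival, overall survival, and twelve adverse-event
#' categories (time to first qualifying occurrence; only events meeting the
#' grade filter are emitted by the simulator, grades themselves are not
#' modelled).
#' @return Character vector of event-type names; AE names carry the
#'   `"ae_"` prefix.
#' @export
event_types <- function() {
  c("pfs", "os",
    paste0("ae_", c("acute_renal_failure", "cardiac_arrhythmias", "diarrhea",
                    "heart_failure", "hypotension", "liver_impairment",
                    "nausea", "neutropenia", "peripheral_neuropathies",
                    "rash", "thrombocytopenia", "vomiting")))
}

ae_types <- function() grep("^ae_", event_types(), value = TRUE)

#' Default MM2-like Ig subtype marginals
#'
#' Subtype probabilities matching the newly diagnosed myeloma cohort summary
#' (IgG 57.3%, IgA 20.2%, IgD 1.4%, IgE 0.4%, IgM 0.4%, biclonal 3.3%,
#' no heavy chain 16.9%).
#' @return Named probability vector over [ig_subtypes()].
#' @export
mm2_subtype_probs <- function() {
  p <- c(403, 142, 10, 3, 3, 23, 119) / 703
  names(p) <- ig_subtypes()
  p
}

#' Simulation configuration for a synthetic randomized trial
#'
#' @param n_patients Number of patients.
#' @param n_periods Follow-up length in 28-day treatment periods.
#' @param subtype_probs Probability vector over [ig_subtypes()]; must sum to 1.
#' @param arm_prob Probability of assignment to the experimental (IRd) arm.
#' @param dynamics List of latent-burden dynamics parameters:
#'   `decay` (named per-arm multiplicative decay, `rd` and `ird`),
#'   `burden_sd_log` (log-sd of the initial burden around its ISS-driven mean),
#'   `process_sd` (sd of the per-period burden innovation),
#'   `iss_coef` (log-burden shift per ISS stage away from II).
#' @param noise_sd Emission noise, expressed as a fraction of each biomarker's
#'   burden loading; 0 gives noise-free emissions.
#' @param baseline_hazards Named vector of per-event log baseline hazards
#'   (the `b0` in `h_t = 1 - exp(-exp(b0 + b_burden * burden + b_arm * arm))`).
#' @param effect_log_hr Named vector of per-event treatment log hazard ratios.
#' @param burden_coef Named vector of per-event burden coefficients.
#' @param censor_rate Per-period probability of random (non-administrative)
#'   censoring; administrative censoring applies at `n_periods`.
#' @param missingness Scalar or per-variable probability of a longitudinal
#'   observation being missing (MCAR).
#' @param dropout_rate Optional per-period monotone-dropout probability; once
#'   a patient drops out all later longitudinal observations are missing.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration including this seed.
#' @param het Optional heterogeneous-effect component, normally set via
#'   [inject_heterogeneous_effect()].
#' @return An object of class `cf_sim_config`.
#' @export
sim_config <- function(n_patients = 703,
                       n_periods = 24,
                       subtype_probs = mm2_subtype_probs(),
                       arm_prob = 0.5,
                       dynamics = list(),
                       noise_sd = 0.15,
                       baseline_hazards = NULL,
                       effect_log_hr = NULL,
                       burden_coef = NULL,
                       censor_rate = 0.01,
                       missingness = 0.1,
                       dropout_rate = 0,
                       seed = 1L,
                       het = NULL) {
  if (!is_count(n_patients) || n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  if (!is_count(n_periods) || n_periods < 2) {
    stop("`n_periods` must be an integer >= 2", call. = FALSE)
  }
  if (length(subtype_probs) != length(ig_subtypes()) ||
      !is_prob(subtype_probs) || abs(sum(subtype_probs) - 1) > 1e-9) {
    stop("`subtype_probs` must be a probability vector over the ",
         length(ig_subtypes()), " Ig subtypes summing to 1", call. = FALSE)
  }
  names(subtype_probs) <- ig_subtypes()
  if (!is_prob(arm_prob) || length(arm_prob) != 1) {
    stop("`arm_prob` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is_prob(censor_rate) || !is_prob(missingness) || !is_prob(dropout_rate)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  if (length(noise_sd) != 1 || !is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be a non-negative scalar", call. = FALSE)
  }
  dyn <- utils::modifyList(
    list(decay = c(rd = 0.95, ird = 0.88), burden_sd_log = 0.6,
         process_sd = 0.02, iss_coef = 0.25),
    dynamics
  )
  if (any(dyn$decay < 0) || dyn$burden_sd_log < 0 || dyn$process_sd < 0) {
    stop("dynamics rates must be non-negative", call. = FALSE)
  }
  ev <- event_types()
  bh <- c(pfs = -3.0, os = -3.8,
          stats::setNames(-4.8 - 0.1 * seq_along(ae_types()), ae_types()))
  if (!is.null(baseline_hazards)) bh[names(baseline_hazards)] <- baseline_hazards
  ef <- c(pfs = -0.35, os = -0.2,
          stats::setNames(rep(0.25, length(ae_types())), ae_types()))
  if (!is.null(effect_log_hr)) ef[names(effect_log_hr)] <- effect_log_hr
  bc <- c(pfs = 1.0, os = 0.8,
          stats::setNames(rep(0.2, length(ae_types())), ae_types()))
  if (!is.null(burden_coef)) bc[names(burden_coef)] <- burden_coef
  structure(
    list(n_patients = as.integer(n_patients),
         n_periods = as.integer(n_periods),
         subtype_probs = subtype_probs, arm_prob = arm_prob,
         dynamics = dyn, noise_sd = noise_sd,
         baseline_hazards = bh[ev], effect_log_hr = ef[ev],
         burden_coef = bc[ev], censor_rate = censor_rate,
         missingness = missingness, dropout_rate = dropout_rate,
         seed = as.integer(seed), het = het),
    class = "cf_sim_config"
  )
}

# Biomarker emission parameters tied to the default normal-range table:
# value = intercept + loading * burden + N(0, (noise_sd * |loading|)^2).
sim_emission_params <- function() {
  data.frame(
    variable = c("m_protein", "kappa_flc", "hemoglobin", "creatinine",
                 "calcium", "albumin"),
    intercept = c(0.5, 10, 135, 85, 2.35, 42),
    loading = c(8, 45, -12, 18, 0.12, -3.5),
    stringsAsFactors = FALSE
  )
}

#' Inject a heterogeneous treatment effect into a simulation configuration
#'
#' Shifts the treatment log hazard ratio on progression by `extra_log_hr`
#' inside the subgroup picked out by a baseline predicate; the ground-truth
#' CATE stored with the cohort reflects the shift.
#'
#' @param config A [sim_config()] object.
#' @param subgroup_predicate Either a function taking the baseline table and
#'   returning a logical vector, or a named list of baseline field = value
#'   pairs (e.g. `list(subtype = "IgA")`). Predicates may reference baseline
#'   fields only; naming a longitudinal variable is an error.
#' @param extra_log_hr Additional log hazard ratio applied to the progression
#'   hazard of treated subgroup members (negative = extra benefit).
#' @return The modified configuration.
#' @export
inject_heterogeneous_effect <- function(config, subgroup_predicate,
                                        extra_log_hr) {
  stopifnot(inherits(config, "cf_sim_config"))
  baseline_fields <- c("patient_id", "age", "sex", "subtype", "iss",
                       "time_since_dx", "arm")
  long_fields <- sim_emission_params()$variable
  if (is.list(subgroup_predicate) && !is.function(subgroup_predicate)) {
    bad <- intersect(names(subgroup_predicate), long_fields)
    if (length(bad)) {
      stop("subgroup predicate may reference baseline fields only; ",
           "longitudinal variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    unknown <- setdiff(names(subgroup_predicate), baseline_fields)
    if (length(unknown)) {
      stop("unknown baseline field(s) in predicate: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  } else if (!is.function(subgroup_predicate)) {
    stop("`subgroup_predicate` must be a function or a named list",
         call. = FALSE)
  }
  config$het <- list(predicate = subgroup_predicate,
                     extra_log_hr = extra_log_hr)
  config
}

eval_predicate <- function(predicate, baseline) {
  if (is.function(predicate)) {
    sel <- predicate(baseline)
  } else {
    sel <- rep(TRUE, nrow(baseline))
    for (f in names(predicate)) {
      sel <- sel & (as.character(baseline[[f]]) %in% predicate[[f]])
    }
  }
  if (!is.logical(sel) || length(sel) != nrow(baseline)) {
    stop("subgroup predicate must return one logical per patient",
         call. = FALSE)
  }
  sel & !is.na(sel)
}

# Discrete-time hazard for one event type given burden and arm.
discrete_hazard <- function(b0, b_burden, burden, b_arm, arm, extra = 0) {
  1 - exp(-exp(b0 + b_burden * burden + b_arm * arm + extra))
}

#' Generate a synthetic randomized trial cohort
#'
#' Draws baseline covariates, randomizes arms independently of covariates,
#' evolves a latent disease-burden state with arm-specific decay, emits
#' biomarkers as affine functions of the burden, draws event times from
#' discrete-time proportional-hazards models on the burden, applies right
#' censoring, and finally applies MCAR (and optionally monotone-dropout)
#' missingness. The returned object carries the ground-truth burden paths and
#' per-patient progression CATE for recovery tests.
#'
#' @param config A [sim_config()] object.
#' @return A `cf_cohort`: list with `baseline` (data.frame), `X`, `M`, `A`
#'   (n x T x d arrays), `periods` (0-based), `outcomes` (patient_id, event,
#'   time, status), `ranges` (normal-range table) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cf_sim_config"))
  n <- config$n_patients
  Tt <- config$n_periods
  em <- sim_emission_params()
  J <- nrow(em)
  ev <- event_types()
  with_seed(config$seed, {
    subtype <- factor(sample(ig_subtypes(), n, TRUE, config$subtype_probs),
                      levels = ig_subtypes())
    iss <- factor(sample(c("I", "II", "III"), n, TRUE,
                         c(0.461, 0.374, 0.165)), levels = c("I", "II", "III"))
    baseline <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n)),
      age = pmin(pmax(round(stats::rnorm(n, 73, 7)), 48), 90),
      sex = factor(sample(c("F", "M"), n, TRUE, c(0.499, 0.501)),
                   levels = c("F", "M")),
      subtype = subtype,
      iss = iss,
      time_since_dx = round(exp(stats::rnorm(n, 0.1, 0.8)), 2),
      stringsAsFactors = FALSE
    )
    # Randomization: arm independent of every covariate.
    arm <- stats::rbinom(n, 1, config$arm_prob)
    baseline$arm <- arm

    dyn <- config$dynamics
    iss_num <- as.integer(iss) - 2L
    b0 <- exp(dyn$iss_coef * iss_num +
                stats::rnorm(n, 0, dyn$burden_sd_log))
    decay <- ifelse(arm == 1, dyn$decay[["ird"]], dyn$decay[["rd"]])
    burden <- matrix(0, n, Tt)
    burden[, 1] <- b0
    if (Tt > 1) {
      for (t in 2:Tt) {
        burden[, t] <- pmax(decay * burden[, t - 1] +
                              stats::rnorm(n, 0, dyn$process_sd), 0)
      }
    }

    X <- array(0, c(n, Tt, J),
               dimnames = list(baseline$patient_id, NULL, em$variable))
    for (j in seq_len(J)) {
      eps <- if (config$noise_sd > 0) {
        matrix(stats::rnorm(n * Tt, 0, config$noise_sd * abs(em$loading[j])),
               n, Tt)
      } else 0
      X[, , j] <- em$intercept[j] + em$loading[j] * burden + eps
    }
    M <- array(1, dim(X), dimnames = dimnames(X))

    # Treatments: lenalidomide + dexamethasone in both arms, ixazomib in IRd.
    A <- array(0, c(n, Tt, 3),
               dimnames = list(baseline$patient_id, NULL,
                               c("len_dose", "ixa_dose", "dex_dose")))
    A[, , "len_dose"] <- 25
    A[, , "dex_dose"] <- 40
    A[, , "ixa_dose"] <- 4 * arm

    het_sel <- if (!is.null(config$het)) {
      eval_predicate(config$het$predicate, baseline)
    } else rep(FALSE, n)
    het_extra <- if (!is.null(config$het)) config$het$extra_log_hr else 0

    # Event times: inverse sampling of the discrete-time hazard per period.
    outcomes <- vector("list", length(ev))
    cens_draw <- matrix(stats::runif(n * Tt), n, Tt)
    cens_time <- apply(cens_draw < config$censor_rate, 1, function(z) {
      w <- which(z)
      if (length(w)) w[1] else Tt
    })
    for (k in seq_along(ev)) {
      e <- ev[k]
      u <- matrix(stats::runif(n * Tt), n, Tt)
      extra <- if (e == "pfs") het_extra * het_sel * arm else 0
      ev_time <- rep(Inf, n)
      for (t in seq_len(Tt)) {
        h <- discrete_hazard(config$baseline_hazards[[e]],
                             config$burden_coef[[e]], burden[, t],
                             config$effect_log_hr[[e]], arm, extra)
        hit <- is.infinite(ev_time) & (u[, t] < h)
        ev_time[hit] <- t
      }
      y <- pmin(ev_time, cens_time)
      status <- as.integer(ev_time <= cens_time & is.finite(ev_time))
      outcomes[[k]] <- data.frame(patient_id = baseline$patient_id,
                                  event = e, time = y, status = status,
                                  stringsAsFactors = FALSE)
    }
    outcomes <- do.call(rbind, outcomes)
    rownames(outcomes) <- NULL

    # Ground-truth CATE on progression risk over the follow-up, computed on
    # the noise-free burden path under each arm.
    cate <- true_cate(config, b0, het_sel)

    cohort <- structure(
      list(baseline = baseline, X = X, M = M, A = A,
           periods = 0:(Tt - 1), outcomes = outcomes,
           ranges = default_normal_ranges(),
           truth = list(burden = burden, cate = cate, config = config)),
      class = "cf_cohort"
    )
    miss_seed <- derive_seed(config$seed, "missingness")
    cohort <- apply_missingness(cohort, config$missingness, seed = miss_seed,
                                dropout_rate = config$dropout_rate)
    cohort
  })
}

# Cumulative progression risk difference (IRd minus Rd) on the deterministic
# burden path; negative values mean IRd reduces predicted progression risk.
true_cate <- function(config, b0, het_sel) {
  Tt <- config$n_periods
  dyn <- config$dynamics
  risk_under <- function(arm) {
    decay <- if (arm == 1) dyn$decay[["ird"]] else dyn$decay[["rd"]]
    extra <- if (arm == 1 && !is.null(config$het)) {
      config$het$extra_log_hr * het_sel
    } else 0
    surv <- rep(1, length(b0))
    b <- b0
    for (t in seq_len(Tt)) {
      h <- discrete_hazard(config$baseline_hazards[["pfs"]],
                           config$burden_coef[["pfs"]], b,
                           config$effect_log_hr[["pfs"]], arm, extra)
      surv <- surv * (1 - h)
      b <- decay * b
    }
    1 - surv
  }
  risk_under(1) - risk_under(0)
}

#' Apply MCAR (and optional monotone dropout) missingness to a panel
#'
#' Observation-mask entries are set to 0 independently with the given rate;
#' the underlying values are retained in `X` but flagged unobserved in `M`.
#'
#' @param cohort A `cf_cohort`.
#' @param rates Scalar or per-variable named vector of missingness
#'   probabilities in `[0, 1]`.
#' @param seed Integer seed for the missingness draws.
#' @param dropout_rate Optional per-period monotone dropout probability.
#' @return The cohort with an updated mask `M`.
#' @export
apply_missingness <- function(cohort, rates, seed = NULL, dropout_rate = 0) {
  stopifnot(inherits(cohort, "cf_cohort"))
  vars <- dimnames(cohort$X)[[3]]
  if (length(rates) == 1 && is.null(names(rates))) {
    rates <- stats::setNames(rep(rates, length(vars)), vars)
  }
  if (!is_prob(rates) || !is_prob(dropout_rate)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  n <- dim(cohort$X)[1]; Tt <- dim(cohort$X)[2]
  with_seed(seed, {
    for (v in vars) {
      r <- if (v %in% names(rates)) rates[[v]] else 0
      if (r > 0) {
        drop_mask <- matrix(stats::runif(n * Tt) < r, n, Tt)
        cohort$M[, , v][drop_mask] <- 0
      }
    }
    if (dropout_rate > 0) {
      dropout_at <- apply(matrix(stats::runif(n * Tt) < dropout_rate, n, Tt),
                          1, function(z) {
                            w <- which(z)
                            if (length(w)) w[1] else Inf
                          })
      for (i in seq_len(n)) {
        if (is.finite(dropout_at[i]) && dropout_at[i] < Tt) {
          cohort$M[i, (dropout_at[i] + 1):Tt, ] <- 0
        }
      }
    }
  })
  cohort
}

#' @export
print.cf_cohort <- function(x, ...) {
  d <- dim(x$X)
  cat("<cf_cohort> ", d[1], " patients, ", d[2], " treatment periods, ",
      d[3], " longitudinal variables\n", sep = "")
  cat("  arms: ", sum(x$baseline$arm == 0), " Rd / ",
      sum(x$baseline$arm == 1), " IRd\n", sep = "")
  cat("  events: ", paste(unique(x$outcomes$event), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

# Outcomes for one event type as a small data.frame (time, status).
outcomes_for <- function(cohort, event) {
  out <- cohort$outcomes[cohort$outcomes$event == event, , drop = FALSE]
  out[match(cohort$baseline$patient_id, out$patient_id), , drop = FALSE]
}
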