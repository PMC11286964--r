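# Cohort readers/writers, configuration files, manifests, and the command
# dispatcher binding the modules into reproducible runs.
#
# CSV dialect: UTF-8, comma separator, '.' decimal, explicit NA token "NA".

#' Write a cohort to a directory of CSV files
#'
#' Emits four CSVs — `baseline.csv` (wide), `longitudinal.csv` (long format:
#' patient_id, period, variable, value, observed), `treatment.csv` (long
#' format), `outcomes.csv` — plus `normal_ranges.csv`, a `truth.json` sidecar
#' of simulation ground truth when present, and a run manifest.
#'
#' @param cohort A `cf_cohort`.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  stopifnot(inherits(cohort, "cf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  n <- dim(cohort$X)[1]; Tt <- dim(cohort$X)[2]
  vars <- dimnames(cohort$X)[[3]]
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(patient_id = rep(cohort$baseline$patient_id, Tt),
               period = rep(0:(Tt - 1), each = n),
               variable = v,
               value = as.vector(cohort$X[, , v]),
               observed = as.vector(cohort$M[, , v]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, file.path(dir, "longitudinal.csv"),
                   row.names = FALSE)
  drugs <- dimnames(cohort$A)[[3]]
  trt <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(patient_id = rep(cohort$baseline$patient_id, Tt),
               period = rep(0:(Tt - 1), each = n),
               drug = d, dose = as.vector(cohort$A[, , d]),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(trt, file.path(dir, "treatment.csv"), row.names = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$ranges)) {
    utils::write.csv(cohort$ranges, file.path(dir, "normal_ranges.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$truth)) {
    truth <- list(cate = cohort$truth$cate,
                  burden = cohort$truth$burden,
                  config = sim_config_as_list(cohort$truth$config))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_manifest(dir, list(n_patients = n, n_periods = Tt,
                           variables = vars), seed = seed)
  invisible(dir)
}

sim_config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$het) && is.function(out$het$predicate)) {
    out$het$predicate <- paste(deparse(out$het$predicate), collapse = " ")
  }
  out
}

# Every run writes a manifest (config hash, seed, package version) next to
# its outputs so artifacts are reconstructible from config + seed alone.
write_manifest <- function(dir, config, seed = NA_integer_) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(
    config = config,
    config_hash = fnv1a32_hex(as.character(cfg_json)),
    seed = seed,
    package = "coxformer",
    version = as.character(utils::packageVersion("coxformer"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a cohort from a directory of CSV files
#'
#' Reads the four CSVs written by [write_cohort()] and validates them: shared
#' patient ids across files, non-negative integer periods, and no duplicate
#' (patient, period, variable) rows; violations raise itemized errors.
#'
#' @param dir Directory containing `baseline.csv`, `longitudinal.csv`,
#'   `treatment.csv`, `outcomes.csv` (and optionally `normal_ranges.csv`,
#'   `truth.json`).
#' @return A validated `cf_cohort`.
#' @export
load_cohort <- function(dir) {
  paths <- file.path(dir, c("baseline.csv", "longitudinal.csv",
                            "treatment.csv", "outcomes.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing cohort file(s): ", paste(basename(missing),
                                           collapse = ", "), call. = FALSE)
  }
  baseline <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  long <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  trt <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  outcomes <- utils::read.csv(paths[4], stringsAsFactors = FALSE)
  baseline$sex <- factor(baseline$sex, levels = c("F", "M"))
  baseline$subtype <- factor(baseline$subtype, levels = ig_subtypes())
  baseline$iss <- factor(baseline$iss, levels = c("I", "II", "III"))

  errors <- character(0)
  ids <- baseline$patient_id
  if (anyDuplicated(ids)) errors <- c(errors, "duplicate patient ids in baseline.csv")
  for (nm in c("longitudinal", "treatment", "outcomes")) {
    tab <- switch(nm, longitudinal = long, treatment = trt,
                  outcomes = outcomes)
    unknown <- setdiff(unique(tab$patient_id), ids)
    if (length(unknown)) {
      errors <- c(errors, paste0(nm, ".csv references unknown patient id(s): ",
                                 paste(utils::head(unknown, 5),
                                       collapse = ", ")))
    }
  }
  if (any(long$period != round(long$period)) || any(long$period < 0)) {
    errors <- c(errors,
                "longitudinal periods must be non-negative integers (28-day treatment periods)")
  }
  dup <- duplicated(long[, c("patient_id", "period", "variable")])
  if (any(dup)) {
    d <- long[dup, ][1, ]
    errors <- c(errors, sprintf(
      "duplicate (patient, period, variable) row(s), e.g. (%s, %s, %s)",
      d$patient_id, d$period, d$variable))
  }
  if (length(errors)) {
    stop("cohort validation failed:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }

  n <- length(ids)
  Tt <- max(long$period) + 1L
  vars <- unique(long$variable)
  X <- array(NA_real_, c(n, Tt, length(vars)),
             dimnames = list(ids, NULL, vars))
  M <- array(0, dim(X), dimnames = dimnames(X))
  idx <- cbind(match(long$patient_id, ids), long$period + 1L,
               match(long$variable, vars))
  X[idx] <- long$value
  M[idx] <- long$observed
  X[is.na(X)] <- 0
  drugs <- unique(trt$drug)
  A <- array(0, c(n, Tt, length(drugs)), dimnames = list(ids, NULL, drugs))
  A[cbind(match(trt$patient_id, ids), trt$period + 1L,
          match(trt$drug, drugs))] <- trt$dose

  ranges_path <- file.path(dir, "normal_ranges.csv")
  ranges <- if (file.exists(ranges_path)) read_normal_ranges(ranges_path)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    list(cate = tr$cate, burden = tr$burden, config = tr$config)
  }
  structure(list(baseline = baseline, X = X, M = M, A = A,
                 periods = 0:(Tt - 1), outcomes = outcomes,
                 ranges = ranges, truth = truth),
            class = "cf_cohort")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names match the arguments of [sim_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `cf_sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$subtype_probs)) {
    cfg$subtype_probs <- unlist(cfg$subtype_probs)
  }
  allowed <- names(formals(sim_config))
  do.call(sim_config, cfg[intersect(names(cfg), allowed)])
}

parse_argv <- function(argv) {
  out <- list(command = if (length(argv)) argv[[1]] else NA_character_)
  i <- 2
  while (i <= length(argv)) {
    key <- sub("^--", "", argv[[i]])
    if (i + 1 <= length(argv)) {
      out[[key]] <- argv[[i + 1]]
      i <- i + 2
    } else {
      out[[key]] <- TRUE
      i <- i + 1
    }
  }
  out
}

cli_usage <- function() {
  message("usage: coxformer <command> [--option value ...]\n",
          "commands: simulate preprocess pretrain finetune evaluate ",
          "forecast predict-events cate subgroup introspect\n",
          "common options: --config <yaml/json> --in <dir|rds> ",
          "--ckpt <rds> --out <path> --seed <int> --epochs <int>")
}

#' Run a pipeline command
#'
#' Thin command dispatcher over the package's functions; every run is
#' governed by a single seed and writes a manifest alongside its outputs.
#' Returns an exit status instead of quitting, so it can be driven by a
#' wrapper script or tested directly.
#'
#' @param argv Character vector: command followed by `--key value` options.
#' @return Integer exit status: 0 on success, 1 on a validation/runtime
#'   error, 2 on usage errors.
#' @export
run_command <- function(argv) {
  opts <- parse_argv(argv)
  cmds <- c("simulate", "preprocess", "pretrain", "finetune", "evaluate",
            "forecast", "predict-events", "cate", "subgroup", "introspect")
  if (is.na(opts$command) || !opts$command %in% cmds) {
    cli_usage()
    return(2L)
  }
  seed <- as.integer(opts$seed %||% 1L)
  num <- function(x, default) if (is.null(x)) default else as.numeric(x)
  readRDS <- function(path) {
    if (!is.character(path) || !file.exists(path)) {
      stop("input file not found: ", path, call. = FALSE)
    }
    base::readRDS(path)
  }
  status <- tryCatch({
    switch(opts$command,
      "simulate" = {
        config <- if (!is.null(opts$config)) read_sim_config(opts$config)
          else sim_config()
        if (!is.null(opts$seed)) config$seed <- seed
        cohort <- generate_cohort(config)
        write_cohort(cohort, opts$out, seed = config$seed)
      },
      "preprocess" = {
        cohort <- load_cohort(opts$`in`)
        prep <- preprocess_cohort(cohort)
        saveRDS(prep, opts$out)
      },
      "pretrain" = {
        cohort <- readRDS(opts$`in`)
        model <- init_model(cohort, encoder_config(), seed = seed)
        model <- pretrain(model, cohort,
                          epochs = num(opts$epochs, 60), seed = seed)
        saveRDS(list(model = model, cohort = cohort), opts$out)
        utils::write.csv(model$loss_curve,
                         file.path(dirname(opts$out), "pretrain_metrics.csv"),
                         row.names = FALSE)
        write_manifest(dirname(opts$out), list(command = "pretrain",
                                               epochs = num(opts$epochs, 60)),
                       seed = seed)
      },
      "finetune" = {
        ck <- readRDS(opts$ckpt)
        ck$model <- finetune_heads(ck$model, ck$cohort,
                                   event_type = opts$event %||% "pfs",
                                   epochs = num(opts$epochs, 150),
                                   seed = seed)
        saveRDS(ck, opts$ckpt)
      },
      "evaluate" = {
        ck <- readRDS(opts$ckpt)
        if (is.null(ck$model$score_range) ||
            !length(ck$model$score_range)) {
          stop("checkpoint has no fine-tuned event head; run `finetune` first",
               call. = FALSE)
        }
        tc <- num(opts$t_cond, 1); th <- num(opts$horizon, 6)
        ev <- names(ck$model$score_range)[1]
        ol <- outcomes_for(ck$cohort, ev)
        scores <- event_score(ck$model, ck$cohort, tc, type = ev)
        ci <- averaged_cindex(scores, ol$time, ol$status)
        truth <- horizon_slice(ck$cohort, tc, th)
        mse <- forecast_mse(rollout(ck$model, ck$cohort, tc, th)$X_pred,
                            truth$X, truth$M)
        mse_locf <- forecast_mse(locf_forecast(ck$cohort, tc, th),
                                 truth$X, truth$M)
        res <- data.frame(task = c(paste0("cindex_", ev), "mse", "mse_locf"),
                          t_cond = tc, t_horizon = c(NA, th, th),
                          value = c(ci, mse, mse_locf))
        utils::write.csv(res, opts$out, row.names = FALSE)
      },
      "forecast" = {
        ck <- readRDS(opts$ckpt)
        tc <- num(opts$t_cond, 1); th <- num(opts$horizon, 6)
        ro <- rollout(ck$model, ck$cohort, tc, th)
        n <- dim(ro$X_pred)[1]
        out <- do.call(rbind, lapply(ck$model$meta$vars, function(v) {
          data.frame(patient_id = rep(ck$cohort$baseline$patient_id, th),
                     period = rep(tc:(tc + th - 1), each = n), variable = v,
                     value = as.vector(ro$X_pred[, , v]))
        }))
        utils::write.csv(out, opts$out, row.names = FALSE)
      },
      "predict-events" = {
        ck <- readRDS(opts$ckpt)
        ev <- opts$event %||% "pfs"
        scores <- event_score(ck$model, ck$cohort, num(opts$t_cond, 1),
                              type = ev)
        utils::write.csv(
          data.frame(patient_id = ck$cohort$baseline$patient_id,
                     event = ev, score = as.vector(scores)),
          opts$out, row.names = FALSE)
      },
      "cate" = {
        ck <- readRDS(opts$ckpt)
        po <- predict_potential_outcomes(ck$model, ck$cohort, horizon = 1)
        utils::write.csv(
          data.frame(patient_id = ck$cohort$baseline$patient_id,
                     y1 = as.vector(po$y1), y0 = as.vector(po$y0),
                     cate = as.vector(po$cate)),
          opts$out, row.names = FALSE)
      },
      "subgroup" = {
        cohort <- readRDS(opts$`in`)
        ds <- discover_subgroup(cohort, seed = seed,
                                pretrain_epochs = num(opts$epochs, 30))
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        utils::write.csv(describe_tree(ds$tree),
                         file.path(opts$out, "tree.csv"), row.names = FALSE)
        rep <- ds$report
        utils::write.csv(
          data.frame(set = c("subgroup", "full"),
                     n = c(rep$subgroup$n, rep$full$n),
                     arm_log_hr = c(rep$subgroup$cox$log_hr,
                                    rep$full$cox$log_hr),
                     cox_p = c(rep$subgroup$cox$p, rep$full$cox$p),
                     logrank_p = c(rep$subgroup$logrank_p,
                                   rep$full$logrank_p)),
          file.path(opts$out, "subgroup_report.csv"), row.names = FALSE)
        write_manifest(opts$out, list(command = "subgroup"), seed = seed)
      },
      "introspect" = {
        ck <- readRDS(opts$ckpt)
        cm <- hidden_correlation_map(ck$model, ck$cohort)
        utils::write.csv(as.data.frame(cm), opts$out, row.names = FALSE)
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
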