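# Interchange formats and the pipeline driver. Tables are plain CSV with
# mandatory headers; nested results are JSON; run configurations are YAML.
# The trial dialect (one row per cue presentation) is:
#   subject_id, run, trial, valence{win|avoid}, required_action{go|nogo},
#   image_id{1|2}, action{go|nogo}, outcome{-1|0|1}, favorable{0|1},
#   shock_delivered{0|1|NA}

TRIAL_COLUMNS <- c("subject_id", "run", "trial", "valence", "required_action",
                   "image_id", "action", "outcome", "favorable",
                   "shock_delivered")

#' Write a trial table
#'
#' @param trials Multi-subject trial data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  out$condition <- NULL
  out$image <- NULL
  out$favorable <- as.integer(out$favorable)
  out$shock_delivered <- as.integer(out$shock_delivered)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(out))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  write.csv(out[, TRIAL_COLUMNS], path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}

#' Read and validate a trial table
#'
#' Parses the pipeline's trial CSV dialect, validates every row (known
#' factor levels, outcome codes consistent with the valence, unique
#' (subject, run, trial) keys) and returns the table ordered by subject and
#' presentation. Malformed rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @return Trial data frame with the derived \code{condition} and global
#'   \code{image} columns restored.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  unknown <- setdiff(names(df), TRIAL_COLUMNS)
  if (length(unknown)) {
    stop("unknown column(s) in trial table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  problems <- character()
  flag <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, paste0(
        what, " at line(s) ", paste(head(line[bad], 5L), collapse = ", "),
        if (sum(bad) > 5L) sprintf(" (+%d more)", sum(bad) - 5L)))
    }
  }
  flag(!df$valence %in% c("win", "avoid"), "invalid valence")
  flag(!df$required_action %in% c("go", "nogo"), "invalid required_action")
  flag(!df$action %in% c("go", "nogo"), "invalid action")
  flag(!df$image_id %in% c(1L, 2L), "invalid image_id")
  flag(!df$outcome %in% c(-1L, 0L, 1L), "invalid outcome code")
  flag(df$valence == "win" & df$outcome == -1L, "shock outcome on win trial")
  flag(df$valence == "avoid" & df$outcome == 1L, "reward outcome on avoid trial")
  flag(!df$favorable %in% c(0L, 1L), "invalid favorable flag")
  key <- paste(df$subject_id, df$run, df$trial)
  flag(duplicated(key), "duplicated (subject, run, trial)")
  if (length(problems)) {
    stop("trial table failed validation:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df$favorable <- df$favorable == 1L
  df$shock_delivered <- ifelse(is.na(df$shock_delivered), NA,
                               df$shock_delivered == 1L)
  df$condition <- paste0(df$required_action, "_to_", df$valence)
  df$image <- cue_image_index(df$valence, df$required_action, df$image_id)
  df <- df[order(df$subject_id, df$run, df$trial), ]
  rownames(df) <- NULL
  df
}

#' Write / read cohort side tables
#'
#' Ground-truth parameters (long: subject_id, parameter, value,
#' unconstrained) and covariates (subject_id, activation, sex, age,
#' total_shocks) round-trip through CSV at full double precision.
#'
#' @param x Data frame.
#' @param path CSV path.
#' @return \code{write_table}: \code{path} invisibly; \code{read_table}: the
#'   data frame.
#' @export
write_table <- function(x, path) {
  df <- x
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble and validate a pipeline run configuration
#'
#' @param seed Integer master seed (required; every stochastic stage derives
#'   a named substream from it).
#' @param n_subjects,n_per_cue,n_runs Simulated cohort design.
#' @param model Model to fit: a \code{plgt_model_spec}, or one of the labels
#'   in \code{\link{enumerate_models}}, or \code{"select"} to run the
#'   stepwise search.
#' @param n_mc Monte-Carlo draws per subject for iBIC.
#' @param n_boot Bootstrap resamples for the mediation stage.
#' @param tol,max_iter EM settings.
#' @param activation_alpha,activation_sd Synthetic activation generator.
#' @return A validated list of class \code{plgt_config}.
#' @export
run_config <- function(seed, n_subjects = 82, n_per_cue = 50, n_runs = 4,
                       model = "select", n_mc = 1000, n_boot = 2000,
                       tol = 1e-3, max_iter = 200,
                       activation_alpha = 0.5, activation_sd = 1) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed)) {
    stop("a numeric `seed` is required: runs must be reproducible from ",
         "config + seed alone", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_subjects = n_subjects,
              n_per_cue = n_per_cue, n_runs = n_runs,
              model = model, n_mc = n_mc, n_boot = n_boot, tol = tol,
              max_iter = max_iter, activation_alpha = activation_alpha,
              activation_sd = activation_sd)
  structure(cfg, class = "plgt_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{run_config}}.
#' @return A \code{plgt_config}.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

resolve_model <- function(model) {
  if (inherits(model, "plgt_model_spec")) return(model)
  if (identical(model, "select")) return("select")
  reg <- enumerate_models()
  if (model %in% names(reg)) return(reg[[model]])
  if (identical(model, "base")) return(reg[[1L]])
  if (identical(model, "full")) return(reg[[length(reg)]])
  stop("unknown model: ", model, call. = FALSE)
}

#' Run the full pipeline
#'
#' Simulate a cohort, fit (or stepwise-select) the model, compute the iBIC,
#' behavioral summaries, and a mediation analysis linking the synthetic
#' activation (X) to avoid-trial accuracy (Y) through the activation-driving
#' parameter's estimate (M), adjusting for sex, age and total shocks. All
#' artifacts are written under \code{out_dir} together with a manifest
#' recording the configuration, seeds, timings, and package version.
#'
#' @param config A \code{plgt_config}.
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress?
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "plgt_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage_done <- character()
  manifest_path <- file.path(out_dir, "manifest.json")
  say <- function(...) if (verbose) message(sprintf(...))
  status <- "running"
  build_manifest <- function() {
    list(config = unclass(config),
         package_version = as.character(utils::packageVersion("plgt")),
         status = status, stages_completed = stage_done,
         timings_sec = timings)
  }
  write_manifest <- function(m) {
    jsonlite::write_json(m, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  on.exit({
    if (!identical(status, "complete")) {
      status <- "failed"
      write_manifest(build_manifest())
    }
  }, add = TRUE)

  stage <- function(name, code) {
    say("[%s]", name)
    t <- system.time(res <- code)[["elapsed"]]
    timings[[name]] <<- round(t, 3)
    stage_done <<- c(stage_done, name)
    res
  }

  gen_spec <- model_spec("valence_sign", "valence", TRUE, TRUE)
  cohort <- stage("simulate", {
    co <- simulate_cohort(default_prior(gen_spec), gen_spec,
                          n_subjects = config$n_subjects,
                          n_per_cue = config$n_per_cue,
                          n_runs = config$n_runs,
                          seed = substream_seed(config$seed, "simulate"),
                          activation_alpha = config$activation_alpha,
                          activation_sd = config$activation_sd)
    write_trials(co$trials, file.path(out_dir, "trials.csv"))
    write_table(co$truth, file.path(out_dir, "truth.csv"))
    write_table(co$covariates, file.path(out_dir, "covariates.csv"))
    co
  })

  model <- resolve_model(config$model)
  fit <- if (identical(model, "select")) {
    sel <- stage("select", stepwise_select(
      cohort$trials, seed = substream_seed(config$seed, "fit"),
      n_mc = config$n_mc, tol = config$tol, max_iter = config$max_iter))
    write_table(sel$path, file.path(out_dir, "selection_path.csv"))
    jsonlite::write_json(
      list(winner = sel$best_spec$label, ibic = sel$best_ibic$ibic),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    sel$best_fit
  } else {
    stage("fit", em_fit(cohort$trials, model,
                        seed = substream_seed(config$seed, "fit"),
                        tol = config$tol, max_iter = config$max_iter))
  }
  ib <- stage("ibic", ibic(fit, cohort$trials, n_mc = config$n_mc,
                           seed = substream_seed(config$seed, "ibic")))
  stage("write_fit", {
    jsonlite::write_json(
      list(model = fit$spec$label,
           population = list(mean = as.list(fit$prior$mean),
                             var = as.list(fit$prior$var)),
           log_evidence = fit$log_evidence, converged = fit$converged,
           em_iterations = nrow(fit$trace),
           ibic = ib$ibic, ibic_mc_se = ib$mc_se),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
    est <- data.frame(subject_id = fit$subject_ids, fit$estimates,
                      check.names = FALSE)
    write_table(est, file.path(out_dir, "estimates.csv"))
    write_table(fit$trace, file.path(out_dir, "em_trace.csv"))
  })

  beh <- stage("behavior", {
    b <- behavior_summary(cohort$trials)
    write_table(b$accuracy, file.path(out_dir, "accuracy.csv"))
    write_table(b$stay_switch, file.path(out_dir, "stay_switch.csv"))
    b
  })

  stage("mediate", {
    m_param <- param_names(fit$spec)[1]
    acc_avoid <- with(beh$accuracy[beh$accuracy$valence == "avoid", ],
                      tapply(accuracy, subject_id, mean, na.rm = TRUE))
    md <- cohort$covariates
    md$mediator <- fit$modes[match(md$subject_id, as.integer(fit$subject_ids)),
                             m_param]
    md$accuracy_avoid <- as.numeric(acc_avoid[as.character(md$subject_id)])
    med <- mediate(md, "activation", "mediator", "accuracy_avoid",
                   covariates = c("sex", "age", "total_shocks"),
                   n_boot = config$n_boot,
                   seed = substream_seed(config$seed, "bootstrap"))
    jsonlite::write_json(
      list(x = "activation", m = m_param, y = "accuracy_avoid",
           paths = as.list(med$paths), indirect = med$indirect,
           ci = med$boot$ci, p = med$boot$p, n_boot = med$boot$n_boot,
           n_used = med$n_used),
      file.path(out_dir, "mediation.json"), auto_unbox = TRUE, digits = NA)
    med
  })

  status <- "complete"
  manifest <- build_manifest()
  manifest$total_sec <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
  write_manifest(manifest)
  say("pipeline complete: %s", out_dir)
  invisible(manifest)
}
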