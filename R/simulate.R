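# Synthetic cohorts. The generator mirrors the study design: 82 subjects,
# four cue categories x two images, ~50 trials per cue across 4 runs, 80/20
# probabilistic feedback, outcomes coded +1/0/-1, and subject parameters
# drawn from normal population distributions on the unconstrained scale --
# exactly the random-effects structure the hierarchical fit assumes.

#' Normal population prior over unconstrained parameters
#'
#' @param mean Named numeric vector of population means (unconstrained
#'   scale), one per free parameter of the model it describes.
#' @param var Named numeric vector of population variances (> 0), same names.
#' @return An object of class \code{plgt_prior}.
#' @export
population_prior <- function(mean, var) {
  stopifnot(length(mean) == length(var),
            !is.null(names(mean)), identical(names(mean), names(var)))
  if (any(var <= 0)) stop("population variances must be > 0", call. = FALSE)
  structure(list(mean = mean, var = var), class = "plgt_prior")
}

#' @export
print.plgt_prior <- function(x, ...) {
  cat("<plgt population prior> (unconstrained scale)\n")
  print(data.frame(mean = x$mean, sd = sqrt(x$var)))
  invisible(x)
}

#' Default generating prior for simulation and recovery studies
#'
#' Unconstrained means chosen so the natural-space population medians are
#' approximately eps = 0.2, rho = 2, b = 0.3, pi = 0.3, with standard
#' deviation 0.5 on the unconstrained scale for every parameter: learnable
#' but non-degenerate behavior. These are a repository convention for
#' simulation studies, not estimates of any real cohort.
#'
#' @param spec A \code{plgt_model_spec}.
#' @param sd Population standard deviation on the unconstrained scale.
#' @return A \code{plgt_prior} over the free parameters of \code{spec}.
#' @export
default_prior <- function(spec, sd = 0.5) {
  nm <- param_names(spec)
  med <- ifelse(startsWith(nm, "eps"), qlogis(0.2),
         ifelse(startsWith(nm, "rho"), log(2), 0.3))
  population_prior(setNames(med, nm), setNames(rep(sd^2, length(nm)), nm))
}

#' Draw subject parameter sets from a population prior
#'
#' Independent normal draws per parameter on the unconstrained scale, mapped
#' to natural space through the model's transforms.
#'
#' @param prior A \code{plgt_prior}.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param spec A \code{plgt_model_spec} whose free parameters match the prior.
#' @return List with matrices \code{unconstrained} and \code{natural}
#'   (\code{n} rows, one named column per parameter).
#' @export
sample_subjects <- function(prior, n, seed, spec) {
  stopifnot(inherits(prior, "plgt_prior"), n >= 1)
  nm <- param_names(spec)
  stopifnot(identical(sort(nm), sort(names(prior$mean))))
  d <- length(nm)
  theta <- with_seed(seed, {
    matrix(rnorm(n * d, mean = rep(prior$mean[nm], each = n),
                 sd = rep(sqrt(prior$var[nm]), each = n)),
           nrow = n, ncol = d, dimnames = list(NULL, nm))
  })
  list(unconstrained = theta, natural = to_natural(theta, spec))
}

#' Simulate one subject's choices on a schedule
#'
#' Forward-samples the generative model: on each trial the action is drawn
#' from the softmax go probability, feedback is drawn from the task's 80/20
#' rule, and values are updated before the next trial.
#'
#' @param params Named natural-space parameter vector.
#' @param spec A \code{plgt_model_spec}.
#' @param schedule A schedule from \code{\link{build_schedule}}.
#' @param seed Integer seed.
#' @param p_correct Feedback reliability (see \code{\link{sample_feedback}}).
#' @return The schedule with added columns \code{action}, \code{outcome},
#'   \code{favorable}, \code{shock_delivered}.
#' @export
simulate_subject <- function(params, spec, schedule, seed, p_correct = 0.8) {
  ex <- expand_params(params, spec)
  n <- nrow(schedule)
  image <- schedule$image
  v_idx <- ifelse(schedule$valence == "avoid", 2L, 1L)
  is_go_cue <- schedule$required_action == "go"
  with_seed(seed, {
    q_go <- numeric(8L); q_nogo <- numeric(8L); v <- numeric(8L)
    action <- character(n); outcome <- integer(n)
    favorable <- logical(n); shock_delivered <- rep(NA, n)
    u_action <- runif(n); u_fav <- runif(n); u_shock <- runif(n)
    for (t in seq_len(n)) {
      s <- image[t]
      dlt <- q_nogo[s] - (q_go[s] + ex$b + ex$pi * v[s])
      p_go <- 1 / (1 + exp(dlt))
      go <- u_action[t] < p_go
      action[t] <- if (go) "go" else "nogo"
      correct <- go == is_go_cue[t]
      fav <- u_fav[t] < if (correct) p_correct else 1 - p_correct
      favorable[t] <- fav
      r <- if (v_idx[t] == 1L) (if (fav) 1L else 0L) else (if (fav) 0L else -1L)
      outcome[t] <- r
      if (r == -1L) shock_delivered[t] <- u_shock[t] < 0.5

      target <- ex$rho[v_idx[t]] * r
      q_old <- if (go) q_go[s] else q_nogo[s]
      delta <- target - q_old
      e <- ex$eps[(v_idx[t] - 1L) * 2L + if (delta >= 0) 1L else 2L]
      if (go) q_go[s] <- q_old + e * delta else q_nogo[s] <- q_old + e * delta
      delta_v <- target - v[s]
      ev <- ex$eps[(v_idx[t] - 1L) * 2L + if (delta_v >= 0) 1L else 2L]
      v[s] <- v[s] + ev * delta_v
    }
    out <- schedule
    out$action <- action
    out$outcome <- outcome
    out$favorable <- favorable
    out$shock_delivered <- shock_delivered
    out
  })
}

#' Simulate a cohort with ground truth and covariates
#'
#' Composes \code{\link{sample_subjects}}, \code{\link{build_schedule}} (one
#' independently shuffled schedule per subject, emulating the randomization
#' of cue-image mappings across participants) and
#' \code{\link{simulate_subject}}. A covariate table is attached containing a
#' synthetic regional "activation" generated as
#' \code{activation = alpha * z(parameter) + noise} for mediation testing,
#' plus sex (Bernoulli 34/82), age (normal, 35.9 +/- 11.2 years) and the
#' subject's total count of delivered shocks.
#'
#' @param prior A \code{plgt_prior} (generating population).
#' @param spec A \code{plgt_model_spec}.
#' @param n_subjects,n_per_cue,n_runs Cohort design; the emulated study used
#'   82 subjects, 50 trials per cue image, 4 runs.
#' @param seed Integer seed; all stages draw from substreams derived from it.
#' @param activation_alpha Slope linking the (z-scored, unconstrained)
#'   activation parameter to the synthetic activation variable.
#' @param activation_sd Noise standard deviation of the activation variable.
#' @param activation_param Which parameter drives activation (default: the
#'   model's first learning rate).
#' @return An object of class \code{plgt_cohort}: list with \code{trials}
#'   (all subjects' rows), \code{truth} (long table of generating
#'   parameters, natural and unconstrained), \code{covariates}, \code{spec},
#'   \code{prior}, and the design settings.
#' @export
simulate_cohort <- function(prior, spec, n_subjects = 82, n_per_cue = 50,
                            n_runs = 4, seed = 1,
                            activation_alpha = 0.5, activation_sd = 1,
                            activation_param = param_names(spec)[1]) {
  subjects <- sample_subjects(prior, n_subjects, substream_seed(seed, "agents"),
                              spec)
  trials <- vector("list", n_subjects)
  shocks <- integer(n_subjects)
  for (i in seq_len(n_subjects)) {
    sched <- build_schedule(n_per_cue, n_runs,
                            substream_seed(seed, "schedule", i))
    tr <- simulate_subject(subjects$natural[i, ], spec, sched,
                           substream_seed(seed, "feedback", i))
    tr <- cbind(subject_id = i, tr)
    shocks[i] <- sum(tr$shock_delivered, na.rm = TRUE)
    trials[[i]] <- tr
  }
  trials <- do.call(rbind, trials)

  covariates <- with_seed(substream_seed(seed, "covariates"), {
    m <- subjects$unconstrained[, activation_param]
    z <- if (sd(m) > 0) (m - mean(m)) / sd(m) else m * 0
    data.frame(
      subject_id = seq_len(n_subjects),
      activation = activation_alpha * z + rnorm(n_subjects, 0, activation_sd),
      sex = rbinom(n_subjects, 1, 34 / 82),
      age = rnorm(n_subjects, 35.9, 11.2),
      total_shocks = shocks
    )
  })

  truth <- data.frame(
    subject_id = rep(seq_len(n_subjects), times = ncol(subjects$natural)),
    parameter = rep(colnames(subjects$natural), each = n_subjects),
    value = as.vector(subjects$natural),
    unconstrained = as.vector(subjects$unconstrained)
  )
  structure(
    list(trials = trials, truth = truth, covariates = covariates,
         spec = spec, prior = prior,
         design = list(n_subjects = n_subjects, n_per_cue = n_per_cue,
                       n_runs = n_runs, seed = seed)),
    class = "plgt_cohort"
  )
}

#' @export
print.plgt_cohort <- function(x, ...) {
  cat("<plgt cohort> ", x$design$n_subjects, " subjects x ",
      8L * x$design$n_per_cue, " trials (", x$design$n_runs, " runs), model ",
      x$spec$label, "\n", sep = "")
  invisible(x)
}

# Split a multi-subject trial table into an ordered per-subject list.
split_subjects <- function(trials) {
  ids <- unique(trials$subject_id)
  out <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    tr[order(tr$run, tr$trial), , drop = FALSE]
  })
  setNames(out, ids)
}
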