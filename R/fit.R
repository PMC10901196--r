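# Hierarchical type-II maximum likelihood. Each subject's free parameters
# are random effects drawn from independent normal population distributions
# on the unconstrained scale. The E-step finds each subject's MAP mode and
# local curvature (Laplace approximation); the M-step updates the population
# mean and variance from the moments of the approximate posteriors; models
# are compared by the integrated BIC, whose group marginal likelihood is
# estimated by Monte Carlo draws from the fitted population distributions.

neg_log_posterior <- function(theta, enc, spec, prior_mean, prior_sd, nm) {
  names(theta) <- nm
  nat <- to_natural(theta, spec)
  ll <- sequence_loglik_draws(enc, matrix(nat, 1L, dimnames = list(NULL, nm)), spec)
  lp <- sum(dnorm(theta, prior_mean, prior_sd, log = TRUE))
  out <- -(ll + lp)
  if (!is.finite(out)) out <- 1e10
  out
}

# Which dense kernel slots (eps 1..4, rho 5..6, b 7, pi 8) each free
# parameter feeds; used to fold the dense gradient back onto the model's
# free parameters.
dense_slot_map <- function(spec) {
  eps_map <- switch(spec$eps,
    single = list(eps = 1:4),
    sign = list(eps_P = c(1L, 3L), eps_N = c(2L, 4L)),
    valence = list(eps_W = 1:2, eps_A = 3:4),
    valence_sign = list(eps_WP = 1L, eps_WN = 2L, eps_AP = 3L, eps_AN = 4L))
  rho_map <- switch(spec$rho,
    single = list(rho = 5:6),
    valence = list(rho_W = 5L, rho_A = 6L))
  c(eps_map, rho_map,
    if (spec$bias) list(b = 7L),
    if (spec$pavlovian) list(pi = 8L))
}

# Gradient of the negative log posterior on the unconstrained scale:
# analytic data gradient from the compiled kernel, chain-ruled through the
# logistic/exp transforms, plus the Gaussian prior term.
neg_log_posterior_grad <- function(theta, enc, spec, prior_mean, prior_sd, nm,
                                   slot_map) {
  names(theta) <- nm
  nat <- to_natural(theta, spec)
  ex <- expand_params(nat, spec)
  res <- seq_loglik_grad_cpp(enc$image, enc$valence, enc$action, enc$outcome,
                             ex$eps, ex$rho, ex$b, ex$pi, enc$n_images)
  g12 <- res$grad
  g <- numeric(length(nm))
  for (j in seq_along(nm)) {
    slots <- slot_map[[nm[j]]]
    x <- nat[[nm[j]]]
    jac <- if (startsWith(nm[j], "eps")) x * (1 - x)
           else if (startsWith(nm[j], "rho")) x
           else 1
    g[j] <- sum(g12[slots]) * jac
  }
  -g + (theta - prior_mean) / prior_sd^2
}

# Full central finite-difference Hessian (step h per coordinate).
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- numeric(d); ej[j] <- h
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h^2)
      }
    }
  }
  H
}

# Laplace approximation to the log marginal likelihood from a negative
# log-posterior objective and its mode: log p(mode) + d/2 log(2 pi)
# - 1/2 log det(H), with H the Hessian of the negative log posterior.
# Exact whenever the log posterior is quadratic.
laplace_evidence <- function(obj, mode, hessian_step = 1e-3, grad = NULL) {
  H <- if (is.null(grad)) {
    fd_hessian(obj, mode, h = hessian_step)
  } else {
    # central differences of the analytic gradient, symmetrized
    d <- length(mode)
    Hg <- matrix(0, d, d)
    for (i in seq_len(d)) {
      ei <- numeric(d); ei[i] <- hessian_step
      Hg[, i] <- (grad(mode + ei) - grad(mode - ei)) / (2 * hessian_step)
    }
    (Hg + t(Hg)) / 2
  }
  ch <- safe_chol(H)
  R <- ch$chol
  d <- length(mode)
  list(
    log_evidence = -obj(mode) + d / 2 * log(2 * pi) - sum(log(diag(R))),
    hessian = H, chol = R, ridge = ch$ridge,
    post_var = diag(chol2inv(R))
  )
}

# Cholesky of H, regularizing by a growing ridge if H is not positive
# definite; returns list(chol, ridge).
safe_chol <- function(H) {
  ridge <- 0
  for (k in 0:6) {
    R <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
    if (!is.null(R)) return(list(chol = R, ridge = ridge))
    ridge <- if (ridge == 0) 1e-6 else ridge * 10
  }
  stop("Hessian could not be regularized to positive definite", call. = FALSE)
}

#' MAP fit of one subject under a population prior
#'
#' Maximizes \code{log p(trials | theta) + log N(theta; mu, sigma^2)} over
#' the unconstrained parameter vector by quasi-Newton (BFGS) from several
#' seeded starts: the prior mean, \code{n_restarts} prior draws, and any
#' supplied warm starts. The curvature at the accepted mode gives the Laplace
#' approximation to the subject's marginal-likelihood contribution
#' \code{log p(trials | mu, sigma^2) ~ log p(mode) + d/2 log(2 pi)
#' - 1/2 log det(-H)}.
#'
#' @param trials One subject's ordered trials.
#' @param prior A \code{plgt_prior} on the unconstrained scale.
#' @param spec A \code{plgt_model_spec}.
#' @param n_restarts Number of random (prior-draw) restarts in addition to
#'   the prior-mean start.
#' @param seed Integer seed for the restart draws.
#' @param starts Optional matrix of extra unconstrained start points (rows).
#' @param reltol Relative convergence tolerance passed to the optimizer.
#' @param hessian_step Central-difference step for the numerical Hessian.
#' @return List with \code{mode} (unconstrained, named), \code{natural},
#'   \code{hessian} (of the negative log posterior), \code{post_var}
#'   (diagonal of its inverse), \code{log_post} (at the mode),
#'   \code{log_evidence} (Laplace), \code{converged}, \code{ridge}
#'   (regularization added to reach positive definiteness, 0 if none).
#' @export
map_fit <- function(trials, prior, spec, n_restarts = 4, seed = 1,
                    starts = NULL, reltol = 1e-8, hessian_step = 1e-3) {
  enc <- if (is.list(trials) && !is.data.frame(trials)) trials else encode_trials(trials)
  map_fit_enc(enc, prior, spec, n_restarts, seed, starts, reltol, hessian_step)
}

map_fit_enc <- function(enc, prior, spec, n_restarts = 4, seed = 1,
                        starts = NULL, reltol = 1e-8, hessian_step = 1e-3) {
  nm <- param_names(spec)
  mu <- prior$mean[nm]
  sdv <- sqrt(prior$var[nm])
  slot_map <- dense_slot_map(spec)
  obj <- function(theta) neg_log_posterior(theta, enc, spec, mu, sdv, nm)
  gr <- function(theta) neg_log_posterior_grad(theta, enc, spec, mu, sdv, nm,
                                               slot_map)

  start_list <- list(mu)
  if (n_restarts > 0) {
    draws <- with_seed(seed, {
      matrix(rnorm(n_restarts * length(nm), rep(mu, each = n_restarts),
                   rep(sdv, each = n_restarts)), nrow = n_restarts)
    })
    for (i in seq_len(n_restarts)) start_list <- c(start_list, list(draws[i, ]))
  }
  if (!is.null(starts)) {
    starts <- rbind(starts)
    for (i in seq_len(nrow(starts))) start_list <- c(start_list, list(starts[i, ]))
  }

  best <- NULL
  any_conv <- FALSE
  for (s0 in start_list) {
    fit <- tryCatch(
      optim(s0, obj, gr, method = "BFGS",
            control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("all optimizer starts failed for this subject", call. = FALSE)
  }

  mode <- setNames(best$par, nm)
  lap <- laplace_evidence(obj, mode, hessian_step = hessian_step, grad = gr)
  if (lap$ridge > 0) {
    # non-PD curvature: retry once from a slightly perturbed mode
    fit2 <- tryCatch(
      optim(mode + 1e-2 * sdv, obj, gr, method = "BFGS",
            control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(fit2) && is.finite(fit2$value) && fit2$value < best$value) {
      best <- fit2
      mode <- setNames(best$par, nm)
      lap <- laplace_evidence(obj, mode, hessian_step = hessian_step, grad = gr)
    }
  }
  list(
    mode = mode,
    natural = to_natural(mode, spec),
    hessian = lap$hessian,
    post_var = setNames(lap$post_var, nm),
    log_post = -best$value,
    log_evidence = lap$log_evidence,
    converged = any_conv,
    ridge = lap$ridge
  )
}

#' Hierarchical EM fit of a cohort
#'
#' Alternates an E-step (per-subject MAP fit and Laplace curvature under the
#' current population prior) with an M-step that re-estimates each
#' parameter's population mean as the mean of the subject modes and its
#' variance as \code{mean(mode^2 + posterior variance) - mean(mode)^2}
#' (moment matching of the approximate posteriors), until the total Laplace
#' evidence changes by less than \code{tol} or \code{max_iter} is reached.
#' After the first iteration each subject's optimizer is warm-started from
#' its previous mode, with random restarts only in the first sweep.
#'
#' @param data A \code{plgt_cohort} or a multi-subject trial data frame.
#' @param spec A \code{plgt_model_spec}.
#' @param prior_init Optional starting \code{plgt_prior}; by default a broad
#'   prior centered at 0 on the unconstrained scale (sd 1.5).
#' @param tol Absolute change in total evidence declaring convergence.
#' @param max_iter Maximum EM sweeps.
#' @param n_restarts Random restarts per subject in the first sweep.
#' @param seed Integer seed (restart draws).
#' @param var_floor Lower bound for population variances.
#' @param reltol Optimizer relative tolerance (per subject).
#' @param verbose Print per-iteration evidence?
#' @return An object of class \code{plgt_fit}: the final prior, per-subject
#'   posteriors (modes, curvatures, evidences), natural-space estimates, the
#'   total approximate log marginal likelihood, the EM trace, and a
#'   convergence flag.
#' @export
em_fit <- function(data, spec, prior_init = NULL, tol = 1e-3, max_iter = 200,
                   n_restarts = 4, seed = 1, var_floor = 1e-6,
                   reltol = 1e-8, verbose = FALSE) {
  trials <- if (inherits(data, "plgt_cohort")) data$trials else data
  subj <- split_subjects(trials)
  n_subj <- length(subj)
  if (n_subj < 2L) stop("hierarchical fitting needs at least 2 subjects", call. = FALSE)
  encs <- lapply(subj, encode_trials)
  nm <- param_names(spec)
  d <- length(nm)

  prior <- if (is.null(prior_init)) {
    population_prior(setNames(rep(0, d), nm), setNames(rep(1.5^2, d), nm))
  } else {
    prior_init
  }
  stopifnot(identical(sort(names(prior$mean)), sort(nm)))

  modes <- matrix(NA_real_, n_subj, d, dimnames = list(names(subj), nm))
  trace <- data.frame(iter = integer(), evidence = numeric(),
                      max_mu_change = numeric(), max_var = numeric())
  posteriors <- vector("list", n_subj)
  prev_evidence <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    total <- 0
    vpost <- matrix(NA_real_, n_subj, d)
    for (i in seq_len(n_subj)) {
      warm <- if (iter > 1L) matrix(modes[i, ], 1L) else NULL
      fit <- map_fit_enc(encs[[i]], prior, spec,
                         n_restarts = if (iter == 1L) n_restarts else 0L,
                         seed = substream_seed(seed, "restarts", i),
                         starts = warm, reltol = reltol)
      posteriors[[i]] <- fit
      modes[i, ] <- fit$mode
      vpost[i, ] <- fit$post_var
      total <- total + fit$log_evidence
    }
    mu_new <- colMeans(modes)
    var_new <- pmax(colMeans(modes^2 + vpost) - mu_new^2, var_floor)
    trace <- rbind(trace, data.frame(
      iter = iter, evidence = total,
      max_mu_change = max(abs(mu_new - prior$mean[nm])),
      max_var = max(var_new)))
    if (verbose) {
      message(sprintf("EM iter %d: evidence %.4f", iter, total))
    }
    prior <- population_prior(setNames(mu_new, nm), setNames(var_new, nm))
    if (abs(total - prev_evidence) < tol) {
      converged <- TRUE
      break
    }
    prev_evidence <- total
  }

  estimates <- to_natural(modes, spec)
  structure(
    list(spec = spec, prior = prior, posteriors = posteriors,
         modes = modes, estimates = estimates,
         log_evidence = total, trace = trace, converged = converged,
         n_subjects = n_subj, n_obs = sum(vapply(encs, function(e) length(e$image), 1L)),
         subject_ids = names(subj)),
    class = "plgt_fit"
  )
}

#' @export
print.plgt_fit <- function(x, ...) {
  cat("<plgt hierarchical fit> model ", x$spec$label, "\n", sep = "")
  cat("  ", x$n_subjects, " subjects, ", x$n_obs, " choices; ",
      nrow(x$trace), " EM iterations (",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("  total Laplace log evidence: ", format(x$log_evidence, digits = 8),
      "\n", sep = "")
  print(data.frame(mu = x$prior$mean, sigma = sqrt(x$prior$var)))
  invisible(x)
}

#' Integrated BIC of a fitted model
#'
#' Estimates each subject's marginal likelihood by Monte Carlo: \code{n_mc}
#' parameter vectors are drawn from the fitted population distributions, the
#' data likelihood is evaluated at each, and the draws are averaged (on the
#' likelihood scale, computed via log-sum-exp). The group log marginal
#' likelihood is the sum over subjects, and the iBIC adds a complexity cost
#' of \code{k log(N)} with \code{k} the number of population-level parameters
#' (a mean and a variance per free parameter) and \code{N} the total number
#' of choices. Smaller is better.
#'
#' @param fit A \code{plgt_fit}.
#' @param data The cohort (or trial data frame) the model was fitted to.
#' @param n_mc Monte-Carlo draws per subject.
#' @param seed Integer seed.
#' @return An object of class \code{plgt_ibic}: list with \code{ibic},
#'   \code{log_marginal}, \code{penalty}, \code{k}, \code{n_obs},
#'   \code{mc_se} (Monte-Carlo standard error of \code{ibic}), \code{n_mc}.
#' @export
ibic <- function(fit, data, n_mc = 1000, seed = 1) {
  stopifnot(inherits(fit, "plgt_fit"), n_mc >= 1)
  trials <- if (inherits(data, "plgt_cohort")) data$trials else data
  subj <- split_subjects(trials)
  spec <- fit$spec
  nm <- param_names(spec)
  mu <- fit$prior$mean[nm]
  sdv <- sqrt(fit$prior$var[nm])
  d <- length(nm)

  log_marg <- 0
  var_sum <- 0
  n_obs <- 0L
  for (i in seq_along(subj)) {
    enc <- encode_trials(subj[[i]])
    n_obs <- n_obs + length(enc$image)
    theta <- with_seed(substream_seed(seed, "mc", i), {
      matrix(rnorm(n_mc * d, rep(mu, each = n_mc), rep(sdv, each = n_mc)),
             nrow = n_mc, dimnames = list(NULL, nm))
    })
    ll <- sequence_loglik_draws(enc, to_natural(theta, spec), spec)
    m <- max(ll)
    w <- exp(ll - m)
    log_marg <- log_marg + m + log(mean(w))
    # delta-method se of log mean(w)
    var_sum <- var_sum + var(w) / (n_mc * mean(w)^2)
  }
  k <- 2L * d
  penalty <- k * log(n_obs)
  structure(
    list(ibic = -2 * log_marg + penalty, log_marginal = log_marg,
         penalty = penalty, k = k, n_obs = n_obs,
         mc_se = 2 * sqrt(var_sum), n_mc = n_mc),
    class = "plgt_ibic"
  )
}

#' @export
print.plgt_ibic <- function(x, ...) {
  cat("<iBIC> ", format(x$ibic, digits = 8), "  (log marginal ",
      format(x$log_marginal, digits = 8), ", penalty ",
      format(x$penalty, digits = 6), ", MC se ",
      format(x$mc_se, digits = 3), ", n_mc ", x$n_mc, ")\n", sep = "")
  invisible(x)
}

# Single-parameter-step expansions of a model spec: add the Pavlovian
# factor, add the bias, refine the learning-rate structure one level
# (single -> sign or valence; sign/valence -> valence_sign), or split the
# outcome impact by valence.
candidate_expansions <- function(spec) {
  out <- list()
  if (!spec$pavlovian) {
    out <- c(out, list(model_spec(spec$eps, spec$rho, spec$bias, TRUE)))
  }
  if (!spec$bias) {
    out <- c(out, list(model_spec(spec$eps, spec$rho, TRUE, spec$pavlovian)))
  }
  eps_next <- switch(spec$eps,
    single = c("sign", "valence_sign"),
    sign = "valence_sign",
    valence = "valence_sign",
    valence_sign = character())
  for (e in eps_next) {
    out <- c(out, list(model_spec(e, spec$rho, spec$bias, spec$pavlovian)))
  }
  if (spec$rho == "single") {
    out <- c(out, list(model_spec(spec$eps, "valence", spec$bias, spec$pavlovian)))
  }
  out
}

#' Greedy stepwise model selection by iBIC
#'
#' Starts from the base model (one learning rate, one outcome impact) and at
#' each step fits every admissible single-parameter expansion (add the
#' Pavlovian factor, add the action bias, split the learning rate by
#' prediction-error sign and/or valence, split the outcome impact by
#' valence), accepts the expansion that lowers the iBIC the most, and stops
#' when no expansion lowers it.
#'
#' @param data A \code{plgt_cohort} or multi-subject trial data frame.
#' @param seed Integer seed governing restarts and Monte-Carlo draws.
#' @param n_mc Monte-Carlo draws per subject for each iBIC.
#' @param start_spec Starting model (default: the 2-parameter base model).
#' @param ... Passed to \code{\link{em_fit}} (tolerances, iteration caps).
#' @param verbose Print progress?
#' @return An object of class \code{plgt_selection}: \code{path} (one row
#'   per evaluated model: step, label, n_free, ibic, accepted), the winning
#'   \code{best_spec}, its \code{best_fit} and \code{best_ibic}.
#' @export
stepwise_select <- function(data, seed = 1, n_mc = 1000,
                            start_spec = model_spec("single", "single"),
                            ..., verbose = FALSE) {
  trials <- if (inherits(data, "plgt_cohort")) data$trials else data
  cache <- new.env(parent = emptyenv())
  score <- function(spec) {
    key <- spec$label
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- em_fit(trials, spec, seed = substream_seed(seed, key), ...)
    ib <- ibic(fit, trials, n_mc = n_mc, seed = substream_seed(seed, paste0("mc_", key)))
    cache[[key]] <- list(fit = fit, ibic = ib)
    cache[[key]]
  }

  current <- start_spec
  cur <- score(current)
  path <- data.frame(step = 0L, model = current$label,
                     n_free = n_free_params(current), ibic = cur$ibic$ibic,
                     accepted = TRUE, stringsAsFactors = FALSE)
  if (verbose) message(sprintf("step 0: %s iBIC %.2f", current$label, cur$ibic$ibic))

  step <- 0L
  repeat {
    step <- step + 1L
    cands <- candidate_expansions(current)
    if (!length(cands)) break
    scores <- lapply(cands, score)
    ibics <- vapply(scores, function(s) s$ibic$ibic, 0)
    best_j <- which.min(ibics)
    accept <- ibics[best_j] < cur$ibic$ibic
    for (j in seq_along(cands)) {
      path <- rbind(path, data.frame(
        step = step, model = cands[[j]]$label,
        n_free = n_free_params(cands[[j]]), ibic = ibics[j],
        accepted = accept && j == best_j, stringsAsFactors = FALSE))
    }
    if (verbose) {
      message(sprintf("step %d: best candidate %s iBIC %.2f (%s)", step,
                      cands[[best_j]]$label, ibics[best_j],
                      if (accept) "accepted" else "rejected"))
    }
    if (!accept) break
    current <- cands[[best_j]]
    cur <- scores[[best_j]]
  }

  structure(
    list(path = path, best_spec = current, best_fit = cur$fit,
         best_ibic = cur$ibic),
    class = "plgt_selection"
  )
}

#' @export
print.plgt_selection <- function(x, ...) {
  cat("<plgt stepwise selection> winner: ", x$best_spec$label,
      " (iBIC ", format(x$best_ibic$ibic, digits = 8), ")\n", sep = "")
  print(x$path, row.names = FALSE)
  invisible(x)
}
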