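test_that("Laplace evidence is exact for conjugate Gaussian toys", {
  # 1 parameter: y | theta ~ N(theta, sy^2), theta ~ N(m0, s0^2);
  # marginal is N(y; m0, sy^2 + s0^2) in closed form
  y <- 1.3; sy <- 0.7; m0 <- -0.4; s0 <- 1.2
  obj <- function(th) {
    -dnorm(y, th[1], sy, log = TRUE) - dnorm(th[1], m0, s0, log = TRUE)
  }
  mode <- (y / sy^2 + m0 / s0^2) / (1 / sy^2 + 1 / s0^2)
  lap <- plgt:::laplace_evidence(obj, mode)
  expect_equal(lap$log_evidence, dnorm(y, m0, sqrt(sy^2 + s0^2), log = TRUE),
               tolerance = 1e-8)
  expect_equal(lap$ridge, 0)

  # 2 independent parameters: evidences add
  y2 <- c(0.5, -2); sy2 <- c(1, 0.5); m02 <- c(0, 1); s02 <- c(2, 0.8)
  obj2 <- function(th) {
    -sum(dnorm(y2, th, sy2, log = TRUE)) - sum(dnorm(th, m02, s02, log = TRUE))
  }
  mode2 <- (y2 / sy2^2 + m02 / s02^2) / (1 / sy2^2 + 1 / s02^2)
  lap2 <- plgt:::laplace_evidence(obj2, mode2)
  expect_equal(lap2$log_evidence,
               sum(dnorm(y2, m02, sqrt(sy2^2 + s02^2), log = TRUE)),
               tolerance = 1e-8)
})

test_that("MAP fitting: prior dominates flat likelihoods, data pull grows with prior width", {
  spec <- base_spec()
  prior <- default_prior(spec)

  # 8 first-encounter trials: the likelihood is constant in theta, so the
  # posterior mode is the prior mean and the evidence is 8 log(1/2)
  tr <- random_trials(40, seed = 51)
  first8 <- tr[!duplicated(tr$image), ]
  first8$trial <- seq_len(nrow(first8))
  fit <- map_fit(first8, prior, spec, n_restarts = 2, seed = 1)
  expect_equal(unname(fit$mode), unname(prior$mean), tolerance = 1e-4)
  expect_equal(fit$log_evidence, nrow(first8) * log(0.5), tolerance = 1e-6)

  # informative data: the mode leaves the prior mean monotonically as the
  # prior widens, toward the (fixed) maximum-likelihood estimate
  sched <- build_schedule(50, 2, seed = 52)
  truth <- c(eps = 0.45, rho = 2.5)
  trs <- simulate_subject(truth, spec, sched, seed = 53)
  mu0 <- c(eps = qlogis(0.15), rho = log(0.8))
  dist <- vapply(c(0.05, 0.5, 5, 50), function(v) {
    f <- map_fit(trs, population_prior(mu0, c(eps = v, rho = v)), spec,
                 n_restarts = 2, seed = 2)
    sqrt(sum((f$mode - mu0)^2))
  }, 0)
  expect_true(all(diff(dist) > 0))
  # widest prior: essentially the MLE, close to the generating values
  f_wide <- map_fit(trs, population_prior(mu0, c(eps = 100, rho = 100)), spec,
                    n_restarts = 2, seed = 3)
  expect_lt(abs(f_wide$natural[["eps"]] - truth[["eps"]]), 0.2)
  expect_lt(abs(f_wide$natural[["rho"]] - truth[["rho"]]), 0.8)
})

test_that("EM shrinks the population variance on a homogeneous cohort", {
  spec <- base_spec()
  sched <- build_schedule(25, 1, seed = 61)
  one <- simulate_subject(c(eps = 0.3, rho = 2), spec, sched, seed = 62)
  trials <- do.call(rbind, lapply(1:6, function(i) cbind(subject_id = i, one)))
  fit <- em_fit(trials, spec, seed = 4, max_iter = 25, n_restarts = 1)
  v <- fit$trace$max_var
  expect_true(all(diff(v) < 1e-8))
  expect_lt(v[length(v)], v[1] / 10)
})

test_that("EM evidence is non-decreasing and refitting at the fixed point stops at once", {
  spec <- base_spec()
  co <- simulate_cohort(default_prior(spec), spec, n_subjects = 10,
                        n_per_cue = 15, n_runs = 1, seed = 63)
  fit <- em_fit(co$trials, spec, seed = 5)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace$evidence) > -0.05))

  refit <- em_fit(co$trials, spec, prior_init = fit$prior, seed = 5,
                  n_restarts = 0)
  expect_lte(nrow(refit$trace), 3L)
  expect_lt(max(abs(refit$prior$mean - fit$prior$mean)), 0.05)
})

test_that("hierarchical estimates track subject-level truth on a base-model cohort", {
  spec <- base_spec()
  co <- simulate_cohort(default_prior(spec), spec, n_subjects = 14,
                        n_per_cue = 50, n_runs = 2, seed = 64)
  fit <- em_fit(co$trials, spec, seed = 6)
  truth <- co$truth
  for (p in c("eps", "rho")) {
    tv <- truth$unconstrained[truth$parameter == p]
    ev <- fit$modes[, p]
    expect_gt(cor(tv, ev), 0.5)
  }
})

test_that("the MC marginal collapses to the plug-in likelihood for a point-mass prior", {
  spec <- base_spec()
  tr <- random_trials(30, seed = 71)
  mu <- c(eps = qlogis(0.35), rho = log(1.4))
  fit <- structure(list(
    spec = spec,
    prior = population_prior(mu, c(eps = 1e-14, rho = 1e-14))
  ), class = "plgt_fit")
  ib <- ibic(fit, tr, n_mc = 200, seed = 7)
  plug_in <- sequence_loglik(tr, to_natural(mu, spec), spec)
  expect_equal(ib$log_marginal, plug_in, tolerance = 1e-6)
  expect_equal(ib$ibic, -2 * plug_in + 4 * log(30), tolerance = 1e-6)
  expect_gt(ib$penalty, 0)
})

test_that("a free parameter with no likelihood contribution costs exactly the penalty", {
  spec0 <- base_spec()
  spec1 <- model_spec("single", "single", bias = TRUE)
  tr <- rbind(cbind_subject(random_trials(40, seed = 72), 1L),
              cbind_subject(random_trials(40, seed = 73), 2L))
  mu <- c(eps = qlogis(0.25), rho = log(1.5))
  prior0 <- population_prior(mu, c(eps = 0.2, rho = 0.2))
  # same population distribution, plus a bias pinned at zero
  prior1 <- population_prior(c(mu, b = 0), c(eps = 0.2, rho = 0.2, b = 1e-14))
  f0 <- structure(list(spec = spec0, prior = prior0), class = "plgt_fit")
  f1 <- structure(list(spec = spec1, prior = prior1), class = "plgt_fit")
  ib0 <- ibic(f0, tr, n_mc = 4000, seed = 8)
  ib1 <- ibic(f1, tr, n_mc = 4000, seed = 8)
  expect_equal(ib1$penalty - ib0$penalty, 2 * log(80))
  expect_gt(ib1$ibic, ib0$ibic)
  expect_equal(ib1$ibic - ib0$ibic, 2 * log(80),
               tolerance = 3 * sqrt(ib0$mc_se^2 + ib1$mc_se^2))
})

test_that("stepwise selection records a valid greedy path", {
  spec <- base_spec()
  co <- simulate_cohort(default_prior(spec), spec, n_subjects = 8,
                        n_per_cue = 10, n_runs = 1, seed = 81)
  sel <- stepwise_select(co$trials, seed = 9, n_mc = 400, max_iter = 30)
  path <- sel$path
  expect_equal(path$model[1], "eps+rho")
  expect_true(path$accepted[1])
  acc <- path[path$accepted, ]
  expect_true(all(diff(acc$ibic) < 0))      # each accepted step lowers iBIC
  expect_lte(nrow(path), 14L)
  expect_equal(sel$best_spec$label, acc$model[nrow(acc)])
  # every evaluated candidate differs from its predecessor by one structure move
  expect_true(all(table(path$model) == 1L))
})
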