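test_that("action weights and softmax match closed forms", {
  spec <- model_spec("single", "single", bias = TRUE, pavlovian = TRUE)
  p0 <- c(eps = 0.2, rho = 2, b = 0, pi = 0)

  st <- agent_state()
  expect_identical(action_weights(st, 1, p0, spec)$p_go, 0.5)

  st$q_go[3] <- 1
  aw <- action_weights(st, 3, p0, spec)
  expect_equal(aw$p_go, 1 / (1 + exp(-1)), tolerance = 1e-10)

  # Pavlovian pull: negative stimulus value suppresses go
  st2 <- agent_state()
  st2$v[2] <- -1
  aw2 <- action_weights(st2, 2, c(eps = 0.2, rho = 2, b = 0, pi = 0.5), spec)
  expect_equal(aw2$w_go, -0.5, tolerance = 1e-12)
  expect_equal(aw2$p_go, 1 / (1 + exp(0.5)), tolerance = 1e-10)

  # probabilities are complementary and lie strictly inside (0, 1)
  for (q in c(-30, -1, 0, 2, 30)) {
    sts <- agent_state(); sts$q_go[1] <- q
    p <- action_weights(sts, 1, p0, spec)$p_go
    expect_true(p > 0 && p < 1)
  }
})

test_that("softmax is shift-invariant and monotone in bias and pavlovian drive", {
  spec <- model_spec("single", "single", bias = TRUE, pavlovian = TRUE)
  base_p <- function(qg, qn, b = 0, v = 0, pav = 0) {
    st <- agent_state(); st$q_go[1] <- qg; st$q_nogo[1] <- qn; st$v[1] <- v
    action_weights(st, 1, c(eps = 0.2, rho = 2, b = b, pi = pav), spec)$p_go
  }
  # adding the same constant to both action values changes nothing
  for (shift in c(-5, 0.3, 12)) {
    expect_equal(base_p(1.2 + shift, -0.4 + shift), base_p(1.2, -0.4),
                 tolerance = 1e-12)
  }
  # p(go) strictly increasing in b and in pi * V
  bs <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(vapply(bs, function(b) base_p(0.2, 0.1, b = b), 0)) > 0))
  pis <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(vapply(pis, function(w) base_p(0, 0, v = 1, pav = w), 0)) > 0))
  expect_true(all(diff(vapply(pis, function(w) base_p(0, 0, v = -1, pav = w), 0)) < 0))
})

test_that("value updates follow the delta rule exactly", {
  spec <- base_spec()
  p <- c(eps = 0.5, rho = 1)
  st <- agent_state()

  up <- apply_update(st, 1, "win", "go", 1, p, spec)
  expect_equal(up$delta, 1)
  expect_equal(up$q, 0.5)
  expect_equal(up$state$q_nogo[1], 0)   # unchosen action untouched

  # zero outcome from zero value: no update for any eps, rho
  for (pp in list(c(eps = 0.1, rho = 3), c(eps = 0.9, rho = 0.2))) {
    up0 <- apply_update(agent_state(), 4, "avoid", "nogo", 0, pp, spec)
    expect_equal(up0$delta, 0)
    expect_equal(up0$q, 0)
  }

  # k-step geometric closed form Q_k = rho * r * (1 - (1 - eps)^k)
  st <- agent_state()
  for (k in 1:3) st <- apply_update(st, 1, "win", "go", 1, p, spec)$state
  expect_equal(st$q_go[1], 1 - 0.5^3, tolerance = 1e-12)
  st2 <- agent_state()
  p2 <- c(eps = 0.3, rho = 2)
  for (k in 1:7) st2 <- apply_update(st2, 2, "avoid", "go", -1, p2, spec)$state
  expect_equal(st2$q_go[2], -2 * (1 - 0.7^7), tolerance = 1e-12)

  expect_error(apply_update(agent_state(), 1, "win", "go", 2, p, spec),
               "-1, 0 or \\+1")
})

test_that("learning-rate lookup respects valence and PE sign", {
  spec <- full_spec()
  p <- c(eps_WP = 0.1, eps_WN = 0.2, eps_AP = 0.3, eps_AN = 0.4,
         rho_W = 1, rho_A = 2, b = 0, pi = 0)
  up <- apply_update(agent_state(), 1, "win", "go", 1, p, spec)
  expect_equal(up$eps_used, 0.1)      # win, positive PE
  up <- apply_update(up$state, 1, "win", "go", 0, p, spec)
  expect_equal(up$eps_used, 0.2)      # win, negative PE (0 - Q < 0)
  up <- apply_update(agent_state(), 5, "avoid", "go", 0, p, spec)
  expect_equal(up$eps_used, 0.3)      # avoid, delta = 0 ties to positive
  up <- apply_update(agent_state(), 5, "avoid", "go", -1, p, spec)
  expect_equal(up$eps_used, 0.4)      # avoid, negative PE
})

test_that("sequence log-likelihood matches trivial closed forms", {
  spec <- base_spec()
  # first encounters with all 8 cues are coin flips when b = pi = 0
  tr <- random_trials(40, seed = 1)
  first8 <- tr[!duplicated(tr$image), ]
  first8$trial <- seq_len(nrow(first8))
  ll <- sequence_loglik(first8, c(eps = 0.7, rho = 3), spec)
  expect_equal(ll, nrow(first8) * log(0.5), tolerance = 1e-12)

  # single trial with known weights: Q(go) = 1 after crafting one update
  spec_b <- model_spec("single", "single", bias = TRUE)
  one <- random_trials(1, seed = 2)
  one$valence <- "win"; one$required_action <- "go"; one$image_id <- 1L
  one$image <- cue_image_index("win", "go", 1L)
  one$action <- "go"; one$outcome <- 1L
  ll1 <- sequence_loglik(one, c(eps = 0.5, rho = 2, b = 1), spec_b)
  expect_equal(ll1, log(1 / (1 + exp(-1))), tolerance = 1e-10)
})

test_that("compiled likelihood equals the two-pass replay oracle", {
  specs <- list(base_spec(),
                model_spec("sign", "single", FALSE, TRUE),
                model_spec("valence", "valence", TRUE, FALSE),
                full_spec())
  for (s in 1:20) {
    n <- sample(5:40, 1)
    tr <- random_trials(n, seed = 100 + s)
    spec <- specs[[(s %% length(specs)) + 1L]]
    set.seed(200 + s)
    theta <- setNames(rnorm(n_free_params(spec)), param_names(spec))
    params <- to_natural(theta, spec)
    expect_equal(sequence_loglik(tr, params, spec),
                 loglik_two_pass(tr, params, spec), tolerance = 1e-10)
  }
})

test_that("likelihood input validation catches unordered or duplicate trials", {
  tr <- random_trials(10, seed = 3)
  p <- c(eps = 0.2, rho = 1)
  bad <- tr[c(2, 1, 3:10), ]
  expect_error(sequence_loglik(bad, p, base_spec()), "sorted")
  dup <- tr; dup$trial[2] <- 1L
  expect_error(sequence_loglik(dup, p, base_spec()), "sorted|duplicated")
  out <- tr; out$outcome[5] <- 2L
  expect_error(sequence_loglik(out, p, base_spec()), "-1, 0 or \\+1")
})

test_that("values stay inside the convex-combination bound |Q|,|V| <= rho", {
  spec <- full_spec()
  set.seed(7)
  for (rep in 1:100) {
    theta <- setNames(rnorm(8, 0, 1.5), param_names(spec))
    params <- to_natural(theta, spec)
    rho_max <- max(params[c("rho_W", "rho_A")])
    st <- agent_state()
    tr <- random_trials(100, seed = 7000 + rep)
    worst <- 0
    for (t in seq_len(nrow(tr))) {
      st <- apply_update(st, tr$image[t], tr$valence[t], tr$action[t],
                         tr$outcome[t], params, spec)$state
      worst <- max(worst, abs(c(st$q_go, st$q_nogo, st$v)))
    }
    expect_lte(worst, rho_max + 1e-12)
  }
})

test_that("simulated choice frequencies match the model's own probabilities", {
  spec <- model_spec("single", "single", bias = TRUE, pavlovian = TRUE)
  params <- c(eps = 0.15, rho = 2, b = 0.4, pi = 0.4)
  sched <- build_schedule(n_per_cue = 1250, n_runs = 1, seed = 9)  # 10^4 trials
  tr <- simulate_subject(params, spec, sched, seed = 10)
  rp <- plgt:::replay_sequence(tr, params, spec)
  # mean simulated go rate vs mean implied p(go): binomial error on 10^4
  se <- sqrt(sum(rp$p_go * (1 - rp$p_go))) / nrow(tr)
  expect_lt(abs(mean(tr$action == "go") - mean(rp$p_go)), 4 * se)
})
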