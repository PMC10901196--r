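# Shared fixtures and independent oracles. Everything here is deliberately
# naive/brute-force so it stays independent of the package's compiled paths.

# Trial-by-trial log-likelihood by explicit replay through the exported
# single-step operations; the independent second route checked against
# sequence_loglik().
loglik_two_pass <- function(trials, params, spec) {
  st <- agent_state()
  ll <- 0
  for (t in seq_len(nrow(trials))) {
    aw <- action_weights(st, trials$image[t], params, spec)
    p <- if (trials$action[t] == "go") aw$p_go else 1 - aw$p_go
    ll <- ll + log(p)
    st <- apply_update(st, trials$image[t], trials$valence[t],
                       trials$action[t], trials$outcome[t], params, spec)$state
  }
  ll
}

# Random but structurally valid single-subject trial sequence (not generated
# by the package's simulator: actions and outcomes are drawn arbitrarily).
random_trials <- function(n, seed) {
  set.seed(seed)
  cues <- cue_conditions()
  idx <- sample(1:8, n, replace = TRUE)
  tr <- cues[idx, ]
  tr$run <- 1L
  tr$trial <- seq_len(n)
  tr$action <- sample(c("go", "nogo"), n, replace = TRUE)
  tr$outcome <- ifelse(tr$valence == "win",
                       sample(0:1, n, replace = TRUE),
                       -sample(0:1, n, replace = TRUE))
  tr$favorable <- (tr$valence == "win" & tr$outcome == 1) |
    (tr$valence == "avoid" & tr$outcome == 0)
  tr$subject_id <- 1L
  rownames(tr) <- NULL
  tr
}

cbind_subject <- function(tr, id) {
  tr$subject_id <- id
  tr
}

# Brute-force stay/switch: for every unfavorable trial scan forward for the
# next trial with the same cue key and compare actions.
switch_scan_oracle <- function(tr, match = "image") {
  key <- if (match == "image") tr$image else tr$condition
  conds <- c("go_to_win", "nogo_to_win", "go_to_avoid", "nogo_to_avoid")
  out <- data.frame(condition = conds, switch_pct = NA_real_, n_eligible = 0L)
  for (cond in conds) {
    n_el <- 0L; n_sw <- 0L
    for (t in seq_len(nrow(tr))) {
      if (tr$favorable[t] || tr$condition[t] != cond) next
      nxt <- which(key == key[t] & seq_len(nrow(tr)) > t)
      if (!length(nxt)) next
      n_el <- n_el + 1L
      if (tr$action[min(nxt)] != tr$action[t]) n_sw <- n_sw + 1L
    }
    i <- match(cond, conds)
    out$n_eligible[i] <- n_el
    if (n_el > 0) out$switch_pct[i] <- 100 * n_sw / n_el
  }
  out
}

# Gauss-Hermite nodes/weights by Golub-Welsch (eigendecomposition of the
# Jacobi matrix), for the quadrature oracle of the Monte-Carlo marginal.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Base-model generating prior used across fixture cohorts.
base_spec <- function() model_spec("single", "single")
full_spec <- function() model_spec("valence_sign", "valence", TRUE, TRUE)
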