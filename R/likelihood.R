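# Forward model and likelihood. The exported single-step operations
# (action_weights, apply_update) define the model one trial at a time over an
# explicit agent state; sequence_loglik runs the whole sequence in compiled
# code. The two routes are intentionally independent implementations of the
# same recursion.

#' Initialize an agent's learning state
#'
#' All action values Q(go), Q(nogo) and stimulus values V start at zero for
#' every cue image, so the first encounter with any cue is a coin flip in the
#' absence of a bias or Pavlovian term.
#'
#' @param n_images Number of distinct cue images (8 in the task design).
#' @return An object of class \code{plgt_agent_state} with matrices/vectors
#'   \code{q_go}, \code{q_nogo}, \code{v}, each of length \code{n_images}.
#' @export
agent_state <- function(n_images = 8L) {
  structure(
    list(q_go = numeric(n_images), q_nogo = numeric(n_images),
         v = numeric(n_images)),
    class = "plgt_agent_state"
  )
}

#' Action weights and choice probability for one cue
#'
#' Computes the softmax inputs for the two actions: the go weight is
#' \code{Q(go) + b + pi * V(s)} (bias and Pavlovian terms only when the model
#' frees them), the no-go weight is \code{Q(nogo)}. The go probability is the
#' two-action softmax, evaluated in the log-sum-exp stabilized form.
#'
#' @param state A \code{plgt_agent_state}.
#' @param image Global cue-image index (1..n_images).
#' @param params Named natural-space parameter vector for \code{spec}.
#' @param spec A \code{plgt_model_spec}.
#' @return List with \code{w_go}, \code{w_nogo}, \code{p_go}.
#' @export
#' @examples
#' st <- agent_state()
#' sp <- model_spec("single", "single")
#' action_weights(st, 1, c(eps = 0.2, rho = 2), sp)$p_go  # 0.5 at Q = V = 0
action_weights <- function(state, image, params, spec) {
  ex <- expand_params(params, spec)
  w_go <- state$q_go[image] + ex$b + ex$pi * state$v[image]
  w_nogo <- state$q_nogo[image]
  # p_go = 1 / (1 + exp(w_nogo - w_go)), stable for extreme weights
  d <- w_nogo - w_go
  p_go <- if (d > 0) exp(-d) / (1 + exp(-d)) else 1 / (1 + exp(d))
  list(w_go = w_go, w_nogo = w_nogo, p_go = p_go)
}

#' Apply one trial's learning update
#'
#' Updates the chosen action's value by \code{eps * delta} with
#' \code{delta = rho * r - Q}, leaving the unchosen action untouched, and
#' updates the stimulus value V with the same parameters from its own
#' prediction error \code{rho * r - V}. The learning rate is looked up by the
#' trial's valence and the sign of the relevant prediction error (a zero
#' prediction error uses the positive-sign rate; with \code{delta = 0} the
#' update is a no-op anyway).
#'
#' @param state A \code{plgt_agent_state}.
#' @param image Global cue-image index.
#' @param valence "win" or "avoid".
#' @param action "go" or "nogo" (the chosen action).
#' @param outcome Displayed outcome r, one of -1, 0, +1.
#' @param params Named natural-space parameter vector.
#' @param spec A \code{plgt_model_spec}.
#' @return List with the updated \code{state}, the action-value prediction
#'   error \code{delta}, the learning rate used for it (\code{eps_used}), and
#'   the new \code{q} and \code{v}.
#' @export
apply_update <- function(state, image, valence, action, outcome, params, spec) {
  if (!outcome %in% c(-1, 0, 1)) {
    stop("`outcome` must be -1, 0 or +1", call. = FALSE)
  }
  ex <- expand_params(params, spec)
  v_idx <- if (valence == "avoid") 2L else 1L
  target <- ex$rho[v_idx] * outcome

  q_old <- if (action == "go") state$q_go[image] else state$q_nogo[image]
  delta <- target - q_old
  eps_used <- ex$eps[(v_idx - 1L) * 2L + if (delta >= 0) 1L else 2L]
  q_new <- q_old + eps_used * delta
  if (action == "go") state$q_go[image] <- q_new else state$q_nogo[image] <- q_new

  delta_v <- target - state$v[image]
  eps_v <- ex$eps[(v_idx - 1L) * 2L + if (delta_v >= 0) 1L else 2L]
  state$v[image] <- state$v[image] + eps_v * delta_v

  list(state = state, delta = delta, eps_used = eps_used,
       q = q_new, v = state$v[image])
}

# Validate and convert one subject's ordered trials into the 0-based integer
# encoding the compiled kernel expects.
encode_trials <- function(trials, n_images = 8L) {
  required <- c("run", "trial", "valence", "required_action", "image_id", "action", "outcome")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trials are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(trials$run, trials$trial)
  if (!identical(ord, seq_len(nrow(trials)))) {
    stop("trials must be sorted by (run, trial) presentation order",
         call. = FALSE)
  }
  key <- paste(trials$run, trials$trial)
  if (anyDuplicated(key)) {
    stop("duplicated (run, trial) indices in trial sequence", call. = FALSE)
  }
  if (!all(trials$outcome %in% c(-1L, 0L, 1L))) {
    stop("outcomes must be -1, 0 or +1", call. = FALSE)
  }
  list(
    image = cue_image_index(trials$valence, trials$required_action,
                            trials$image_id) - 1L,
    valence = as.integer(trials$valence == "avoid"),
    action = as.integer(trials$action == "go"),
    outcome = as.integer(trials$outcome),
    n_images = as.integer(n_images)
  )
}

#' Log-likelihood of one subject's choice sequence
#'
#' Sums \code{log p(chosen action)} over an ordered trial sequence under the
#' model: softmax choice over action weights, with values updated trial by
#' trial. Per-image learning state threads across runs. Implemented in
#' compiled code; it is checked in the test suite against an independent
#' trial-by-trial replay built from \code{\link{action_weights}} and
#' \code{\link{apply_update}}.
#'
#' @param trials One subject's trials, ordered by (run, trial); needs columns
#'   \code{run, trial, valence, required_action, image_id, action, outcome}.
#' @param params Named natural-space parameter vector for \code{spec}.
#' @param spec A \code{plgt_model_spec}.
#' @return The log-likelihood (finite scalar).
#' @export
sequence_loglik <- function(trials, params, spec) {
  enc <- encode_trials(trials)
  ex <- expand_params(params, spec)
  seq_loglik_cpp(enc$image, enc$valence, enc$action, enc$outcome,
                 ex$eps, ex$rho, ex$b, ex$pi, enc$n_images)
}

# Log-likelihood at many natural-space parameter draws (rows of theta_nat,
# named columns); the Monte-Carlo marginal-likelihood workhorse.
sequence_loglik_draws <- function(enc, theta_nat, spec) {
  ex <- expand_params_matrix(theta_nat, spec)
  seq_loglik_many_cpp(enc$image, enc$valence, enc$action, enc$outcome,
                      ex$eps, ex$rho, ex$b, ex$pi, enc$n_images)
}

# Per-trial replay under fixed parameters: p(go) and Q(go) - Q(nogo) before
# each choice. Shared by value trajectories and diagnostics.
replay_sequence <- function(trials, params, spec) {
  enc <- encode_trials(trials)
  ex <- expand_params(params, spec)
  seq_replay_cpp(enc$image, enc$valence, enc$action, enc$outcome,
                 ex$eps, ex$rho, ex$b, ex$pi, enc$n_images)
}
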