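# The model family. Every member is a Q-learning observation model with
# softmax choice and Rescorla-Wagner delta-rule updates: Q is updated by
# eps * (rho * r - Q), the go weight may add a constant bias b and a
# Pavlovian term pi * V(s), where the stimulus value V is updated with the
# same learning rates from the same scaled outcome. Members differ only in
# which of the 12 candidate parameters they free:
#   eps            one learning rate
#   eps_P, eps_N   split by prediction-error sign
#   eps_W, eps_A   split by valence (win / avoid)
#   eps_WP, eps_WN, eps_AP, eps_AN   split by valence x sign
#   rho / rho_W, rho_A               subjective impact of outcomes
#   b              action (go) bias
#   pi             Pavlovian factor

EPS_STRUCTURES <- c("single", "sign", "valence", "valence_sign")
RHO_STRUCTURES <- c("single", "valence")

#' Define one member of the model family
#'
#' @param eps Learning-rate structure: \code{"single"} (one rate),
#'   \code{"sign"} (split by prediction-error sign: positive vs negative),
#'   \code{"valence"} (split by win vs avoid), or \code{"valence_sign"}
#'   (fully split: four rates).
#' @param rho Outcome-impact structure: \code{"single"} or \code{"valence"}.
#' @param bias Logical: include the constant go bias \code{b}?
#' @param pavlovian Logical: include the Pavlovian factor \code{pi} coupling
#'   the stimulus value into the go weight?
#' @param label Optional display label; a canonical one is built otherwise.
#' @return An object of class \code{plgt_model_spec}.
#' @export
#' @examples
#' model_spec("single", "single")                 # 2-parameter base model
#' model_spec("valence_sign", "valence", TRUE, TRUE)  # full 8-parameter model
model_spec <- function(eps = "single", rho = "single", bias = FALSE,
                       pavlovian = FALSE, label = NULL) {
  eps <- match.arg(eps, EPS_STRUCTURES)
  rho <- match.arg(rho, RHO_STRUCTURES)
  stopifnot(is.logical(bias), is.logical(pavlovian))
  spec <- structure(
    list(eps = eps, rho = rho, bias = isTRUE(bias), pavlovian = isTRUE(pavlovian)),
    class = "plgt_model_spec"
  )
  spec$label <- if (is.null(label)) spec_label(spec) else label
  spec
}

spec_label <- function(spec) {
  eps_part <- switch(spec$eps,
    single = "eps", sign = "epsP.epsN", valence = "epsW.epsA",
    valence_sign = "eps4")
  rho_part <- switch(spec$rho, single = "rho", valence = "rhoW.rhoA")
  paste0(c(eps_part, rho_part, if (spec$bias) "b", if (spec$pavlovian) "pi"),
         collapse = "+")
}

#' @export
print.plgt_model_spec <- function(x, ...) {
  cat("<plgt model spec> ", x$label, "\n", sep = "")
  cat("  free parameters (", n_free_params(x), "): ",
      paste(param_names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Free-parameter names of a model
#'
#' @param spec A \code{plgt_model_spec}.
#' @return Character vector of parameter names, drawn from the 12 candidates
#'   \code{eps, eps_P, eps_N, eps_WP, eps_WN, eps_AP, eps_AN, rho, rho_W,
#'   rho_A, b, pi}.
#' @export
param_names <- function(spec) {
  eps_names <- switch(spec$eps,
    single = "eps",
    sign = c("eps_P", "eps_N"),
    valence = c("eps_W", "eps_A"),
    valence_sign = c("eps_WP", "eps_WN", "eps_AP", "eps_AN"))
  rho_names <- switch(spec$rho, single = "rho", valence = c("rho_W", "rho_A"))
  c(eps_names, rho_names, if (spec$bias) "b", if (spec$pavlovian) "pi")
}

#' @rdname param_names
#' @export
n_free_params <- function(spec) length(param_names(spec))

# Transform family per parameter: learning rates live in (0,1) via the
# logistic, outcome impacts in (0, Inf) via exp, b and pi are unbounded.
param_transforms <- function(spec) {
  nm <- param_names(spec)
  tr <- ifelse(startsWith(nm, "eps"), "logistic",
        ifelse(startsWith(nm, "rho"), "exp", "identity"))
  setNames(tr, nm)
}

#' Map parameters between unconstrained and natural space
#'
#' Estimation works on an unconstrained scale; \code{to_natural} applies the
#' logistic to learning rates, \code{exp} to outcome impacts, and the
#' identity to \code{b} and \code{pi}. \code{to_unconstrained} is the exact
#' inverse.
#'
#' @param theta Named numeric vector (or matrix with named columns) of
#'   unconstrained values for \code{to_natural}; natural values for
#'   \code{to_unconstrained}.
#' @param spec A \code{plgt_model_spec}.
#' @return Numeric vector/matrix of the same shape.
#' @export
to_natural <- function(theta, spec) {
  tr <- param_transforms(spec)
  apply_transform(theta, tr, inverse = FALSE)
}

#' @rdname to_natural
#' @export
to_unconstrained <- function(theta, spec) {
  tr <- param_transforms(spec)
  apply_transform(theta, tr, inverse = TRUE)
}

apply_transform <- function(theta, tr, inverse) {
  f <- function(x, type) {
    switch(type,
      logistic = if (inverse) qlogis(x) else plogis(x),
      exp = if (inverse) log(x) else exp(x),
      identity = x)
  }
  if (is.matrix(theta)) {
    stopifnot(identical(colnames(theta), names(tr)))
    out <- theta
    for (j in seq_along(tr)) out[, j] <- f(theta[, j], tr[j])
    out
  } else {
    stopifnot(all(names(tr) %in% names(theta)))
    out <- theta[names(tr)]
    for (j in seq_along(tr)) out[j] <- f(out[j], tr[j])
    out
  }
}

# Expand a named natural-space parameter vector to the canonical dense form
# consumed by the likelihood kernel: eps[WP, WN, AP, AN], rho[W, A], b, pi.
expand_params <- function(params, spec) {
  eps <- switch(spec$eps,
    single = rep(params[["eps"]], 4L),
    sign = c(params[["eps_P"]], params[["eps_N"]],
             params[["eps_P"]], params[["eps_N"]]),
    valence = c(params[["eps_W"]], params[["eps_W"]],
                params[["eps_A"]], params[["eps_A"]]),
    valence_sign = c(params[["eps_WP"]], params[["eps_WN"]],
                     params[["eps_AP"]], params[["eps_AN"]]))
  rho <- switch(spec$rho,
    single = rep(params[["rho"]], 2L),
    valence = c(params[["rho_W"]], params[["rho_A"]]))
  list(eps = eps, rho = rho,
       b = if (spec$bias) params[["b"]] else 0,
       pi = if (spec$pavlovian) params[["pi"]] else 0)
}

# Matrix version: rows are draws, columns named parameters (natural space).
expand_params_matrix <- function(theta_nat, spec) {
  n <- nrow(theta_nat)
  cn <- colnames(theta_nat)
  col <- function(nm) theta_nat[, nm]
  eps <- switch(spec$eps,
    single = matrix(col("eps"), n, 4L),
    sign = cbind(col("eps_P"), col("eps_N"), col("eps_P"), col("eps_N")),
    valence = cbind(col("eps_W"), col("eps_W"), col("eps_A"), col("eps_A")),
    valence_sign = cbind(col("eps_WP"), col("eps_WN"), col("eps_AP"), col("eps_AN")))
  rho <- switch(spec$rho,
    single = matrix(col("rho"), n, 2L),
    valence = cbind(col("rho_W"), col("rho_A")))
  list(eps = eps, rho = rho,
       b = if (spec$bias) col("b") else numeric(n),
       pi = if (spec$pavlovian) col("pi") else numeric(n))
}

#' The default 14-model registry
#'
#' The candidate set explored by the stepwise selection narrative: from the
#' base model (one \code{eps}, one \code{rho}) through the addition of the
#' Pavlovian factor, prediction-error-sign and valence splits of the learning
#' rate, the valence split of the outcome impact, and the action bias, up to
#' the full 8-parameter model. The membership is a convention covering the
#' expansions the stepwise search can visit; pass your own list of
#' \code{\link{model_spec}} objects to explore a different family.
#'
#' @return Named list of 14 \code{plgt_model_spec} objects, ordered by
#'   increasing complexity with the base model first and the full model last.
#' @export
#' @examples
#' length(enumerate_models())
#' enumerate_models()[[1]]
enumerate_models <- function() {
  specs <- list(
    model_spec("single", "single", FALSE, FALSE),
    model_spec("single", "single", TRUE, FALSE),
    model_spec("single", "single", FALSE, TRUE),
    model_spec("single", "single", TRUE, TRUE),
    model_spec("sign", "single", FALSE, FALSE),
    model_spec("sign", "single", FALSE, TRUE),
    model_spec("sign", "single", TRUE, TRUE),
    model_spec("sign", "valence", TRUE, TRUE),
    model_spec("single", "valence", FALSE, TRUE),
    model_spec("sign", "valence", FALSE, TRUE),
    model_spec("valence_sign", "single", FALSE, TRUE),
    model_spec("valence_sign", "single", TRUE, TRUE),
    model_spec("valence_sign", "valence", FALSE, TRUE),
    model_spec("valence_sign", "valence", TRUE, TRUE)
  )
  setNames(specs, vapply(specs, `[[`, "", "label"))
}

#' Serialize / deserialize a model specification as JSON
#'
#' The JSON dialect is \code{{"eps": "valence_sign", "rho": "valence",
#' "bias": true, "pavlovian": true}}.
#'
#' @param spec A \code{plgt_model_spec}.
#' @param path File path.
#' @return \code{read_model_spec} returns a \code{plgt_model_spec};
#'   \code{write_model_spec} returns \code{path} invisibly.
#' @export
write_model_spec <- function(spec, path) {
  jsonlite::write_json(
    list(eps = spec$eps, rho = spec$rho, bias = spec$bias,
         pavlovian = spec$pavlovian),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(eps = x$eps, rho = x$rho, bias = isTRUE(x$bias),
             pavlovian = isTRUE(x$pavlovian))
}
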