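# Single-mediator path analysis. The X -> M -> Y decomposition uses three
# least-squares regressions:
#   Y = i1 + c X            (+ covariates)
#   Y = i2 + c' X + b M     (+ covariates)
#   M = i3 + a X            (+ covariates)
# For least-squares fits c - c' = a * b holds algebraically; the indirect
# effect a * b is tested by case-resampling bootstrap (percentile CI).

build_design <- function(data, x, m, y, covariates) {
  cols <- c(x, m, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("data are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data[, cols, drop = FALSE]
  keep <- complete.cases(df)
  list(df = df[keep, , drop = FALSE], n_dropped = sum(!keep))
}

# The three regressions on a prepared numeric matrix; fast path shared with
# the bootstrap. Z: covariate matrix (possibly 0 columns), all with intercept.
paths_from_matrices <- function(X, M, Y, Z) {
  n <- length(X)
  base <- cbind(`(Intercept)` = rep(1, n), Z)
  f1 <- stats::lm.fit(cbind(base, X = X), Y)              # c
  f2 <- stats::lm.fit(cbind(base, X = X, M = M), Y)       # c', b
  f3 <- stats::lm.fit(cbind(base, X = X), M)              # a
  rank_needed <- ncol(base) + 2L
  if (f2$rank < rank_needed) {
    stop("degenerate (rank-deficient) design; check for collinear columns ",
         "among X, M and covariates", call. = FALSE)
  }
  rdf <- function(f) length(f$residuals) - f$rank
  list(
    a = unname(f3$coefficients["X"]),
    b = unname(f2$coefficients["M"]),
    c = unname(f1$coefficients["X"]),
    c_prime = unname(f2$coefficients["X"]),
    intercepts = c(i1 = unname(f1$coefficients[1]),
                   i2 = unname(f2$coefficients[1]),
                   i3 = unname(f3$coefficients[1])),
    resid_var = c(e1 = sum(f1$residuals^2) / rdf(f1),
                  e2 = sum(f2$residuals^2) / rdf(f2),
                  e3 = sum(f3$residuals^2) / rdf(f3))
  )
}

#' Fit the single-mediator path model
#'
#' Estimates paths \code{a} (X to M), \code{b} (M to Y given X), \code{c}
#' (total X to Y), \code{c'} (direct X to Y given M) and the indirect effect
#' \code{a * b} by least squares. Covariates are adjusted for by including
#' them as regressors in all three equations. Variables are z-scored by
#' default (standardized paths); raw-scale paths are returned alongside.
#'
#' @param data Data frame of subject-level variables.
#' @param x,m,y Column names of the independent variable, mediator, outcome.
#' @param covariates Character vector of adjustment covariate columns.
#' @param standardize Z-score X, M, Y (and covariates) before fitting?
#' @return An object of class \code{plgt_mediation}: paths (standardized and
#'   raw), intercepts, residual variances, \code{indirect = a * b},
#'   \code{n_used}, \code{n_dropped}.
#' @export
#' @examples
#' d <- data.frame(x = rnorm(50))
#' d$m <- 2 * d$x
#' d$y <- 3 * d$m
#' fit_paths(d, "x", "m", "y", standardize = FALSE)$paths
fit_paths <- function(data, x, m, y, covariates = character(),
                      standardize = TRUE) {
  prep <- build_design(data, x, m, y, covariates)
  df <- prep$df
  n <- nrow(df)
  if (n < length(covariates) + 4L) {
    stop("too few complete cases for the mediation design", call. = FALSE)
  }
  for (v in c(x, m, y)) {
    if (sd(df[[v]]) == 0) {
      stop("variable `", v, "` has zero variance", call. = FALSE)
    }
  }
  Z <- as.matrix(df[, covariates, drop = FALSE])
  raw <- paths_from_matrices(df[[x]], df[[m]], df[[y]], Z)
  std <- if (standardize) {
    zs <- function(v) (v - mean(v)) / sd(v)
    Zs <- if (ncol(Z)) apply(Z, 2L, zs) else Z
    paths_from_matrices(zs(df[[x]]), zs(df[[m]]), zs(df[[y]]), Zs)
  } else {
    raw
  }
  structure(
    list(paths = c(a = std$a, b = std$b, c = std$c, c_prime = std$c_prime),
         indirect = std$a * std$b,
         intercepts = std$intercepts, resid_var = std$resid_var,
         raw_paths = c(a = raw$a, b = raw$b, c = raw$c, c_prime = raw$c_prime),
         raw_indirect = raw$a * raw$b,
         standardized = standardize,
         n_used = n, n_dropped = prep$n_dropped,
         vars = list(x = x, m = m, y = y, covariates = covariates)),
    class = "plgt_mediation"
  )
}

#' @export
print.plgt_mediation <- function(x, ...) {
  cat("<single-mediator model> ", x$vars$x, " -> ", x$vars$m, " -> ",
      x$vars$y, if (length(x$vars$covariates))
        paste0("  (adjusting for ", paste(x$vars$covariates, collapse = ", "), ")"),
      "\n", sep = "")
  cat(sprintf("  a = %.4f, b = %.4f, c = %.4f, c' = %.4f, a*b = %.4f%s\n",
              x$paths["a"], x$paths["b"], x$paths["c"], x$paths["c_prime"],
              x$indirect, if (x$standardized) " (standardized)" else ""))
  if (!is.null(x$boot)) {
    cat(sprintf("  bootstrap 95%% CI for a*b: [%.4f, %.4f], p = %.4g (%d resamples)\n",
                x$boot$ci[1], x$boot$ci[2], x$boot$p, x$boot$n_boot))
  }
  cat("  n =", x$n_used, "complete cases (", x$n_dropped, "dropped )\n")
  invisible(x)
}

#' Bootstrap test of the indirect effect
#'
#' Case-resampling bootstrap of subjects with replacement: the three
#' regressions are refitted on each resample and the indirect effect
#' \code{a * b} recorded. Returns the percentile 95% confidence interval and
#' a two-sided p-value \code{2 * min(frac <= 0, frac >= 0)}. Degenerate
#' resamples (zero variance in X, M or Y) are redrawn and counted.
#'
#' @param data,x,m,y,covariates,standardize As in \code{\link{fit_paths}}.
#' @param n_boot Number of bootstrap resamples (>= 200; default 5000).
#' @param seed Integer seed.
#' @param conf Confidence level for the percentile interval.
#' @return List with \code{indirect} (point estimate), \code{ci}, \code{p},
#'   \code{boot} (the resampled indirect effects), \code{n_boot},
#'   \code{n_redrawn}.
#' @export
bootstrap_indirect <- function(data, x, m, y, covariates = character(),
                               n_boot = 5000, seed = 1, standardize = TRUE,
                               conf = 0.95) {
  if (n_boot < 200) stop("`n_boot` must be at least 200", call. = FALSE)
  point <- fit_paths(data, x, m, y, covariates, standardize = standardize)
  df <- build_design(data, x, m, y, covariates)$df
  n <- nrow(df)
  Xv <- df[[x]]; Mv <- df[[m]]; Yv <- df[[y]]
  Z <- as.matrix(df[, covariates, drop = FALSE])
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v
  ab <- numeric(n_boot)
  n_redrawn <- 0L
  with_seed(seed, {
    for (k in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(Xv[idx]) > 0 && sd(Mv[idx]) > 0 && sd(Yv[idx]) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      xi <- Xv[idx]; mi <- Mv[idx]; yi <- Yv[idx]
      zi <- Z[idx, , drop = FALSE]
      if (standardize) {
        xi <- zs(xi); mi <- zs(mi); yi <- zs(yi)
        if (ncol(zi)) zi <- apply(zi, 2L, zs)
      }
      p <- tryCatch(paths_from_matrices(xi, mi, yi, zi), error = function(e) NULL)
      if (is.null(p)) {
        ab[k] <- NA_real_
      } else {
        ab[k] <- p$a * p$b
      }
    }
  })
  ab <- ab[!is.na(ab)]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(ab, c(alpha, 1 - alpha), type = 6))
  p_val <- 2 * min(mean(ab <= 0), mean(ab >= 0))
  list(indirect = point$indirect, ci = ci, p = min(p_val, 1),
       boot = ab, n_boot = n_boot, n_redrawn = n_redrawn)
}

#' Full mediation analysis
#'
#' Fits the path model and attaches the bootstrap test of the indirect
#' effect.
#'
#' @inheritParams bootstrap_indirect
#' @return A \code{plgt_mediation} with a \code{boot} element.
#' @export
mediate <- function(data, x, m, y, covariates = character(), n_boot = 5000,
                    seed = 1, standardize = TRUE) {
  fit <- fit_paths(data, x, m, y, covariates, standardize = standardize)
  boot <- bootstrap_indirect(data, x, m, y, covariates, n_boot = n_boot,
                             seed = seed, standardize = standardize)
  fit$boot <- boot[c("ci", "p", "n_boot", "n_redrawn")]
  fit$boot_draws <- boot$boot
  fit
}
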