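#' Conditional-independence test counter
#'
#' The number of CI tests performed is the hardware-independent runtime proxy
#' used to compare search algorithms. Search tests and equivalence tests are
#' counted in separate fields, since equivalence testing is common to all
#' algorithms being compared.
#'
#' @return An environment of class `test_counter` with fields `search` and
#'   `equiv`.
#' @export
new_test_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$search <- 0L
  e$equiv <- 0L
  class(e) <- "test_counter"
  e
}

#' @export
print.test_counter <- function(x, ...) {
  cat(sprintf("<test_counter> search: %d, equivalence: %d\n", x$search, x$equiv))
  invisible(x)
}

#' Reset a test counter
#' @param counter a [new_test_counter()].
#' @return The counter, invisibly.
#' @export
reset_counter <- function(counter) {
  counter$search <- 0L
  counter$equiv <- 0L
  invisible(counter)
}

#' Read counter totals
#' @param counter a [new_test_counter()].
#' @return Named integer vector with elements `search` and `equiv`.
#' @export
ci_counts <- function(counter) {
  c(search = counter$search, equiv = counter$equiv)
}

bump_counter <- function(counter, purpose) {
  if (is.null(counter)) return(invisible(NULL))
  if (purpose == "search") counter$search <- counter$search + 1L
  else counter$equiv <- counter$equiv + 1L
  invisible(NULL)
}

eq_test_result <- function(statistic, pvalue, dof, test_name, degenerate = FALSE) {
  structure(list(statistic = statistic, pvalue = pvalue, dof = as.integer(dof),
                 test_name = test_name, degenerate = degenerate),
            class = "eq_test")
}

#' @export
print.eq_test <- function(x, ...) {
  cat(sprintf("<eq_test> %s: statistic = %.4g, dof = %d, p = %.4g%s\n",
              x$test_name, x$statistic, x$dof, x$pvalue,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

# Covariance of cbind(X, y), computed once per base dataset and cached.
# All Fisher-z partial correlations are O(k^3) submatrix inversions on it.
dataset_cov <- function(dataset) {
  if (is.null(dataset$cache$covXy)) {
    dataset$cache$covXy <- stats::cov(cbind(dataset$X, dataset$y))
  }
  dataset$cache$covXy
}

#' Fisher-z partial correlation test
#'
#' Tests dependence of feature `x` with the continuous outcome given the
#' conditioning set, using the sample partial correlation r obtained from the
#' inverse of the covariance submatrix over \{x, T\} and the conditioning
#' features. The statistic is sqrt(n - |cond| - 3) * atanh(r) with a
#' two-sided standard-normal p-value.
#'
#' Near-singular conditioning covariances (condition number > 1e10) receive a
#' ridge jitter of 1e-8 on the diagonal and the result is flagged; r is
#' clipped to +/-(1 - 1e-12) before atanh so deterministic relations yield a
#' finite statistic. A zero-variance `x` returns p = 1 with the degenerate
#' flag set.
#'
#' @param view an `eq_dataset` or `eq_view` with continuous outcome.
#' @param x active feature index.
#' @param cond integer vector of active conditioning feature indices.
#' @param counter optional [new_test_counter()], incremented by one.
#' @param purpose `"search"` or `"equiv"`: which counter field to increment.
#' @return An `eq_test` result (statistic, p-value, dof = |cond|).
#' @export
fisher_z_test <- function(view, x, cond = integer(0), counter = NULL,
                          purpose = "search") {
  v <- as_view(view)
  ds <- v$base
  if (ds$outcome_type != "continuous") stop("fisher_z_test needs a continuous outcome")
  cond <- as.integer(cond)
  x <- as.integer(x)
  act <- active_features(v)
  if (!(x %in% act)) stop("x is not active in the view")
  if (x %in% cond) stop("x must not be in the conditioning set")
  if (length(cond) > 0L && !all(cond %in% act)) stop("conditioning set not active")
  n <- n_samples(ds)
  if (n <= length(cond) + 3L) stop("too few samples for the conditioning set size")
  bump_counter(counter, purpose)

  S_all <- dataset_cov(ds)
  yi <- n_features(ds) + 1L
  idx <- c(x, yi, cond)
  S <- S_all[idx, idx, drop = FALSE]
  if (S[1L, 1L] < 1e-14) {
    return(eq_test_result(0, 1, length(cond), "fisher_z", degenerate = TRUE))
  }
  flagged <- FALSE
  if (rcond_sym(S) < 1e-10) {
    S <- S + diag(1e-8, nrow(S))
    flagged <- TRUE
  }
  P <- solve(S)
  r <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  r <- max(min(r, 1 - 1e-12), -(1 - 1e-12))
  stat <- sqrt(n - length(cond) - 3) * atanh(r)
  p <- 2 * stats::pnorm(-abs(stat))
  eq_test_result(stat, p, length(cond), "fisher_z", degenerate = flagged)
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev)) return(0)
  lo <- min(ev); hi <- max(ev)
  if (hi <= 0) return(0)
  max(lo, 0) / hi
}

# ---- logistic fits ---------------------------------------------------------

# Ordinary logistic MLE via stats::glm.fit; on nonconvergence or separation
# the model is refit once with a small L2 penalty (1e-6) by Newton-IRLS and
# flagged. Returns coefficients, total log-likelihood and deviance.
fit_logistic_raw <- function(Z, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Z, y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  ok <- isTRUE(fit$converged) && !sep && all(is.finite(fit$coefficients))
  if (!ok) {
    pf <- irls_penalized(Z, y, lambda = 1e-6)
    return(list(coef = pf$coef, loglik = pf$loglik,
                deviance = -2 * pf$loglik, flagged = TRUE))
  }
  mu <- clip01(fit$fitted.values)
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coef = fit$coefficients, loglik = ll, deviance = -2 * ll, flagged = FALSE)
}

clip01 <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# Newton-IRLS with L2 penalty on the non-intercept coefficients (column 1 of
# Z is assumed to be the intercept). Tolerance 1e-8 on the penalized
# log-likelihood, at most 100 iterations. Applying the same penalty to both
# nested models keeps the likelihood-ratio test valid.
irls_penalized <- function(Z, y, lambda = 1e-6, tol = 1e-8, maxit = 100L) {
  p <- ncol(Z)
  D <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  obj_old <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    mu <- clip01(stats::plogis(eta))
    w <- mu * (1 - mu)
    g <- drop(crossprod(Z, y - mu)) - drop(D %*% beta)
    H <- crossprod(Z, Z * w) + D
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, p), g)
    })
    beta <- beta + step
    eta <- drop(Z %*% beta)
    mu <- clip01(stats::plogis(eta))
    obj <- sum(y * log(mu) + (1 - y) * log(1 - mu)) - 0.5 * sum(beta^2 * diag(D))
    if (abs(obj - obj_old) < tol) break
    obj_old <- obj
  }
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coef = beta, loglik = ll)
}

design_matrix <- function(dataset, features) {
  cbind(1, dataset$X[, features, drop = FALSE])
}

#' Logistic likelihood-ratio test
#'
#' Tests dependence of the features `x` with a binary outcome given the
#' conditioning set by fitting nested logistic regressions on `cond` and on
#' `cond` plus `x`. The statistic is the difference in deviances, referred to
#' a chi-square with dof equal to the number of added features.
#'
#' @inheritParams fisher_z_test
#' @param x one or more active feature indices to add to the nested model.
#' @return An `eq_test` result.
#' @export
logistic_lrt <- function(view, x, cond = integer(0), counter = NULL,
                         purpose = "search") {
  v <- as_view(view)
  ds <- v$base
  if (ds$outcome_type != "binary") stop("logistic_lrt needs a binary outcome")
  x <- as.integer(x)
  cond <- as.integer(cond)
  act <- active_features(v)
  if (!all(x %in% act)) stop("x is not active in the view")
  if (any(x %in% cond)) stop("x must not be in the conditioning set")
  bump_counter(counter, purpose)

  y <- ds$y
  f0 <- fit_logistic_raw(design_matrix(ds, cond), y)
  f1 <- fit_logistic_raw(design_matrix(ds, c(cond, x)), y)
  if (f1$flagged && !f0$flagged) {
    # penalty must hit both nested models for the LRT to stay valid
    pf0 <- irls_penalized(design_matrix(ds, cond), y, lambda = 1e-6)
    f0 <- list(coef = pf0$coef, loglik = pf0$loglik,
               deviance = -2 * pf0$loglik, flagged = TRUE)
  }
  stat <- max(f0$deviance - f1$deviance, 0)
  dof <- length(x)
  p <- stats::pchisq(stat, df = dof, lower.tail = FALSE)
  eq_test_result(stat, p, dof, "logistic_lrt",
                 degenerate = f0$flagged || f1$flagged)
}

# Multi-dof Gaussian likelihood-ratio test for nested linear models:
# statistic n * log(RSS0 / RSS1), chi-square with dof added features.
gaussian_lrt <- function(view, x, cond = integer(0), counter = NULL,
                         purpose = "equiv") {
  v <- as_view(view)
  ds <- v$base
  x <- as.integer(x)
  cond <- as.integer(cond)
  bump_counter(counter, purpose)
  y <- ds$y
  n <- length(y)
  rss0 <- linear_rss(design_matrix(ds, cond), y)
  rss1 <- linear_rss(design_matrix(ds, c(cond, x)), y)
  stat <- max(n * log(rss0 / max(rss1, 1e-300)), 0)
  dof <- length(x)
  p <- stats::pchisq(stat, df = dof, lower.tail = FALSE)
  eq_test_result(stat, p, dof, "gaussian_lrt")
}

linear_rss <- function(Z, y) {
  fit <- stats::lm.fit(Z, y)
  sum(fit$residuals^2)
}

#' Conditional-independence test (dispatch)
#'
#' Dispatches on the outcome type of the base dataset: Fisher-z partial
#' correlation for continuous outcomes, logistic likelihood-ratio test for
#' binary outcomes.
#'
#' @inheritParams fisher_z_test
#' @return An `eq_test` result.
#' @export
ci_test <- function(view, x, cond = integer(0), counter = NULL,
                    purpose = "search") {
  v <- as_view(view)
  if (v$base$outcome_type == "continuous") {
    fisher_z_test(v, x, cond, counter, purpose)
  } else {
    logistic_lrt(v, x, cond, counter, purpose)
  }
}

# Multi-dof CI test used by the equivalence module: tests T vs a SET of added
# features given cond, via a likelihood-ratio test in the outcome's model
# family. Counts one equivalence-side CI test.
ci_test_multi <- function(view, xs, cond = integer(0), counter = NULL,
                          purpose = "equiv") {
  v <- as_view(view)
  if (length(xs) == 0L) {
    # nothing added: identical nested models, no test actually performed
    return(eq_test_result(0, 1, 0L, "lrt_empty"))
  }
  if (v$base$outcome_type == "continuous") {
    gaussian_lrt(v, xs, cond, counter, purpose)
  } else {
    logistic_lrt(v, xs, cond, counter, purpose)
  }
}
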