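#' Fit a predictive model on a feature set
#'
#' Ordinary least squares with Gaussian likelihood (continuous outcome;
#' `sigma2` is the maximum-likelihood residual variance) or logistic maximum
#' likelihood (binary outcome). A singular design receives a ridge jitter of
#' 1e-8 and the fit is flagged.
#'
#' @param view an `eq_dataset` or `eq_view`.
#' @param features integer vector of active feature indices (may be empty:
#'   intercept-only model).
#' @return A list of class `fitted_model` with elements `family`,
#'   `features`, `coef` (intercept first), `sigma2` (linear family only) and
#'   `flagged`.
#' @export
fit_model <- function(view, features = integer(0)) {
  v <- as_view(view)
  ds <- v$base
  features <- sort(as.integer(features))
  if (length(features) > 0L && !all(features %in% active_features(v))) {
    stop("features must be active in the view")
  }
  Z <- design_matrix(ds, features)
  y <- ds$y
  if (ds$outcome_type == "continuous") {
    fit <- stats::lm.fit(Z, y)
    flagged <- fit$rank < ncol(Z)
    if (flagged) {
      beta <- solve(crossprod(Z) + diag(1e-8, ncol(Z)), crossprod(Z, y))
      beta <- drop(beta)
      res <- y - drop(Z %*% beta)
    } else {
      beta <- fit$coefficients
      res <- fit$residuals
    }
    sigma2 <- sum(res^2) / length(y)
    out <- list(family = "linear_gaussian", features = features,
                coef = unname(beta), sigma2 = max(sigma2, 1e-300),
                flagged = flagged)
  } else {
    f <- fit_logistic_raw(Z, y)
    out <- list(family = "logistic", features = features,
                coef = unname(f$coef), sigma2 = NULL, flagged = f$flagged)
  }
  class(out) <- "fitted_model"
  out
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s on {%s}%s\n", x$family,
              paste(x$features, collapse = ", "),
              if (isTRUE(x$flagged)) " (flagged)" else ""))
  invisible(x)
}

model_predictions <- function(model, view) {
  ds <- as_view(view)$base
  eta <- drop(design_matrix(ds, model$features) %*% model$coef)
  if (model$family == "logistic") clip01(stats::plogis(eta)) else eta
}

#' Per-sample log-likelihood contributions
#'
#' Gaussian or Bernoulli log-density of each sample at the fitted
#' parameters; the sum equals the model's total log-likelihood. Bernoulli
#' probabilities are clipped to \[1e-12, 1 - 1e-12\] before the log.
#'
#' @param model a [fit_model()] result.
#' @param view the dataset it was fitted on.
#' @return Numeric vector of length `n_samples`.
#' @export
loglik_vector <- function(model, view) {
  ds <- as_view(view)$base
  y <- ds$y
  mu <- model_predictions(model, view)
  if (model$family == "linear_gaussian") {
    stats::dnorm(y, mean = mu, sd = sqrt(model$sigma2), log = TRUE)
  } else {
    y * log(mu) + (1 - y) * log(1 - mu)
  }
}

#' Variance of the per-sample log-likelihood ratio
#'
#' The variance (denominator n) of the differences `ll_x - ll_y`: the
#' model-equivalence statistic. Zero when the two models fit every sample
#' equally well.
#'
#' @param ll_x,ll_y equal-length numeric vectors of per-sample
#'   log-likelihood contributions (or, for the prediction-based variant,
#'   per-sample predictions).
#' @return The statistic (a nonnegative number).
#' @export
vuong_variance_statistic <- function(ll_x, ll_y) {
  if (length(ll_x) != length(ll_y)) stop("vectors must have equal length")
  d <- ll_x - ll_y
  mean((d - mean(d))^2)
}

#' Paired-swap permutation test of model equivalence
#'
#' Under the null hypothesis that the two models are equivalent, whether a
#' per-sample value comes from the first or the second model is
#' exchangeable: each permutation independently swaps the pair
#' `(ll_x[i], ll_y[i])` with probability 0.5 and the variance statistic is
#' recomputed. The p-value counts permutation statistics less than or equal
#' to the observed one, including the observed sample itself:
#' `(1 + sum(s_i <= s)) / (B + 1)`, hence always in (0, 1].
#'
#' The test rejects for a small observed variance relative to the
#' sign-swapped distribution: swapping a pair flips the sign of its
#' difference, so when the mean per-sample difference is nonzero (one model
#' systematically better) the swapped differences have inflated variance and
#' the observed statistic falls in the lower tail.
#'
#' The same engine serves the prediction-based model-equivalence variant:
#' pass per-sample prediction vectors instead of log-likelihood vectors.
#'
#' @inheritParams vuong_variance_statistic
#' @param B number of permutations (at least 100).
#' @param seed integer seed for the swap draws.
#' @return A list of class `permutation_result` with `observed`, `permuted`
#'   (length B), `pvalue`, `B` and `seed`.
#' @export
permutation_variance_test <- function(ll_x, ll_y, B = 1000L, seed = 1L) {
  if (length(ll_x) != length(ll_y)) stop("vectors must have equal length")
  B <- as.integer(B)
  if (B < 100L) stop("B must be at least 100")
  d <- ll_x - ll_y
  n <- length(d)
  msq <- mean(d^2)
  s <- msq - mean(d)^2
  permuted <- with_seed(seed, {
    # swapping pair i negates d[i]; var_n(+-d) = mean(d^2) - mean(+-d)^2
    signs <- matrix(1 - 2L * stats::rbinom(B * n, 1L, 0.5), nrow = B)
    msq - (drop(signs %*% d) / n)^2
  })
  pvalue <- (1 + sum(permuted <= s + 1e-15)) / (B + 1)
  structure(list(observed = s, permuted = permuted, pvalue = pvalue,
                 B = B, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> s = %.4g, B = %d, p = %.4g\n",
              x$observed, x$B, x$pvalue))
  invisible(x)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Information-equivalence test (comprehensive approach)
#'
#' Tests whether two feature sets carry the same information about the
#' outcome by comparing each set's model with the model on the union:
#' multi-degree-of-freedom likelihood-ratio tests of `T` versus
#' `set_y \ set_x` given `set_x`, and of `set_x \ set_y` given `set_y`
#' (dof = number of added features). The sets are declared equivalent when
#' neither test rejects at `alpha_eq`.
#'
#' @param view an `eq_dataset` or `eq_view`.
#' @param set_x,set_y integer vectors of active feature indices (may
#'   overlap; identical sets are trivially equivalent with both p = 1).
#' @param alpha_eq significance level.
#' @param counter optional [new_test_counter()] (equivalence field).
#' @return List with `test_xy` (adds `set_y \ set_x` to `set_x`), `test_yx`,
#'   and logical `equivalent`.
#' @export
ieq_test <- function(view, set_x, set_y, alpha_eq = 0.05, counter = NULL) {
  v <- as_view(view)
  set_x <- sort(as.integer(set_x))
  set_y <- sort(as.integer(set_y))
  add_xy <- setdiff(set_y, set_x)
  add_yx <- setdiff(set_x, set_y)
  t_xy <- ci_test_multi(v, add_xy, set_x, counter)
  t_yx <- ci_test_multi(v, add_yx, set_y, counter)
  list(test_xy = t_xy, test_yx = t_yx,
       equivalent = t_xy$pvalue >= alpha_eq && t_yx$pvalue >= alpha_eq)
}

#' J-test of feature-set equivalence
#'
#' Uses each model's in-sample predictions as a one-dimensional proxy for
#' the information its feature set carries: tests `T` versus the predictions
#' of the `set_x` model given `set_y`, and vice versa, each with one degree
#' of freedom. More sample-efficient than the comprehensive approach but
#' blind to interactions between the two sets.
#'
#' @inheritParams ieq_test
#' @return List with `test_xy`, `test_yx` and logical `equivalent`.
#' @export
jtest <- function(view, set_x, set_y, alpha_eq = 0.05) {
  v <- as_view(view)
  ds <- v$base
  set_x <- sort(as.integer(set_x))
  set_y <- sort(as.integer(set_y))
  if (identical(set_x, set_y)) {
    t1 <- eq_test_result(0, 1, 0L, "jtest")
    return(list(test_xy = t1, test_yx = t1, equivalent = TRUE))
  }
  px <- model_predictions(fit_model(v, set_x), v)
  py <- model_predictions(fit_model(v, set_y), v)
  t_xy <- jtest_one(ds, px, set_y)   # do set_x's predictions add to set_y?
  t_yx <- jtest_one(ds, py, set_x)
  list(test_xy = t_xy, test_yx = t_yx,
       equivalent = t_xy$pvalue >= alpha_eq && t_yx$pvalue >= alpha_eq)
}

jtest_one <- function(ds, pred, cond_features) {
  Z0 <- design_matrix(ds, cond_features)
  Z1 <- cbind(Z0, pred)
  y <- ds$y
  n <- length(y)
  if (ds$outcome_type == "continuous") {
    stat <- max(n * log(linear_rss(Z0, y) / max(linear_rss(Z1, y), 1e-300)), 0)
  } else {
    f0 <- fit_logistic_raw(Z0, y)
    f1 <- fit_logistic_raw(Z1, y)
    stat <- max(f0$deviance - f1$deviance, 0)
  }
  eq_test_result(stat, stats::pchisq(stat, 1, lower.tail = FALSE), 1L, "jtest")
}

#' Two-stage equivalence decision
#'
#' The recommended pipeline: a permutation variance test on the two models'
#' per-sample log-likelihood vectors acts as a cheap filter against clearly
#' non-equivalent candidates; candidates that survive are then subjected to
#' the information-equivalence test. A candidate is accepted only when both
#' stages pass at `alpha_eq`.
#'
#' Note that a strict superset of the reference passes both
#' information-equivalence directions by construction; minimality is the
#' backward phase's responsibility, not this decision's.
#'
#' @param view an `eq_dataset` or `eq_view`.
#' @param candidate,reference integer feature-index vectors.
#' @param config a [search_config()] (supplies `alpha_eq`, `n_permutations`
#'   and the base seed).
#' @param counter optional [new_test_counter()].
#' @param seed optional integer overriding the derived permutation seed.
#' @return A list of class `equivalence_verdict` with `peq_pvalue`,
#'   `ieq_pvalue_xy`, `ieq_pvalue_yx` and logical `equivalent`.
#' @export
equivalence_decision <- function(view, candidate, reference,
                                 config = search_config(), counter = NULL,
                                 seed = NULL) {
  v <- as_view(view)
  candidate <- sort(as.integer(candidate))
  reference <- sort(as.integer(reference))
  if (is.null(seed)) seed <- derive_eq_seed(config$seed, candidate, reference)
  if (identical(candidate, reference)) {
    return(structure(list(peq_pvalue = 1, ieq_pvalue_xy = 1,
                          ieq_pvalue_yx = 1, equivalent = TRUE),
                     class = "equivalence_verdict"))
  }
  m_c <- fit_model(v, candidate)
  m_r <- fit_model(v, reference)
  peq <- permutation_variance_test(loglik_vector(m_c, v), loglik_vector(m_r, v),
                                   B = config$n_permutations, seed = seed)
  if (peq$pvalue < config$alpha_eq) {
    return(structure(list(peq_pvalue = peq$pvalue, ieq_pvalue_xy = NA_real_,
                          ieq_pvalue_yx = NA_real_, equivalent = FALSE),
                     class = "equivalence_verdict"))
  }
  ieq <- ieq_test(v, candidate, reference, config$alpha_eq, counter)
  structure(list(peq_pvalue = peq$pvalue,
                 ieq_pvalue_xy = ieq$test_xy$pvalue,
                 ieq_pvalue_yx = ieq$test_yx$pvalue,
                 equivalent = ieq$equivalent),
            class = "equivalence_verdict")
}

#' @export
print.equivalence_verdict <- function(x, ...) {
  cat(sprintf("<equivalence_verdict> %s (PEQ p = %.3g, IEQ p = %.3g / %.3g)\n",
              if (x$equivalent) "equivalent" else "not equivalent",
              x$peq_pvalue, x$ieq_pvalue_xy, x$ieq_pvalue_yx))
  invisible(x)
}

# Deterministic permutation seed per (base seed, candidate, reference) so the
# same candidate gets the same verdict in every search algorithm and rerun.
derive_eq_seed <- function(seed, candidate, reference) {
  h <- (as.numeric(seed) + 1009 * sum(candidate) + 97 * length(candidate) +
        31 * sum(reference)) %% 2147483629
  as.integer(h) + 1L
}

#' Best achievable expected accuracy of a discrete joint distribution
#'
#' Maximum expected 0-1 accuracy over all deterministic decision rules
#' mapping the feature configuration to an outcome value: for each feature
#' configuration the rule picks the outcome value with the largest joint
#' probability, so the optimum is the sum over configurations of the maximal
#' joint mass. Used to study what the accuracy loss can and cannot detect
#' about feature-set equivalence.
#'
#' @param joint data frame with a probability column `p`, an outcome column
#'   `t`, and one or more feature columns; probabilities must be nonnegative
#'   and sum to one.
#' @return The expected accuracy of the best rule, in \[0, 1\].
#' @export
bayes_expected_accuracy <- function(joint) {
  if (!is.data.frame(joint) || !all(c("p", "t") %in% names(joint))) {
    stop("joint must be a data frame with columns 'p' and 't'")
  }
  p <- joint$p
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8) {
    stop("probabilities must be nonnegative and sum to 1")
  }
  xcols <- setdiff(names(joint), c("p", "t"))
  if (length(xcols) == 0L) {
    key <- rep("", nrow(joint))
  } else {
    key <- do.call(paste, c(joint[xcols], sep = "\r"))
  }
  # per configuration: the best rule claims the outcome with most mass
  mass <- tapply(p, list(key, joint$t), sum, default = 0)
  sum(apply(mass, 1L, max))
}
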