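# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: partial correlations via explicit
# residual regressions, logistic likelihoods via a hand-coded Newton solver.

fam_key <- function(s) paste(sort(s), collapse = ",")

family_keys <- function(solset) {
  sols <- if (inherits(solset, "solution_set")) solset$solutions else solset
  sort(vapply(sols, fam_key, character(1)))
}

# residual-regression partial correlation of x and y given columns Z
partial_cor_residuals <- function(x, y, Z = NULL) {
  if (is.null(Z) || NCOL(Z) == 0L) return(stats::cor(x, y))
  Z1 <- cbind(1, Z)
  rx <- stats::lm.fit(Z1, x)$residuals
  ry <- stats::lm.fit(Z1, y)$residuals
  stats::cor(rx, ry)
}

# plain Newton-Raphson logistic MLE, written independently of the package
irls_logistic_oracle <- function(Z, y, maxit = 60L, tol = 1e-12) {
  beta <- rep(0, ncol(Z))
  for (it in seq_len(maxit)) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    delta <- solve(crossprod(Z, Z * W), crossprod(Z, y - mu))
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  eta <- drop(Z %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  list(coef = beta, loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

# equivalence oracle: accept exactly the enumerated ground-truth family
oracle_equivalence_fn <- function(truth) {
  keys <- family_keys(enumerate_true_solutions(truth))
  function(candidate, reference) fam_key(candidate) %in% keys
}

# small dense linear-Gaussian dataset with no special structure
random_dataset <- function(n = 300, p = 6, k_signal = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- rowSums(X[, seq_len(k_signal), drop = FALSE]) + stats::rnorm(n)
  eq_dataset(X, y, "continuous")
}
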