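test_that("model fitting has the right closed forms", {
  set.seed(1)
  n <- 100
  x <- rnorm(n)
  y <- 2 * x + 1
  ds <- eq_dataset(cbind(x, rnorm(n)), y, "continuous")
  m0 <- fit_model(ds, integer(0))
  expect_equal(m0$coef, mean(y), tolerance = 1e-10)
  expect_equal(m0$sigma2, mean((y - mean(y))^2), tolerance = 1e-10)
  m1 <- fit_model(ds, 1L)
  expect_equal(m1$coef, c(1, 2), tolerance = 1e-8)

  yb <- rbinom(n, 1, plogis(x))
  dsb <- eq_dataset(cbind(x, rnorm(n)), yb, "binary")
  mb <- fit_model(dsb, 1L)
  oracle <- irls_logistic_oracle(cbind(1, x), yb)
  expect_equal(sum(loglik_vector(mb, dsb)), oracle$loglik, tolerance = 1e-6)
})

test_that("per-sample log-likelihoods sum to the model log-likelihood", {
  set.seed(2)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3)
  y <- X[, 1] + rnorm(n)
  ds <- eq_dataset(X, y, "continuous")
  m <- fit_model(ds, c(1L, 2L))
  ll <- loglik_vector(m, ds)
  lmfit <- lm(y ~ X[, 1] + X[, 2])
  expect_equal(sum(ll), as.numeric(logLik(lmfit)), tolerance = 1e-8)
  # manual Gaussian density evaluation
  mu <- cbind(1, X[, 1:2]) %*% m$coef
  expect_equal(ll, dnorm(y, mu, sqrt(m$sigma2), log = TRUE), tolerance = 1e-12)

  yb <- rbinom(n, 1, 0.5)
  dsb <- eq_dataset(X, yb, "binary")
  m5 <- structure(list(family = "logistic", features = integer(0), coef = 0,
                       flagged = FALSE), class = "fitted_model")
  expect_equal(loglik_vector(m5, dsb), rep(log(0.5), n), tolerance = 1e-12)
})

test_that("the variance statistic matches a naive two-pass oracle", {
  expect_equal(vuong_variance_statistic(1:5, 1:5), 0)
  expect_equal(vuong_variance_statistic(c(1, -1), c(0, 0)), 1)
  set.seed(3)
  a <- rnorm(50)
  b <- rnorm(50)
  d <- a - b
  expect_equal(vuong_variance_statistic(a, b),
               sum((d - sum(d) / 50)^2) / 50, tolerance = 1e-12)
  expect_error(vuong_variance_statistic(1:3, 1:4), "equal length")
})

test_that("permutation variance test behaves at the degenerate null and under shifts", {
  ll <- rnorm(100)
  res <- permutation_variance_test(ll, ll, B = 200, seed = 1)
  expect_equal(res$observed, 0)
  expect_true(all(res$permuted == 0))
  expect_equal(res$pvalue, 1)

  # systematically different models: permuted statistics dominate s
  set.seed(4)
  d <- rnorm(300, mean = 2, sd = 0.5)
  res2 <- permutation_variance_test(d, rep(0, 300), B = 500, seed = 2)
  expect_lt(res2$pvalue, 0.01)
  expect_gt(mean(res2$permuted > res2$observed), 0.99)

  # the +1/+1 correction keeps p-values strictly positive
  expect_gte(res2$pvalue, 1 / 501)
})

test_that("permutation p-values are reproducible from their seed", {
  set.seed(5)
  a <- rnorm(80)
  b <- a + rnorm(80, sd = 0.3)
  r1 <- permutation_variance_test(a, b, B = 150, seed = 7)
  r2 <- permutation_variance_test(a, b, B = 150, seed = 7)
  expect_identical(r1$pvalue, r2$pvalue)
  expect_identical(r1$permuted, r2$permuted)
})

test_that("information-equivalence testing is symmetric and sane on identical sets", {
  ds <- random_dataset(n = 300, p = 5, seed = 6)
  same <- ieq_test(ds, c(1L, 2L), c(2L, 1L))
  expect_true(same$equivalent)
  expect_equal(same$test_xy$pvalue, 1)
  expect_equal(same$test_yx$pvalue, 1)

  ab <- ieq_test(ds, c(1L, 3L), c(2L, 4L))
  ba <- ieq_test(ds, c(2L, 4L), c(1L, 3L))
  expect_equal(ab$test_xy$pvalue, ba$test_yx$pvalue, tolerance = 1e-12)
  expect_equal(ab$test_yx$pvalue, ba$test_xy$pvalue, tolerance = 1e-12)
})

test_that("planted near-copies are information equivalent, split signals are not", {
  accept <- 0L
  reject <- 0L
  for (s in 1:30) {
    set.seed(600 + s)
    n <- 1000
    L <- rnorm(n)
    x1 <- L + 1e-3 * rnorm(n)
    x2 <- L + 1e-3 * rnorm(n)
    w <- rnorm(n)
    y <- L + w + rnorm(n)
    ds <- eq_dataset(cbind(x1, x2, w), y, "continuous")
    if (ieq_test(ds, c(1L, 3L), c(2L, 3L), alpha_eq = 0.01)$equivalent) {
      accept <- accept + 1L
    }
    # {X, W} vs {Y, W} where T = X + Y + W: equally predictive but not
    # information equivalent (each adds signal given the other)
    xa <- rnorm(n); xb <- rnorm(n)
    y2 <- xa + xb + w + rnorm(n)
    ds2 <- eq_dataset(cbind(xa, xb, w), y2, "continuous")
    if (!ieq_test(ds2, c(1L, 3L), c(2L, 3L), alpha_eq = 0.05)$equivalent) {
      reject <- reject + 1L
    }
  }
  expect_gte(accept, 27L)
  expect_gte(reject, 27L)
})

test_that("the J-test separates equivalent from non-equivalent sets", {
  ds <- random_dataset(n = 300, p = 5, seed = 8)
  expect_true(jtest(ds, c(1L, 2L), c(1L, 2L))$equivalent)
  good <- 0L
  bad <- 0L
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 800
    L <- rnorm(n)
    x1 <- L + 1e-3 * rnorm(n)
    x2 <- L + 1e-3 * rnorm(n)
    noise <- rnorm(n)
    y <- L + rnorm(n)
    ds <- eq_dataset(cbind(x1, x2, noise), y, "continuous")
    if (jtest(ds, 1L, 2L, alpha_eq = 0.01)$equivalent) good <- good + 1L
    if (!jtest(ds, 1L, 3L, alpha_eq = 0.05)$equivalent) bad <- bad + 1L
  }
  expect_gte(good, 18L)
  expect_gte(bad, 18L)
})

test_that("the two-stage decision accepts twins and its monotonicity holds", {
  cfg <- search_config(alpha_eq = 0.01, n_permutations = 500, seed = 5)
  accept <- 0L
  for (s in 1:20) {
    gen <- generate_synthetic(synth_spec(
      n_samples = 2000, n_indispensable = 1, class_sizes = c(2L),
      n_redundant = 0, n_irrelevant = 2, seed = 800 + s))
    fam <- enumerate_true_solutions(gen$truth)$solutions
    v <- equivalence_decision(gen$dataset, fam[[2]], fam[[1]], cfg)
    if (v$equivalent) {
      accept <- accept + 1L
      expect_gte(v$peq_pvalue, cfg$alpha_eq)
      expect_gte(min(v$ieq_pvalue_xy, v$ieq_pvalue_yx), cfg$alpha_eq)
    }
  }
  expect_gte(accept, 17L)

  # candidate identical to the reference is trivially equivalent
  ds <- random_dataset(seed = 9)
  expect_true(equivalence_decision(ds, c(1L, 2L), c(1L, 2L), cfg)$equivalent)
})

test_that("a superset of the reference passes the decision (minimality is not its job)", {
  gen <- generate_synthetic(synth_spec(
    n_samples = 2000, n_indispensable = 2, class_sizes = integer(0),
    n_redundant = 0, n_irrelevant = 3, seed = 77))
  ref <- gen$truth$indispensable
  cand <- sort(c(ref, gen$truth$irrelevant[1]))
  v <- equivalence_decision(gen$dataset, cand, ref,
                            search_config(n_permutations = 500, seed = 77))
  expect_true(v$equivalent)
})

test_that("expected accuracy of the optimal rule matches exact enumeration", {
  expect_equal(bayes_expected_accuracy(toy_discrete("peq_accuracy_toy")), 0.75)
  det <- data.frame(x = c(0, 1), t = c(0, 1), p = c(0.5, 0.5))
  expect_equal(bayes_expected_accuracy(det), 1.0)
  coin <- data.frame(x = c(0, 0, 1, 1), t = c(0, 1, 0, 1), p = rep(0.25, 4))
  expect_equal(bayes_expected_accuracy(coin), 0.5)
  expect_error(bayes_expected_accuracy(data.frame(x = 1, t = 1, p = 2)),
               "sum to 1")
})
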