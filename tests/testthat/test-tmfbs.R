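test_that("failure cache maintains a minimal antichain", {
  cache <- new_failure_cache()
  expect_false(rule2_applies(cache, c(3L, 7L)))
  record_failure(cache, c(1L, 2L, 3L))
  record_failure(cache, c(1L, 2L))          # removes its stored superset
  expect_identical(cache$sets, list(c(1L, 2L)))
  record_failure(cache, c(1L, 2L, 9L))      # implied: no-op
  expect_identical(cache$sets, list(c(1L, 2L)))
  record_failure(cache, 5L)
  expect_true(rule2_applies(cache, c(2L, 1L, 4L)))
  expect_true(rule2_applies(cache, c(5L, 8L)))
  expect_false(rule2_applies(cache, c(2L, 4L)))
})

test_that("antichain pruning never changes rule-2 answers", {
  for (s in 1:20) {
    set.seed(s)
    cache <- new_failure_cache()
    naive <- list()
    for (i in 1:15) {
      e <- sort(sample(1:8, sample(1:4, 1)))
      record_failure(cache, e)
      naive[[length(naive) + 1L]] <- e
    }
    for (i in 1:20) {
      q <- sort(sample(1:8, sample(1:5, 1)))
      brute <- any(vapply(naive, function(e) all(e %in% q), logical(1)))
      expect_identical(rule2_applies(cache, q), brute)
    }
  }
})

test_that("a unique planted blanket yields a single-solution family", {
  gen <- generate_synthetic(synth_spec(
    n_samples = 2000, n_indispensable = 2, class_sizes = integer(0),
    n_redundant = 1, n_irrelevant = 3, seed = 42))
  cfg <- suite_config(seed = 42)
  res <- run_tmfbs(gen$dataset, cfg,
                   equivalence_fn = oracle_equivalence_fn(gen$truth))
  expect_identical(res$solutions$solutions,
                   list(run_tfbs(gen$dataset, cfg)))
  expect_false(res$stats$limit_hit)
})

test_that("planted equivalence classes of sizes 2 and 3 give all 6 solutions", {
  gen <- generate_synthetic(synth_spec(
    n_samples = 2000, n_indispensable = 2, class_sizes = c(2L, 3L),
    n_redundant = 0, n_irrelevant = 3, seed = 11))
  res <- run_tmfbs(gen$dataset, suite_config(seed = 11),
                   equivalence_fn = oracle_equivalence_fn(gen$truth))
  expect_length(res$solutions$solutions, 6L)
  expect_identical(family_keys(res$solutions),
                   family_keys(enumerate_true_solutions(gen$truth)))
})

test_that("the first solution of the search is the reference of the template", {
  for (s in c(3, 8)) {
    gen <- generate_synthetic(synth_spec(
      n_samples = 1500, n_indispensable = 1, class_sizes = c(2L),
      n_redundant = 1, n_irrelevant = 3, seed = s))
    cfg <- suite_config(seed = s)
    res <- run_tmfbs(gen$dataset, cfg,
                     equivalence_fn = oracle_equivalence_fn(gen$truth))
    expect_identical(reference_solution(res$solutions),
                     run_tfbs(gen$dataset, cfg))
  }
})

test_that("pruning rules change the work done but never the family", {
  gen <- generate_synthetic(synth_spec(
    n_samples = 2000, n_indispensable = 2, class_sizes = c(2L, 2L),
    n_redundant = 1, n_irrelevant = 3, seed = 21))
  eqfn <- oracle_equivalence_fn(gen$truth)
  run_with <- function(...) {
    cfg <- suite_config(seed = 21, ...)
    counter <- new_test_counter()
    res <- run_tmfbs(gen$dataset, cfg, eqfn, counter)
    list(keys = family_keys(res$solutions), tests = res$stats$ci_tests_search)
  }
  full <- run_with()
  none <- run_with(prune1 = FALSE, prune2 = FALSE, prune3 = FALSE)
  expect_identical(full$keys, none$keys)
  expect_lte(full$tests, none$tests)
})

test_that("no selected-set state is ever visited twice", {
  for (s in c(5, 13)) {
    gen <- generate_synthetic(synth_spec(
      n_samples = 1500, n_indispensable = 1, class_sizes = c(3L),
      n_redundant = 1, n_irrelevant = 3, seed = s))
    res <- run_tmfbs(gen$dataset,
                     suite_config(seed = s, track_states = TRUE,
                                  prune1 = FALSE, prune2 = FALSE,
                                  prune3 = FALSE),
                     equivalence_fn = oracle_equivalence_fn(gen$truth))
    expect_identical(anyDuplicated(res$stats$states), 0L)
  }
})

test_that("solution and state limits are reported, not raised", {
  gen <- generate_synthetic(synth_spec(
    n_samples = 1500, n_indispensable = 1, class_sizes = c(3L),
    n_redundant = 0, n_irrelevant = 2, seed = 31))
  res <- run_tmfbs(gen$dataset, suite_config(seed = 31, max_solutions = 1L),
                   equivalence_fn = oracle_equivalence_fn(gen$truth))
  expect_length(res$solutions$solutions, 1L)
  expect_true(res$stats$limit_hit)

  res2 <- run_tmfbs(gen$dataset,
                    suite_config(seed = 31, max_visited_states = 2L),
                    equivalence_fn = oracle_equivalence_fn(gen$truth))
  expect_true(res2$stats$limit_hit)
})
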