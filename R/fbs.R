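#' Search configuration
#'
#' @param alpha significance level of the search conditional-independence
#'   tests, in (0, 1].
#' @param alpha_eq significance level of the equivalence tests.
#' @param n_permutations number of permutations B of the variance test
#'   (at least 100; 1000 matches the reference experimental setup).
#' @param max_solutions cap on the number of returned solutions.
#' @param max_visited_states cap on the number of search states visited.
#' @param seed integer seed controlling every random choice made during a
#'   search (permutation draws of the equivalence tests).
#' @param prune1,prune2,prune3 enable the three pruning rules of the
#'   multiple-solutions search.
#' @param track_states record the selected-set signature of every visited
#'   state in the run statistics (instrumentation for state-repetition
#'   checks).
#' @return A list of class `search_config`.
#' @export
search_config <- function(alpha = 0.05, alpha_eq = 0.05, n_permutations = 1000L,
                          max_solutions = 1000L,
                          max_visited_states = 100L * max_solutions,
                          seed = 1L, prune1 = TRUE, prune2 = TRUE,
                          prune3 = TRUE, track_states = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, alpha_eq > 0, alpha_eq <= 1,
            n_permutations >= 100L, max_solutions >= 1L,
            max_visited_states >= 1L)
  structure(list(alpha = alpha, alpha_eq = alpha_eq,
                 n_permutations = as.integer(n_permutations),
                 max_solutions = as.integer(max_solutions),
                 max_visited_states = as.integer(max_visited_states),
                 seed = as.integer(seed), prune1 = isTRUE(prune1),
                 prune2 = isTRUE(prune2), prune3 = isTRUE(prune3),
                 track_states = isTRUE(track_states)),
            class = "search_config")
}

test_pvalue <- function(res) {
  # flagged/degenerate tests are treated conservatively as p = 1
  if (isTRUE(res$degenerate)) 1 else res$pvalue
}

#' Candidate ordering for forward selection
#'
#' Runs one CI test per active, non-selected feature given the selected set,
#' and returns the features with p-value below `alpha` in ascending p-value
#' order (ties broken by lower base-dataset index). This ordering is
#' admissible for the search template: it is empty when nothing more should
#' be selected, is disjoint from the selected set, and lists every feature
#' that could be selected at this iteration in order of preference.
#'
#' @param view an `eq_dataset` or `eq_view`.
#' @param selected integer vector of currently selected (active) features.
#' @param config a [search_config()].
#' @param counter optional [new_test_counter()].
#' @return A list of class `fbs_ordering` with parallel `features` and
#'   `pvalues`.
#' @export
order_variables_fbs <- function(view, selected, config, counter = NULL) {
  v <- as_view(view)
  cand <- setdiff(active_features(v), selected)
  pv <- vapply(cand, function(ci) {
    test_pvalue(ci_test(v, ci, selected, counter, purpose = "search"))
  }, numeric(1))
  keep <- pv < config$alpha
  cand <- cand[keep]
  pv <- pv[keep]
  o <- order(pv, cand)
  structure(list(features = cand[o], pvalues = pv[o]), class = "fbs_ordering")
}

#' Backward phase of forward-backward selection
#'
#' Repeatedly removes the selected feature with the highest conditional
#' p-value (given the other selected features) that is strictly above
#' `alpha`, until every survivor is significant given the rest.
#'
#' @inheritParams order_variables_fbs
#' @return Integer vector: the surviving selected features, sorted.
#' @export
backward_phase_fbs <- function(view, selected, config, counter = NULL) {
  v <- as_view(view)
  selected <- sort(as.integer(selected))
  repeat {
    if (length(selected) == 0L) break
    pv <- vapply(seq_along(selected), function(i) {
      test_pvalue(ci_test(v, selected[i], selected[-i], counter,
                          purpose = "search"))
    }, numeric(1))
    worst <- max(pv)
    if (worst <= config$alpha) break
    drop_i <- which(pv == worst)[1L]  # ties: lowest index leaves first
    selected <- selected[-drop_i]
  }
  selected
}

#' Single-solution forward-backward selection
#'
#' The greedy template: starting from the empty set, repeatedly order the
#' remaining candidates and select the top one until the ordering is empty;
#' then apply one backward pass to remove false positives. The result is the
#' reference solution for the multiple-solutions search.
#'
#' @param dataset an [eq_dataset()] (or an embedded view of one).
#' @param config a [search_config()].
#' @param counter optional [new_test_counter()].
#' @param order_fn,backward_fn an admissible ordering/backward-phase pair
#'   with the signatures of [order_variables_fbs()] and
#'   [backward_phase_fbs()]; the defaults instantiate the template as
#'   forward-backward selection.
#' @return Integer vector of selected feature indices, sorted (possibly
#'   empty).
#' @export
run_tfbs <- function(dataset, config = search_config(), counter = NULL,
                     order_fn = order_variables_fbs,
                     backward_fn = backward_phase_fbs) {
  v <- as_view(dataset)
  selected <- integer(0)
  repeat {
    ord <- order_fn(v, selected, config, counter)
    if (length(ord$features) == 0L) break
    selected <- c(selected, ord$features[1L])
  }
  backward_fn(v, selected, config, counter)
}
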