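#' IGS embedded-dataset generator
#'
#' For every solution `S_j` found under exclusion set `E_j`, proposes the
#' exclusion sets `E_j + {X}` for each `X` in `S_j`. Proposals that were
#' already processed, or that extend a recorded failed exclusion set, are
#' filtered out. Survivors are returned deduplicated in deterministic order
#' (by size, then lexicographically).
#'
#' @param solutions list of integer feature-index vectors.
#' @param exclusions parallel list: the exclusion set each solution was
#'   found under.
#' @param processed character vector of keys (see [solution_key] semantics)
#'   of exclusion sets already run.
#' @param cache a [new_failure_cache()].
#' @return List of integer exclusion sets.
#' @export
igs_generate <- function(solutions, exclusions, processed,
                         cache = new_failure_cache()) {
  stopifnot(length(solutions) == length(exclusions))
  props <- list()
  for (j in seq_along(solutions)) {
    for (x in solutions[[j]]) {
      props[[length(props) + 1L]] <- sort(unique(c(exclusions[[j]], x)))
    }
  }
  if (length(props) == 0L) return(list())
  keys <- vapply(props, solution_key, character(1))
  keep <- !duplicated(keys) & !(keys %in% processed)
  props <- props[keep]
  keep2 <- vapply(props, function(e) !rule2_applies(cache, e), logical(1))
  props <- props[keep2]
  ord <- order(lengths(props),
               vapply(props, function(e) {
                 paste(formatC(e, width = 8L, flag = "0"), collapse = ",")
               }, character(1)))
  props[ord]
}

#' TIE* with the IGS generator (baseline multiple-solutions search)
#'
#' Finds the reference solution with [run_tfbs()] on the full dataset, then
#' repeatedly reruns the full single-solution algorithm on embedded datasets
#' proposed by [igs_generate()]: for each new equivalent solution, the
#' exclusion sets removing one of its members are queued. An embedded
#' dataset that yields no equivalent solution has its exclusion set recorded
#' as failed, which blocks all supersets. No exclusion set is run more than
#' once. The worklist is FIFO over proposal batches, each batch sorted by
#' (size, lexicographic order).
#'
#' Shares the CI tests, configuration and equivalence decision with
#' [run_tmfbs()], so the search-test counters of the two algorithms are
#' directly comparable.
#'
#' @inheritParams run_tmfbs
#' @return A list with `solutions` (a [solution_set()], reference first) and
#'   `stats` as in [run_tmfbs()] (`nodes_visited` counts single-solution
#'   runs).
#' @export
run_tie_star_igs <- function(dataset, config = search_config(),
                             equivalence_fn = NULL, counter = NULL) {
  v <- as_view(dataset)
  if (is.null(counter)) counter <- new_test_counter()
  if (is.null(equivalence_fn)) {
    equivalence_fn <- make_equivalence_fn(v, config, counter)
  }
  snap <- ci_counts(counter)
  cache <- new_failure_cache()

  base_E <- sort(v$excluded)
  ref <- run_tfbs(v, config, counter)
  nodes <- 1L
  M <- list(ref)
  Mkeys <- solution_key(ref)
  excl <- list(base_E)
  processed <- solution_key(base_E)
  limit <- FALSE

  worklist <- igs_generate(M, excl, processed, cache)
  while (length(worklist) > 0L) {
    if (length(M) >= config$max_solutions || nodes >= config$max_visited_states) {
      limit <- TRUE
      break
    }
    E <- worklist[[1L]]
    worklist <- worklist[-1L]
    key <- solution_key(E)
    if (key %in% processed) next
    if (rule2_applies(cache, E)) next  # cache may have grown since queuing
    processed <- c(processed, key)
    nodes <- nodes + 1L
    cand <- run_tfbs(embed_view(v, setdiff(E, v$excluded)), config, counter)
    ckey <- solution_key(cand)
    if (length(cand) > 0L && ckey %in% Mkeys) {
      next  # equivalent solution rediscovered: neither a failure nor new
    }
    if (length(cand) > 0L && isTRUE(equivalence_fn(cand, ref))) {
      M[[length(M) + 1L]] <- cand
      Mkeys <- c(Mkeys, ckey)
      excl[[length(excl) + 1L]] <- E
      worklist <- c(worklist,
                    igs_generate(list(cand), list(E), processed, cache))
    } else {
      record_failure(cache, E)
    }
  }

  counts <- ci_counts(counter) - snap
  list(solutions = solution_set(M),
       stats = list(nodes_visited = nodes,
                    ci_tests_search = unname(counts["search"]),
                    ci_tests_equiv = unname(counts["equiv"]),
                    solutions_found = length(M),
                    limit_hit = limit))
}
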