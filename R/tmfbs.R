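#' Failure cache of exclusion sets
#'
#' Stores exclusion sets whose embedded datasets yielded no equivalent
#' solution. Since no equivalent solution can exist in any further-embedded
#' dataset either, the cache is kept as a minimal antichain: inserting a set
#' discards any stored superset, and inserting a superset of a stored set is
#' a no-op.
#'
#' @return An environment of class `failure_cache` holding a list of
#'   feature-index sets.
#' @export
new_failure_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$sets <- list()
  class(e) <- "failure_cache"
  e
}

#' @export
print.failure_cache <- function(x, ...) {
  cat(sprintf("<failure_cache> %d failed exclusion set(s)\n", length(x$sets)))
  invisible(x)
}

#' Pruning Rule 2 predicate
#'
#' True when some recorded failed exclusion set is a subset of `exclusion`:
#' the state about to be explored lives inside a dataset already known to
#' contain no equivalent solution.
#'
#' @param cache a [new_failure_cache()].
#' @param exclusion integer vector of excluded feature indices.
#' @return Logical.
#' @export
rule2_applies <- function(cache, exclusion) {
  exclusion <- as.integer(exclusion)
  for (s in cache$sets) {
    if (all(s %in% exclusion)) return(TRUE)
  }
  FALSE
}

#' Record a failed exclusion set
#'
#' Call after the subtree rooted at the state with this total exclusion set
#' yielded no equivalent solution. Maintains the antichain invariant.
#'
#' @inheritParams rule2_applies
#' @return The cache, invisibly.
#' @export
record_failure <- function(cache, exclusion) {
  exclusion <- sort(unique(as.integer(exclusion)))
  for (s in cache$sets) {
    if (all(s %in% exclusion)) return(invisible(cache))  # already implied
  }
  keep <- vapply(cache$sets, function(s) !all(exclusion %in% s), logical(1))
  cache$sets <- c(cache$sets[keep], list(exclusion))
  invisible(cache)
}

#' Default equivalence decision function for the searches
#'
#' Wraps [equivalence_decision()] over the full dataset with a permutation
#' seed derived deterministically from the configuration seed and the
#' candidate set, so identical candidates receive identical verdicts across
#' algorithms and reruns.
#'
#' @param dataset an [eq_dataset()].
#' @param config a [search_config()].
#' @param counter optional [new_test_counter()].
#' @return A `function(candidate, reference)` returning a logical.
#' @export
make_equivalence_fn <- function(dataset, config, counter = NULL) {
  v <- as_view(dataset)
  function(candidate, reference) {
    equivalence_decision(v, candidate, reference, config, counter)$equivalent
  }
}

#' Multiple-solutions forward-backward search (TMFBS)
#'
#' Backtracking extension of [run_tfbs()]: instead of following only the top
#' candidate at each step, every candidate spawns a child state, and each
#' candidate already tried is excluded from all subsequent sibling states so
#' that no set of selected features is ever visited twice. Leaves (states
#' with an empty candidate ordering) run the backward phase and yield a
#' candidate solution; the first one is the reference solution (identical to
#' the [run_tfbs()] output) and later ones join the family if the
#' equivalence decision accepts them against the reference.
#'
#' Three sound pruning rules cut the search: (1) if a child subtree
#' contributes no new equivalent solution, the remaining siblings are
#' abandoned and the child's exclusion set is recorded as failed; (2) a
#' state whose exclusion set contains a recorded failed set is not explored;
#' (3) if a child subtree contributed solutions but none contains the
#' variable selected into it, the remaining siblings are abandoned. Rules
#' 1 and 3 are applied when a child returns, Rule 2 before the descent.
#'
#' The search is depth-first with an explicit frame stack. It stops when
#' exhausted or when `max_solutions` / `max_visited_states` is reached
#' (reported via `limit_hit`, never an error).
#'
#' @param dataset an [eq_dataset()].
#' @param config a [search_config()].
#' @param equivalence_fn `function(candidate, reference) -> logical`;
#'   defaults to [make_equivalence_fn()] on `dataset`.
#' @param counter optional [new_test_counter()]; created if missing.
#' @param order_fn,backward_fn an admissible ordering/backward-phase pair,
#'   as in [run_tfbs()]; defaults instantiate forward-backward selection.
#' @return A list with `solutions` (a [solution_set()], reference first) and
#'   `stats` (`nodes_visited`, `ci_tests_search`, `ci_tests_equiv`,
#'   `solutions_found`, `limit_hit`, and `states` when
#'   `config$track_states`).
#' @export
run_tmfbs <- function(dataset, config = search_config(),
                      equivalence_fn = NULL, counter = NULL,
                      order_fn = order_variables_fbs,
                      backward_fn = backward_phase_fbs) {
  v <- as_view(dataset)
  if (is.null(counter)) counter <- new_test_counter()
  if (is.null(equivalence_fn)) {
    equivalence_fn <- make_equivalence_fn(v, config, counter)
  }
  snap <- ci_counts(counter)

  st <- new.env(parent = emptyenv())
  st$M <- list()
  st$Mkeys <- character(0)
  st$ref <- NULL
  st$cache <- new_failure_cache()
  st$nodes <- 0L
  st$limit <- FALSE
  st$states <- character(0)

  add_candidate <- function(candidate) {
    # returns 1L if the candidate enters the family as a new solution
    if (is.null(st$ref)) {
      st$ref <- candidate
      accepted <- TRUE
    } else {
      key <- solution_key(candidate)
      if (key %in% st$Mkeys) return(0L)   # duplicate: not new for the rules
      accepted <- isTRUE(equivalence_fn(candidate, st$ref))
    }
    if (!accepted) return(0L)
    st$M[[length(st$M) + 1L]] <- candidate
    st$Mkeys <- c(st$Mkeys, solution_key(candidate))
    1L
  }

  frames <- list()
  new_frame <- function(E, Sp, parent, sel_var) {
    st$nodes <- st$nodes + 1L
    if (config$track_states) {
      st$states <- c(st$states, paste(sort(Sp), collapse = ","))
    }
    f <- new.env(parent = emptyenv())
    f$E <- E; f$Sp <- Sp; f$parent <- parent; f$sel_var <- sel_var
    f$m_start <- length(st$M)
    f$newc <- 0L
    f$stopped <- FALSE
    f$i <- 1L
    view_E <- embed_view(v, setdiff(E, v$excluded))
    ord <- order_fn(view_E, Sp, config, counter)
    f$C <- ord$features
    if (length(f$C) == 0L) {
      candidate <- backward_fn(view_E, Sp, config, counter)
      f$newc <- add_candidate(candidate)
    }
    f
  }

  frames[[1L]] <- new_frame(sort(v$excluded), integer(0), NA_integer_, NA_integer_)
  while (length(frames) > 0L) {
    f <- frames[[length(frames)]]
    if (length(st$M) >= config$max_solutions && !st$limit &&
        f$i <= length(f$C) && !f$stopped) {
      st$limit <- TRUE
    }
    if (st$limit) f$stopped <- TRUE
    if (f$stopped || f$i > length(f$C)) {
      # frame finished: pop and apply Rules 1 and 3 in its parent
      frames[[length(frames)]] <- NULL
      p <- f$parent
      if (!is.na(p)) {
        parent <- frames[[p]]
        parent$newc <- parent$newc + f$newc
        if (f$newc == 0L && !st$limit) {
          record_failure(st$cache, f$E)   # Corollary-1 bookkeeping
          if (config$prune1) parent$stopped <- TRUE
        } else if (f$newc > 0L && config$prune3) {
          subtree <- st$M[seq.int(f$m_start + 1L, length(st$M))]
          if (!any(vapply(subtree, function(s) f$sel_var %in% s, logical(1)))) {
            parent$stopped <- TRUE
          }
        }
      }
      next
    }
    i <- f$i
    f$i <- i + 1L
    E_child <- sort(c(f$E, f$C[seq_len(i - 1L)]))
    if (config$prune2 && rule2_applies(st$cache, E_child)) {
      f$stopped <- TRUE
      next
    }
    if (st$nodes >= config$max_visited_states) {
      st$limit <- TRUE
      f$stopped <- TRUE
      next
    }
    frames[[length(frames) + 1L]] <-
      new_frame(E_child, c(f$Sp, f$C[i]), length(frames), f$C[i])
  }

  counts <- ci_counts(counter) - snap
  stats <- list(nodes_visited = st$nodes,
                ci_tests_search = unname(counts["search"]),
                ci_tests_equiv = unname(counts["equiv"]),
                solutions_found = length(st$M),
                limit_hit = st$limit)
  if (config$track_states) stats$states <- st$states
  list(solutions = solution_set(st$M), stats = stats)
}
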