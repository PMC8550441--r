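#' Specification of a synthetic blanket-discovery problem
#'
#' Describes a linear-Gaussian (or logistic) data-generating process with a
#' known family of Markov blankets. Each equivalence class is realised as a
#' latent standard-normal variable with several observed near-copies
#' (`member = latent + epsilon * noise`), so that any single member screens
#' off the others; indispensable features are independent standard normals;
#' the outcome is linear in the indispensable features and the class latents
#' (plus unit Gaussian noise, or a logistic link for binary outcomes).
#' Redundant features are high-noise copies of an indispensable feature or
#' class latent: marginally informative but screened off by their anchor,
#' hence in no minimal solution. Irrelevant features are independent noise.
#' Column order is shuffled by the seed.
#'
#' @param n_samples number of rows.
#' @param n_indispensable number of features present in every solution.
#' @param class_sizes integer vector: sizes of the equivalence classes
#'   (each class contributes one member per solution).
#' @param n_redundant number of redundant features.
#' @param n_irrelevant number of irrelevant features.
#' @param epsilon standard deviation of the copy noise inside a class
#'   (near-deterministic copies by default; exact copies would make the
#'   covariance singular).
#' @param beta coefficient magnitude of every blanket term in the outcome.
#' @param outcome `"continuous"` or `"binary"`.
#' @param seed integer seed; identical specs generate identical data.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 2000L, n_indispensable = 2L,
                       class_sizes = c(2L), n_redundant = 1L,
                       n_irrelevant = 2L, epsilon = 1e-3, beta = 1,
                       outcome = c("continuous", "binary"), seed = 1L) {
  outcome <- match.arg(outcome)
  stopifnot(n_samples >= 10L, n_indispensable >= 0L, n_redundant >= 0L,
            n_irrelevant >= 0L, epsilon > 0, all(class_sizes >= 1L))
  if (n_redundant > 0L && n_indispensable == 0L && length(class_sizes) == 0L) {
    stop("redundant features need an indispensable feature or class to anchor on")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_indispensable = as.integer(n_indispensable),
                 class_sizes = as.integer(class_sizes),
                 n_redundant = as.integer(n_redundant),
                 n_irrelevant = as.integer(n_irrelevant),
                 epsilon = epsilon, beta = beta, outcome = outcome,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic dataset with known ground truth
#'
#' @param spec a [synth_spec()].
#' @return A list with `dataset` (an [eq_dataset()]) and `truth` (class
#'   `ground_truth`: `indispensable`, `classes`, `redundant`, `irrelevant`,
#'   all as feature indices of the shuffled dataset, partitioning the
#'   feature universe).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_samples
  a <- spec$n_indispensable
  ks <- spec$class_sizes
  p <- a + sum(ks) + spec$n_redundant + spec$n_irrelevant

  with_seed(spec$seed, {
    ind <- if (a > 0L) matrix(stats::rnorm(n * a), n, a) else NULL
    latents <- lapply(ks, function(k) stats::rnorm(n))
    members <- list()
    for (j in seq_along(ks)) {
      for (m in seq_len(ks[j])) {
        members[[length(members) + 1L]] <-
          latents[[j]] + spec$epsilon * stats::rnorm(n)
      }
    }
    lp <- rep(0, n)
    if (a > 0L) lp <- lp + spec$beta * rowSums(ind)
    for (L in latents) lp <- lp + spec$beta * L
    y <- if (spec$outcome == "continuous") lp + stats::rnorm(n)
         else stats::rbinom(n, 1L, stats::plogis(lp))
    anchors <- c(if (a > 0L) lapply(seq_len(a), function(j) ind[, j]),
                 latents)
    red <- list()
    for (j in seq_len(spec$n_redundant)) {
      anc <- anchors[[((j - 1L) %% length(anchors)) + 1L]]
      red[[j]] <- anc + stats::rnorm(n)
    }
    irr <- if (spec$n_irrelevant > 0L)
      matrix(stats::rnorm(n * spec$n_irrelevant), n, spec$n_irrelevant)
      else NULL

    cols <- c(if (a > 0L) lapply(seq_len(a), function(j) ind[, j]),
              members, red,
              if (spec$n_irrelevant > 0L)
                lapply(seq_len(spec$n_irrelevant), function(j) irr[, j]))
    Xc <- do.call(cbind, cols)
    pos <- sample.int(p)        # canonical column i lands at column pos[i]
    X <- matrix(0, n, p)
    X[, pos] <- Xc
  })

  class_idx <- list()
  off <- a
  for (j in seq_along(ks)) {
    class_idx[[j]] <- sort(pos[off + seq_len(ks[j])])
    off <- off + ks[j]
  }
  truth <- structure(
    list(indispensable = sort(pos[seq_len(a)]),
         classes = class_idx,
         redundant = sort(pos[a + sum(ks) + seq_len(spec$n_redundant)]),
         irrelevant = sort(pos[a + sum(ks) + spec$n_redundant +
                                 seq_len(spec$n_irrelevant)])),
    class = "ground_truth")
  ds <- eq_dataset(X, y, spec$outcome,
                   feature_names = paste0("F", seq_len(p)))
  list(dataset = ds, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat("  indispensable:", paste(x$indispensable, collapse = ", "), "\n")
  for (j in seq_along(x$classes)) {
    cat(sprintf("  class %d: %s\n", j, paste(x$classes[[j]], collapse = ", ")))
  }
  cat("  redundant:", paste(x$redundant, collapse = ", "), "\n")
  cat("  irrelevant:", paste(x$irrelevant, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate the true solution family of a synthetic ground truth
#'
#' The Cartesian product: every solution consists of all indispensable
#' features plus exactly one member of each equivalence class, giving
#' `prod(class sizes)` solutions (one when there are no classes).
#'
#' @param truth a `ground_truth` from [generate_synthetic()].
#' @return A [solution_set()].
#' @export
enumerate_true_solutions <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(truth$classes) == 0L) {
    return(solution_set(list(truth$indispensable)))
  }
  combos <- expand.grid(truth$classes, KEEP.OUT.ATTRS = FALSE)
  sols <- lapply(seq_len(nrow(combos)), function(i) {
    sort(c(truth$indispensable, as.integer(unlist(combos[i, ]))))
  })
  solution_set(sols)
}

#' Printed toy discrete distributions
#'
#' Two small joint distributions used to study equivalence notions on paper:
#' `peq_accuracy_toy` is the binary pair with P(T=1|X=1) = 0.9,
#' P(T=1|X=0) = 0.6, P(X=1) = 0.5 (the accuracy-optimal rule ignores X, so
#' accuracy cannot separate \{X\} from the empty set); `xor_toy` has fair
#' independent binary W, X, Y and T = W OR (X XOR Y) (X alone carries no
#' information about T, yet \{X, W\} and \{Y, W\} differ informationally).
#'
#' @param name `"peq_accuracy_toy"` or `"xor_toy"`.
#' @return Data frame with feature columns, outcome column `t` and
#'   probability column `p` (summing to one).
#' @export
toy_discrete <- function(name = c("peq_accuracy_toy", "xor_toy")) {
  name <- match.arg(name)
  if (name == "peq_accuracy_toy") {
    return(data.frame(x = c(1, 1, 0, 0), t = c(1, 0, 1, 0),
                      p = c(0.5 * 0.9, 0.5 * 0.1, 0.5 * 0.6, 0.5 * 0.4)))
  }
  grid <- expand.grid(w = 0:1, x = 0:1, y = 0:1, t = 0:1,
                      KEEP.OUT.ATTRS = FALSE)
  tt <- as.integer(grid$w | xor(grid$x, grid$y))
  grid$p <- ifelse(grid$t == tt, 1 / 8, 0)
  grid
}
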