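#' Construct a dataset for blanket discovery
#'
#' Bundles a numeric feature matrix with an outcome vector. Features are
#' addressed by integer column index everywhere inside the package; names are
#' only used at I/O boundaries.
#'
#' @param X numeric matrix, samples in rows, features in columns.
#' @param y outcome vector, length `nrow(X)`. Continuous, or binary in {0,1}.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param feature_names optional character vector of unique feature names;
#'   defaults to `colnames(X)` or `F1..Fp`.
#'
#' @return An object of class `eq_dataset` with elements `X`, `y`,
#'   `outcome_type`, `feature_names` and an internal cache environment.
#' @export
eq_dataset <- function(X, y, outcome_type = c("continuous", "binary"),
                       feature_names = NULL) {
  outcome_type <- match.arg(outcome_type)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) < 10L) stop("at least 10 samples are required")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  if (is.null(feature_names)) {
    feature_names <- colnames(X)
    # matrices assembled with cbind() often carry empty or repeated names;
    # only explicitly supplied names are held to the uniqueness contract
    if (is.null(feature_names) || any(!nzchar(feature_names)) ||
        anyDuplicated(feature_names)) {
      feature_names <- paste0("F", seq_len(ncol(X)))
    }
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(X)) {
    stop("feature_names length must equal ncol(X)")
  }
  dup <- feature_names[duplicated(feature_names)]
  if (length(dup) > 0L) {
    stop("duplicate feature names: ", paste(unique(dup), collapse = ", "))
  }
  if (outcome_type == "binary") {
    if (!all(y %in% c(0, 1))) stop("binary outcome must take values in {0,1}")
    if (length(unique(y)) < 2L) stop("binary outcome is constant")
  }
  colnames(X) <- feature_names
  structure(
    list(X = X, y = y, outcome_type = outcome_type,
         feature_names = feature_names, cache = new.env(parent = emptyenv())),
    class = "eq_dataset"
  )
}

#' @export
print.eq_dataset <- function(x, ...) {
  cat(sprintf("<eq_dataset> %d samples x %d features, %s outcome\n",
              nrow(x$X), ncol(x$X), x$outcome_type))
  invisible(x)
}

n_features <- function(dataset) ncol(dataset$X)
n_samples <- function(dataset) nrow(dataset$X)

#' Read a tabular dataset from CSV/TSV
#'
#' Comma-separated with a mandatory header row and `.` decimal; tab-separated
#' is auto-detected from a `.tsv` extension. One column is designated as the
#' outcome; all remaining columns become features in file order.
#'
#' @param path file path.
#' @param target name of the outcome column.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return An [eq_dataset()].
#' @export
read_dataset <- function(path, target, outcome_type = c("continuous", "binary")) {
  outcome_type <- match.arg(outcome_type)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  nms <- names(df)
  dup <- nms[duplicated(nms)]
  if (length(dup) > 0L) {
    stop("duplicate column name in header: ", paste(unique(dup), collapse = ", "))
  }
  if (!(target %in% nms)) stop("target column not found: ", target)
  num <- vector("list", length(nms))
  for (j in seq_along(nms)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]))
    if (length(bad) > 0L || anyNA(df[[j]])) {
      row <- if (length(bad) > 0L) bad[1L] else which(is.na(df[[j]]))[1L]
      stop(sprintf("non-numeric value at row %d, column '%s'", row, nms[j]))
    }
    num[[j]] <- v
  }
  names(num) <- nms
  y <- num[[target]]
  keep <- setdiff(nms, target)
  X <- do.call(cbind, num[keep])
  colnames(X) <- keep
  eq_dataset(X, y, outcome_type, feature_names = keep)
}

#' Write a dataset to CSV/TSV
#'
#' Inverse of [read_dataset()]: features in order, outcome appended as the
#' last column.
#'
#' @param dataset an [eq_dataset()].
#' @param path output path; `.tsv` extension selects tab separation.
#' @param target name to use for the outcome column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, target = "outcome") {
  stopifnot(inherits(dataset, "eq_dataset"))
  if (target %in% dataset$feature_names) {
    stop("target name collides with a feature name: ", target)
  }
  df <- as.data.frame(dataset$X, check.names = FALSE)
  df[[target]] <- dataset$y
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Embedded (exclusion-set) view of a dataset
#'
#' An embedded view removes a set of features from consideration without
#' copying the data: many views share one base matrix. Views compose —
#' embedding a view unions the exclusion sets.
#'
#' @param view an `eq_dataset` or `eq_view`.
#' @param exclude integer indices (into the base dataset) to exclude; must be
#'   active in `view`.
#' @return An object of class `eq_view` with elements `base` and `excluded`.
#' @export
embed_view <- function(view, exclude = integer(0)) {
  v <- as_view(view)
  exclude <- as.integer(exclude)
  if (length(exclude) > 0L) {
    act <- active_features(v)
    bad <- setdiff(exclude, act)
    if (length(bad) > 0L) {
      stop("cannot exclude features not active in the view: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(base = v$base, excluded = sort(unique(c(v$excluded, exclude)))),
            class = "eq_view")
}

as_view <- function(view) {
  if (inherits(view, "eq_view")) return(view)
  if (inherits(view, "eq_dataset")) {
    return(structure(list(base = view, excluded = integer(0)), class = "eq_view"))
  }
  stop("expected an eq_dataset or eq_view")
}

#' Active features of a view
#'
#' @param view an `eq_dataset` or `eq_view`.
#' @return Integer indices of active features, in base-dataset order.
#' @export
active_features <- function(view) {
  v <- as_view(view)
  setdiff(seq_len(n_features(v$base)), v$excluded)
}

#' @export
print.eq_view <- function(x, ...) {
  cat(sprintf("<eq_view> %d of %d features active (%d excluded)\n",
              length(active_features(x)), n_features(x$base),
              length(x$excluded)))
  invisible(x)
}

# ---- solution sets ---------------------------------------------------------

#' Solution set (family of equivalent feature sets)
#'
#' The first element is the reference solution found by the single-solution
#' algorithm; every other element passed the equivalence decision against it.
#'
#' @param solutions list of feature-index (or feature-name) vectors; each is
#'   stored sorted and duplicate-free. All must be distinct as sets.
#' @return An object of class `solution_set`.
#' @export
solution_set <- function(solutions) {
  solutions <- lapply(solutions, function(s) sort(unique(s)))
  keys <- vapply(solutions, function(s) paste(s, collapse = ","), character(1))
  if (anyDuplicated(keys)) stop("solutions must be distinct as sets")
  structure(list(solutions = solutions), class = "solution_set")
}

#' @export
print.solution_set <- function(x, ...) {
  cat(sprintf("<solution_set> %d solution(s)\n", length(x$solutions)))
  for (i in seq_along(x$solutions)) {
    tag <- if (i == 1L) " (reference)" else ""
    cat(sprintf("  [%d] {%s}%s\n", i,
                paste(x$solutions[[i]], collapse = ", "), tag))
  }
  invisible(x)
}

#' Reference solution of a solution set
#' @param solset a [solution_set()].
#' @return The first (reference) solution.
#' @export
reference_solution <- function(solset) {
  stopifnot(inherits(solset, "solution_set"))
  if (length(solset$solutions) == 0L) return(NULL)
  solset$solutions[[1L]]
}

solution_key <- function(s) paste(sort(unique(s)), collapse = ",")

same_family <- function(a, b) {
  ka <- sort(vapply(a$solutions, solution_key, character(1)))
  kb <- sort(vapply(b$solutions, solution_key, character(1)))
  identical(ka, kb)
}

#' Write a solution family as JSON
#'
#' Schema `equiset-solutions-v1`: a list of lists of feature names, first
#' entry the reference solution.
#'
#' @param solset a [solution_set()] of integer feature indices.
#' @param path output path.
#' @param feature_names names used to translate indices; if `NULL` the
#'   solutions are assumed to already hold names.
#' @return `path`, invisibly.
#' @export
write_solutions <- function(solset, path, feature_names = NULL) {
  stopifnot(inherits(solset, "solution_set"))
  sols <- lapply(solset$solutions, function(s) {
    if (is.null(feature_names)) as.character(s) else feature_names[s]
  })
  obj <- list(schema = "equiset-solutions-v1", solutions = sols)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a solution family from JSON
#'
#' @param path a file written by [write_solutions()].
#' @return A [solution_set()] of character feature-name vectors.
#' @export
read_solutions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$schema) || obj$schema != "equiset-solutions-v1") {
    stop("not an equiset-solutions-v1 file: ", path)
  }
  solution_set(lapply(obj$solutions, function(s) unlist(lapply(s, as.character))))
}
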