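#' @name msg
#' @title Multiple-solutions graph
#'
#' @description
#' A solution family is compactly represented as a single-root,
#' single-leaf directed acyclic graph: every inner node carries one or more
#' feature sets, and every root-to-leaf path, with one feature-set choice
#' per node, yields a solution as the union of the chosen sets. The builder
#' starts from a star graph (one node per solution), then applies forward
#' merging (children sharing a parent and features), backward merging
#' (parents sharing children and features) and OR merging (nodes with
#' identical parents and children collapse into one multi-set node). Every
#' operation preserves the decoded family exactly; the construction is
#' greedy, so minimality of the graph is not claimed.
NULL

msg_new <- function() {
  g <- list(nodes = list(), parents = list(), children = list(),
            root = NA_integer_, leaf = NA_integer_, next_id = 1L)
  class(g) <- "msg"
  g
}

msg_add_node <- function(g, sets = list(), role = "var") {
  id <- g$next_id
  g$next_id <- id + 1L
  key <- as.character(id)
  g$nodes[[key]] <- list(id = id, role = role, sets = sets)
  g$parents[[key]] <- integer(0)
  g$children[[key]] <- integer(0)
  list(g = g, id = id)
}

msg_add_edge <- function(g, from, to) {
  kf <- as.character(from); kt <- as.character(to)
  if (!(to %in% g$children[[kf]])) {
    g$children[[kf]] <- sort(c(g$children[[kf]], to))
    g$parents[[kt]] <- sort(c(g$parents[[kt]], from))
  }
  g
}

msg_remove_edge <- function(g, from, to) {
  kf <- as.character(from); kt <- as.character(to)
  g$children[[kf]] <- setdiff(g$children[[kf]], to)
  g$parents[[kt]] <- setdiff(g$parents[[kt]], from)
  g
}

msg_remove_node <- function(g, id) {
  key <- as.character(id)
  for (p in g$parents[[key]]) g$children[[as.character(p)]] <-
    setdiff(g$children[[as.character(p)]], id)
  for (ch in g$children[[key]]) g$parents[[as.character(ch)]] <-
    setdiff(g$parents[[as.character(ch)]], id)
  g$nodes[[key]] <- NULL
  g$parents[[key]] <- NULL
  g$children[[key]] <- NULL
  g
}

msg_node_ids <- function(g) {
  sort(vapply(g$nodes, function(n) n$id, integer(1)))
}

msg_var_ids <- function(g) {
  ids <- msg_node_ids(g)
  ids[vapply(as.character(ids), function(k) g$nodes[[k]]$role == "var",
             logical(1))]
}

msg_feature_count <- function(g) {
  sum(vapply(g$nodes, function(n) sum(lengths(n$sets)), numeric(1)))
}

#' @export
print.msg <- function(x, ...) {
  cat(sprintf("<msg> %d nodes (incl. s, t), %d edges\n",
              length(x$nodes), sum(lengths(x$children))))
  invisible(x)
}

# replace an empty-var node by direct parent-to-child edges
msg_drop_empty <- function(g, id) {
  key <- as.character(id)
  ps <- g$parents[[key]]
  cs <- g$children[[key]]
  g <- msg_remove_node(g, id)
  for (p in ps) for (ch in cs) g <- msg_add_edge(g, p, ch)
  g
}

set_key <- function(s) paste(s, collapse = "\r")

# Greedy grouping: repeatedly take the feature with the most occurrences
# among the remaining sets (ties: smallest feature) and group every
# remaining set containing it.
split_by_most_frequent_feature <- function(sets_list) {
  pool <- seq_along(sets_list)
  groups <- list()
  while (length(pool) > 0L) {
    feats <- sort(unique(unlist(sets_list[pool])))
    counts <- vapply(feats, function(f) {
      sum(vapply(pool, function(i) f %in% sets_list[[i]], logical(1)))
    }, numeric(1))
    f <- feats[which.max(counts)]
    grp <- pool[vapply(pool, function(i) f %in% sets_list[[i]], logical(1))]
    groups[[length(groups) + 1L]] <- grp
    pool <- setdiff(pool, grp)
  }
  groups
}

# ---- merge operations (each optionally verified for decode invariance and
# ---- the node/feature accounting it must satisfy) --------------------------

msg_checked <- function(g, expr_fun, feat_delta = NULL, node_delta = NULL,
                        check = FALSE) {
  if (!check) return(expr_fun(g))
  before_fam <- decode_keys(g)
  before_feat <- msg_feature_count(g)
  before_nodes <- length(g$nodes)
  g2 <- expr_fun(g)
  if (!identical(decode_keys(g2), before_fam)) {
    stop("internal error: merge operation changed the decoded family")
  }
  if (!is.null(feat_delta) &&
      !isTRUE(all.equal(before_feat - msg_feature_count(g2), feat_delta))) {
    stop("internal error: feature-count accounting violated")
  }
  if (!is.null(node_delta) &&
      (before_nodes - length(g2$nodes)) != node_delta) {
    stop("internal error: node-count accounting violated")
  }
  g2
}

# Operation 1 / 2: merge a group of single-set nodes sharing features and an
# identical set of parents (forward) or children (backward).
msg_shared_merge <- function(g, ids, direction = c("forward", "backward"),
                             check = FALSE) {
  direction <- match.arg(direction)
  keys <- as.character(ids)
  Fp <- Reduce(intersect, lapply(keys, function(k) g$nodes[[k]]$sets[[1L]]))
  stopifnot(length(Fp) > 0L)
  do_merge <- function(g) {
    if (direction == "forward") {
      P <- g$parents[[keys[1L]]]
      res <- msg_add_node(g, sets = list(sort(Fp)))
      g <- res$g; np <- res$id
      for (id in ids) for (p in g$parents[[as.character(id)]])
        g <- msg_remove_edge(g, p, id)
      for (p in P) g <- msg_add_edge(g, p, np)
      for (id in ids) g <- msg_add_edge(g, np, id)
    } else {
      C <- g$children[[keys[1L]]]
      res <- msg_add_node(g, sets = list(sort(Fp)))
      g <- res$g; np <- res$id
      for (id in ids) for (ch in g$children[[as.character(id)]])
        g <- msg_remove_edge(g, id, ch)
      for (id in ids) g <- msg_add_edge(g, id, np)
      for (ch in C) g <- msg_add_edge(g, np, ch)
    }
    for (id in ids) {
      k <- as.character(id)
      rest <- setdiff(g$nodes[[k]]$sets[[1L]], Fp)
      if (length(rest) == 0L) {
        g <- msg_drop_empty(g, id)
      } else {
        g$nodes[[k]]$sets <- list(sort(rest))
      }
    }
    attr(g, "last_new_node") <- np
    g
  }
  msg_checked(g, do_merge,
              feat_delta = (length(ids) - 1L) * length(Fp), check = check)
}

# Operation 3: collapse nodes with identical parents and children into one
# node holding all their feature sets.
msg_or_merge <- function(g, ids, check = FALSE) {
  keys <- as.character(ids)
  do_merge <- function(g) {
    keep <- keys[1L]
    sets <- g$nodes[[keep]]$sets
    for (k in keys[-1L]) sets <- c(sets, g$nodes[[k]]$sets)
    if (anyDuplicated(vapply(sets, set_key, character(1)))) {
      stop("internal error: OR merge would create duplicate feature sets")
    }
    g$nodes[[keep]]$sets <- sets
    for (id in ids[-1L]) g <- msg_remove_node(g, id)
    g
  }
  msg_checked(g, do_merge, feat_delta = 0, node_delta = length(ids) - 1L,
              check = check)
}

# ---- compression passes ----------------------------------------------------

#' Forward compression pass
#'
#' Groups the children of `node` greedily by their most frequent shared
#' feature; each multi-member group is merged (a new node takes the group's
#' feature intersection, the group members lose those features, members left
#' empty are removed with full parent-to-child rewiring) and the pass
#' recurses on each newly created node until the leaf is reached.
#'
#' @param g an `msg` graph.
#' @param node node id to start from (defaults to the root).
#' @param check verify decode-invariance and feature accounting after every
#'   merge.
#' @return The compressed graph.
#' @export
forward_compress <- function(g, node = g$root, check = FALSE) {
  key <- as.character(node)
  kids <- g$children[[key]]
  kids <- kids[vapply(as.character(kids),
                      function(k) g$nodes[[k]]$role == "var", logical(1))]
  if (length(kids) == 0L) return(g)
  # group only among children sharing an identical parent set
  psig <- vapply(as.character(kids),
                 function(k) paste(g$parents[[k]], collapse = ","), character(1))
  new_nodes <- integer(0)
  for (sig in unique(psig)) {
    sub <- kids[psig == sig]
    sets <- lapply(as.character(sub), function(k) g$nodes[[k]]$sets[[1L]])
    groups <- split_by_most_frequent_feature(sets)
    for (grp in groups) {
      if (length(grp) < 2L) next
      g <- msg_shared_merge(g, sub[grp], "forward", check = check)
      new_nodes <- c(new_nodes, attr(g, "last_new_node"))
    }
  }
  for (np in new_nodes) g <- forward_compress(g, np, check = check)
  g
}

#' Backward compression pass
#'
#' Mirror image of [forward_compress()] starting from the leaf: the parents
#' of `node` are first grouped by identical child sets (a parent of the leaf
#' may also be a parent of another node), then by shared features; each
#' multi-member group is merged towards the leaf. The pass recurses on every
#' parent, including nodes created by earlier merges, until the root is
#' reached.
#'
#' @inheritParams forward_compress
#' @param node node id to start from (defaults to the leaf).
#' @param visited internal: ids already processed in this pass.
#' @return The compressed graph.
#' @export
backward_compress <- function(g, node = g$leaf, check = FALSE,
                              visited = new.env(parent = emptyenv())) {
  key <- as.character(node)
  pars <- g$parents[[key]]
  pars <- pars[vapply(as.character(pars),
                      function(k) g$nodes[[k]]$role == "var", logical(1))]
  if (length(pars) > 0L) {
    csig <- vapply(as.character(pars),
                   function(k) paste(g$children[[k]], collapse = ","),
                   character(1))
    for (sig in unique(csig)) {
      sub <- pars[csig == sig]
      if (length(sub) < 2L) next
      sets <- lapply(as.character(sub), function(k) g$nodes[[k]]$sets[[1L]])
      groups <- split_by_most_frequent_feature(sets)
      for (grp in groups) {
        if (length(grp) < 2L) next
        g <- msg_shared_merge(g, sub[grp], "backward", check = check)
      }
    }
  }
  # recurse on the (possibly new) parents of this node
  repeat {
    todo <- setdiff(g$parents[[key]], c(g$root))
    todo <- todo[!vapply(as.character(todo),
                         function(k) isTRUE(visited[[k]]), logical(1))]
    if (length(todo) == 0L) break
    p <- todo[1L]
    visited[[as.character(p)]] <- TRUE
    g <- backward_compress(g, p, check = check, visited = visited)
  }
  g
}

#' OR compression pass
#'
#' Repeatedly merges every maximal set of two or more nodes that share both
#' an identical parent set and an identical child set into a single node
#' carrying all their feature sets, until no merge applies. Node count drops
#' by group size minus one per merge; the total feature count is unchanged.
#'
#' @inheritParams forward_compress
#' @return The compressed graph.
#' @export
or_compress <- function(g, check = FALSE) {
  repeat {
    ids <- msg_var_ids(g)
    if (length(ids) < 2L) return(g)
    sig <- vapply(as.character(ids), function(k) {
      paste(paste(g$parents[[k]], collapse = ","),
            paste(g$children[[k]], collapse = ","), sep = "|")
    }, character(1))
    tab <- table(sig)
    mult <- names(tab)[tab >= 2L]
    if (length(mult) == 0L) return(g)
    grp <- ids[sig == mult[1L]]
    g <- msg_or_merge(g, grp, check = check)
  }
}

#' Build a multiple-solutions graph from a solution family
#'
#' Creates the star graph (root -> one node per solution -> leaf), then
#' applies forward compression, backward compression and OR merging.
#' Decoding the result reproduces the input family exactly.
#'
#' @param M a [solution_set()] or plain list of distinct feature sets
#'   (integer indices or character names). An empty set is allowed only as
#'   the sole solution.
#' @param check verify decode-invariance and the operation accounting after
#'   every individual merge.
#' @return An `msg` graph.
#' @export
build_msg <- function(M, check = FALSE) {
  sols <- if (inherits(M, "solution_set")) M$solutions else
    solution_set(M)$solutions
  if (length(sols) == 0L) stop("need at least one solution")
  if (any(lengths(sols) == 0L) && length(sols) > 1L) {
    stop("the empty set is allowed only as the sole solution")
  }
  g <- msg_new()
  res <- msg_add_node(g, role = "s"); g <- res$g; g$root <- res$id
  res <- msg_add_node(g, role = "t"); g <- res$g; g$leaf <- res$id
  if (length(sols) == 1L && length(sols[[1L]]) == 0L) {
    return(msg_add_edge(g, g$root, g$leaf))
  }
  for (s in sols) {
    res <- msg_add_node(g, sets = list(sort(s)))
    g <- res$g
    g <- msg_add_edge(g, g$root, res$id)
    g <- msg_add_edge(g, res$id, g$leaf)
  }
  g <- forward_compress(g, g$root, check = check)
  g <- backward_compress(g, g$leaf, check = check)
  or_compress(g, check = check)
}

# ---- decoding --------------------------------------------------------------

decode_keys <- function(g, cap = 1e6) {
  sols <- decode_solutions(g, cap = cap)$solutions
  sort(vapply(sols, solution_key, character(1)))
}

#' Decode a multiple-solutions graph
#'
#' Enumerates every root-to-leaf directed path and every per-node
#' feature-set choice along it; each combination yields a solution as the
#' union of the chosen sets. Distinct unions are returned.
#'
#' @param g an `msg` graph.
#' @param cap error out if the number of path/choice combinations exceeds
#'   this guard (decoding is meant for verification and display).
#' @return A [solution_set()] of the encoded solutions.
#' @export
decode_solutions <- function(g, cap = 10000L) {
  paths <- list()
  walk <- function(id, acc) {
    if (id == g$leaf) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible(NULL))
    }
    k <- as.character(id)
    nxt <- if (g$nodes[[k]]$role == "var") c(acc, id) else acc
    for (ch in g$children[[k]]) walk(ch, nxt)
  }
  walk(g$root, integer(0))
  total <- sum(vapply(paths, function(p) {
    prod(vapply(as.character(p), function(k) length(g$nodes[[k]]$sets),
                numeric(1)))
  }, numeric(1)))
  if (total > cap) {
    stop(sprintf("decoding would enumerate %.0f combinations (cap %d)",
                 total, cap))
  }
  out <- list()
  seen <- character(0)
  for (p in paths) {
    partial <- list(NULL)
    for (k in as.character(p)) {
      partial <- unlist(lapply(partial, function(acc) {
        lapply(g$nodes[[k]]$sets, function(s) sort(unique(c(acc, s))))
      }), recursive = FALSE)
    }
    for (s in partial) {
      s <- if (is.null(s)) vector(mode = "integer") else s
      key <- set_key(s)
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- s
      }
    }
  }
  solution_set(out)
}

#' Feature taxonomy induced by a solution family
#'
#' Indispensable features appear in every solution; replaceable features in
#' some but not all; the rest of the universe is outside all solutions.
#' Splitting that last bucket into redundant versus irrelevant requires an
#' existential search over conditioning contexts and is not decided here.
#'
#' @param M a [solution_set()] or list of feature vectors.
#' @param universe vector of all features under consideration.
#' @return Named character vector over `universe` with values
#'   `"indispensable"`, `"replaceable"` or `"outside_all_solutions"`.
#' @export
classify_features <- function(M, universe) {
  sols <- if (inherits(M, "solution_set")) M$solutions else M
  if (length(sols) == 0L) stop("M must be nonempty")
  indis <- Reduce(intersect, sols)
  inall <- Reduce(union, sols)
  out <- rep("outside_all_solutions", length(universe))
  out[universe %in% inall] <- "replaceable"
  out[universe %in% indis] <- "indispensable"
  names(out) <- as.character(universe)
  out
}

# ---- export ----------------------------------------------------------------

format_sets <- function(sets) {
  paste(vapply(sets, function(s) {
    paste0("{", paste(s, collapse = ","), "}")
  }, character(1)), collapse = " | ")
}

#' Export a multiple-solutions graph to DOT
#'
#' Deterministic Graphviz output: nodes in id order, root and leaf rendered
#' as special point-style nodes, multi-set nodes labelled with
#' `|`-separated sets.
#'
#' @param g an `msg` graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_dot <- function(g, path) {
  lines <- c("digraph MSG {", "  rankdir=LR;")
  for (id in msg_node_ids(g)) {
    k <- as.character(id)
    nd <- g$nodes[[k]]
    if (nd$role == "var") {
      lines <- c(lines, sprintf("  n%d [shape=box, label=\"%s\"];",
                                id, format_sets(nd$sets)))
    } else {
      lines <- c(lines, sprintf("  n%d [shape=circle, label=\"%s\"];",
                                id, nd$role))
    }
  }
  for (id in msg_node_ids(g)) {
    for (ch in sort(g$children[[as.character(id)]])) {
      lines <- c(lines, sprintf("  n%d -> n%d;", id, ch))
    }
  }
  lines <- c(lines, "}")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Serialize a multiple-solutions graph to JSON
#'
#' @param g an `msg` graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msg_json <- function(g, path) {
  ids <- msg_node_ids(g)
  nodes <- lapply(ids, function(id) {
    nd <- g$nodes[[as.character(id)]]
    list(id = id, role = nd$role, sets = lapply(nd$sets, as.list))
  })
  edges <- list()
  for (id in ids) {
    for (ch in sort(g$children[[as.character(id)]])) {
      edges[[length(edges) + 1L]] <- c(id, ch)
    }
  }
  jsonlite::write_json(list(schema = "equiset-msg-v1", root = g$root,
                            leaf = g$leaf, nodes = nodes, edges = edges),
                       path, auto_unbox = TRUE)
  invisible(path)
}
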