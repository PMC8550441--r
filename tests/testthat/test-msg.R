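make_star <- function(sols) {
  g <- equiset:::msg_new()
  res <- equiset:::msg_add_node(g, role = "s"); g <- res$g; g$root <- res$id
  res <- equiset:::msg_add_node(g, role = "t"); g <- res$g; g$leaf <- res$id
  for (s in sols) {
    res <- equiset:::msg_add_node(g, sets = list(sort(s)))
    g <- res$g
    g <- equiset:::msg_add_edge(g, g$root, res$id)
    g <- equiset:::msg_add_edge(g, res$id, g$leaf)
  }
  g
}

node_set_keys <- function(g) {
  sort(unlist(lapply(g$nodes, function(n) {
    if (n$role == "var") vapply(n$sets, function(s) paste(s, collapse = ","),
                                character(1))
  })))
}

test_that("forward merging factors out the shared feature", {
  g <- make_star(list(c("F1", "F2"), c("F1", "F3")))
  g <- forward_compress(g, check = TRUE)
  expect_setequal(node_set_keys(g), c("F1", "F2", "F3"))
  dec <- decode_solutions(g)
  expect_identical(family_keys(dec),
                   family_keys(list(c("F1", "F2"), c("F1", "F3"))))

  # pairwise-disjoint children: the forward pass changes nothing
  g2 <- make_star(list("A", "B", "C"))
  g3 <- forward_compress(g2, check = TRUE)
  expect_identical(node_set_keys(g3), node_set_keys(g2))
})

test_that("backward merging factors shared features towards the leaf", {
  g <- make_star(list(c("F1", "F2"), c("F1", "F3")))
  g <- backward_compress(g, check = TRUE)
  expect_setequal(node_set_keys(g), c("F1", "F2", "F3"))
  expect_identical(family_keys(decode_solutions(g)),
                   family_keys(list(c("F1", "F2"), c("F1", "F3"))))

  # parents with no shared features stay untouched
  g2 <- backward_compress(make_star(list("A", "B")), check = TRUE)
  expect_setequal(node_set_keys(g2), c("A", "B"))
})

test_that("OR merging collapses interchangeable siblings into one node", {
  g <- or_compress(make_star(list("F7", "F8")), check = TRUE)
  vars <- Filter(function(n) n$role == "var", g$nodes)
  expect_length(vars, 1L)
  expect_length(vars[[1]]$sets, 2L)
  expect_identical(family_keys(decode_solutions(g)),
                   family_keys(list("F7", "F8")))

  # a chain graph has nothing to merge
  chain <- build_msg(list(c("A", "B")))
  expect_identical(family_keys(decode_solutions(or_compress(chain, check = TRUE))),
                   family_keys(list(c("A", "B"))))
})

test_that("the four-set worked example compresses into the expected shape", {
  M <- list(c("F1", "F2", "F3"), c("F1", "F2", "F4", "F5"),
            c("F1", "F2", "F5", "F6", "F7"), c("F1", "F2", "F5", "F6", "F8"))
  g <- build_msg(M, check = TRUE)
  dec <- decode_solutions(g)
  expect_length(dec$solutions, 4L)
  expect_identical(family_keys(dec), family_keys(M))
  # the two terminal alternatives end up as one OR node
  keys <- lapply(g$nodes, function(n) if (n$role == "var") n$sets)
  or_nodes <- Filter(function(s) !is.null(s) && length(s) > 1, keys)
  expect_length(or_nodes, 1L)
  expect_identical(sort(unname(unlist(or_nodes))), c("F7", "F8"))
})

test_that("graph construction validates its input family", {
  expect_error(build_msg(list(c(1L, 2L), c(2L, 1L))), "distinct")
  expect_error(build_msg(list(integer(0), 1L)), "sole solution")
  single <- build_msg(list(c(3L, 1L)))
  expect_identical(decode_solutions(single)$solutions, list(c(1L, 3L)))
  empty <- build_msg(list(integer(0)))
  expect_identical(family_keys(decode_solutions(empty)), "")
})

test_that("compression is lossless over random families", {
  for (s in 1:40) {
    M <- random_family(s)
    g <- build_msg(M, check = TRUE)
    expect_identical(family_keys(decode_solutions(g)), family_keys(M))
  }
})

test_that("built graphs satisfy the structural invariants", {
  for (s in c(2, 9, 17)) {
    M <- random_family(s)
    g <- build_msg(M)
    ids <- equiset:::msg_node_ids(g)
    for (id in ids) {
      k <- as.character(id)
      nd <- g$nodes[[k]]
      if (nd$role == "s") expect_length(g$parents[[k]], 0)
      else expect_gte(length(g$parents[[k]]), 1L)
      if (nd$role == "t") expect_length(g$children[[k]], 0)
      else expect_gte(length(g$children[[k]]), 1L)
      if (nd$role == "var") expect_true(all(lengths(nd$sets) > 0))
    }
    # acyclicity: repeatedly strip sources until nothing remains
    children <- g$children
    remaining <- ids
    repeat {
      sources <- remaining[vapply(as.character(remaining), function(k) {
        !any(vapply(as.character(remaining), function(j) {
          as.integer(k) %in% children[[j]]
        }, logical(1)))
      }, logical(1))]
      if (length(sources) == 0L) break
      remaining <- setdiff(remaining, sources)
    }
    expect_length(remaining, 0L)
  }
})

test_that("decoding respects its combination cap", {
  M <- lapply(1:6, function(i) c(i, i + 10L))
  g <- build_msg(M)
  expect_error(decode_solutions(g, cap = 1L), "cap")
})

test_that("feature classification follows the set algebra of the family", {
  one <- classify_features(list(c(1L, 3L)), 1:4)
  expect_identical(unname(one), c("indispensable", "outside_all_solutions",
                                  "indispensable", "outside_all_solutions"))
  two <- classify_features(list(c(1L, 2L), c(1L, 3L)), 1:4)
  expect_identical(unname(two[1:3]),
                   c("indispensable", "replaceable", "replaceable"))

  gen <- generate_synthetic(synth_spec(
    n_samples = 50, n_indispensable = 2, class_sizes = c(2L, 3L),
    n_redundant = 1, n_irrelevant = 2, seed = 4))
  cls <- classify_features(enumerate_true_solutions(gen$truth),
                           seq_len(n_features <- ncol(gen$dataset$X)))
  expect_setequal(which(cls == "indispensable"), gen$truth$indispensable)
  expect_setequal(which(cls == "replaceable"), unlist(gen$truth$classes))
  expect_setequal(which(cls == "outside_all_solutions"),
                  c(gen$truth$redundant, gen$truth$irrelevant))
})

test_that("DOT export is deterministic and well-formed", {
  g <- build_msg(list(c("A", "B")))
  p1 <- withr::local_tempfile(fileext = ".dot")
  p2 <- withr::local_tempfile(fileext = ".dot")
  export_dot(g, p1)
  export_dot(g, p2)
  expect_identical(readLines(p1), readLines(p2))
  lines <- readLines(p1)
  expect_match(lines[1], "^digraph")
  expect_identical(tail(lines, 1), "}")
  expect_length(grep("->", lines), 2L)  # chain graph: two edges

  g4 <- build_msg(list(c("F1", "F2"), c("F1", "F3")))
  p3 <- withr::local_tempfile(fileext = ".dot")
  export_dot(g4, p3)
  txt <- readLines(p3)
  # every edge references a declared node; labels carry the sets
  declared <- sub(" \\[.*", "", sub("^  ", "", grep("\\[", txt, value = TRUE)))
  edges <- grep("->", txt, value = TRUE)
  ends <- unlist(regmatches(edges, gregexpr("n[0-9]+", edges)))
  expect_true(all(ends %in% declared))
})

test_that("graph JSON serialization includes every node and edge", {
  g <- build_msg(list(c("F1", "F2"), c("F1", "F3")))
  path <- withr::local_tempfile(fileext = ".json")
  write_msg_json(g, path)
  obj <- jsonlite::read_json(path)
  expect_identical(obj$schema, "equiset-msg-v1")
  expect_length(obj$nodes, length(g$nodes))
  expect_length(obj$edges, sum(lengths(g$children)))
})
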