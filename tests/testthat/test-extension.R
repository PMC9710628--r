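# a model over upper-case element names; keys are the folded names
simple_model <- function(names, pos = "", neg = "") {
  parse_model(write_model_tsv(names, pos = pos, neg = neg))
}

ees_from <- function(reg, tgt, sign, paper = "P1") {
  build_ees(make_records(reg, tgt, sign, rep_len(paper, length(reg))))
}

test_that("a generated cluster interprets into a directed signed entity graph", {
  ees <- ees_from(c("A", "B"), c("B", "C"), c("positive", "negative"))
  model <- simple_model(c("A", "X"))
  ic <- interpret_cluster(ees$events$key, ees, model, label = 1L)
  expect_setequal(ic$entities, c("a", "b", "c"))
  expect_equal(nrow(ic$edges), 2L)
  expect_equal(ic$edges$sign[ic$edges$src == "a"], "positive")
  expect_equal(ic$edges$sign[ic$edges$src == "b"], "negative")
  expect_equal(ic$overlap_nodes, "a")
  expect_setequal(ic$new_nodes, c("b", "c"))
  expect_equal(ic$node_overlap, 100 / 3)
})

test_that("node overlap is the percentage of cluster entities already in the model", {
  expect_equal(node_overlap(c("a", "b"), c("x", "y")), 0)
  expect_equal(node_overlap(c("a", "b"), c("a", "b", "c")), 100)
  expect_equal(node_overlap(c("a", "b", "c", "d", "e"), c("a", "b", "c")), 60)
  expect_error(node_overlap(character(0), "a"), "empty")
})

test_that("return paths start and end in the model and use only cluster edges", {
  model <- simple_model(c("X", "Y"))
  ees <- ees_from(c("X", "N1"), c("N1", "Y"), "positive")
  ic <- interpret_cluster(ees$events$key, ees, model, label = 1L)
  paths <- find_return_paths(list(ic), model)
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$nodes, c("x", "n1", "y"))
  expect_equal(paths[[1]]$clusters, 1L)

  # no cluster edge incident to a model node: nothing to find
  far <- interpret_cluster(ees_from("N2", "N3", "positive")$events$key,
                           ees_from("N2", "N3", "positive"), model, label = 1L)
  expect_length(find_return_paths(list(far), model), 0L)
})

test_that("a return path can span clusters and pass through model nodes", {
  model <- simple_model(c("X", "Y", "Z"))
  e1 <- ees_from("X", "N1", "positive")
  e2 <- ees_from(c("N1", "Y"), c("Y", "N2"), "positive")
  e3 <- ees_from("N2", "Z", "positive")
  ics <- list(interpret_cluster(e1$events$key, e1, model, label = 1L),
              interpret_cluster(e2$events$key, e2, model, label = 2L),
              interpret_cluster(e3$events$key, e3, model, label = 3L))
  paths <- find_return_paths(ics, model)
  # the two-cluster path X -> n1 -> Y exists and records both clusters
  hit <- Filter(function(p) identical(p$nodes, c("x", "n1", "y")), paths)
  expect_length(hit, 1L)
  expect_equal(hit[[1]]$clusters, c(1L, 2L))
  # a longer path continues through the interior model node y
  long <- Filter(function(p) identical(p$nodes, c("x", "n1", "y", "n2", "z")),
                 paths)
  expect_length(long, 1L)
  expect_equal(long[[1]]$clusters, 1:3)

  # every emitted path satisfies the defining invariants
  union_edges <- do.call(rbind, lapply(ics, `[[`, "edges"))
  for (p in paths) {
    expect_true(p$nodes[1] %in% model$nodes)
    expect_true(p$nodes[length(p$nodes)] %in% model$nodes)
    for (i in seq_len(nrow(p$edges))) {
      expect_equal(p$edges$src[i], p$nodes[i])       # head-to-tail
      expect_equal(p$edges$dst[i], p$nodes[i + 1])
      expect_true(any(union_edges$src == p$edges$src[i] &
                        union_edges$dst == p$edges$dst[i] &
                        union_edges$sign == p$edges$sign[i]))
    }
  }

  # the depth bound is respected
  short <- find_return_paths(ics, model, max_len = 2L)
  expect_true(all(vapply(short, function(p) nrow(p$edges) <= 2L, TRUE)))
})

# helpers to build scored clusters directly for the selection rule
score_row <- function(label, fc, ifp, p_l = 1L, size = 2L) {
  data.frame(label = label, size = size, P_l = p_l, fc_pa_avg = fc,
             if_pa_avg = ifp)
}
fake_ic <- function(label, entities, model, edges = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(src = entities[1], dst = entities[2],
                        sign = "positive",
                        event_key = paste(entities[1], entities[2], "positive",
                                          sep = "|"),
                        stringsAsFactors = FALSE)
  }
  structure(list(label = label, entities = entities, edges = edges,
                 overlap_nodes = intersect(entities, model$nodes),
                 new_nodes = setdiff(entities, model$nodes),
                 node_overlap = node_overlap(entities, model$nodes)),
            class = "interpreted_cluster")
}

test_that("the selection rule fires on literature support, model support, both, or neither", {
  model <- simple_model(c("X", "Y", "Z"))
  clusters <- rbind(score_row(1L, fc = 0.5, ifp = 9.0),   # best on both scores
                    score_row(2L, fc = 0.5, ifp = 2.0),   # min fc only
                    score_row(3L, fc = 2.0, ifp = 5.0))
  ics <- list(fake_ic(1L, c("n1", "n2"), model),
              fake_ic(2L, c("n3", "n4"), model),
              fake_ic(3L, c("n5", "n6"), model))

  sel <- select_clusters(clusters, ics, paths = list())
  expect_equal(sel$selected, 1L)
  expect_equal(sel$reasons[["1"]], "literature")

  # model support: overlap above threshold AND on a return path
  ic2 <- fake_ic(2L, c("x", "y", "n3"), model,
                 edges = data.frame(src = c("x", "n3"), dst = c("n3", "y"),
                                    sign = "positive",
                                    event_key = c("x|n3|positive",
                                                  "n3|y|positive")))
  paths <- find_return_paths(list(ic2), model)
  expect_gt(length(paths), 0L)
  sel2 <- select_clusters(clusters, list(ics[[1]], ic2, ics[[3]]), paths)
  expect_setequal(sel2$selected, c(1L, 2L))
  expect_equal(sel2$reasons[["2"]], "model-support")

  # high overlap but no return path, or a path but low overlap: not selected
  sel3 <- select_clusters(clusters, list(ics[[1]], ic2, ics[[3]]),
                          paths = list())
  expect_equal(sel3$selected, 1L)
  low_overlap <- fake_ic(2L, c("x", "y", "n3", "n4", "n5", "n6", "n7"), model)
  sel4 <- select_clusters(clusters, list(ics[[1]], low_overlap, ics[[3]]),
                          paths)
  expect_equal(sel4$selected, 1L)

  # neither disjunct anywhere: empty selection with a diagnostic
  none <- select_clusters(rbind(score_row(1L, 0.5, 2.0),
                                score_row(2L, 2.0, 9.0)),
                          list(fake_ic(1L, c("n1", "n2"), model),
                               fake_ic(2L, c("n3", "n4"), model)),
                          paths = list())
  expect_length(none$selected, 0L)
  expect_equal(none$diagnostic$best_fc_pa_avg, 1L)
  expect_equal(none$diagnostic$best_if_pa_avg, 2L)
})

test_that("a single cluster with defined averages is trivially selected", {
  model <- simple_model(c("X", "Y"))
  sel <- select_clusters(score_row(1L, 1.0, 3.0),
                         list(fake_ic(1L, c("n1", "n2"), model)),
                         paths = list())
  expect_equal(sel$selected, 1L)
})

test_that("clusters sharing a return path with a selected cluster are merged", {
  model <- simple_model(c("X", "Y"))
  ic1 <- fake_ic(1L, c("x", "n1"), model,
                 edges = data.frame(src = "x", dst = "n1", sign = "positive",
                                    event_key = "x|n1|positive"))
  ic2 <- fake_ic(2L, c("n1", "y"), model,
                 edges = data.frame(src = "n1", dst = "y", sign = "positive",
                                    event_key = "n1|y|positive"))
  paths <- find_return_paths(list(ic1, ic2), model)
  clusters <- rbind(score_row(1L, 0.5, 9.0), score_row(2L, 2.0, 1.0))
  sel <- select_clusters(clusters, list(ic1, ic2), paths)
  expect_setequal(sel$selected, c(1L, 2L))
  expect_true("return-path-merge" %in% sel$reasons[["2"]])
  expect_setequal(sel$events, c("x|n1|positive", "n1|y|positive"))
})

test_that("selection is invariant to cluster order and undefined averages only pass via model support", {
  model <- simple_model(c("X", "Y"))
  clusters <- rbind(score_row(1L, 0.5, 9.0), score_row(2L, 1.0, 2.0),
                    score_row(3L, NA_real_, NA_real_, p_l = 0L, size = 1L))
  ics <- list(fake_ic(1L, c("n1", "n2"), model),
              fake_ic(2L, c("n3", "n4"), model),
              fake_ic(3L, c("n5", "n6"), model))
  a <- select_clusters(clusters, ics, list())
  perm <- c(3, 1, 2)
  b <- select_clusters(clusters[perm, ], ics[perm], list())
  expect_setequal(a$selected, b$selected)
  expect_false(3L %in% a$selected)
})

test_that("extending a model adds new elements with the _ext suffix and is idempotent", {
  model <- simple_model(c("X", "Y"), pos = c("", "X"))
  ees <- ees_from(c("X", "N1"), c("N1", "Y"), c("positive", "negative"))
  ic <- interpret_cluster(ees$events$key, ees, model, label = 1L)
  paths <- find_return_paths(list(ic), model)
  sel <- select_clusters(score_row(1L, 0.5, 3.0), list(ic), paths)
  ext <- extend_model(model, sel, ees)

  expect_true(all(paste(model$edges$src, model$edges$dst, model$edges$sign) %in%
                    paste(ext$edges$src, ext$edges$dst, ext$edges$sign)))
  expect_true("N1_ext" %in% ext$elements$name)
  expect_true(any(ext$edges$src == "x" & ext$edges$dst == "n1_ext"))
  expect_true(any(ext$edges$src == "n1_ext" & ext$edges$dst == "y" &
                    ext$edges$sign == "negative"))
  # the negative regulation lands in the negative influence expression
  y_row <- ext$elements[ext$elements$name == "Y", ]
  expect_match(y_row$neg_expr, "N1_ext")

  ext2 <- extend_model(ext, sel, ees)
  expect_equal(ext$elements, ext2$elements)
  expect_equal(ext$edges, ext2$edges)

  # a cluster fully inside the model only adds missing edges
  inner_ees <- ees_from("Y", "X", "positive")
  inner <- interpret_cluster(inner_ees$events$key, inner_ees, model, label = 1L)
  sel_inner <- select_clusters(score_row(1L, 0.5, 3.0), list(inner), list())
  ext3 <- extend_model(model, sel_inner, inner_ees)
  expect_equal(length(ext3$nodes), length(model$nodes))
  expect_equal(nrow(ext3$edges), nrow(model$edges) + 1L)

  # empty selection: unchanged with a warning
  none <- select_clusters(rbind(score_row(1L, 0.5, 2.0),
                                score_row(2L, 2.0, 9.0)),
                          list(fake_ic(1L, c("n1", "n2"), model),
                               fake_ic(2L, c("n3", "n4"), model)), list())
  expect_warning(same <- extend_model(model, none, ees), "unchanged")
  expect_equal(same$edges, model$edges)
})

test_that("merging clusters that share an entity keeps a single copy with union edges", {
  model <- simple_model(c("X", "Y"))
  ees <- ees_from(c("X", "N1"), c("N1", "Y"), "positive")
  ic1 <- interpret_cluster(ees$events$key[1], ees, model, label = 1L)
  ic2 <- interpret_cluster(ees$events$key[2], ees, model, label = 2L)
  paths <- find_return_paths(list(ic1, ic2), model)
  sel <- select_clusters(rbind(score_row(1L, 0.5, 9.0),
                               score_row(2L, 1.0, 1.0)),
                         list(ic1, ic2), paths)
  ext <- extend_model(model, sel, ees)
  expect_equal(sum(ext$elements$name == "N1_ext"), 1L)
  expect_true(any(ext$edges$src == "x" & ext$edges$dst == "n1_ext"))
  expect_true(any(ext$edges$src == "n1_ext" & ext$edges$dst == "y"))
})

test_that("the element-of-interest mode pairs source and target clusters on a return path", {
  model <- simple_model(c("X", "Y"))
  # cluster 1 regulates n1 (n1 as target), cluster 2 has n1 as source
  ees <- ees_from(c("X", "N1"), c("N1", "Y"), "positive")
  ic1 <- interpret_cluster(ees$events$key[grep("^x", ees$events$key)],
                           ees, model, label = 1L)
  ic2 <- interpret_cluster(ees$events$key[grep("^n1", ees$events$key)],
                           ees, model, label = 2L)
  paths <- find_return_paths(list(ic1, ic2), model)
  # literature scores deliberately favour neither
  clusters <- rbind(score_row(1L, 0.5, 2.0), score_row(2L, 2.0, 9.0))
  sel <- select_clusters(clusters, list(ic1, ic2), paths,
                         element_of_interest = "n1")
  expect_setequal(sel$selected, c(1L, 2L))
  expect_true("element-of-interest" %in% sel$reasons[["1"]])
})
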