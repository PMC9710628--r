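#' Node overlap between a cluster and the baseline model
#'
#' Percentage of an interpreted cluster's entities that are already model
#' elements: `|cluster_nodes ∩ model_nodes| / |cluster_nodes| * 100`. A
#' model-support score: high overlap means the cluster is well connected to
#' the baseline model.
#'
#' @param cluster_nodes character vector of entity keys (non-empty).
#' @param model_nodes character vector of model element keys.
#' @return percentage in \[0, 100\].
#' @export
node_overlap <- function(cluster_nodes, model_nodes) {
  if (length(cluster_nodes) == 0L) {
    stop("node overlap is undefined for an empty cluster", call. = FALSE)
  }
  100 * length(intersect(cluster_nodes, model_nodes)) / length(unique(cluster_nodes))
}

#' Interpret a generated cluster as an entity graph
#'
#' A generated cluster is a set of event nodes; its interpreted form is the
#' directed signed entity graph those events describe: every event
#' (regulator, regulated, sign) becomes an edge, duplicate edges merge, and
#' the entity set is split into overlap nodes (already in the baseline
#' model) and new nodes.
#'
#' @param events character vector of event keys (from `eclg_clusters$events`).
#' @param ees the `ees` the events come from.
#' @param model the baseline `model_graph`.
#' @param label cluster label carried through to the result.
#' @return object of class `interpreted_cluster`: list with `label`,
#'   `entities`, `edges` (src, dst, sign, event_key), `overlap_nodes`,
#'   `new_nodes` and `node_overlap` (percentage).
#' @export
interpret_cluster <- function(events, ees, model, label = NA_integer_) {
  stopifnot(inherits(ees, "ees"), inherits(model, "model_graph"))
  rows <- ees$events[ees$events$key %in% events, , drop = FALSE]
  if (nrow(rows) != length(unique(events))) {
    stop("cluster contains events absent from the EES", call. = FALSE)
  }
  edges <- unique(data.frame(src = rows$regulator_key, dst = rows$regulated_key,
                             sign = rows$sign, event_key = rows$key,
                             stringsAsFactors = FALSE))
  entities <- sort(unique(c(edges$src, edges$dst)))
  overlap <- intersect(entities, model$nodes)
  structure(list(label = label,
                 entities = entities,
                 edges = edges,
                 overlap_nodes = overlap,
                 new_nodes = setdiff(entities, overlap),
                 node_overlap = node_overlap(entities, model$nodes)),
            class = "interpreted_cluster")
}

#' @export
print.interpreted_cluster <- function(x, ...) {
  cat("Interpreted cluster", x$label, ":", length(x$entities), "entities,",
      nrow(x$edges), "directed edges, NO =",
      format(x$node_overlap, digits = 4), "%\n")
  invisible(x)
}

#' Find return paths between clusters and the baseline model
#'
#' A return path is a directed path whose edges all come from interpreted
#' clusters and whose first and last nodes are baseline-model elements;
#' interior nodes may be model elements or new entities. Such paths show
#' that the clusters feed back into the model rather than only hanging off
#' it. Enumeration is a depth-bounded DFS over simple paths in the union of
#' all interpreted-cluster edges.
#'
#' @param clusters list of `interpreted_cluster` objects.
#' @param model the baseline `model_graph`.
#' @param max_len maximum number of edges per path (bounded search; simple
#'   path enumeration is exponential without a cap).
#' @return list of `return_path` objects: `nodes` (entity key sequence),
#'   `edges` (data.frame src, dst, sign), `clusters` (labels whose edges
#'   the path uses).
#' @export
find_return_paths <- function(clusters, model, max_len = 6L) {
  stopifnot(inherits(model, "model_graph"), max_len >= 1L)
  if (length(clusters) == 0L) return(list())
  ed <- do.call(rbind, lapply(clusters, function(cl) {
    if (nrow(cl$edges) == 0L) return(NULL)
    cbind(cl$edges[, c("src", "dst", "sign")], cluster = cl$label)
  }))
  if (is.null(ed) || nrow(ed) == 0L) return(list())
  # merge parallel copies of the same signed edge across clusters
  ekey <- paste(ed$src, ed$dst, ed$sign, sep = "|")
  by_edge <- split(ed$cluster, ekey)
  uniq <- !duplicated(ekey)
  edges <- ed[uniq, c("src", "dst", "sign"), drop = FALSE]
  edges$clusters <- lapply(ekey[uniq], function(k) sort(unique(by_edge[[k]])))
  rownames(edges) <- NULL
  out_edges <- split(seq_len(nrow(edges)), edges$src)

  model_nodes <- model$nodes
  paths <- list()
  walk <- function(node, visited, edge_ids) {
    if (length(edge_ids) > 0L && node %in% model_nodes) {
      paths[[length(paths) + 1L]] <<- edge_ids
    }
    if (length(edge_ids) >= max_len) return(invisible())
    for (e in out_edges[[node]]) {
      nxt <- edges$dst[e]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), c(edge_ids, e))
    }
  }
  for (start in intersect(sort(model_nodes), names(out_edges))) {
    walk(start, start, integer(0))
  }
  lapply(paths, function(ids) {
    structure(list(
      nodes = c(edges$src[ids[1L]], edges$dst[ids]),
      edges = edges[ids, c("src", "dst", "sign"), drop = FALSE],
      clusters = sort(unique(unlist(edges$clusters[ids])))
    ), class = "return_path")
  })
}

#' @export
print.return_path <- function(x, ...) {
  cat("Return path:", paste(x$nodes, collapse = " -> "),
      "( clusters", paste(x$clusters, collapse = ", "), ")\n")
  invisible(x)
}

#' Select the best clusters for model extension
#'
#' A cluster qualifies for extension when either both literature-support
#' criteria hold - its average pair frequency class is the minimum and its
#' average weighted inverse frequency the maximum over all generated
#' clusters (ties all qualify) - or both model-support criteria hold: node
#' overlap above `no_threshold` percent and membership in at least one
#' return path. When a selected cluster shares a return path with other
#' clusters, those clusters are merged into the same extension set, so that
#' the extension connects back to the model as one piece.
#'
#' Clusters without intra-cluster edges have undefined literature averages
#' and can only qualify through model support.
#'
#' @param clusters the `clusters` data.frame of an `eclg_clusters` result
#'   (or an `eclg_clusters` object).
#' @param interpreted list of `interpreted_cluster` objects, one per
#'   generated cluster.
#' @param paths list of `return_path` objects from [find_return_paths()].
#' @param no_threshold node-overlap percentage required by the
#'   model-support rule (strict inequality).
#' @param element_of_interest optional entity key; when given, pairs of
#'   clusters containing the element as a regulated target and as a
#'   regulator source are checked for return paths first, and a connected
#'   pair is preferred as the selection.
#' @return object of class `extension_result`: `selected` labels, `reasons`
#'   per selected cluster, `events` (merged event keys), `entities`,
#'   `edges`, the score `table` (with node overlap), `paths` and a
#'   `diagnostic` (best cluster per criterion) when nothing qualifies.
#' @export
select_clusters <- function(clusters, interpreted, paths, no_threshold = 50,
                            element_of_interest = NULL) {
  if (inherits(clusters, "eclg_clusters")) clusters <- clusters$clusters
  stopifnot(is.data.frame(clusters))
  labels <- clusters$label
  no <- vapply(interpreted, function(x) x$node_overlap, 0)
  ilab <- vapply(interpreted, function(x) as.integer(x$label), 0L)
  no <- no[match(labels, ilab)]
  tab <- cbind(clusters, node_overlap = no)

  on_path <- lapply(stats::setNames(labels, labels), function(l) {
    which(vapply(paths, function(p) l %in% p$clusters, TRUE))
  })
  path_partners <- function(l) {
    hits <- on_path[[as.character(l)]]
    sort(unique(unlist(lapply(paths[hits], `[[`, "clusters"))))
  }

  defined <- !is.na(tab$fc_pa_avg)
  lit <- defined &
    tab$fc_pa_avg == suppressWarnings(min(tab$fc_pa_avg[defined])) &
    tab$if_pa_avg == suppressWarnings(max(tab$if_pa_avg[defined]))
  support <- tab$node_overlap > no_threshold &
    vapply(on_path[as.character(labels)], length, 0L) > 0L

  reasons <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_along(labels)) {
    r <- character(0)
    if (isTRUE(lit[i])) r <- c(r, "literature")
    if (isTRUE(support[i])) r <- c(r, "model-support")
    reasons[[i]] <- r
  }

  selected <- labels[lit | support]

  # element-of-interest mode: prefer source/target cluster pairs connected
  # by a return path through the element
  if (!is.null(element_of_interest)) {
    as_target <- labels[vapply(interpreted, function(x) {
      element_of_interest %in% x$edges$dst
    }, TRUE)[match(labels, ilab)]]
    as_source <- labels[vapply(interpreted, function(x) {
      element_of_interest %in% x$edges$src
    }, TRUE)[match(labels, ilab)]]
    for (a in as_target) for (b in as_source) {
      if (a == b) next
      joint <- any(vapply(paths, function(p) all(c(a, b) %in% p$clusters), TRUE))
      if (joint) {
        selected <- union(selected, c(a, b))
        reasons[[as.character(a)]] <- union(reasons[[as.character(a)]],
                                            "element-of-interest")
        reasons[[as.character(b)]] <- union(reasons[[as.character(b)]],
                                            "element-of-interest")
      }
    }
  }

  # merge: clusters sharing a return path with a selected cluster join the
  # extension set (transitively, so a chain of paths merges as one)
  repeat {
    extra <- setdiff(unlist(lapply(selected, path_partners)), selected)
    if (!length(extra)) break
    for (l in extra) {
      reasons[[as.character(l)]] <- union(reasons[[as.character(l)]],
                                          "return-path-merge")
    }
    selected <- sort(c(selected, extra))
  }
  selected <- sort(selected)

  diagnostic <- NULL
  if (!length(selected)) {
    diagnostic <- list(
      best_fc_pa_avg = if (any(defined)) labels[defined][which.min(tab$fc_pa_avg[defined])] else NA,
      best_if_pa_avg = if (any(defined)) labels[defined][which.max(tab$if_pa_avg[defined])] else NA,
      best_node_overlap = labels[which.max(tab$node_overlap)]
    )
  }

  sel_int <- interpreted[ilab %in% selected]
  edges <- unique(do.call(rbind, c(list(
    data.frame(src = character(0), dst = character(0), sign = character(0),
               event_key = character(0), stringsAsFactors = FALSE)),
    lapply(sel_int, `[[`, "edges"))))
  rownames(edges) <- NULL
  structure(list(
    selected = selected,
    reasons = reasons[as.character(selected)],
    events = sort(unique(edges$event_key)),
    entities = sort(unique(c(edges$src, edges$dst))),
    edges = edges,
    table = tab,
    paths = paths,
    no_threshold = no_threshold,
    diagnostic = diagnostic
  ), class = "extension_result")
}

#' @export
print.extension_result <- function(x, ...) {
  if (!length(x$selected)) {
    cat("No cluster satisfied the selection rule.\n")
    if (!is.null(x$diagnostic)) {
      cat("  best by avg pair FC:", x$diagnostic$best_fc_pa_avg,
          "; best by avg inverse frequency:", x$diagnostic$best_if_pa_avg,
          "; best by node overlap:", x$diagnostic$best_node_overlap, "\n")
    }
  } else {
    cat("Selected clusters:", paste(x$selected, collapse = ", "), "\n")
    for (l in names(x$reasons)) {
      cat("  cluster", l, ":", paste(x$reasons[[l]], collapse = " + "), "\n")
    }
    cat("  merged extension:", length(x$events), "events over",
        length(x$entities), "entities;", length(x$paths), "return paths\n")
  }
  invisible(x)
}

#' Extend a baseline model with the selected clusters
#'
#' Adds the union of the selected interpreted clusters' entity edges to the
#' model. Entities absent from the baseline become new elements whose name
#' carries the suffix `_ext` (database identifiers are carried over), and
#' every added regulation is appended to the regulated element's positive
#' or negative influence-set expression, joined by `,` (OR). Baseline edges
#' are never removed, and extending twice with the same result is a no-op
#' the second time.
#'
#' @param model the baseline `model_graph`.
#' @param result an `extension_result` with at least one selected cluster
#'   (an empty selection returns the model unchanged with a warning).
#' @param ees the `ees`, used for display names and identifiers of new
#'   entities.
#' @return the extended `model_graph`.
#' @export
extend_model <- function(model, result, ees) {
  stopifnot(inherits(model, "model_graph"), inherits(result, "extension_result"),
            inherits(ees, "ees"))
  if (!length(result$selected)) {
    warning("empty selection: model returned unchanged")
    return(model)
  }
  elements <- model$elements

  # display name, type, id of an entity as seen in the EES
  entity_info <- function(key) {
    ev <- ees$events
    i <- match(key, ev$regulator_key)
    if (!is.na(i)) {
      return(list(name = ev$regulator_name[i], type = ev$regulator_type[i],
                  db_id = ev$regulator_id[i]))
    }
    i <- match(key, ev$regulated_key)
    if (!is.na(i)) {
      return(list(name = ev$regulated_name[i], type = ev$regulated_type[i],
                  db_id = ev$regulated_id[i]))
    }
    list(name = key, type = "", db_id = "")
  }

  # entity key in the EES -> element key in the (possibly already extended)
  # model; new name-keyed entities land on the key of their "_ext" name
  remap <- stats::setNames(result$entities, result$entities)
  for (key in result$entities) {
    if (key %in% elements$key) next
    info <- entity_info(key)
    nm <- paste0(info$name, "_ext")
    ext_key <- canonical_key(nm, info$db_id)
    remap[key] <- ext_key
    if (ext_key %in% elements$key) next  # already added by an earlier run
    elements <- rbind(elements, data.frame(
      name = nm, type = info$type, db_id = info$db_id,
      variable = nm, pos_expr = "", neg_expr = "", evidence = "",
      stringsAsFactors = FALSE, key = ext_key
    ))
  }
  src <- unname(remap[result$edges$src])
  dst <- unname(remap[result$edges$dst])

  existing <- paste(model$edges$src, model$edges$dst, model$edges$sign)
  display <- stats::setNames(elements$name, elements$key)
  for (i in seq_len(nrow(result$edges))) {
    if (paste(src[i], dst[i], result$edges$sign[i]) %in% existing) next
    row <- match(dst[i], elements$key)
    if (is.na(row)) next  # defensive: target should always be an element now
    col <- if (result$edges$sign[i] == "positive") "pos_expr" else "neg_expr"
    token <- unname(display[src[i]])
    if (is.na(token)) token <- src[i]
    toks <- tryCatch(tokenize_influence_expr(elements[[col]][row])$token,
                     error = function(e) character(0))
    if (token %in% toks) next
    elements[[col]][row] <- if (nzchar(trimws(elements[[col]][row]))) {
      paste(elements[[col]][row], token, sep = ", ")
    } else token
  }
  model_from_elements(elements)
}
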