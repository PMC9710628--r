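#' Run the full literature-driven model-extension pipeline
#'
#' Orchestrates every stage: parse the reading table, build the extracted
#' event set, assemble the event collaboration graph, filter it to the
#' candidate graph, cluster by weighted modularity, interpret clusters
#' against the baseline model, find return paths, apply the selection rule
#' and extend the model; when a gold model is supplied the selection is
#' also scored by precision/recall. Intermediate artifacts and a fully
#' resolved configuration are written when `out_dir` is given, so a run is
#' reproducible from its outputs alone.
#'
#' @param reading path to a reading table, a `reading_parse` object, or a
#'   records data.frame.
#' @param model path to a BioRECIPES-style table or a `model_graph`.
#' @param gold optional gold-standard model (path or `model_graph`).
#' @param out_dir optional output directory for artifacts.
#' @param fc_threshold frequency-class filter threshold (integer or
#'   `"auto"`, the mean class rounded half-up).
#' @param neighbor_filter keep only most-frequent events and their
#'   co-occurrence neighbours.
#' @param drop_isolated drop nodes left without edges after filtering.
#' @param weight_key clustering edge weight (`"if_pa"`, `"fc_pa"`,
#'   `"f_ij"`).
#' @param no_threshold node-overlap percentage for the model-support rule.
#' @param max_path_len return-path search depth (edges).
#' @param element_of_interest optional entity key for the focused selection
#'   mode.
#' @param node_order_seed seed for the clustering sweep order.
#' @param reading_columns,model_columns column maps for the two parsers.
#' @param verbose log per-stage counts with `message()`.
#' @return object of class `litnetext_run` with every stage result:
#'   `parse`, `ees`, `eclg`, `candidate`, `clusters`, `interpreted`,
#'   `paths`, `selection`, `extended`, `evaluation` (NULL without a gold
#'   model) and the resolved `config`.
#' @export
run_pipeline <- function(reading, model, gold = NULL, out_dir = NULL,
                         fc_threshold = "auto", neighbor_filter = FALSE,
                         drop_isolated = FALSE, weight_key = "if_pa",
                         no_threshold = 50, max_path_len = 6L,
                         element_of_interest = NULL, node_order_seed = 1L,
                         reading_columns = default_reading_columns(),
                         model_columns = default_model_columns(),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  parse <- NULL
  if (is.character(reading)) {
    parse <- stage("parse reading table",
                   parse_reading_table(reading, reading_columns))
    say("parsed reading table: ", parse$report$rows_kept, " records (",
        parse$report$rows_dropped, " dropped)")
    records <- parse$records
  } else records <- reading

  if (is.character(model)) {
    model <- stage("parse model", parse_model(model, model_columns))
  }
  stopifnot(inherits(model, "model_graph"))
  if (!is.null(gold) && is.character(gold)) {
    gold <- stage("parse gold model", parse_model(gold, model_columns))
  }

  ees <- stage("build EES", build_ees(records))
  say("extracted event set: N = ", ees$N, ", M = ", ees$M,
      ", f_max = ", ees$f_max)
  corroborating <- flag_model_events(ees, model)
  if (length(corroborating)) {
    say(length(corroborating), " events match existing model edges (flagged,",
        " kept)")
  }

  eclg <- stage("build ECLG", build_eclg(ees))
  say("event collaboration graph: ", igraph::vcount(eclg$graph), " nodes, ",
      igraph::ecount(eclg$graph), " edges")

  candidate <- stage("filter ECLG",
                     filter_eclg(eclg, fc_threshold = fc_threshold,
                                 neighbor_filter = neighbor_filter,
                                 drop_isolated = drop_isolated))
  say("candidate ECLG after FC threshold ",
      candidate$filter_report$fc_threshold, ": ",
      candidate$filter_report$nodes_after, " nodes (",
      candidate$filter_report$removed_by_fc, " rare events removed)")

  clusters <- stage("cluster", louvain(candidate, weight_key = weight_key,
                                       node_order_seed = node_order_seed))
  covered <- unique(unlist(ees$papers[unlist(clusters$events)]))
  say("generated ", nrow(clusters$clusters), " clusters (Q = ",
      format(clusters$partition$Q, digits = 4), "), covering ",
      length(covered), " papers")

  interpreted <- stage("interpret clusters", lapply(
    seq_len(nrow(clusters$clusters)), function(i) {
      interpret_cluster(clusters$events[[i]], ees, model,
                        label = clusters$clusters$label[i])
    }))

  paths <- stage("return paths",
                 find_return_paths(interpreted, model, max_len = max_path_len))
  say(length(paths), " return paths found")

  selection <- stage("select clusters",
                     select_clusters(clusters, interpreted, paths,
                                     no_threshold = no_threshold,
                                     element_of_interest = element_of_interest))
  say("selected clusters: ",
      if (length(selection$selected)) paste(selection$selected, collapse = ", ")
      else "none")

  extended <- if (length(selection$selected)) {
    stage("extend model", extend_model(model, selection, ees))
  } else {
    say("empty selection: model left unchanged")
    model
  }

  evaluation <- NULL
  if (!is.null(gold)) {
    evaluation <- stage("evaluate",
                        evaluate_extension(selection, gold, model, ees))
  } else {
    say("no gold model given: evaluation skipped")
  }

  config <- list(fc_threshold = fc_threshold,
                 fc_threshold_resolved = candidate$filter_report$fc_threshold,
                 neighbor_filter = neighbor_filter,
                 drop_isolated = drop_isolated,
                 weight_key = weight_key, no_threshold = no_threshold,
                 max_path_len = max_path_len,
                 element_of_interest = element_of_interest,
                 node_order_seed = node_order_seed)

  run <- structure(list(parse = parse, ees = ees, eclg = eclg,
                        candidate = candidate, clusters = clusters,
                        interpreted = interpreted, paths = paths,
                        selection = selection, extended = extended,
                        evaluation = evaluation,
                        corroborating_events = corroborating,
                        config = config), class = "litnetext_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' Write every pipeline artifact to a directory
#'
#' @param run a `litnetext_run`.
#' @param out_dir output directory (created if needed).
#' @export
write_run_artifacts <- function(run, out_dir) {
  stopifnot(inherits(run, "litnetext_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_ees(run$ees, p("ees.tsv"))
  if (!is.null(run$parse)) {
    jsonlite::write_json(run$parse$report, p("parse_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  export_graphml(run$candidate, p("candidate_eclg.graphml"))
  write_eclg_tables(run$candidate, p("eclg_nodes.tsv"), p("eclg_edges.tsv"))
  assignment <- run$clusters$partition$assignment
  write_table_file(data.frame(event_key = names(assignment),
                              cluster = unname(assignment)),
                   p("cluster_membership.tsv"))
  write_table_file(run$selection$table, p("cluster_scores.tsv"))
  jsonlite::write_json(list(
    selected = run$selection$selected,
    reasons = run$selection$reasons,
    no_threshold = run$selection$no_threshold,
    weight_note = if (run$config$weight_key == "fc_pa")
      "clustering used inverted pair frequency class (max - fc + 1)" else NULL,
    filter_report = run$candidate$filter_report,
    corroborating_events = run$corroborating_events,
    rankings = list(
      by_fc_pa_avg = run$selection$table$label[order(run$selection$table$fc_pa_avg)],
      by_if_pa_avg = run$selection$table$label[order(-run$selection$table$if_pa_avg)],
      by_node_overlap = run$selection$table$label[order(-run$selection$table$node_overlap)]
    ),
    return_paths = lapply(run$paths, function(x)
      list(nodes = x$nodes, clusters = x$clusters))
  ), p("selection_report.json"), auto_unbox = TRUE, pretty = TRUE,
  null = "null", na = "null")
  write_model(run$extended, p("extended_model.tsv"))
  if (!is.null(run$evaluation)) {
    write_eval_report(run$evaluation, p("eval_report.json"))
  }
  jsonlite::write_json(run$config, p("run_config.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.litnetext_run <- function(x, ...) {
  cat("Literature-driven model extension run\n")
  print(x$ees)
  print(x$candidate)
  cat("Clusters:", nrow(x$clusters$clusters), "; selected:",
      if (length(x$selection$selected))
        paste(x$selection$selected, collapse = ", ") else "none", "\n")
  cat("Extended model:", length(x$extended$nodes), "elements,",
      nrow(x$extended$edges), "edges\n")
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
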