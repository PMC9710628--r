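#' Precision and recall against a gold-standard model
#'
#' Scores a selected extension against a curated gold model. Precision is
#' the fraction of selected events (entities) that are part of the gold
#' model. Recall is computed against the recoverable part of the gold
#' model only: gold events (entities) that actually occur in the extracted
#' event set and are absent from the baseline model - items the method
#' could possibly have found. Events are compared as (regulator, regulated,
#' sign) triples on canonical keys; with `sign_specific = FALSE` the sign
#' is ignored in matching.
#'
#' @param result an `extension_result`.
#' @param gold the gold-standard `model_graph`.
#' @param baseline the baseline `model_graph`.
#' @param ees the `ees` the selection was made from.
#' @param sign_specific whether the interaction sign is part of event
#'   identity during matching.
#' @return object of class `eval_report`: the four scores
#'   (`event_precision`, `entity_precision`, `event_recall`,
#'   `entity_recall`; precision is NA for an empty selection) and the
#'   underlying true/false positive and false negative sets.
#' @export
evaluate_extension <- function(result, gold, baseline, ees,
                               sign_specific = TRUE) {
  stopifnot(inherits(result, "extension_result"), inherits(gold, "model_graph"),
            inherits(baseline, "model_graph"), inherits(ees, "ees"))
  tag <- function(src, dst, sign) {
    if (sign_specific) paste(src, dst, sign, sep = "|") else paste(src, dst, sep = "|")
  }
  sel_events <- unique(tag(result$edges$src, result$edges$dst, result$edges$sign))
  gold_events <- unique(tag(gold$edges$src, gold$edges$dst, gold$edges$sign))
  base_events <- unique(tag(baseline$edges$src, baseline$edges$dst,
                            baseline$edges$sign))
  ees_events <- unique(tag(ees$events$regulator_key, ees$events$regulated_key,
                           ees$events$sign))

  sel_entities <- result$entities
  gold_entities <- gold$nodes
  base_entities <- baseline$nodes
  ees_entities <- unique(c(ees$events$regulator_key, ees$events$regulated_key))

  recoverable_events <- setdiff(intersect(gold_events, ees_events), base_events)
  recoverable_entities <- setdiff(intersect(gold_entities, ees_entities),
                                  base_entities)

  tp_events <- intersect(sel_events, gold_events)
  tp_entities <- intersect(sel_entities, gold_entities)

  ratio <- function(num, den) if (den == 0L) NA_real_ else num / den
  structure(list(
    event_precision = ratio(length(tp_events), length(sel_events)),
    entity_precision = ratio(length(tp_entities), length(sel_entities)),
    event_recall = if (length(recoverable_events) == 0L) NA_real_ else
      length(intersect(sel_events, recoverable_events)) /
      length(recoverable_events),
    entity_recall = if (length(recoverable_entities) == 0L) NA_real_ else
      length(intersect(sel_entities, recoverable_entities)) /
      length(recoverable_entities),
    true_events = sort(tp_events),
    false_positive_events = sort(setdiff(sel_events, gold_events)),
    false_negative_events = sort(setdiff(recoverable_events, sel_events)),
    true_entities = sort(tp_entities),
    false_positive_entities = sort(setdiff(sel_entities, gold_entities)),
    false_negative_entities = sort(setdiff(recoverable_entities, sel_entities)),
    recoverable_events = sort(recoverable_events),
    recoverable_entities = sort(recoverable_entities),
    sign_specific = sign_specific
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)
  cat("Evaluation against the gold model",
      if (!x$sign_specific) "(sign-agnostic)" else "", "\n")
  cat("  event precision :", fmt(x$event_precision),
      " event recall :", fmt(x$event_recall), "\n")
  cat("  entity precision:", fmt(x$entity_precision),
      " entity recall:", fmt(x$entity_recall), "\n")
  cat("  recoverable gold events:", length(x$recoverable_events),
      "; false negatives:", length(x$false_negative_events), "\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
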