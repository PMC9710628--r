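#' Default column map for machine-reading tables
#'
#' Maps the logical fields of an extracted event to the column headers of a
#' typical reading-engine export: one row per event, a directed signed
#' interaction between a regulator entity and a regulated entity, together
#' with the source paper and the evidence sentence.
#'
#' @return named character vector: logical field -> column header.
#' @export
default_reading_columns <- function() {
  c(regulator_name = "Regulator Name",
    regulator_type = "Regulator Type",
    regulator_id   = "Regulator ID",
    regulated_name = "Regulated Name",
    regulated_type = "Regulated Type",
    regulated_id   = "Regulated ID",
    interaction    = "Interaction",
    paper_id       = "Paper ID",
    evidence       = "Evidence")
}

# interaction-sign lexicon; unknown tokens cause the row to be dropped
.sign_lexicon <- list(
  positive = c("increases", "activates", "positive", "+"),
  negative = c("decreases", "inhibits", "negative", "-")
)

normalize_sign <- function(token) {
  tok <- tolower(trimws(token))
  out <- rep(NA_character_, length(tok))
  out[tok %in% .sign_lexicon$positive] <- "positive"
  out[tok %in% .sign_lexicon$negative] <- "negative"
  out
}

.mandatory_fields <- c("regulator_name", "regulated_name", "interaction", "paper_id")
.optional_fields <- c("regulator_type", "regulator_id", "regulated_type",
                      "regulated_id", "evidence")

#' Parse a machine-reading event table
#'
#' Reads a delimited table (TSV or CSV; dialect inferred from the extension)
#' of extracted events, normalizes entity names and interaction signs, and
#' drops rows that cannot be used (missing regulator/regulated name, missing
#' paper identifier, or an interaction token outside the sign lexicon).
#'
#' @param path file path of the table.
#' @param column_map named character vector mapping logical fields
#'   (see [default_reading_columns()]) to column headers in the file.
#'   Optional fields missing from the file are filled with "".
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return object of class `reading_parse`: a list with `records` (a
#'   data.frame of normalized event records) and `report` (rows read,
#'   rows kept, drop counts by reason).
#' @export
parse_reading_table <- function(path, column_map = default_reading_columns(),
                                sep = NULL) {
  defaults <- default_reading_columns()
  missing_map <- setdiff(names(defaults), names(column_map))
  column_map <- c(column_map, defaults[missing_map])

  raw <- read_table_file(path, sep)
  for (field in .mandatory_fields) {
    if (!column_map[[field]] %in% names(raw)) {
      stop("reading table is missing mandatory column '", column_map[[field]],
           "' (field ", field, ")", call. = FALSE)
    }
  }
  rows_read <- nrow(raw)
  get_col <- function(field) {
    header <- column_map[[field]]
    if (header %in% names(raw)) raw[[header]] else rep("", rows_read)
  }
  rec <- data.frame(
    regulator_name = trimws(get_col("regulator_name")),
    regulator_type = trimws(get_col("regulator_type")),
    regulator_id   = trimws(get_col("regulator_id")),
    regulated_name = trimws(get_col("regulated_name")),
    regulated_type = trimws(get_col("regulated_type")),
    regulated_id   = trimws(get_col("regulated_id")),
    sign           = normalize_sign(get_col("interaction")),
    paper_id       = trimws(get_col("paper_id")),
    evidence       = get_col("evidence"),
    stringsAsFactors = FALSE
  )

  reasons <- character(0)
  drop <- rep(FALSE, rows_read)
  flag <- function(bad, why) {
    new <- bad & !drop
    if (any(new)) reasons <<- c(reasons, rep(why, sum(new)))
    drop <<- drop | bad
  }
  if (rows_read > 0L) {
    flag(!nzchar(rec$regulator_name), "empty regulator name")
    flag(!nzchar(rec$regulated_name), "empty regulated name")
    flag(is.na(rec$sign), "unknown interaction token")
    flag(!nzchar(rec$paper_id), "empty paper id")
  }
  records <- rec[!drop, , drop = FALSE]
  rownames(records) <- NULL

  report <- list(
    rows_read = rows_read,
    rows_kept = nrow(records),
    rows_dropped = sum(drop),
    drop_reasons = as.list(table(reasons))
  )
  structure(list(records = records, report = report), class = "reading_parse")
}

#' @export
print.reading_parse <- function(x, ...) {
  cat("Machine-reading parse:", x$report$rows_read, "rows read,",
      x$report$rows_kept, "kept,", x$report$rows_dropped, "dropped\n")
  if (length(x$report$drop_reasons)) {
    for (r in names(x$report$drop_reasons)) {
      cat("  -", r, ":", x$report$drop_reasons[[r]], "\n")
    }
  }
  invisible(x)
}

#' Build the extracted event set (EES)
#'
#' Groups normalized event records into distinct events. A distinct event is
#' identified by (regulator canonical key, regulated canonical key, sign);
#' interaction subtype is not part of the identity. For each distinct event
#' the occurrence count f_i (number of records) and the set of supporting
#' papers are collected. Duplicate sentences within one paper raise f_i but
#' add only one paper, so occurrence counts and paper-based co-occurrence
#' stay distinct quantities.
#'
#' @param records data.frame of event records as produced by
#'   [parse_reading_table()], or a `reading_parse` object.
#' @return object of class `ees`: list with `events` (one row per distinct
#'   event: key, endpoint keys/names/types/ids, sign, `f_i`, `n_papers`),
#'   `papers` (named list: event key -> character vector of paper ids),
#'   `records` (the input records with their event key), and the summary
#'   counts `N` (total events), `M` (distinct events) and `f_max`.
#' @export
build_ees <- function(records) {
  if (inherits(records, "reading_parse")) records <- records$records
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    events <- data.frame(key = character(0), regulator_key = character(0),
                         regulated_key = character(0), sign = character(0),
                         regulator_name = character(0), regulator_type = character(0),
                         regulator_id = character(0), regulated_name = character(0),
                         regulated_type = character(0), regulated_id = character(0),
                         f_i = integer(0), n_papers = integer(0),
                         stringsAsFactors = FALSE)
    return(structure(list(events = events, papers = list(), records = records,
                          N = 0L, M = 0L, f_max = 0L), class = "ees"))
  }
  reg_key <- canonical_key(records$regulator_name, records$regulator_id)
  tgt_key <- canonical_key(records$regulated_name, records$regulated_id)
  key <- event_key(reg_key, tgt_key, records$sign)
  records$key <- key

  ord_keys <- sort(unique(key))
  idx <- split(seq_len(nrow(records)), factor(key, levels = ord_keys))
  first <- vapply(idx, `[`, 0L, 1L)
  events <- data.frame(
    key = ord_keys,
    regulator_key = reg_key[first],
    regulated_key = tgt_key[first],
    sign = records$sign[first],
    regulator_name = records$regulator_name[first],
    regulator_type = records$regulator_type[first],
    regulator_id = records$regulator_id[first],
    regulated_name = records$regulated_name[first],
    regulated_type = records$regulated_type[first],
    regulated_id = records$regulated_id[first],
    f_i = vapply(idx, length, 0L),
    n_papers = vapply(idx, function(i) length(unique(records$paper_id[i])), 0L),
    stringsAsFactors = FALSE
  )
  rownames(events) <- NULL
  papers <- lapply(idx, function(i) sort(unique(records$paper_id[i])))

  structure(list(events = events, papers = papers, records = records,
                 N = nrow(records), M = nrow(events),
                 f_max = max(events$f_i)), class = "ees")
}

#' @export
print.ees <- function(x, ...) {
  cat("Extracted event set:", x$N, "events,", x$M, "distinct (f_max =",
      x$f_max, ")\n")
  cat("  papers:", length(unique(x$records$paper_id)), "\n")
  invisible(x)
}

#' Write an EES back to the reading-table dialect
#'
#' Writes the normalized per-occurrence records so that re-parsing with
#' [parse_reading_table()] and [build_ees()] reproduces identical events and
#' counts.
#'
#' @param ees an `ees` object.
#' @param path output file (TSV, or CSV by extension).
#' @export
write_ees <- function(ees, path) {
  stopifnot(inherits(ees, "ees"))
  cols <- default_reading_columns()
  out <- data.frame(
    ees$records$regulator_name, ees$records$regulator_type,
    ees$records$regulator_id, ees$records$regulated_name,
    ees$records$regulated_type, ees$records$regulated_id,
    ees$records$sign, ees$records$paper_id, ees$records$evidence,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unname(cols)
  write_table_file(out, path)
  invisible(path)
}

#' Flag EES events already present in a model
#'
#' Events whose (regulator, regulated, sign) triple matches an existing model
#' edge corroborate the model rather than extend it. They are flagged (never
#' removed): classification of corroborating/contradicting evidence is
#' assumed to have happened upstream, but the flag is useful in run reports.
#'
#' @param ees an `ees` object.
#' @param model a `model_graph` object.
#' @return character vector of event keys that match a model edge.
#' @export
flag_model_events <- function(ees, model) {
  stopifnot(inherits(ees, "ees"), inherits(model, "model_graph"))
  model_keys <- event_key(model$edges$src, model$edges$dst, model$edges$sign)
  ees$events$key[ees$events$key %in% model_keys]
}
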