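#' Default column map for BioRECIPES-style element tables
#'
#' One row per model element: its name, type, database identifier, state
#' variable, the influence-set expressions listing positive and negative
#' regulators, and free-text evidence. In the expressions `!` is logical
#' NOT, `()` group for logical AND and `,` separates alternatives (OR).
#'
#' @return named character vector: logical field -> column header.
#' @export
default_model_columns <- function() {
  c(name     = "Element Name",
    type     = "Element Type",
    db_id    = "Element ID",
    variable = "Variable",
    pos_expr = "Positive Regulators",
    neg_expr = "Negative Regulators",
    evidence = "Evidence")
}

# Tokenize an influence-set expression on { '!', '(', ')', ',' }.
# Returns data.frame(token, negated). '!' flips the sign of the token (or
# parenthesized group) it prefixes; nesting is tracked with a stack so that
# "!(A, B)" negates both tokens. Unbalanced parentheses are an error.
tokenize_influence_expr <- function(expr) {
  empty <- data.frame(token = character(0), negated = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(expr) || is.na(expr) || !nzchar(trimws(expr))) return(empty)
  chars <- strsplit(expr, "")[[1]]
  tokens <- character(0)
  negated <- logical(0)
  neg_stack <- FALSE        # effective negation of the enclosing context
  pending_neg <- FALSE
  buf <- character(0)
  flush_buf <- function() {
    tok <- trimws(paste(buf, collapse = ""))
    if (nzchar(tok)) {
      tokens <<- c(tokens, tok)
      negated <<- c(negated, xor(neg_stack[length(neg_stack)], pending_neg))
      pending_neg <<- FALSE
    }
    buf <<- character(0)
  }
  for (ch in chars) {
    if (ch == "!") {
      flush_buf()
      pending_neg <- !pending_neg
    } else if (ch == "(") {
      flush_buf()
      neg_stack <- c(neg_stack, xor(neg_stack[length(neg_stack)], pending_neg))
      pending_neg <- FALSE
    } else if (ch == ")") {
      flush_buf()
      if (length(neg_stack) == 1L) stop("unbalanced parentheses", call. = FALSE)
      neg_stack <- neg_stack[-length(neg_stack)]
    } else if (ch == ",") {
      flush_buf()
      pending_neg <- FALSE
    } else {
      buf <- c(buf, ch)
    }
  }
  flush_buf()
  if (length(neg_stack) != 1L) stop("unbalanced parentheses", call. = FALSE)
  data.frame(token = tokens, negated = negated, stringsAsFactors = FALSE)
}

# Build a model_graph from an element data.frame with the logical columns
# name/type/db_id/variable/pos_expr/neg_expr/evidence.
model_from_elements <- function(elements) {
  stopifnot(is.data.frame(elements))
  if (nrow(elements) == 0L) stop("model has no elements", call. = FALSE)
  for (col in names(default_model_columns())) {
    if (is.null(elements[[col]])) elements[[col]] <- rep("", nrow(elements))
    elements[[col]][is.na(elements[[col]])] <- ""
  }
  elements$key <- canonical_key(elements$name, elements$db_id)

  # regulator tokens may be written as element names or state variables
  fold <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  lookup <- c(stats::setNames(elements$key, fold(elements$name)),
              stats::setNames(elements$key, fold(elements$variable)))
  lookup <- lookup[nzchar(names(lookup))]

  src <- character(0); dst <- character(0); sgn <- character(0)
  for (i in seq_len(nrow(elements))) {
    for (side in c("pos_expr", "neg_expr")) {
      toks <- tryCatch(tokenize_influence_expr(elements[[side]][i]),
                       error = function(e) {
                         stop("element '", elements$name[i], "': ",
                              conditionMessage(e), call. = FALSE)
                       })
      if (nrow(toks) == 0L) next
      base_sign <- if (side == "pos_expr") "positive" else "negative"
      s <- ifelse(toks$negated,
                  ifelse(base_sign == "positive", "negative", "positive"),
                  base_sign)
      k <- lookup[fold(toks$token)]
      k[is.na(k)] <- fold(toks$token)[is.na(k)]
      src <- c(src, unname(k))
      dst <- c(dst, rep(elements$key[i], nrow(toks)))
      sgn <- c(sgn, s)
    }
  }
  edges <- unique(data.frame(src = src, dst = dst, sign = sgn,
                             stringsAsFactors = FALSE))
  edges <- edges[order(edges$src, edges$dst, edges$sign), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(elements$key, edges$src, edges$dst)))
  key_to_name <- stats::setNames(elements$name, elements$key)
  structure(list(elements = elements, nodes = nodes, edges = edges,
                 key_to_name = key_to_name), class = "model_graph")
}

#' Parse a BioRECIPES-style model table
#'
#' Reads an element table (TSV/CSV) and exposes the model as a directed
#' signed graph: each regulator appearing in an element's positive
#' (negative) influence-set expression contributes a positive (negative)
#' edge into that element, with `!` flipping the sign of the token it
#' prefixes. The AND/OR structure of the update functions is preserved
#' verbatim in the element table for round-tripping; only the influence
#' structure is used downstream.
#'
#' @param path file path of the element table.
#' @param column_map named character vector mapping logical fields (see
#'   [default_model_columns()]) to column headers.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return object of class `model_graph`: list with `elements` (the table,
#'   plus canonical `key`), `nodes` (canonical keys), `edges`
#'   (src, dst, sign) and `key_to_name`.
#' @export
parse_model <- function(path, column_map = default_model_columns(), sep = NULL) {
  defaults <- default_model_columns()
  missing_map <- setdiff(names(defaults), names(column_map))
  column_map <- c(column_map, defaults[missing_map])
  raw <- read_table_file(path, sep)
  if (nrow(raw) == 0L) stop("model has no elements", call. = FALSE)
  if (!column_map[["name"]] %in% names(raw)) {
    stop("model table is missing column '", column_map[["name"]], "'",
         call. = FALSE)
  }
  elements <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                         name = trimws(raw[[column_map[["name"]]]]))
  for (field in setdiff(names(defaults), "name")) {
    header <- column_map[[field]]
    elements[[field]] <- if (header %in% names(raw)) raw[[header]] else ""
  }
  elements <- elements[nzchar(elements$name), , drop = FALSE]
  if (nrow(elements) == 0L) stop("model has no elements", call. = FALSE)
  model_from_elements(elements)
}

#' Write a model back to the BioRECIPES-style table
#'
#' Re-parsing the written table yields a graph with identical nodes and
#' edges.
#'
#' @param model a `model_graph` object.
#' @param path output file (TSV, or CSV by extension).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "model_graph"))
  cols <- default_model_columns()
  out <- model$elements[, names(cols), drop = FALSE]
  names(out) <- unname(cols)
  write_table_file(out, path)
  invisible(path)
}

#' Convert a model to an igraph object
#'
#' @param model a `model_graph`.
#' @return a directed igraph with edge attribute `sign`.
#' @export
model_to_igraph <- function(model) {
  stopifnot(inherits(model, "model_graph"))
  g <- igraph::graph_from_data_frame(model$edges, directed = TRUE,
                                     vertices = data.frame(name = model$nodes))
  g
}

#' Export a model or an event collaboration graph as GraphML
#'
#' @param x a `model_graph` or an `eclg` object.
#' @param path output `.graphml` file.
#' @export
export_graphml <- function(x, path) {
  g <- if (inherits(x, "model_graph")) model_to_igraph(x)
       else if (inherits(x, "eclg")) x$graph
       else stop("cannot export object of class ", paste(class(x), collapse = "/"))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
print.model_graph <- function(x, ...) {
  cat("Model graph:", length(x$nodes), "elements,", nrow(x$edges),
      "signed edges\n")
  invisible(x)
}
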