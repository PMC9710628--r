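#' Frequency class of a single event
#'
#' The frequency class of a distinct event with occurrence count `f_i` in an
#' extracted event set whose most frequent event occurs `f_max` times is
#' `floor(0.5 - log2(f_i / f_max))`. The most frequent event(s) get class 0;
#' an event half as frequent gets class 1; each further halving adds one
#' class. Borrowed from the frequency-class ("Haufigkeitsklasse") metric for
#' word frequencies in corpus linguistics.
#'
#' @param f_i occurrence count(s) of the event, integer >= 1.
#' @param f_max occurrence count of the most frequent event; `f_i <= f_max`.
#' @return integer frequency class(es), >= 0.
#' @export
fc_ia <- function(f_i, f_max) frequency_class(f_i, f_max)

#' Frequency class of a pair of events
#'
#' Same construction as [fc_ia()] applied to co-occurrence counts: `f_ij` is
#' the number of distinct papers in which both events occur, and
#' `f_max_pair` the largest such count over all co-occurring pairs. Low
#' values mean strong co-occurrence support.
#'
#' @param f_ij co-occurrence count(s), integer >= 1.
#' @param f_max_pair maximum co-occurrence count; `f_ij <= f_max_pair`.
#' @return integer frequency class(es), >= 0.
#' @export
fc_pa <- function(f_ij, f_max_pair) frequency_class(f_ij, f_max_pair)

frequency_class <- function(f, fmax) {
  if (length(fmax) == 1L) fmax <- rep(fmax, length(f))
  if (any(f <= 0) || any(fmax <= 0)) {
    stop("frequency class needs positive counts", call. = FALSE)
  }
  if (any(f > fmax)) stop("frequency exceeds the maximum frequency", call. = FALSE)
  as.integer(floor(0.5 - log2(f / fmax)))
}

#' Weighted inverse-frequency pair score
#'
#' `if_pa = f_ij * (ln(N / f_i) + ln(N / f_j))`: the co-occurrence count of
#' a pair of events weighted by the summed log inverse relative frequencies
#' of the two events. Unlike the pair frequency class, this score grows with
#' co-occurrence and favours rare but repeatedly co-mentioned events; high
#' values mean strong support.
#'
#' @param f_ij number of distinct papers containing both events, >= 1.
#' @param f_i,f_j occurrence counts of the two events, >= 1.
#' @param N total number of events in the extracted event set.
#' @return numeric score(s) >= 0.
#' @export
if_pa <- function(f_ij, f_i, f_j, N) {
  if (any(f_ij <= 0) || any(f_i <= 0) || any(f_j <= 0) || any(N <= 0)) {
    stop("if_pa needs positive counts", call. = FALSE)
  }
  if (any(f_i > N) || any(f_j > N)) {
    stop("event frequency cannot exceed the total event count", call. = FALSE)
  }
  f_ij * (log(N / f_i) + log(N / f_j))
}

#' Build the event collaboration graph (ECLG)
#'
#' The ECLG is a weighted undirected graph with one node per distinct event
#' of the extracted event set and one edge for every pair of events that
#' co-occur in at least one common paper. Node weights are the occurrence
#' frequency class [fc_ia()]; edge weights are the number of shared papers
#' `f_ij`, the pair frequency class [fc_pa()] and the weighted inverse
#' frequency [if_pa()].
#'
#' @param ees an `ees` object with at least one distinct event.
#' @return object of class `eclg`: list with `graph` (igraph; vertex
#'   attributes `f_i`, `fc_ia`; edge attributes `f_ij`, `fc_pa`, `if_pa`),
#'   `N`, `f_max`, `f_max_pair` and `filter_report` (NULL until filtered).
#' @export
build_eclg <- function(ees) {
  stopifnot(inherits(ees, "ees"))
  if (ees$M < 1L) stop("nothing to build: the event set is empty", call. = FALSE)
  ev <- ees$events

  # invert event -> papers into paper -> events, then count shared papers
  paper_events <- split(
    rep(names(ees$papers), lengths(ees$papers)),
    unlist(ees$papers, use.names = FALSE)
  )
  pair_count <- new.env(parent = emptyenv())
  for (evs in paper_events) {
    evs <- sort(unique(evs))
    if (length(evs) < 2L) next
    pairs <- utils::combn(evs, 2L)
    for (p in seq_len(ncol(pairs))) {
      k <- paste(pairs[1L, p], pairs[2L, p], sep = "\r")
      pair_count[[k]] <- (if (is.null(pair_count[[k]])) 0L else pair_count[[k]]) + 1L
    }
  }
  pair_keys <- sort(ls(pair_count))
  f_ij <- vapply(pair_keys, function(k) pair_count[[k]], 0L)
  ends <- strsplit(pair_keys, "\r", fixed = TRUE)
  e_from <- vapply(ends, `[`, "", 1L)
  e_to <- vapply(ends, `[`, "", 2L)

  fmax <- ees$f_max
  fc <- fc_ia(ev$f_i, fmax)
  vertices <- data.frame(name = ev$key, f_i = ev$f_i, fc_ia = fc,
                         stringsAsFactors = FALSE)
  f_max_pair <- if (length(f_ij)) max(f_ij) else 0L
  if (length(f_ij)) {
    fi <- stats::setNames(ev$f_i, ev$key)
    edges <- data.frame(from = e_from, to = e_to, f_ij = f_ij,
                        fc_pa = fc_pa(f_ij, f_max_pair),
                        if_pa = if_pa(f_ij, fi[e_from], fi[e_to], ees$N),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        f_ij = integer(0), fc_pa = integer(0),
                        if_pa = numeric(0), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  structure(list(graph = g, N = ees$N, f_max = fmax, f_max_pair = f_max_pair,
                 filter_report = NULL), class = "eclg")
}

eclg_nodes <- function(g) {
  data.frame(key = igraph::V(g$graph)$name,
             f_i = igraph::V(g$graph)$f_i,
             fc_ia = igraph::V(g$graph)$fc_ia,
             stringsAsFactors = FALSE)
}

eclg_edges <- function(g) {
  el <- igraph::as_edgelist(g$graph)
  data.frame(from = el[, 1L], to = el[, 2L],
             f_ij = igraph::E(g$graph)$f_ij,
             fc_pa = igraph::E(g$graph)$fc_pa,
             if_pa = igraph::E(g$graph)$if_pa,
             stringsAsFactors = FALSE)
}

#' Filter an ECLG down to the candidate graph
#'
#' Removes the least frequent events: every node whose frequency class
#' exceeds `fc_threshold` is dropped with its incident edges. The default
#' threshold `"auto"` is the mean frequency class over all distinct events,
#' rounded half-up to an integer. Optionally, nodes not adjacent to any
#' most-frequent node (class 0) can also be removed, keeping only events
#' that co-occur with the best-supported ones. Pair metrics are recomputed
#' on the surviving graph, since the maximum co-occurrence count may change.
#'
#' @param g an `eclg` object.
#' @param fc_threshold integer >= 0, or `"auto"`.
#' @param neighbor_filter if TRUE, additionally keep only class-0 nodes and
#'   their neighbours.
#' @param drop_isolated if TRUE, drop nodes left without edges (by default
#'   they are retained and may form singleton clusters).
#' @return the filtered `eclg`; `$filter_report` records the resolved
#'   threshold and per-rule removal counts.
#' @export
filter_eclg <- function(g, fc_threshold = "auto", neighbor_filter = FALSE,
                        drop_isolated = FALSE) {
  stopifnot(inherits(g, "eclg"))
  fc <- igraph::V(g$graph)$fc_ia
  if (identical(fc_threshold, "auto")) {
    fc_threshold <- round_half_up(mean(fc))
  }
  fc_threshold <- as.integer(fc_threshold)
  if (is.na(fc_threshold) || fc_threshold < 0L) {
    stop("fc_threshold must be a non-negative integer or \"auto\"", call. = FALSE)
  }
  graph <- g$graph
  too_rare <- igraph::V(graph)$name[igraph::V(graph)$fc_ia > fc_threshold]
  graph <- igraph::delete_vertices(graph, too_rare)

  removed_neighbor <- character(0)
  if (neighbor_filter) {
    top <- which(igraph::V(graph)$fc_ia == 0L)
    keep <- rep(FALSE, igraph::vcount(graph))
    keep[top] <- TRUE
    if (length(top)) {
      nb <- unlist(igraph::adjacent_vertices(graph, top))
      keep[nb] <- TRUE
    }
    removed_neighbor <- igraph::V(graph)$name[!keep]
    graph <- igraph::delete_vertices(graph, removed_neighbor)
  }

  removed_isolated <- character(0)
  if (drop_isolated) {
    removed_isolated <- igraph::V(graph)$name[igraph::degree(graph) == 0L]
    graph <- igraph::delete_vertices(graph, removed_isolated)
  }

  if (igraph::vcount(graph) == 0L) {
    stop("empty candidate ECLG: filtering removed every node", call. = FALSE)
  }

  # pair metrics are re-derived on the graph now in force
  f_ij <- igraph::E(graph)$f_ij
  f_max_pair <- if (length(f_ij)) max(f_ij) else 0L
  if (length(f_ij)) {
    igraph::E(graph)$fc_pa <- fc_pa(f_ij, f_max_pair)
    el <- igraph::as_edgelist(graph)
    fi <- stats::setNames(igraph::V(graph)$f_i, igraph::V(graph)$name)
    igraph::E(graph)$if_pa <- if_pa(f_ij, fi[el[, 1L]], fi[el[, 2L]], g$N)
  }
  out <- g
  out$graph <- graph
  out$f_max_pair <- f_max_pair
  out$filter_report <- list(
    fc_threshold = fc_threshold,
    removed_by_fc = length(too_rare),
    removed_by_neighbor_rule = length(removed_neighbor),
    removed_isolated = length(removed_isolated),
    nodes_before = igraph::vcount(g$graph),
    nodes_after = igraph::vcount(graph),
    f_max_pair_before = g$f_max_pair,
    f_max_pair_after = f_max_pair
  )
  out
}

#' Write ECLG node and edge tables
#'
#' @param g an `eclg`.
#' @param nodes_path TSV for the node attribute table (event key, f_i,
#'   fc_ia); NULL to skip.
#' @param edges_path TSV for the weighted edge list; NULL to skip.
#' @export
write_eclg_tables <- function(g, nodes_path = NULL, edges_path = NULL) {
  stopifnot(inherits(g, "eclg"))
  if (!is.null(nodes_path)) write_table_file(eclg_nodes(g), nodes_path)
  if (!is.null(edges_path)) write_table_file(eclg_edges(g), edges_path)
  invisible(g)
}

#' @export
print.eclg <- function(x, ...) {
  cat("Event collaboration graph:", igraph::vcount(x$graph), "events,",
      igraph::ecount(x$graph), "co-occurrence edges\n")
  cat("  N =", x$N, " f_max =", x$f_max, " f_max_pair =", x$f_max_pair, "\n")
  if (!is.null(x$filter_report)) {
    cat("  filtered at FC threshold", x$filter_report$fc_threshold, "(",
        x$filter_report$removed_by_fc, "rare nodes removed )\n")
  }
  invisible(x)
}
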