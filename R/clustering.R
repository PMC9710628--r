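#' Edge weights used for clustering
#'
#' Modularity treats a large weight as a strong tie. The weighted inverse
#' frequency `if_pa` and the raw co-occurrence count `f_ij` already grow
#' with support, so they are used as-is. The pair frequency class `fc_pa` is
#' the opposite: low class means strong support, so it is inverted to
#' `max(fc_pa) - fc_pa + 1` before weighting (recorded in run reports).
#'
#' @param g an `eclg`.
#' @param weight_key one of `"if_pa"`, `"fc_pa"`, `"f_ij"`.
#' @return numeric vector of clustering weights, one per edge.
#' @export
clustering_weights <- function(g, weight_key = c("if_pa", "fc_pa", "f_ij")) {
  weight_key <- match.arg(weight_key)
  stopifnot(inherits(g, "eclg"))
  switch(weight_key,
         if_pa = igraph::E(g$graph)$if_pa,
         f_ij = as.numeric(igraph::E(g$graph)$f_ij),
         fc_pa = {
           fc <- igraph::E(g$graph)$fc_pa
           if (length(fc)) max(fc) - fc + 1 else numeric(0)
         })
}

# resolve an assignment (named, or in vertex order) to vertex order
resolve_assignment <- function(g, assignment) {
  nodes <- igraph::V(g$graph)$name
  if (!is.null(names(assignment))) {
    if (!all(nodes %in% names(assignment))) {
      stop("assignment does not cover every ECLG node", call. = FALSE)
    }
    assignment <- assignment[nodes]
  }
  if (length(assignment) != length(nodes)) {
    stop("assignment does not cover every ECLG node", call. = FALSE)
  }
  unname(assignment)
}

#' Weighted modularity of a partition
#'
#' Modularity `Q = (1/2m) * sum_{u,v} [w_uv - sigma_u * sigma_v / (2m)] *
#' delta(c_u, c_v)`, summed over ordered node pairs, where `w_uv` is the
#' edge weight (0 when no edge), `sigma_u` the summed weight of edges
#' incident to `u`, and `m` the total edge weight. Measures how much
#' intra-community weight exceeds the degree-based null expectation.
#'
#' @param g an `eclg`.
#' @param assignment community labels, named by event key or in vertex
#'   order.
#' @param weight_key edge weight to use (see [clustering_weights()]).
#' @return the modularity Q.
#' @export
modularity_q <- function(g, assignment, weight_key = "if_pa") {
  memb <- resolve_assignment(g, assignment)
  w <- clustering_weights(g, weight_key)
  m <- sum(w)
  if (m <= 0) stop("graph has no weighted edges", call. = FALSE)
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  sigma <- numeric(igraph::vcount(g$graph))
  for (e in seq_along(w)) {
    sigma[el[e, 1L]] <- sigma[el[e, 1L]] + w[e]
    sigma[el[e, 2L]] <- sigma[el[e, 2L]] + w[e]
  }
  intra <- memb[el[, 1L]] == memb[el[, 2L]]
  w_in <- tapply(w[intra], memb[el[intra, 1L]], sum)
  sigma_c <- tapply(sigma, memb, sum)
  q <- sum(as.numeric(sigma_c)^2) / (2 * m)^2
  sum(as.numeric(w_in)) / m - q
}

#' Modularity gain of moving a node into a community
#'
#' The first-phase move gain of weighted Louvain: for a node `u` currently
#' in a singleton community, the change in modularity if `u` joined
#' community `c_v` is
#' `[(S_v + 2*sigma_uv)/(2m) - ((S_tot + sigma_u)/(2m))^2] -
#'  [S_v/(2m) - (S_tot/(2m))^2 - (sigma_u/(2m))^2]`
#' with `S_v` the intra-community edge weight of `c_v`, `S_tot` the weight
#' incident to its nodes, `sigma_u` the weight incident to `u` and
#' `sigma_uv` the weight from `u` into `c_v`. For an isolated `u` this
#' equals the recomputed modularity difference.
#'
#' @param g an `eclg`.
#' @param u event key of the node to move (must currently be a singleton).
#' @param target_community label of the community to move into.
#' @param assignment current community labels (named or in vertex order).
#' @param weight_key edge weight to use.
#' @return the modularity gain; 0 when `u` is already (alone) in the target.
#' @export
delta_q <- function(g, u, target_community, assignment, weight_key = "if_pa") {
  memb <- resolve_assignment(g, assignment)
  nodes <- igraph::V(g$graph)$name
  ui <- match(u, nodes)
  if (is.na(ui)) stop("unknown node: ", u, call. = FALSE)
  if (sum(memb == memb[ui]) != 1L) {
    stop("delta_q is defined for a node in a singleton community", call. = FALSE)
  }
  if (memb[ui] == target_community) return(0)
  target <- which(memb == target_community)
  if (!length(target)) stop("unknown target community", call. = FALSE)
  w <- clustering_weights(g, weight_key)
  m <- sum(w)
  if (m <= 0) stop("graph has no weighted edges", call. = FALSE)
  el <- igraph::as_edgelist(g$graph, names = FALSE)
  sigma <- numeric(length(nodes))
  for (e in seq_along(w)) {
    sigma[el[e, 1L]] <- sigma[el[e, 1L]] + w[e]
    sigma[el[e, 2L]] <- sigma[el[e, 2L]] + w[e]
  }
  in_target <- el[, 1L] %in% target & el[, 2L] %in% target
  s_v <- sum(w[in_target])
  s_tot <- sum(sigma[target])
  sigma_u <- sigma[ui]
  touch_u <- (el[, 1L] == ui & el[, 2L] %in% target) |
    (el[, 2L] == ui & el[, 1L] %in% target)
  sigma_uv <- sum(w[touch_u])
  ((s_v + 2 * sigma_uv) / (2 * m) - ((s_tot + sigma_u) / (2 * m))^2) -
    (s_v / (2 * m) - (s_tot / (2 * m))^2 - (sigma_u / (2 * m))^2)
}

# ---- internal multi-level Louvain ------------------------------------------
# Graph representation: n nodes, edge list (i, j, w) with i != j, and a
# self-loop vector `sl` (a community's internal weight appears as 2 * W_in
# after contraction, so that sigma and m are preserved across levels).

louvain_phase1 <- function(n, edges, sl, m, sweep, tol) {
  memb <- seq_len(n)
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      i <- edges$i[e]; j <- edges$j[e]; w <- edges$w[e]
      adj[[i]] <- rbind(adj[[i]], c(j, w))
      adj[[j]] <- rbind(adj[[j]], c(i, w))
    }
  }
  sigma <- sl
  for (u in seq_len(n)) if (!is.null(adj[[u]])) sigma[u] <- sigma[u] + sum(adj[[u]][, 2L])
  s_tot <- sigma  # one community per node at the start
  moved_any <- FALSE
  repeat {
    moved_pass <- FALSE
    for (u in sweep) {
      if (is.null(adj[[u]])) next
      c_old <- memb[u]
      nbr_comm <- memb[adj[[u]][, 1L]]
      k_uc <- tapply(adj[[u]][, 2L], nbr_comm, sum)
      s_tot[c_old] <- s_tot[c_old] - sigma[u]
      cand <- as.integer(names(k_uc))
      if (!c_old %in% cand) {
        cand <- c(cand, c_old)
        k_uc <- c(k_uc, stats::setNames(0, c_old))
      }
      gain <- as.numeric(k_uc) / m -
        s_tot[cand] * sigma[u] / (2 * m^2)
      best <- which(gain == max(gain))
      # ties: lowest community label wins
      best <- best[which.min(cand[best])]
      c_new <- cand[best]
      g_old <- gain[match(c_old, cand)]
      if (c_new != c_old && gain[best] - g_old > tol) {
        memb[u] <- c_new
        s_tot[c_new] <- s_tot[c_new] + sigma[u]
        moved_pass <- TRUE
        moved_any <- TRUE
      } else {
        s_tot[c_old] <- s_tot[c_old] + sigma[u]
      }
    }
    if (!moved_pass) break
  }
  list(memb = memb, moved = moved_any)
}

louvain_internal <- function(n, edges, tol, seed) {
  sl <- numeric(n)
  memb_global <- seq_len(n)
  m <- sum(edges$w)
  level <- 0L
  repeat {
    level <- level + 1L
    n_cur <- max(memb_global)
    sweep <- with_seed(seed + level - 1L, sample.int(n_cur))
    res <- louvain_phase1(n_cur, edges, sl, m, sweep, tol)
    if (!res$moved) break
    comm <- match(res$memb, sort(unique(res$memb)))
    memb_global <- comm[memb_global]
    # contract: aggregate edges between communities, fold intra weight and
    # existing self-loops into the new self-loops (intra counted twice)
    k <- max(comm)
    new_sl <- numeric(k)
    for (u in seq_along(sl)) new_sl[comm[u]] <- new_sl[comm[u]] + sl[u]
    if (nrow(edges)) {
      ci <- comm[edges$i]; cj <- comm[edges$j]
      intra <- ci == cj
      for (e in which(intra)) new_sl[ci[e]] <- new_sl[ci[e]] + 2 * edges$w[e]
      inter <- !intra
      if (any(inter)) {
        a <- pmin(ci[inter], cj[inter]); b <- pmax(ci[inter], cj[inter])
        agg <- rowsum(edges$w[inter], paste(a, b, sep = "\r"))
        parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
        edges <- data.frame(i = as.integer(vapply(parts, `[`, "", 1L)),
                            j = as.integer(vapply(parts, `[`, "", 2L)),
                            w = as.numeric(agg))
      } else {
        edges <- edges[0L, , drop = FALSE]
      }
    }
    sl <- new_sl
    if (k == n_cur) break  # no contraction progress
  }
  memb_global
}

#' Louvain community detection on the candidate ECLG
#'
#' Two-phase greedy weighted-modularity maximization: phase one starts from
#' singleton communities and repeatedly moves each node to the neighbouring
#' community with the largest positive modularity gain until no move
#' improves Q; phase two contracts communities into super-nodes and the
#' phases repeat until a whole iteration yields no increase. Node sweep
#' order is the canonical (sorted) node order shuffled deterministically by
#' `node_order_seed`; among equal gains the lowest community label wins, and
#' a gain must exceed `tol` to count as an improvement. Disconnected
#' components are handled naturally (no move can cross them).
#'
#' @param g an `eclg` (usually the filtered candidate graph).
#' @param weight_key edge weight to cluster on (see [clustering_weights()]).
#' @param node_order_seed integer seed for the sweep-order shuffle.
#' @param tol minimal modularity gain counted as an improvement.
#' @return object of class `eclg_clusters`: list with `partition`
#'   (`assignment` named by event key with contiguous integer labels, `Q`,
#'   `m`, `weight_key`, `node_order_seed`) and `clusters` (one row per
#'   generated cluster: `label`, `size`, `P_l` intra-cluster edge count,
#'   `fc_pa_avg`, `if_pa_avg`; averages are NA when a cluster has no intra
#'   edge) plus `events` (list of event keys per cluster).
#' @export
louvain <- function(g, weight_key = "if_pa", node_order_seed = 1L,
                    tol = 1e-12) {
  stopifnot(inherits(g, "eclg"))
  nodes <- sort(igraph::V(g$graph)$name)
  n <- length(nodes)
  if (igraph::ecount(g$graph) == 0L) {
    warning("ECLG has no edges: every node forms its own cluster")
    memb <- seq_len(n)
    q <- NA_real_
    m <- 0
  } else {
    w <- clustering_weights(g, weight_key)
    el <- igraph::as_edgelist(g$graph)
    i <- match(el[, 1L], nodes); j <- match(el[, 2L], nodes)
    edges <- data.frame(i = pmin(i, j), j = pmax(i, j), w = w)
    m <- sum(w)
    memb <- louvain_internal(n, edges, tol, node_order_seed)
    q <- modularity_q(g, stats::setNames(memb, nodes), weight_key)
  }
  # contiguous labels, numbered by first appearance in canonical node order
  memb <- match(memb, unique(memb))
  assignment <- stats::setNames(memb, nodes)

  labels <- sort(unique(memb))
  events <- lapply(labels, function(l) nodes[memb == l])
  names(events) <- labels
  rows <- lapply(labels, function(l) {
    av <- cluster_averages(g, events[[as.character(l)]])
    data.frame(label = l, size = length(events[[as.character(l)]]),
               P_l = av$P_l, fc_pa_avg = av$fc_pa_avg,
               if_pa_avg = av$if_pa_avg)
  })
  clusters <- do.call(rbind, rows)
  rownames(clusters) <- NULL
  structure(list(
    partition = list(assignment = assignment, Q = q, m = m,
                     weight_key = weight_key,
                     node_order_seed = node_order_seed),
    clusters = clusters,
    events = events
  ), class = "eclg_clusters")
}

#' Average pair metrics of a generated cluster
#'
#' Averages the pair frequency class and the weighted inverse frequency
#' over the `P_l` ECLG edges with both endpoints inside the cluster. With
#' no intra-cluster edge the averages are undefined (NA) and the cluster
#' cannot take part in literature-support ranking.
#'
#' @param g an `eclg`.
#' @param events character vector of the cluster's event keys.
#' @return list with `P_l`, `fc_pa_avg`, `if_pa_avg`.
#' @export
cluster_averages <- function(g, events) {
  stopifnot(inherits(g, "eclg"))
  sub <- igraph::induced_subgraph(g$graph, events)
  p_l <- igraph::ecount(sub)
  if (p_l == 0L) {
    return(list(P_l = 0L, fc_pa_avg = NA_real_, if_pa_avg = NA_real_))
  }
  list(P_l = p_l,
       fc_pa_avg = mean(igraph::E(sub)$fc_pa),
       if_pa_avg = mean(igraph::E(sub)$if_pa))
}

#' @export
print.eclg_clusters <- function(x, ...) {
  cat("Generated clusters:", nrow(x$clusters), "communities (Q =",
      format(x$partition$Q, digits = 4), "on", x$partition$weight_key,
      "weights)\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}
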