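#' Configuration for the synthetic reading-output generator
#'
#' The generator emulates the structure of a machine-reading event set:
#' repeated events across papers, with planted co-occurrence communities.
#' Events of a community draw their occurrences from that community's
#' papers, so they co-occur densely with one another and (almost) never
#' with events of other communities; `cross_paper_rate` controls the rare
#' leakage of an event into another community's paper.
#'
#' @param n_communities number of planted communities.
#' @param events_per_community distinct events per community.
#' @param papers_per_community papers per community.
#' @param entities_per_community size of each community's entity pool;
#'   `NULL` scales it with the event count (about 0.6 events per entity,
#'   minimum 4).
#' @param cross_paper_rate probability that an event also occurs once in a
#'   paper of another community.
#' @param freq_min,freq_max per-event occurrence counts are uniform on
#'   `freq_min:freq_max` unless `zipf_exponent` is given.
#' @param zipf_exponent optional Zipf exponent; occurrence counts are then
#'   drawn from `1:freq_max` with probability proportional to `k^-s`.
#' @param model_overlap_fraction fraction of entity labels reused from the
#'   baseline model (when one is supplied to [generate_ees()]), so that
#'   node overlap and return paths are exercised.
#' @param n_model_elements number of elements in generated models
#'   (see [generate_model_pair()]).
#' @param seed RNG seed; all generation is deterministic given the config.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_communities = 3L, events_per_community = 15L,
                         papers_per_community = 5L,
                         entities_per_community = NULL,
                         cross_paper_rate = 0.02,
                         freq_min = 1L, freq_max = 5L, zipf_exponent = NULL,
                         model_overlap_fraction = 0.2, n_model_elements = 20L,
                         seed = 1L) {
  stopifnot(n_communities >= 1L, events_per_community >= 1L,
            papers_per_community >= 1L,
            cross_paper_rate >= 0, cross_paper_rate <= 1,
            freq_min >= 1L, freq_max >= freq_min,
            model_overlap_fraction >= 0, model_overlap_fraction <= 1,
            n_model_elements >= 2L)
  if (!is.null(entities_per_community)) {
    stopifnot(entities_per_community >= 2L)
    entities_per_community <- as.integer(entities_per_community)
  }
  structure(list(n_communities = as.integer(n_communities),
                 events_per_community = as.integer(events_per_community),
                 papers_per_community = as.integer(papers_per_community),
                 entities_per_community = entities_per_community,
                 cross_paper_rate = cross_paper_rate,
                 freq_min = as.integer(freq_min),
                 freq_max = as.integer(freq_max),
                 zipf_exponent = zipf_exponent,
                 model_overlap_fraction = model_overlap_fraction,
                 n_model_elements = as.integer(n_model_elements),
                 seed = as.integer(seed)), class = "synth_config")
}

draw_frequency <- function(cfg, n, at_least = cfg$freq_min) {
  lo <- max(cfg$freq_min, at_least)
  if (!is.null(cfg$zipf_exponent)) {
    k <- seq.int(max(lo, 1L), cfg$freq_max)
    p <- k^(-cfg$zipf_exponent)
    sample(k, n, replace = TRUE, prob = p / sum(p))
  } else {
    sample(seq.int(lo, max(lo, cfg$freq_max)), n, replace = TRUE)
  }
}

#' Generate a synthetic reading table with planted communities
#'
#' Emits a table in the machine-reading dialect consumed by
#' [parse_reading_table()], together with the ground-truth community of
#' every distinct event. Optionally, a set of events to inject (for
#' instance the part of a gold model removed to create a baseline) is
#' planted as one additional community with its own papers; injected
#' events get at least two occurrences, emulating events well enough
#' supported in the literature to have made it into a curated model.
#'
#' @param cfg a `synth_config`.
#' @param model optional `model_graph` whose element names seed a fraction
#'   (`model_overlap_fraction`) of the entity labels.
#' @param inject_events optional data.frame with columns `src_name`,
#'   `dst_name`, `sign`: events planted as an extra community.
#' @return list with `table` (the reading table data.frame), `truth`
#'   (named integer vector: event key -> planted community; the injected
#'   community has the largest label) and `config`.
#' @export
generate_ees <- function(cfg, model = NULL, inject_events = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n_ent <- if (!is.null(cfg$entities_per_community)) cfg$entities_per_community
             else max(4L, ceiling(cfg$events_per_community * 0.6))
    if (cfg$events_per_community > n_ent * (n_ent - 1L) * 2L) {
      stop("infeasible config: more distinct events than the entity space allows",
           call. = FALSE)
    }
    model_names <- if (!is.null(model)) unname(model$key_to_name) else character(0)

    # injected events claim their keys first so no noise community can
    # accidentally duplicate (and thereby merge with) an injected event
    used_keys <- if (!is.null(inject_events) && nrow(inject_events) > 0L) {
      event_key(canonical_key(inject_events$src_name),
                canonical_key(inject_events$dst_name), inject_events$sign)
    } else character(0)
    communities <- list()
    for (c_id in seq_len(cfg$n_communities)) {
      n_overlap <- min(length(model_names),
                       round(cfg$model_overlap_fraction * n_ent))
      pool <- c(if (n_overlap > 0L) sample(model_names, n_overlap),
                sprintf("ENT_%d_%d", c_id, seq_len(n_ent - n_overlap)))
      ev <- data.frame(src_name = character(0), dst_name = character(0),
                       sign = character(0), stringsAsFactors = FALSE)
      attempts <- 0L
      while (nrow(ev) < cfg$events_per_community) {
        attempts <- attempts + 1L
        if (attempts > 1000L * cfg$events_per_community) {
          stop("infeasible config: could not draw enough distinct events",
               call. = FALSE)
        }
        pair <- sample(pool, 2L)
        sgn <- sample(c("positive", "negative"), 1L)
        key <- event_key(canonical_key(pair[1L]), canonical_key(pair[2L]), sgn)
        if (key %in% used_keys) next
        used_keys <- c(used_keys, key)
        ev <- rbind(ev, data.frame(src_name = pair[1L], dst_name = pair[2L],
                                   sign = sgn, stringsAsFactors = FALSE))
      }
      communities[[c_id]] <- ev
    }
    if (!is.null(inject_events) && nrow(inject_events) > 0L) {
      communities[[cfg$n_communities + 1L]] <- inject_events[,
        c("src_name", "dst_name", "sign"), drop = FALSE]
    }

    papers <- lapply(seq_along(communities), function(c_id) {
      sprintf("PMID%03d%02d", c_id, seq_len(cfg$papers_per_community))
    })

    rows <- list()
    truth <- integer(0)
    for (c_id in seq_along(communities)) {
      ev <- communities[[c_id]]
      injected <- c_id > cfg$n_communities
      f <- draw_frequency(cfg, nrow(ev), at_least = if (injected) 2L else cfg$freq_min)
      for (i in seq_len(nrow(ev))) {
        key <- event_key(canonical_key(ev$src_name[i]),
                         canonical_key(ev$dst_name[i]), ev$sign[i])
        truth[key] <- c_id
        ids <- sample(papers[[c_id]], f[i], replace = f[i] > length(papers[[c_id]]))
        if (length(communities) > 1L && stats::runif(1) < cfg$cross_paper_rate) {
          other <- sample(setdiff(seq_along(communities), c_id), 1L)
          ids <- c(ids, sample(papers[[other]], 1L))
        }
        for (pid in ids) {
          rows[[length(rows) + 1L]] <- data.frame(
            src = ev$src_name[i], dst = ev$dst_name[i], sign = ev$sign[i],
            paper = pid, stringsAsFactors = FALSE)
        }
      }
    }
    occ <- do.call(rbind, rows)
    table <- data.frame(
      check.names = FALSE, stringsAsFactors = FALSE,
      "Regulator Name" = occ$src, "Regulator Type" = "protein",
      "Regulator ID" = "", "Regulated Name" = occ$dst,
      "Regulated Type" = "protein", "Regulated ID" = "",
      "Interaction" = ifelse(occ$sign == "positive", "increases", "decreases"),
      "Paper ID" = occ$paper,
      "Evidence" = sprintf("%s %s %s.", occ$src,
                           ifelse(occ$sign == "positive", "activates", "inhibits"),
                           occ$dst)
    )
    list(table = table, truth = truth, config = cfg)
  })
}

#' Write a synthetic reading table to disk
#'
#' @param synth result of [generate_ees()].
#' @param path output TSV/CSV file.
#' @export
write_synthetic_ees <- function(synth, path) {
  write_table_file(synth$table, path)
  invisible(path)
}

#' Generate a paired gold and truncated baseline model
#'
#' Generates a random directed signed element graph as the gold model, then
#' derives a baseline by removing part of it, mirroring the ways curated
#' models are truncated in benchmark studies: removing all direct
#' regulators of a set of key elements, removing the directed paths between
#' chosen element pairs, or removing edges at random. The removed edges are
#' returned as the recoverable target set.
#'
#' @param cfg a `synth_config` (`n_model_elements`, `seed`).
#' @param truncation one of `"remove_regulators"`, `"remove_paths"`,
#'   `"remove_random_edges"`.
#' @param amount fraction in (0, 1) controlling how much is removed (key
#'   elements, element pairs, or edges, respectively).
#' @return list with `gold` and `baseline` (`model_graph`s) and `removed`
#'   (data.frame of removed edges with element names:
#'   `src_name`, `dst_name`, `sign`).
#' @export
generate_model_pair <- function(cfg,
                                truncation = c("remove_regulators",
                                               "remove_paths",
                                               "remove_random_edges"),
                                amount = 0.25) {
  stopifnot(inherits(cfg, "synth_config"), amount > 0, amount < 1)
  truncation <- match.arg(truncation)
  with_seed(cfg$seed + 10000L, {
    n <- cfg$n_model_elements
    names_all <- sprintf("MOD%02d", seq_len(n))
    edges <- list()
    for (v in seq(2L, n)) {  # each element regulated by 1-3 earlier ones
      regs <- sample(seq_len(v - 1L), min(v - 1L, sample(1:3, 1L)))
      for (r in regs) {
        edges[[length(edges) + 1L]] <- data.frame(
          src_name = names_all[r], dst_name = names_all[v],
          sign = sample(c("positive", "negative"), 1L),
          stringsAsFactors = FALSE)
      }
    }
    gold_edges <- do.call(rbind, edges)

    removed_idx <- switch(truncation,
      remove_random_edges = {
        k <- max(1L, round(amount * nrow(gold_edges)))
        sort(sample(seq_len(nrow(gold_edges)), k))
      },
      remove_regulators = {
        k <- max(1L, round(amount * n))
        key_players <- sample(names_all[-1L], k)  # first element has no regulators
        which(gold_edges$dst_name %in% key_players)
      },
      remove_paths = {
        g <- igraph::graph_from_data_frame(
          gold_edges[, c("src_name", "dst_name")], directed = TRUE,
          vertices = data.frame(name = names_all))
        n_pairs <- max(1L, round(amount * n / 2))
        drop <- integer(0)
        for (p in seq_len(n_pairs)) {
          pair <- sample(names_all, 2L)
          repeat {
            keep <- setdiff(seq_len(nrow(gold_edges)), drop)
            gk <- igraph::graph_from_data_frame(
              gold_edges[keep, c("src_name", "dst_name")], directed = TRUE,
              vertices = data.frame(name = names_all))
            sp <- suppressWarnings(igraph::shortest_paths(
              gk, pair[1L], pair[2L], mode = "out", output = "epath"))
            ep <- sp$epath[[1L]]
            if (length(ep) == 0L) break
            e1 <- igraph::ends(gk, ep[1L])
            hit <- which(gold_edges$src_name == e1[1L] &
                           gold_edges$dst_name == e1[2L])
            drop <- union(drop, hit[1L])
          }
        }
        sort(drop)
      })
    if (length(removed_idx) >= nrow(gold_edges)) {
      stop("truncation would empty the model", call. = FALSE)
    }
    removed <- gold_edges[removed_idx, , drop = FALSE]
    rownames(removed) <- NULL
    base_edges <- gold_edges[-removed_idx, , drop = FALSE]

    as_model <- function(edge_df) {
      pos <- lapply(stats::setNames(names_all, names_all), function(v) {
        edge_df$src_name[edge_df$dst_name == v & edge_df$sign == "positive"]
      })
      neg <- lapply(stats::setNames(names_all, names_all), function(v) {
        edge_df$src_name[edge_df$dst_name == v & edge_df$sign == "negative"]
      })
      model_from_elements(data.frame(
        name = names_all, type = "protein", db_id = "", variable = names_all,
        pos_expr = vapply(pos, paste, "", collapse = ", "),
        neg_expr = vapply(neg, paste, "", collapse = ", "),
        evidence = "", stringsAsFactors = FALSE))
    }
    list(gold = as_model(gold_edges), baseline = as_model(base_edges),
         removed = removed)
  })
}
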