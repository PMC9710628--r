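# Shared fixture builders. Everything is generated in code; nothing binary.

# event records data.frame from parallel vectors
make_records <- function(reg, tgt, sign, paper, reg_id = "", tgt_id = "",
                         evidence = "") {
  n <- length(reg)
  data.frame(regulator_name = reg, regulator_type = rep("protein", n),
             regulator_id = rep_len(reg_id, n), regulated_name = tgt,
             regulated_type = rep("protein", n),
             regulated_id = rep_len(tgt_id, n), sign = sign,
             paper_id = paper, evidence = rep_len(evidence, n),
             stringsAsFactors = FALSE)
}

# write a reading table in the default dialect
write_reading_tsv <- function(df, path = tempfile(fileext = ".tsv"),
                              interaction = NULL) {
  cols <- litnetext::default_reading_columns()
  out <- data.frame(df$regulator_name, df$regulator_type, df$regulator_id,
                    df$regulated_name, df$regulated_type, df$regulated_id,
                    if (is.null(interaction)) df$sign else interaction,
                    df$paper_id, df$evidence,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unname(cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# write a model element table in the default dialect
write_model_tsv <- function(name, pos = "", neg = "", type = "protein",
                            db_id = "", variable = name,
                            path = tempfile(fileext = ".tsv")) {
  cols <- litnetext::default_model_columns()
  out <- data.frame(name, rep_len(type, length(name)),
                    rep_len(db_id, length(name)), variable,
                    rep_len(pos, length(name)), rep_len(neg, length(name)),
                    rep_len("", length(name)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- unname(cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a hand-built ECLG for clustering tests: edge weights land on if_pa so the
# default weight key uses them directly
mk_eclg <- function(edges, w = rep(1, nrow(edges)), nodes = NULL,
                    fc_ia = 0L, f_i = 1L) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  n_e <- nrow(edges)
  ed <- data.frame(from = edges$from, to = edges$to,
                   f_ij = rep_len(1L, n_e), fc_pa = rep_len(0L, n_e),
                   if_pa = w, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = nodes, f_i = rep_len(f_i, length(nodes)),
                          fc_ia = rep_len(fc_ia, length(nodes))))
  structure(list(graph = g, N = 10L, f_max = 1L, f_max_pair = 1L,
                 filter_report = NULL), class = "eclg")
}

# all edges of a clique over a node vector
clique_edges <- function(v) {
  p <- t(utils::combn(v, 2))
  data.frame(from = p[, 1], to = p[, 2], stringsAsFactors = FALSE)
}

# every set partition of n items (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(a, k) {
    if (length(a) == n) {
      out[[length(out) + 1L]] <<- a
      return(invisible())
    }
    for (v in seq_len(k + 1L)) rec(c(a, v), max(k, v))
  }
  rec(integer(0), 0L)
  out
}

# random EES for formula-oracle properties: returns the ees plus the raw
# per-event paper sets recomputed independently from the record rows
random_ees <- function(max_events = 30L, n_papers = 6L) {
  n_rows <- sample(3:60, 1L)
  ents <- LETTERS[1:6]
  reg <- sample(ents, n_rows, replace = TRUE)
  tgt <- sample(ents, n_rows, replace = TRUE)
  sign <- sample(c("positive", "negative"), n_rows, replace = TRUE)
  paper <- sprintf("P%d", sample(seq_len(n_papers), n_rows, replace = TRUE))
  rec <- make_records(reg, tgt, sign, paper)
  ees <- litnetext::build_ees(rec)
  if (ees$M > max_events) return(random_ees(max_events, n_papers))
  ees
}

# minimal extension_result for evaluation tests
mk_result <- function(src, dst, sign) {
  edges <- data.frame(src = src, dst = dst, sign = sign,
                      event_key = paste(src, dst, sign, sep = "|"),
                      stringsAsFactors = FALSE)
  structure(list(selected = 1L, reasons = list("1" = "literature"),
                 events = edges$event_key,
                 entities = sort(unique(c(src, dst))), edges = edges,
                 table = NULL, paths = list(), no_threshold = 50,
                 diagnostic = NULL), class = "extension_result")
}

# small two-community synthetic pipeline fixture shared by pipeline and
# acceptance tests
default_e2e_fixture <- function(seed = 1L) {
  cfg <- litnetext::synth_config(seed = seed)
  pair <- litnetext::generate_model_pair(cfg, "remove_random_edges",
                                         amount = 0.25)
  synth <- litnetext::generate_ees(cfg, model = pair$baseline,
                                   inject_events = pair$removed)
  path <- write_reading_tsv_from_table(synth$table)
  list(cfg = cfg, pair = pair, synth = synth, reading = path)
}

write_reading_tsv_from_table <- function(tab, path = tempfile(fileext = ".tsv")) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
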