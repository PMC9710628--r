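#' Canonical entity key
#'
#' Entities extracted by machine reading are unstable in their surface names
#' (case, spacing, synonyms), while database accessions (UniProt, GO, HMDB,
#' ...) are stable. The canonical key is therefore the database identifier
#' when one is present, and otherwise the case-folded, whitespace-collapsed
#' name. Model elements use the same rule so that node-overlap and
#' return-path computations compare like with like.
#'
#' @param name character vector of entity names.
#' @param db_id character vector of database identifiers ("" or NA if absent).
#' @return character vector of canonical keys.
#' @export
canonical_key <- function(name, db_id = "") {
  name <- as.character(name)
  db_id <- as.character(db_id)
  if (length(db_id) == 1L && length(name) > 1L) db_id <- rep(db_id, length(name))
  stopifnot(length(name) == length(db_id))
  folded <- tolower(gsub("\\s+", " ", trimws(name)))
  id <- trimws(db_id)
  id[is.na(id)] <- ""
  out <- ifelse(nzchar(id), id, folded)
  out
}

# key of a distinct event: regulator key, regulated key, sign
event_key <- function(reg_key, tgt_key, sign) {
  paste(reg_key, tgt_key, sign, sep = "|")
}

# split an event key back into its three components
split_event_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    src = vapply(parts, `[`, "", 1L),
    dst = vapply(parts, `[`, "", 2L),
    sign = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-up to an integer (base round() is round-half-even)
round_half_up <- function(x) as.integer(floor(x + 0.5))

# delimiter from a file extension: tab unless .csv
infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_file <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  if (is.null(sep)) sep <- infer_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE,
                    na.strings = character(0))
}

write_table_file <- function(df, path, sep = NULL) {
  if (is.null(sep)) sep <- infer_sep(path)
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write file: ", path, " (", conditionMessage(e), ")",
                              call. = FALSE))
  invisible(ok)
}
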