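#' Canonicalize words
#'
#' Normalizes free-text words to canonical node labels: lower-case, trimmed of
#' surrounding whitespace, with internal runs of whitespace collapsed to a
#' single space. No lemmatization or diacritic folding is applied, so node
#' identity stays auditable against the raw responses. The transformation is
#' idempotent.
#'
#' @param x Character vector of raw words. `NA` stays `NA`.
#' @return Character vector of canonical words.
#' @examples
#' canonicalize_words(c("  Katze ", "HUND", "ice   cream"))
#' @export
canonicalize_words <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[[:space:]]+", " ", out)
  out[is.na(x)] <- NA_character_
  out
}

.assoc_cols <- c("participant_id", "encounter_index", "cue", "r1", "r2", "r3",
                 "is_repeat")

.check_header <- function(found, required, path) {
  missing <- setdiff(required, found)
  if (length(missing) > 0) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read per-participant association records
#'
#' Reads a CSV of cue encounters with up to three responses each. Every word is
#' canonicalized (see [canonicalize_words()]); empty response cells become
#' missing (`NA`), never empty strings; rows with an empty cue are rejected.
#' Records are returned ordered by participant and encounter index.
#'
#' @param path Path to a CSV with columns `participant_id`, `encounter_index`,
#'   `cue`, `r1`, `r2`, `r3`, `is_repeat` (0/1).
#' @return A data frame of association records, one row per cue encounter, with
#'   `is_repeat` logical and response columns `r1`..`r3` canonical or `NA`.
#' @export
load_associations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  .check_header(names(raw), .assoc_cols, path)
  rec <- data.frame(
    participant_id = trimws(raw$participant_id),
    encounter_index = as.integer(raw$encounter_index),
    cue = canonicalize_words(raw$cue),
    r1 = canonicalize_words(raw$r1),
    r2 = canonicalize_words(raw$r2),
    r3 = canonicalize_words(raw$r3),
    is_repeat = as.integer(raw$is_repeat) != 0L,
    stringsAsFactors = FALSE
  )
  for (col in c("r1", "r2", "r3")) {
    rec[[col]][!is.na(rec[[col]]) & rec[[col]] == ""] <- NA_character_
  }
  bad <- is.na(rec$cue) | rec$cue == ""
  if (any(bad)) {
    stop("integrity error: ", sum(bad), " row(s) with empty cue", call. = FALSE)
  }
  key <- paste(rec$participant_id, rec$encounter_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("integrity error: duplicate (participant_id, encounter_index) key",
         call. = FALSE)
  }
  rec <- rec[order(rec$participant_id, rec$encounter_index), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Write association records
#'
#' Inverse of [load_associations()]: writes the canonical record table so that
#' reloading reproduces it exactly. Missing responses are written as empty
#' cells.
#'
#' @param records Association record data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(records, path) {
  out <- records
  out$is_repeat <- as.integer(out$is_repeat)
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read verbal-fluency retrieval sequences
#'
#' Reads ordered fluency retrievals. Within a (participant, task, task_key)
#' sequence, duplicated words are collapsed to their first occurrence; the
#' number of dropped duplicates is recorded in the `"n_duplicates_dropped"`
#' attribute.
#'
#' @param path CSV with columns `participant_id`, `task` (category|letter),
#'   `task_key`, `position`, `word`.
#' @return Data frame with one row per retained retrieval, ordered by position
#'   within sequence.
#' @export
load_fluency <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  .check_header(names(raw), c("participant_id", "task", "task_key", "position",
                              "word"), path)
  flu <- data.frame(
    participant_id = trimws(raw$participant_id),
    task = trimws(raw$task),
    task_key = canonicalize_words(raw$task_key),
    position = as.integer(raw$position),
    word = canonicalize_words(raw$word),
    stringsAsFactors = FALSE
  )
  if (!all(flu$task %in% c("category", "letter"))) {
    stop("schema error: task must be 'category' or 'letter'", call. = FALSE)
  }
  flu <- flu[order(flu$participant_id, flu$task, flu$task_key, flu$position), ,
             drop = FALSE]
  seq_id <- paste(flu$participant_id, flu$task, flu$task_key, sep = "\r")
  dup <- duplicated(paste(seq_id, flu$word, sep = "\r"))
  out <- flu[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_duplicates_dropped") <- sum(dup)
  out
}

#' Read episodic study/recall lists
#'
#' Reads the long-format episodic memory table and checks that every recalled
#' list has a matching studied list.
#'
#' @param path CSV with columns `participant_id`, `list_id`, `phase`
#'   (studied|recalled), `position`, `word`.
#' @return Data frame ordered by participant, list, phase and position.
#' @export
load_episodic <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  .check_header(names(raw), c("participant_id", "list_id", "phase", "position",
                              "word"), path)
  epi <- data.frame(
    participant_id = trimws(raw$participant_id),
    list_id = trimws(raw$list_id),
    phase = trimws(raw$phase),
    position = as.integer(raw$position),
    word = canonicalize_words(raw$word),
    stringsAsFactors = FALSE
  )
  if (!all(epi$phase %in% c("studied", "recalled"))) {
    stop("schema error: phase must be 'studied' or 'recalled'", call. = FALSE)
  }
  key <- function(ph) unique(paste(epi$participant_id, epi$list_id,
                                   sep = "\r")[epi$phase == ph])
  orphans <- setdiff(key("recalled"), key("studied"))
  if (length(orphans) > 0) {
    stop("integrity error: recalled list without matching studied list",
         call. = FALSE)
  }
  epi <- epi[order(epi$participant_id, epi$list_id, epi$phase, epi$position), ,
             drop = FALSE]
  rownames(epi) <- NULL
  epi
}

#' Read paired-associate trials
#'
#' @param path CSV with columns `participant_id`, `cue`, `target`, `recalled`
#'   (0/1).
#' @return Data frame with logical `recalled`.
#' @export
load_paired <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  .check_header(names(raw), c("participant_id", "cue", "target", "recalled"),
                path)
  data.frame(
    participant_id = trimws(raw$participant_id),
    cue = canonicalize_words(raw$cue),
    target = canonicalize_words(raw$target),
    recalled = as.integer(raw$recalled) != 0L,
    stringsAsFactors = FALSE
  )
}

#' Read the participants table
#'
#' Group membership (young/old) and age are carried in this separate table,
#' never inferred from the association data.
#'
#' @param path CSV with columns `participant_id`, `age`, `group` (young|old).
#' @return Data frame with integer `age`.
#' @export
load_participants <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  .check_header(names(raw), c("participant_id", "age", "group"), path)
  grp <- trimws(raw$group)
  if (!all(grp %in% c("young", "old"))) {
    stop("schema error: group must be 'young' or 'old'", call. = FALSE)
  }
  data.frame(
    participant_id = trimws(raw$participant_id),
    age = as.integer(raw$age),
    group = grp,
    stringsAsFactors = FALSE
  )
}

#' Read all behavioural task tables at once
#'
#' @param fluency,episodic,paired Paths to the respective CSV files; `NULL`
#'   entries are skipped.
#' @return Named list with elements `fluency`, `episodic`, `paired` (missing
#'   ones `NULL`).
#' @export
load_behavior <- function(fluency = NULL, episodic = NULL, paired = NULL) {
  list(
    fluency = if (!is.null(fluency)) load_fluency(fluency),
    episodic = if (!is.null(episodic)) load_episodic(episodic),
    paired = if (!is.null(paired)) load_paired(paired)
  )
}

#' Export a semantic network
#'
#' Writes either a 3-column weighted edge-list TSV (`word_a`, `word_b`,
#' `weight`, with `word_a < word_b` lexicographically and one row per
#' undirected edge) or GraphML. GraphML preserves isolated nodes; the
#' edge-list format represents edges only.
#'
#' @param net A semantic network (igraph, see [build_individual_network()]).
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (igraph::vcount(net) < 1) stop("network has no nodes", call. = FALSE)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(net, what = "edges")
    a <- pmin(el$from, el$to)
    b <- pmax(el$from, el$to)
    out <- data.frame(word_a = a, word_b = b,
                      weight = if (nrow(el)) el$weight else numeric(0),
                      stringsAsFactors = FALSE)
    out <- out[order(out$word_a, out$word_b), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Load a semantic network written by [export_network()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"graphml"`.
#' @return An igraph semantic network with a `weight` edge attribute.
#' @export
load_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(g)
  }
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "numeric"),
                           encoding = "UTF-8")
  .check_header(names(tab), c("word_a", "word_b", "weight"), path)
  igraph::graph_from_data_frame(tab, directed = FALSE)
}
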