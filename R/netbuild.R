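#' @keywords internal
.record_pairs <- function(records, include_repeats = TRUE) {
  if (!include_repeats) records <- records[!records$is_repeat, , drop = FALSE]
  cue <- rep(records$cue, 3L)
  resp <- c(records$r1, records$r2, records$r3)
  keep <- !is.na(resp) & resp != cue
  data.frame(cue = cue[keep], resp = resp[keep], stringsAsFactors = FALSE)
}

#' @keywords internal
.network_from_pairs <- function(pairs, owner, group = NA_character_) {
  a <- pmin(pairs$cue, pairs$resp)
  b <- pmax(pairs$cue, pairs$resp)
  key <- paste(a, b, sep = "\r")
  cnt <- table(key)
  ab <- do.call(rbind, strsplit(names(cnt), "\r", fixed = TRUE))
  edges <- data.frame(from = ab[, 1], to = ab[, 2],
                      weight = as.numeric(cnt), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::graph_attr(g, "owner") <- owner
  igraph::graph_attr(g, "group") <- group
  g
}

#' Build one participant's semantic network
#'
#' Places a weighted, undirected edge between each cue and each of its
#' responses; the edge weight is the number of times that unordered
#' cue-response pair occurred across all response positions and encounters.
#' A response identical to its cue is discarded (no self-loops). Every cue and
#' every response becomes a node, including responses never used as cues, so
#' isolated nodes cannot arise.
#'
#' @param records Association records (see [load_associations()]) for exactly
#'   one participant.
#' @param include_repeats Should second encounters of repeated cues contribute
#'   edges? Default `TRUE`: both encounters count toward the response yield.
#' @param group Optional group label stored as network metadata.
#' @return An undirected igraph with integer `weight` edge attribute and graph
#'   attributes `owner` (the participant id) and `group`.
#' @export
build_individual_network <- function(records, include_repeats = TRUE,
                                     group = NA_character_) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no association records supplied", call. = FALSE)
  }
  pid <- unique(records$participant_id)
  if (length(pid) != 1) {
    stop("records span ", length(pid),
         " participants; expected exactly one", call. = FALSE)
  }
  pairs <- .record_pairs(records, include_repeats)
  if (nrow(pairs) == 0) stop("records yield no cue-response pairs", call. = FALSE)
  .network_from_pairs(pairs, owner = pid, group = group)
}

#' Build the aggregate network of a cohort
#'
#' Pools every participant's cue-response pairs under the same construction
#' rule as [build_individual_network()]; weights sum across participants,
#' giving the aggregate a more graded pattern of edge strengths than any
#' individual network.
#'
#' @param records Association records for two or more participants.
#' @inheritParams build_individual_network
#' @return An igraph semantic network with `owner = "aggregate"`.
#' @export
build_aggregate_network <- function(records, include_repeats = TRUE) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no association records supplied", call. = FALSE)
  }
  if (length(unique(records$participant_id)) < 2) {
    stop("aggregate network requires >= 2 participants", call. = FALSE)
  }
  pairs <- .record_pairs(records, include_repeats)
  .network_from_pairs(pairs, owner = "aggregate")
}

#' Induce networks on their common node set
#'
#' Restricts each network to the intersection of all node sets, keeping edge
#' weights unchanged. All returned networks have the identical node count,
#' which equalizes lexicon coverage when comparing structure across
#' participants. Nodes whose every neighbour falls outside the intersection
#' become isolated but are retained.
#'
#' @param nets List of two or more semantic networks.
#' @return List of induced networks, same order and metadata as the input.
#' @export
common_subnetworks <- function(nets) {
  if (length(nets) < 2) stop("need >= 2 networks", call. = FALSE)
  shared <- Reduce(intersect, lapply(nets, function(g) igraph::V(g)$name))
  if (length(shared) == 0) stop("node-set intersection is empty", call. = FALSE)
  lapply(nets, function(g) {
    igraph::induced_subgraph(g, igraph::V(g)[igraph::V(g)$name %in% shared])
  })
}
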