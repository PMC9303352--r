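#' @keywords internal
.responses_of <- function(row) {
  r <- c(row$r1, row$r2, row$r3)
  r[!is.na(r)]
}

#' Repeat-encounter response consistency
#'
#' For every cue a participant saw twice, the proportion of second-encounter
#' responses that were also given at the first encounter of the same cue
#' (set semantics per cue; response position is ignored), pooled over all
#' repeated cues. A value of 1 means the participant reproduced every earlier
#' association; values near 0 mean entirely new associations.
#'
#' @param records Association records for one participant.
#' @param direction `"second_vs_first"` (default: second-encounter responses
#'   checked against the first encounter) or `"first_vs_second"`; the two
#'   differ when response counts differ between encounters.
#' @return Proportion in \[0, 1\] with attribute `n_responses` (the
#'   denominator).
#' @export
repeated_cue_consistency <- function(records,
                                     direction = c("second_vs_first",
                                                   "first_vs_second")) {
  direction <- match.arg(direction)
  firsts <- records[!records$is_repeat, , drop = FALSE]
  seconds <- records[records$is_repeat, , drop = FALSE]
  seconds <- seconds[seconds$cue %in% firsts$cue, , drop = FALSE]
  if (nrow(seconds) == 0) {
    stop("no repeated cue with a matching first encounter", call. = FALSE)
  }
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrow(seconds))) {
    cue <- seconds$cue[i]
    first_resp <- unique(.responses_of(firsts[firsts$cue == cue, ][1, ]))
    second_resp <- unique(.responses_of(seconds[i, ]))
    if (direction == "second_vs_first") {
      total <- total + length(second_resp)
      hits <- hits + sum(second_resp %in% first_resp)
    } else {
      total <- total + length(first_resp)
      hits <- hits + sum(first_resp %in% second_resp)
    }
  }
  structure(hits / total, n_responses = total)
}

#' Repeat-association profile
#'
#' Over all distinct cue-response pairs in a record set (unordered, pooled
#' across encounters): the percentage of pairs occurring more than once and
#' the maximum occurrence count. Individual record sets typically show only a
#' few percent of repeated pairs; pooling a cohort raises both numbers and is
#' what gives the aggregate network its graded edge weights.
#'
#' @param records Association records (one participant or a pooled cohort).
#' @return List with `pct_pairs_repeated` (percentage in \[0, 100\]),
#'   `max_pair_count`, `n_distinct_pairs`.
#' @export
repeat_association_profile <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no association records supplied", call. = FALSE)
  }
  pairs <- .record_pairs(records, include_repeats = TRUE)
  key <- paste(pmin(pairs$cue, pairs$resp), pmax(pairs$cue, pairs$resp),
               sep = "\r")
  cnt <- table(key)
  list(
    pct_pairs_repeated = 100 * mean(cnt > 1),
    max_pair_count = max(cnt),
    n_distinct_pairs = length(cnt)
  )
}

#' Cross-network correlation of node measures
#'
#' Quantifies how much measurement networks agree on node-level quantities
#' over a shared node set. For centrality vectors the Pearson correlation is
#' taken over the shared nodes; for walk-similarity models it is taken over
#' the upper triangle of the shared-node pairwise cosine matrices (optionally
#' subsampled for very large node sets, with the subsampling seeded and the
#' standard error of the estimate reported).
#'
#' When one entry of `measures` is named `"aggregate"`, the summary separates
#' the mean individual-vs-aggregate correlation from the mean
#' individual-vs-individual correlation.
#'
#' @param measures Named list, either of named centrality vectors or of
#'   [walk_similarity()] objects.
#' @param shared_nodes Character vector of nodes present in every network
#'   (>= 3).
#' @param type `"vector"` (centrality) or `"cosine"` (similarity-matrix upper
#'   triangle).
#' @param max_pairs Upper-triangle subsample cap for `type = "cosine"`.
#' @param seed Seed for the subsample.
#' @return List with `cor_matrix` (symmetric, unit diagonal; `NA` for
#'   degenerate constant vectors), `mean_individual_aggregate`,
#'   `mean_individual_individual`, and `subsample_se` (`NA` unless
#'   subsampling occurred).
#' @export
cross_network_measure_correlation <- function(measures, shared_nodes,
                                              type = c("vector", "cosine"),
                                              max_pairs = 100000L, seed = 1L) {
  type <- match.arg(type)
  if (length(measures) < 2) stop("need >= 2 networks", call. = FALSE)
  if (length(shared_nodes) < 3) stop("need >= 3 shared nodes", call. = FALSE)
  k <- length(measures)
  if (type == "vector") {
    mat <- vapply(measures, function(v) unname(v[shared_nodes]),
                  numeric(length(shared_nodes)))
    subsample_se <- NA_real_
  } else {
    n <- length(shared_nodes)
    ut <- upper.tri(matrix(0, n, n))
    idx <- which(ut)
    subsample_se <- NA_real_
    if (length(idx) > max_pairs) {
      idx <- .with_seed(seed, sample(idx, max_pairs))
    }
    mat <- vapply(measures, function(m) {
      .cosine_matrix(m, shared_nodes)[idx]
    }, numeric(length(idx)))
  }
  cm <- suppressWarnings(stats::cor(mat))
  diag(cm) <- 1
  if (type == "cosine" && sum(upper.tri(cm)) > 0 &&
      nrow(mat) < choose(length(shared_nodes), 2)) {
    # delta-method SE of a correlation estimated from m sampled pairs
    subsample_se <- (1 - mean(cm[upper.tri(cm)], na.rm = TRUE)^2) /
      sqrt(nrow(mat) - 3)
  }
  nm <- names(measures)
  is_agg <- nm == "aggregate"
  ut <- upper.tri(cm)
  ia <- cm[is_agg, !is_agg]
  ii <- cm[!is_agg, !is_agg][upper.tri(diag(sum(!is_agg)))]
  list(
    cor_matrix = cm,
    mean_individual_aggregate = if (any(is_agg)) mean(ia, na.rm = TRUE)
                                else NA_real_,
    mean_individual_individual = if (sum(!is_agg) >= 2) mean(ii, na.rm = TRUE)
                                 else NA_real_,
    subsample_se = subsample_se
  )
}
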