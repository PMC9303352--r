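#' @keywords internal
.effect_row <- function(participant_id, task, network_source, statistic,
                        value, n_retrieved, n_comparison) {
  data.frame(participant_id = participant_id, task = task,
             network_source = network_source, statistic = statistic,
             value = value, n_retrieved = n_retrieved,
             n_comparison = n_comparison, stringsAsFactors = FALSE)
}

#' Fluency retrieval-centrality effect
#'
#' Difference in mean scaled PageRank between candidate words the participant
#' retrieved and candidate words present in the network but not retrieved.
#' For the category task the candidate set is an explicit category word list;
#' for the letter task it is every network word starting with the task letter.
#' Retrieved items absent from the network are dropped and counted.
#'
#' @param centrality Scaled PageRank vector (see [pagerank()]) of the network
#'   the effect is evaluated under.
#' @param items Character vector: the retrieval sequence (already
#'   deduplicated).
#' @param candidates Character vector of candidate words; must all be network
#'   nodes.
#' @param participant_id,task,network_source Metadata carried into the result.
#' @return One-row effect data frame (`value` = mean retrieved - mean
#'   nonretrieved, with support sizes) plus attribute `n_items_dropped`.
#' @export
fluency_retrieval_effect <- function(centrality, items, candidates,
                                     participant_id = NA_character_,
                                     task = "fluency",
                                     network_source = "individual") {
  nodes <- names(centrality)
  if (!all(candidates %in% nodes)) {
    stop("candidates must be a subset of network nodes", call. = FALSE)
  }
  dropped <- sum(!(items %in% nodes))
  retrieved <- intersect(items, candidates)
  nonretrieved <- setdiff(candidates, items)
  if (length(retrieved) == 0) {
    stop("undefined effect: no retrieved candidate is in the network",
         call. = FALSE)
  }
  if (length(nonretrieved) == 0) {
    stop("undefined effect: every candidate was retrieved (empty comparison set)",
         call. = FALSE)
  }
  out <- .effect_row(participant_id, task, network_source,
                     "centrality_retrieved_minus_nonretrieved",
                     mean(centrality[retrieved]) - mean(centrality[nonretrieved]),
                     length(retrieved), length(nonretrieved))
  attr(out, "n_items_dropped") <- dropped
  out
}

#' Mean cosine similarity by retrieval lag
#'
#' For each lag 1..`max_lag`, the mean cosine between words `lag` positions
#' apart in the retrieval sequence. Both words of a pair must be network
#' nodes; pairs involving out-of-network items are excluded, the sequence is
#' not re-spliced around them. Semantically guided retrieval shows up as
#' lag-1 similarity exceeding lag-3 similarity.
#'
#' @param model A [walk_similarity()] object.
#' @param items Retrieval sequence (deduplicated, in order).
#' @param max_lag Largest lag, default 3.
#' @param participant_id,task,network_source Metadata.
#' @return Data frame with one row per lag: `lag`, `value` (mean cosine, `NA`
#'   when no pair exists at that lag), `n_pairs`.
#' @export
fluency_lag_similarity <- function(model, items, max_lag = 3L,
                                   participant_id = NA_character_,
                                   task = "fluency",
                                   network_source = "individual") {
  in_net <- items %in% model$nodes
  n <- length(items)
  rows <- lapply(seq_len(max_lag), function(lag) {
    if (n > lag) {
      i <- seq_len(n - lag)
      ok <- in_net[i] & in_net[i + lag]
      vals <- if (any(ok)) {
        cosine_similarity(model, items[i][ok], items[i + lag][ok])
      } else {
        numeric(0)
      }
    } else {
      vals <- numeric(0)
    }
    data.frame(participant_id = participant_id, task = task,
               network_source = network_source, lag = lag,
               value = if (length(vals)) mean(vals) else NA_real_,
               n_pairs = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Episodic recall-status profile
#'
#' Splits the union of studied and recalled words (restricted to network
#' nodes) into retrieved (studied and recalled), missing (studied, not
#' recalled) and intrusions (recalled, not studied, but present in the
#' network), and reports for each status the mean scaled PageRank and the
#' mean cosine to the retrieved words. For a retrieved word the
#' cosine-to-retrieved excludes the word itself. Words absent from the network
#' are excluded and counted.
#'
#' @param centrality Scaled PageRank vector.
#' @param model A [walk_similarity()] object over the same network (may be
#'   `NULL` to skip the similarity profile).
#' @param studied,recalled Character vectors of canonical words.
#' @param participant_id,network_source Metadata.
#' @return Data frame with one row per status: `n`, `mean_centrality`,
#'   `mean_cosine_to_retrieved` (`NA` when undefined), and attribute
#'   `n_words_dropped` (out-of-network words).
#' @export
episodic_profile <- function(centrality, model, studied, recalled,
                             participant_id = NA_character_,
                             network_source = "individual") {
  nodes <- names(centrality)
  studied <- unique(studied)
  recalled <- unique(recalled)
  dropped <- sum(!(unique(c(studied, recalled)) %in% nodes))
  studied_n <- intersect(studied, nodes)
  recalled_n <- intersect(recalled, nodes)
  if (length(studied_n) == 0) {
    stop("no studied word is in the network", call. = FALSE)
  }
  status <- list(
    retrieved = intersect(studied_n, recalled_n),
    missing = setdiff(studied_n, recalled_n),
    intrusion = setdiff(recalled_n, studied_n)
  )
  retrieved <- status$retrieved
  sim_to_retrieved <- function(w, is_retrieved) {
    others <- if (is_retrieved) setdiff(retrieved, w) else retrieved
    if (length(others) == 0) return(NA_real_)
    mean(cosine_similarity(model, rep(w, length(others)), others))
  }
  rows <- lapply(names(status), function(st) {
    ws <- status[[st]]
    data.frame(
      participant_id = participant_id, network_source = network_source,
      status = st, n = length(ws),
      mean_centrality = if (length(ws)) mean(centrality[ws]) else NA_real_,
      mean_cosine_to_retrieved =
        if (length(ws) && !is.null(model) && length(retrieved)) {
          mean(vapply(ws, sim_to_retrieved, numeric(1),
                      is_retrieved = (st == "retrieved")))
        } else {
          NA_real_
        },
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_words_dropped") <- dropped
  out
}

#' Paired-associate similarity effect
#'
#' Difference in mean cue-target cosine between recalled and unrecalled word
#' pairs. Only pairs with both words in the network enter the comparison.
#'
#' @param model A [walk_similarity()] object.
#' @param pairs Data frame with columns `cue`, `target`, `recalled` (logical),
#'   e.g. from [load_paired()].
#' @param participant_id,network_source Metadata.
#' @return One-row effect data frame (`value` = mean recalled cosine - mean
#'   unrecalled cosine).
#' @export
paired_associate_effect <- function(model, pairs,
                                    participant_id = NA_character_,
                                    network_source = "individual") {
  in_net <- pairs$cue %in% model$nodes & pairs$target %in% model$nodes
  use <- pairs[in_net, , drop = FALSE]
  n_rec <- sum(use$recalled)
  n_un <- sum(!use$recalled)
  if (n_rec == 0 || n_un == 0) {
    stop("undefined effect: need both recalled and unrecalled in-network pairs",
         call. = FALSE)
  }
  cos <- cosine_similarity(model, use$cue, use$target)
  out <- .effect_row(participant_id, "paired_associates", network_source,
                     "cosine_recalled_minus_unrecalled",
                     mean(cos[use$recalled]) - mean(cos[!use$recalled]),
                     n_rec, n_un)
  attr(out, "n_pairs_dropped") <- sum(!in_net)
  out
}

#' Compare effects under individual versus aggregate networks
#'
#' Pairs each participant's effect computed under their own network with the
#' effect computed by applying the aggregate network's measures to the same
#' behavioural data, and summarizes per task. No significance test is
#' attached: with cohorts of this size the comparison is descriptive.
#'
#' @param effects_ind,effects_agg Effect data frames (rows from the effect
#'   functions) with `network_source` `"individual"` and `"aggregate"`; must
#'   cover the same participants and tasks.
#' @return Data frame with one row per (task, statistic): `mean_individual`,
#'   `mean_aggregate`, `difference` (aggregate - individual), `n_participants`.
#' @export
compare_individual_vs_aggregate <- function(effects_ind, effects_agg) {
  key <- function(d) sort(paste(d$participant_id, d$task, d$statistic,
                                sep = "\r"))
  if (!identical(key(effects_ind), key(effects_agg))) {
    stop("individual and aggregate effects cover different participants/tasks",
         call. = FALSE)
  }
  agg_mean <- function(d) stats::aggregate(
    d["value"], by = list(task = d$task, statistic = d$statistic), FUN = mean)
  mi <- agg_mean(effects_ind)
  ma <- agg_mean(effects_agg)
  names(mi)[3] <- "mean_individual"
  names(ma)[3] <- "mean_aggregate"
  out <- merge(mi, ma, by = c("task", "statistic"))
  out$difference <- out$mean_aggregate - out$mean_individual
  cnt <- stats::aggregate(effects_ind["value"],
                          by = list(task = effects_ind$task,
                                    statistic = effects_ind$statistic),
                          FUN = length)
  names(cnt)[3] <- "n_participants"
  merge(out, cnt, by = c("task", "statistic"))
}
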