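#' Ground-truth network parameters for one group
#'
#' Parameters of the small-world ground-truth lexicon generator. The defaults
#' for `group_params("young")` and `group_params("old")` encode the
#' qualitative young/old contrast the analysis is designed to detect: older
#' adults' lexicons are larger and sparser (lower mean degree), less locally
#' clustered, and consequently have longer shortest paths.
#'
#' @param group `"young"` or `"old"`.
#' @param n_words Lexicon size (>= 50). Defaults: 2000 (young), 2600 (old).
#' @param target_mean_degree Mean degree including the hub overlay; the
#'   lattice part (`target_mean_degree - 2 * hub_overlay`) must round to an
#'   even integer >= 2. Defaults: 12 (young), 8 (old).
#' @param clustering_control In \[0, 1\]; 1 keeps the clustered ring lattice
#'   intact, lower values rewire more edges (rewiring probability is
#'   `1 - clustering_control`), monotonically lowering realized clustering.
#'   Defaults: 0.90 (young), 0.30 (old).
#' @param participant_rewire Fraction of edges degree-preservingly rewired to
#'   turn the group's base network into one participant's idiosyncratic
#'   truth. Default 0.10.
#' @param prominence_sd Standard deviation (log scale) of the log-normal
#'   node prominence (truncated at `exp(2.5 * prominence_sd)`) that sets
#'   associative edge strengths
#'   (`w_ij = ceiling(prominence_i * prominence_j)`, capped at 50) and
#'   attracts the hub-overlay edges. Word frequency in natural lexicons is
#'   strongly skewed; prominence reproduces that skew, giving heterogeneous
#'   centrality and frequency-biased responses. Default 2.
#' @param hub_overlay Number of extra edges per word (on average) drawn with
#'   a uniformly chosen first endpoint and a prominence-proportional second
#'   endpoint. This overlays the clustered lattice with the heavy-tailed
#'   degree distribution of real association lexicons, in which a few
#'   high-frequency words are responses to very many cues. Counted inside
#'   `target_mean_degree` (each unit contributes 2 to the mean degree).
#'   Defaults: 4 (young), 2 (old) — the old group's sparser overlay, lower
#'   degree and larger lexicon jointly lengthen its shortest paths.
#' @param n_categories Number of semantic categories. The first is labelled
#'   `"animals"`.
#' @param category_size Words per category.
#' @param category_cohesion Extra within-category edges per member (uniform
#'   first endpoint, prominence-proportional second), reflecting the dense
#'   internal wiring of taxonomic categories in association norms. Default 1.
#' @param scale Multiplies `n_words` and `category_size` (rounded), for
#'   reduced-scale simulation studies.
#' @return Object of class `group_params`.
#' @export
group_params <- function(group = c("young", "old"), n_words = NULL,
                         target_mean_degree = NULL, clustering_control = NULL,
                         participant_rewire = 0.10, prominence_sd = 2,
                         hub_overlay = NULL, n_categories = 8L,
                         category_size = 80L, category_cohesion = 1,
                         scale = 1) {
  group <- match.arg(group)
  defaults <- list(
    young = list(n_words = 2000L, target_mean_degree = 12L,
                 clustering_control = 0.90, hub_overlay = 4),
    old = list(n_words = 2600L, target_mean_degree = 8L,
               clustering_control = 0.30, hub_overlay = 2)
  )[[group]]
  if (is.null(hub_overlay)) hub_overlay <- defaults$hub_overlay
  p <- list(
    group = group,
    n_words = as.integer(round((if (is.null(n_words)) defaults$n_words
                                else n_words) * scale)),
    target_mean_degree = if (is.null(target_mean_degree))
      defaults$target_mean_degree else as.integer(target_mean_degree),
    clustering_control = if (is.null(clustering_control))
      defaults$clustering_control else clustering_control,
    participant_rewire = participant_rewire,
    prominence_sd = prominence_sd,
    hub_overlay = hub_overlay,
    category_cohesion = category_cohesion,
    n_categories = as.integer(n_categories),
    category_size = as.integer(round(category_size * scale))
  )
  if (p$n_words < 50) stop("n_words must be >= 50", call. = FALSE)
  if (p$target_mean_degree < 2) {
    stop("target_mean_degree must be >= 2", call. = FALSE)
  }
  if (p$clustering_control < 0 || p$clustering_control > 1) {
    stop("clustering_control must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_categories * p$category_size > p$n_words) {
    stop("categories exceed lexicon size", call. = FALSE)
  }
  class(p) <- "group_params"
  p
}

#' Behavioural simulation parameters
#'
#' Governs how synthetic participants respond. Retrieval log-odds are coupled
#' to scaled PageRank with slope `beta_centrality` and to cosine similarity
#' with slope `beta_similarity`; setting both to 0 yields behaviour unrelated
#' to network structure (the null used for calibration checks).
#'
#' @param beta_centrality Slope of retrieval log-odds on scaled PageRank
#'   (centred at its mean of 1). Scaled PageRank is heavy-tailed (hub words
#'   reach 10-20), so a moderate slope already makes hub retrieval nearly
#'   certain. Default 0.5.
#' @param beta_similarity Slope on cosine similarity (which spans roughly
#'   0-0.5 on these networks). Default 25.
#' @param fluency_length Retrievals per fluency sequence (>= 4). Default 20.
#' @param episodic_list_length,episodic_n_lists Words per studied list and
#'   number of lists. Defaults 20 and 2.
#' @param n_pairs Paired-associate trials. Default 80.
#' @param repeat_fidelity q in \[0, 1\]: probability that a repeat-encounter
#'   response copies the same-position first-encounter response; otherwise a
#'   different association (one not given at the first encounter) is
#'   produced. Default 0.53, a moderate consistency typical of repeated free
#'   association.
#' @param noise_rate Probability an association response is an idiosyncratic
#'   uniform draw from the lexicon instead of a ground-truth neighbour.
#'   Default 0.05.
#' @param intrusion_rate Per-recalled-word probability of injecting a
#'   non-studied neighbour as an intrusion. Default 0.1.
#' @param episodic_intercept,paired_intercept Base log-odds of recall.
#'   Defaults 0 and -1.5.
#' @return Object of class `behavior_params`.
#' @export
behavior_params <- function(beta_centrality = 0.5, beta_similarity = 25,
                            fluency_length = 20L, episodic_list_length = 20L,
                            episodic_n_lists = 2L, n_pairs = 80L,
                            repeat_fidelity = 0.53, noise_rate = 0.05,
                            intrusion_rate = 0.1, episodic_intercept = 0,
                            paired_intercept = -1.5) {
  if (fluency_length < 4) stop("fluency_length must be >= 4", call. = FALSE)
  if (repeat_fidelity < 0 || repeat_fidelity > 1) {
    stop("repeat_fidelity must lie in [0, 1]", call. = FALSE)
  }
  p <- list(beta_centrality = beta_centrality,
            beta_similarity = beta_similarity,
            fluency_length = as.integer(fluency_length),
            episodic_list_length = as.integer(episodic_list_length),
            episodic_n_lists = as.integer(episodic_n_lists),
            n_pairs = as.integer(n_pairs),
            repeat_fidelity = repeat_fidelity,
            noise_rate = noise_rate,
            intrusion_rate = intrusion_rate,
            episodic_intercept = episodic_intercept,
            paired_intercept = paired_intercept)
  class(p) <- "behavior_params"
  p
}

#' Build a synthetic lexicon of word tokens
#'
#' Tokens are a random lower-case initial letter followed by a zero-padded
#' index (e.g. `"s00421"`), so letter-fluency candidate sets exist while the
#' tokens stay linguistically neutral. A shared lexicon lets different
#' participants' and groups' ground-truth networks overlap in node identity.
#'
#' @param n Number of tokens.
#' @param seed Integer seed.
#' @return Character vector of unique canonical tokens.
#' @export
make_lexicon <- function(n, seed = 1L) {
  .with_seed(seed, sprintf("%s%05d", sample(letters, n, replace = TRUE),
                           seq_len(n)))
}

#' @keywords internal
.prominence_weights <- function(g) {
  pr <- igraph::V(g)$prominence
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  igraph::E(g)$weight <- pmin(50, ceiling(pr[el[, 1]] * pr[el[, 2]]))
  g
}

#' @keywords internal
.ensure_connected <- function(g) {
  comp <- igraph::components(g)
  if (comp$no > 1) {
    giant <- which.max(comp$csize)
    for (cid in setdiff(seq_len(comp$no), giant)) {
      from <- which(comp$membership == cid)[1]
      to <- which(comp$membership == giant)[1]
      g <- igraph::add_edges(g, c(from, to))
    }
  }
  g
}

#' Generate a ground-truth semantic network
#'
#' Watts-Strogatz-style construction: a ring lattice of `n_words` nodes with
#' `target_mean_degree` neighbours each, rewired with probability
#' `1 - clustering_control`. Rewired edges choose their new endpoint
#' preferentially, proportionally to node prominence, so the lexicon acquires
#' the heavy-tailed degree distribution typical of free-association networks
#' (a few hub words connected to very many cues) while the intact lattice
#' part preserves local clustering. Lowering the clustering control therefore
#' lowers realized C at fixed mean degree, while degree and size govern path
#' length. The graph is forced connected by linking any stray component into
#' the giant component. Contiguous lattice blocks receive category labels
#' (vertex attribute `category`; the first block is `"animals"`).
#'
#' @param params A [group_params()] object.
#' @param seed Integer seed; the same (params, seed, lexicon) always yields
#'   the identical graph.
#' @param lexicon Optional character vector of node names (at least
#'   `n_words`; the first `n_words` are used). Defaults to a lexicon built
#'   from `seed`. Supplying one shared lexicon across calls makes networks
#'   comparable across participants and groups.
#' @param category_span Index range (from 1) within which category blocks are
#'   placed; defaults to `n_words`. Using the smallest group's `n_words`
#'   keeps category membership identical across groups.
#' @return Semantic network (igraph) with unit edge weights and graph
#'   attribute `group`.
#' @export
generate_truth_network <- function(params, seed = 1L, lexicon = NULL,
                                   category_span = NULL) {
  stopifnot(inherits(params, "group_params"))
  n <- params$n_words
  lattice_degree <- params$target_mean_degree - 2 * params$hub_overlay
  nei <- as.integer(round(lattice_degree / 2))
  if (nei < 1 || 2 * nei >= n) {
    stop("unsatisfiable degree/size combination", call. = FALSE)
  }
  if (is.null(lexicon)) lexicon <- make_lexicon(n, seed)
  if (length(lexicon) < n) stop("lexicon shorter than n_words", call. = FALSE)
  span <- if (is.null(category_span)) n else as.integer(category_span)
  if (params$category_size * params$n_categories > span) {
    stop("categories exceed category_span", call. = FALSE)
  }
  .with_seed(seed, {
    # truncated at exp(2.5 sd): keeps the heavy tail but prevents a single
    # extreme draw from wiring to most of the lexicon
    prominence <- pmin(stats::rlnorm(n, 0, params$prominence_sd),
                       exp(2.5 * params$prominence_sd))
    g <- igraph::sample_smallworld(1, n, nei, p = 0)
    g <- igraph::simplify(g)
    el <- igraph::ends(g, igraph::E(g), names = FALSE)
    rewire_mask <- stats::runif(nrow(el)) < 1 - params$clustering_control
    if (any(rewire_mask)) {
      el[rewire_mask, 2] <- sample.int(n, sum(rewire_mask), replace = TRUE,
                                       prob = prominence)
    }
    n_extra <- round(params$hub_overlay * n)
    if (n_extra > 0) {
      extra <- cbind(sample.int(n, n_extra, replace = TRUE),
                     sample.int(n, n_extra, replace = TRUE,
                                prob = prominence))
      el <- rbind(el, extra)
    }
    keep <- el[, 1] != el[, 2]
    g <- igraph::simplify(igraph::graph_from_edgelist(el[keep, , drop = FALSE],
                                                      directed = FALSE))
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    igraph::V(g)$name <- lexicon[seq_len(n)]
    g <- .ensure_connected(g)
    igraph::V(g)$prominence <- prominence
    g <- .prominence_weights(g)
    # categories sample the whole span so each spans the full centrality
    # hierarchy, as real-world taxonomic vocabularies do; membership is a
    # deterministic function of the lexicon, shared across groups
    cat_lab <- rep(NA_character_, n)
    cat_names <- c("animals",
                   sprintf("category%02d", seq_len(params$n_categories - 1) + 1))
    members <- .with_seed(1L, sample.int(span,
                                         params$n_categories *
                                           params$category_size))
    cat_lab[members] <- rep(cat_names, each = params$category_size)
    igraph::V(g)$category <- cat_lab
    if (params$category_cohesion > 0) {
      n_in <- round(params$category_cohesion * params$category_size)
      for (cn in cat_names) {
        mem <- which(cat_lab == cn)
        g <- igraph::add_edges(g, rbind(
          sample(mem, n_in, replace = TRUE),
          sample(mem, n_in, replace = TRUE, prob = prominence[mem])))
      }
      g <- igraph::simplify(g)
      g <- .prominence_weights(g)
    }
    igraph::graph_attr(g, "group") <- params$group
    g
  })
}

#' Derive one participant's truth network from a group base
#'
#' Applies degree-preserving edge rewiring to `participant_rewire` of the
#' base network's edges, modelling idiosyncratic experience on top of the
#' shared group structure, then reconnects stray components. Node names,
#' categories and metadata are retained.
#'
#' @param base Group base network from [generate_truth_network()].
#' @param params The matching [group_params()] object.
#' @param seed Integer seed.
#' @return Semantic network for one participant.
#' @export
individual_truth <- function(base, params, seed = 1L) {
  .with_seed(seed, {
    n_swap <- round(params$participant_rewire * igraph::ecount(base))
    g <- igraph::rewire(base, igraph::keeping_degseq(niter = n_swap))
    g <- .ensure_connected(g)
    # weights derive from the shared node prominences, so participants agree
    # on which words are strong even where their wiring differs
    .prominence_weights(g)
  })
}

#' @keywords internal
.sample_weighted <- function(pool, weights, size) {
  if (length(pool) == 0 || size == 0) return(character(0))
  size <- min(size, length(pool))
  if (length(pool) == 1) return(pool)
  pool[sample.int(length(pool), size, prob = weights)]
}

#' Simulate one participant's association responses
#'
#' Each cue encounter receives up to three responses drawn without
#' replacement from the cue's ground-truth neighbourhood (proportionally to
#' edge weight), except that with probability `noise_rate` a response is an
#' idiosyncratic uniform draw from the lexicon. `n_repeat_cues` of the cues
#' are encountered a second time; each repeat response copies the
#' same-position first-encounter response with probability `repeat_fidelity`
#' and otherwise is a different association, i.e. one not given at the first
#' encounter. A cue yielding fewer than three responses is counted in the
#' `"n_short_responses"` attribute.
#'
#' @param truth Ground-truth network ([generate_truth_network()] or
#'   [individual_truth()]).
#' @param n_unique_cues,n_repeat_cues Encounter design;
#'   `n_repeat_cues <= n_unique_cues <= |V|`. Ignored if `cues` is given
#'   (then `n_unique_cues = length(cues)`).
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @param participant_id Participant label.
#' @param cues Optional fixed cue list (canonical words, all in `truth`), as
#'   when every participant answers the same experimenter-chosen cues.
#' @return Association record data frame in the [load_associations()] schema.
#' @export
simulate_associations <- function(truth, n_unique_cues, n_repeat_cues,
                                  params = behavior_params(), seed = 1L,
                                  participant_id = "P01", cues = NULL) {
  nodes <- igraph::V(truth)$name
  if (!is.null(cues)) {
    if (!all(cues %in% nodes)) stop("cues outside lexicon", call. = FALSE)
    n_unique_cues <- length(cues)
  }
  if (n_unique_cues > length(nodes)) {
    stop("n_unique_cues exceeds lexicon size", call. = FALSE)
  }
  if (n_repeat_cues > n_unique_cues) {
    stop("n_repeat_cues exceeds n_unique_cues", call. = FALSE)
  }
  adj <- igraph::as_adj_list(truth)
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  names(adj) <- nodes
  ew <- igraph::E(truth)$weight
  wts <- lapply(igraph::incident_edges(truth, igraph::V(truth)),
                function(e) ew[as.integer(e)])
  names(wts) <- nodes
  .with_seed(seed, {
    if (is.null(cues)) cues <- sample(nodes, n_unique_cues)
    n_short <- 0L

    draw_one <- function(cue, chosen, exclude) {
      use_noise <- stats::runif(1) < params$noise_rate
      nb <- adj[[cue]]
      keep <- !(nb %in% c(chosen, exclude, cue))
      if (use_noise || !any(keep)) {
        if (!use_noise && params$noise_rate == 0) return(NA_character_)
        pool <- setdiff(nodes, c(cue, chosen, exclude))
        if (length(pool) == 0) return(NA_character_)
        return(pool[sample.int(length(pool), 1)])
      }
      .sample_weighted(nb[keep], wts[[cue]][keep], 1)
    }

    respond <- function(cue, exclude = character(0)) {
      chosen <- character(0)
      for (j in 1:3) {
        r <- draw_one(cue, chosen, exclude)
        if (is.na(r)) break
        chosen <- c(chosen, r)
      }
      if (length(chosen) < 3) n_short <<- n_short + 1L
      c(chosen, rep(NA_character_, 3 - length(chosen)))
    }

    first <- t(vapply(cues, respond, character(3)))
    rec <- data.frame(
      participant_id = participant_id,
      encounter_index = seq_len(n_unique_cues),
      cue = cues, r1 = first[, 1], r2 = first[, 2], r3 = first[, 3],
      is_repeat = FALSE, stringsAsFactors = FALSE
    )
    if (n_repeat_cues > 0) {
      rep_cues <- sample(cues, n_repeat_cues)
      rep_rows <- lapply(seq_along(rep_cues), function(i) {
        cue <- rep_cues[i]
        first_resp <- as.character(stats::na.omit(first[match(cue, cues), ]))
        chosen <- character(0)
        for (j in 1:3) {
          copy <- j <= length(first_resp) &&
            stats::runif(1) < params$repeat_fidelity &&
            !(first_resp[j] %in% chosen)
          r <- if (copy) first_resp[j]
               else draw_one(cue, chosen, exclude = first_resp)
          if (is.na(r)) break
          chosen <- c(chosen, r)
        }
        if (length(chosen) < 3) n_short <<- n_short + 1L
        chosen <- c(chosen, rep(NA_character_, 3 - length(chosen)))
        data.frame(participant_id = participant_id,
                   encounter_index = n_unique_cues + i, cue = cue,
                   r1 = chosen[1], r2 = chosen[2], r3 = chosen[3],
                   is_repeat = TRUE, stringsAsFactors = FALSE)
      })
      rec <- rbind(rec, do.call(rbind, rep_rows))
    }
    rownames(rec) <- NULL
    attr(rec, "n_short_responses") <- n_short
    rec
  })
}

#' Expected response yield of an association design
#'
#' Closed form for the number of responses a full protocol elicits:
#' `responses_per_cue * (n_unique + n_repeat)` — e.g. three responses to
#' 3,000 unique plus 600 repeated cues yield 10,800 responses per
#' participant.
#'
#' @param n_unique,n_repeat Cue counts.
#' @param responses_per_cue Responses requested per encounter (default 3).
#' @return Expected total number of responses.
#' @export
expected_response_yield <- function(n_unique, n_repeat,
                                    responses_per_cue = 3L) {
  responses_per_cue * (n_unique + n_repeat)
}

#' Simulate a verbal-fluency retrieval sequence
#'
#' The first item is sampled from the candidate set with probability
#' proportional to `exp(beta_centrality * PR)`; each subsequent item is
#' sampled among unretrieved candidates proportionally to
#' `exp(beta_centrality * PR + beta_similarity * cosine-to-previous)`.
#' Retrieval stops after `fluency_length` items or when candidates are
#' exhausted (a shorter sequence, flagged via the `"exhausted"` attribute).
#' Probabilities are computed on the max-shifted log scale, so very large
#' slopes degrade gracefully into deterministic argmax retrieval.
#'
#' @param centrality Scaled PageRank over the ground-truth network.
#' @param model [walk_similarity()] object whose rows cover `candidates`.
#' @param candidates Candidate words (category members, or words with the
#'   task letter).
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @param participant_id,task,task_key Metadata for the output rows.
#' @return Fluency data frame in the [load_fluency()] schema.
#' @export
simulate_fluency <- function(centrality, model, candidates,
                             params = behavior_params(), seed = 1L,
                             participant_id = "P01", task = "category",
                             task_key = "animals") {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  .with_seed(seed, {
    pool <- candidates
    seqn <- character(0)
    while (length(seqn) < params$fluency_length && length(pool) > 0) {
      x <- params$beta_centrality * centrality[pool]
      if (length(seqn) > 0 && params$beta_similarity != 0) {
        x <- x + params$beta_similarity *
          cosine_similarity(model, rep(seqn[length(seqn)], length(pool)), pool)
      }
      p <- exp(x - max(x))
      nxt <- pool[sample.int(length(pool), 1, prob = p)]
      seqn <- c(seqn, nxt)
      pool <- setdiff(pool, nxt)
    }
    out <- data.frame(participant_id = participant_id, task = task,
                      task_key = task_key, position = seq_along(seqn),
                      word = seqn, stringsAsFactors = FALSE)
    attr(out, "exhausted") <- length(seqn) < params$fluency_length
    out
  })
}

#' Simulate an episodic study/recall trial
#'
#' A studied list is sampled uniformly from the lexicon; each studied word is
#' recalled with probability
#' `plogis(episodic_intercept + beta_centrality * (PR - 1))` (scaled
#' PageRank, centred at its mean of 1). Intrusions are injected from
#' non-studied ground-truth neighbours of recalled words, each recalled word
#' triggering one with probability `intrusion_rate`. Recall order is a
#' random permutation of recalled words and intrusions.
#'
#' @param truth Ground-truth network (source of intrusion neighbours).
#' @param centrality Scaled PageRank over `truth`.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @param participant_id,list_id Metadata.
#' @return Episodic data frame in the [load_episodic()] schema.
#' @export
simulate_episodic <- function(truth, centrality, params = behavior_params(),
                              seed = 1L, participant_id = "P01",
                              list_id = "L1") {
  nodes <- names(centrality)
  if (params$episodic_list_length > length(nodes)) {
    stop("list length exceeds lexicon size", call. = FALSE)
  }
  .with_seed(seed, {
    studied <- sample(nodes, params$episodic_list_length)
    p <- stats::plogis(params$episodic_intercept +
                         params$beta_centrality * (centrality[studied] - 1))
    recalled <- studied[stats::runif(length(studied)) < p]
    intr <- character(0)
    if (params$intrusion_rate > 0 && length(recalled) > 0) {
      for (w in recalled) {
        if (stats::runif(1) < params$intrusion_rate) {
          nb <- names(igraph::neighbors(truth, w))
          cand <- setdiff(nb, c(studied, intr))
          if (length(cand) > 0) intr <- c(intr, sample(cand, 1))
        }
      }
    }
    out_recall <- if (length(c(recalled, intr)) > 0) {
      sample(c(recalled, intr))
    } else {
      character(0)
    }
    rbind(
      data.frame(participant_id = participant_id, list_id = list_id,
                 phase = "studied", position = seq_along(studied),
                 word = studied, stringsAsFactors = FALSE),
      if (length(out_recall) > 0) {
        data.frame(participant_id = participant_id, list_id = list_id,
                   phase = "recalled", position = seq_along(out_recall),
                   word = out_recall, stringsAsFactors = FALSE)
      }
    )
  })
}

#' Sample the word pairs for a paired-associate trial set
#'
#' Deterministic companion of [simulate_paired()]: returns the cue-target
#' pairs that the same `(truth, params, seed)` call will use, so a
#' row-restricted similarity model can be built beforehand. Pairs span a
#' range of relatedness: one third direct neighbours, one third two-step
#' neighbours, one third random pairs.
#'
#' @param truth Ground-truth network.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @return Data frame with columns `cue`, `target`.
#' @export
simulated_pair_words <- function(truth, params = behavior_params(),
                                 seed = 1L) {
  nodes <- igraph::V(truth)$name
  .with_seed(seed, {
    n_adj <- floor(params$n_pairs / 3)
    n_two <- floor(params$n_pairs / 3)
    n_rand <- params$n_pairs - n_adj - n_two
    el <- igraph::as_data_frame(truth, what = "edges")
    pick <- el[sample.int(nrow(el), min(n_adj, nrow(el))), , drop = FALSE]
    cue <- pick$from
    target <- pick$to
    for (i in seq_len(n_two)) {
      a <- sample(nodes, 1)
      nb1 <- names(igraph::neighbors(truth, a))
      two_away <- unique(unlist(lapply(nb1, function(x) {
        names(igraph::neighbors(truth, x))
      })))
      cand <- setdiff(two_away, c(a, nb1))
      b <- if (length(cand) > 0) sample(cand, 1) else
        sample(setdiff(nodes, a), 1)
      cue <- c(cue, a)
      target <- c(target, b)
    }
    for (i in seq_len(n_rand)) {
      ab <- sample(nodes, 2)
      cue <- c(cue, ab[1])
      target <- c(target, ab[2])
    }
    data.frame(cue = cue, target = target, stringsAsFactors = FALSE)
  })
}

#' Simulate paired-associate trials
#'
#' Uses the pairs from [simulated_pair_words()] and draws recall as
#' `Bernoulli(plogis(paired_intercept + beta_similarity * cosine))`.
#'
#' @param truth Ground-truth network.
#' @param model [walk_similarity()] covering the sampled pair words.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed (the pair sample uses `seed`, the outcomes
#'   `seed + 1`).
#' @param participant_id Metadata.
#' @return Paired-associate data frame in the [load_paired()] schema.
#' @export
simulate_paired <- function(truth, model, params = behavior_params(),
                            seed = 1L, participant_id = "P01") {
  if (params$n_pairs < 2) stop("need >= 2 pairs", call. = FALSE)
  pw <- simulated_pair_words(truth, params, seed)
  .with_seed(seed + 1L, {
    cos <- cosine_similarity(model, pw$cue, pw$target)
    p <- stats::plogis(params$paired_intercept + params$beta_similarity * cos)
    data.frame(participant_id = participant_id, cue = pw$cue,
               target = pw$target,
               recalled = stats::runif(length(p)) < p,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort
#'
#' Generates a young and an old group base network over one shared lexicon,
#' derives each participant's idiosyncratic truth network by degree-preserving
#' rewiring, and simulates for every participant: an association record set
#' over a cue list shared by the whole cohort, two fluency sequences (animal
#' category and letter task), episodic trials and paired-associate trials,
#' with retrieval coupled to the ground-truth centrality and similarity. All
#' randomness derives from the single `seed`. Optionally writes every table,
#' the truth networks and the category word list to `out_dir` in the
#' package's CSV schemas.
#'
#' @param n_per_group Participants per group (default 4, i.e. a cohort of 8).
#' @param n_unique_cues,n_repeat_cues Encounter design per participant
#'   (defaults 600 and 120, a fifth of the 3,000/600 full protocol).
#' @param young,old [group_params()] for the two groups.
#' @param behavior A [behavior_params()] object.
#' @param letter Task letter for letter fluency. Default `"s"`.
#' @param include_behavior Simulate the behavioural tasks too (default).
#'   `FALSE` generates networks and associations only, which is much faster
#'   for structure-focused simulation studies.
#' @param seed Integer root seed.
#' @param out_dir Optional output directory.
#' @return List with `participants`, `associations`, `fluency`, `episodic`,
#'   `paired` (data frames, `NULL` when `include_behavior = FALSE`), `truths`
#'   (named list of igraphs), `category_words` (the animal list), `cues`
#'   (shared cue list), and `params`.
#' @export
simulate_cohort <- function(n_per_group = 4L, n_unique_cues = 1200L,
                            n_repeat_cues = 240L,
                            young = group_params("young"),
                            old = group_params("old"),
                            behavior = behavior_params(), letter = "s",
                            include_behavior = TRUE, seed = 1L,
                            out_dir = NULL) {
  groups <- rep(c("young", "old"), each = n_per_group)
  ids <- sprintf("P%02d", seq_along(groups))
  n_max <- max(young$n_words, old$n_words)
  n_min <- min(young$n_words, old$n_words)
  lexicon <- make_lexicon(n_max, seed)
  base <- list(
    young = generate_truth_network(young, seed = seed + 1L, lexicon = lexicon,
                                   category_span = n_min),
    old = generate_truth_network(old, seed = seed + 2L, lexicon = lexicon,
                                 category_span = n_min)
  )
  shared_cues <- .with_seed(seed + 3L,
                            sample(lexicon[seq_len(n_min)], n_unique_cues))
  ages <- .with_seed(seed + 4L, {
    ifelse(groups == "young", sample(24:28, length(groups), replace = TRUE),
           sample(68:70, length(groups), replace = TRUE))
  })
  sub_seeds <- .with_seed(seed + 5L, {
    matrix(sample.int(2^31 - 2, length(ids) * 6), nrow = length(ids))
  })
  animals <- igraph::V(base$young)$name[
    !is.na(igraph::V(base$young)$category) &
      igraph::V(base$young)$category == "animals"]
  truths <- list()
  assoc <- list()
  flu <- list()
  epi <- list()
  par_tr <- list()
  for (i in seq_along(ids)) {
    gp <- if (groups[i] == "young") young else old
    truth <- individual_truth(base[[groups[i]]], gp, seed = sub_seeds[i, 1])
    rec <- simulate_associations(truth, n_unique_cues, n_repeat_cues,
                                 behavior, seed = sub_seeds[i, 2],
                                 participant_id = ids[i], cues = shared_cues)
    truths[[ids[i]]] <- truth
    assoc[[i]] <- rec
    if (!include_behavior) next
    pr <- pagerank(truth)
    s_words <- grep(paste0("^", letter), igraph::V(truth)$name, value = TRUE)
    pair_words <- simulated_pair_words(truth, behavior,
                                       seed = sub_seeds[i, 5])
    rows_needed <- unique(c(animals, s_words, pair_words$cue,
                            pair_words$target))
    model <- walk_similarity(truth, use_ppmi = TRUE, rows = rows_needed)
    f1 <- simulate_fluency(pr, model, animals, behavior,
                           seed = sub_seeds[i, 3], participant_id = ids[i],
                           task = "category", task_key = "animals")
    f2 <- simulate_fluency(pr, model, s_words, behavior,
                           seed = sub_seeds[i, 3] + 1L,
                           participant_id = ids[i], task = "letter",
                           task_key = letter)
    ep <- lapply(seq_len(behavior$episodic_n_lists), function(l) {
      simulate_episodic(truth, pr, behavior, seed = sub_seeds[i, 4] + l,
                        participant_id = ids[i],
                        list_id = sprintf("L%d", l))
    })
    pa <- simulate_paired(truth, model, behavior, seed = sub_seeds[i, 5],
                          participant_id = ids[i])
    flu[[i]] <- rbind(f1, f2)
    epi[[i]] <- do.call(rbind, ep)
    par_tr[[i]] <- pa
  }
  out <- list(
    participants = data.frame(participant_id = ids, age = ages,
                              group = groups, stringsAsFactors = FALSE),
    associations = do.call(rbind, assoc),
    fluency = if (include_behavior) do.call(rbind, flu),
    episodic = if (include_behavior) do.call(rbind, epi),
    paired = if (include_behavior) do.call(rbind, par_tr),
    truths = truths,
    category_words = animals,
    cues = shared_cues,
    params = list(n_per_group = n_per_group, n_unique_cues = n_unique_cues,
                  n_repeat_cues = n_repeat_cues, young = unclass(young),
                  old = unclass(old), behavior = unclass(behavior),
                  letter = letter, seed = seed)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_associations(out$associations, file.path(out_dir, "associations.csv"))
    utils::write.csv(out$participants, file.path(out_dir, "participants.csv"),
                     row.names = FALSE)
    if (include_behavior) {
      utils::write.csv(out$fluency, file.path(out_dir, "fluency.csv"),
                       row.names = FALSE, na = "")
      utils::write.csv(out$episodic, file.path(out_dir, "episodic.csv"),
                       row.names = FALSE, na = "")
      pa <- out$paired
      pa$recalled <- as.integer(pa$recalled)
      utils::write.csv(pa, file.path(out_dir, "paired.csv"), row.names = FALSE)
    }
    writeLines(animals, file.path(out_dir, "animals.txt"))
    for (id in names(truths)) {
      export_network(truths[[id]],
                     file.path(out_dir, sprintf("truth_%s.tsv", id)), "tsv")
    }
    jsonlite::write_json(out$params, file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  out
}
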