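#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one list, with the
#' defaults recorded in the emitted provenance file. Either simulation
#' parameters (`simulate = TRUE`) or input paths must be supplied.
#'
#' @param simulate Generate a synthetic cohort (default) instead of reading
#'   input files.
#' @param paths Named list of input paths (`associations`, `participants`,
#'   `fluency`, `episodic`, `paired`, `category_list`) used when
#'   `simulate = FALSE`.
#' @param n_per_group,n_unique_cues,n_repeat_cues,young,old,behavior,letter
#'   Passed to [simulate_cohort()] when simulating.
#' @param include_repeats Use repeat encounters when building networks.
#' @param damping PageRank damping factor.
#' @param alpha Walk-similarity decay.
#' @param use_ppmi PPMI-reweight edges for similarity (centrality always uses
#'   raw counts).
#' @param letter_rule `"task_letter"`: letter-fluency candidates are network
#'   words starting with the task letter; `"retrieved_initials"`: words
#'   starting with any letter that begins a retrieved word.
#' @param consistency_direction Passed to [repeated_cue_consistency()].
#' @param seed Root seed; every stage derives its randomness from it.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(simulate = TRUE, paths = list(),
                            n_per_group = 4L, n_unique_cues = 1200L,
                            n_repeat_cues = 240L,
                            young = group_params("young"),
                            old = group_params("old"),
                            behavior = behavior_params(), letter = "s",
                            include_repeats = TRUE, damping = 0.85,
                            alpha = 0.75, use_ppmi = TRUE,
                            letter_rule = c("task_letter",
                                            "retrieved_initials"),
                            consistency_direction = "second_vs_first",
                            seed = 1L) {
  cfg <- list(simulate = simulate, paths = paths, n_per_group = n_per_group,
              n_unique_cues = n_unique_cues, n_repeat_cues = n_repeat_cues,
              young = young, old = old, behavior = behavior, letter = letter,
              include_repeats = include_repeats, damping = damping,
              alpha = alpha, use_ppmi = use_ppmi,
              letter_rule = match.arg(letter_rule),
              consistency_direction = consistency_direction, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; `young`, `old`
#' and `behavior` may be given as nested maps of the corresponding
#' constructor arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$young)) args$young <- do.call(group_params,
                                               c(list(group = "young"),
                                                 y$young[setdiff(names(y$young), "group")]))
  if (!is.null(y$old)) args$old <- do.call(group_params,
                                           c(list(group = "old"),
                                             y$old[setdiff(names(y$old), "group")]))
  if (!is.null(y$behavior)) args$behavior <- do.call(behavior_params, y$behavior)
  do.call(pipeline_config, args)
}

#' @keywords internal
.letter_candidates <- function(nodes, items, task_key, rule) {
  if (rule == "task_letter") {
    grep(paste0("^", task_key), nodes, value = TRUE)
  } else {
    initials <- unique(substr(items, 1, 1))
    nodes[substr(nodes, 1, 1) %in% initials]
  }
}

#' @keywords internal
.effects_for_source <- function(pid, nodes, pr, model, flu, epi, par_tr,
                                category_words, letter_rule, source) {
  out <- list()
  for (tk in unique(flu$task)) {
    sub <- flu[flu$task == tk, , drop = FALSE]
    items <- sub$word[order(sub$position)]
    cands <- if (tk == "category") {
      intersect(category_words, nodes)
    } else {
      .letter_candidates(nodes, items, sub$task_key[1], letter_rule)
    }
    task_lab <- if (tk == "category") "fluency_animals" else "fluency_letter"
    eff <- fluency_retrieval_effect(pr, items, cands, participant_id = pid,
                                    task = task_lab, network_source = source)
    out[[length(out) + 1]] <- .effect_row(pid, task_lab, source,
                                          eff$statistic, eff$value,
                                          eff$n_retrieved, eff$n_comparison)
    lag <- fluency_lag_similarity(model, items, max_lag = 3,
                                  participant_id = pid, task = task_lab,
                                  network_source = source)
    for (r in seq_len(nrow(lag))) {
      out[[length(out) + 1]] <- .effect_row(
        pid, task_lab, source, sprintf("lag%d_mean_cosine", lag$lag[r]),
        lag$value[r], lag$n_pairs[r], NA_integer_)
    }
  }
  studied <- unique(epi$word[epi$phase == "studied"])
  recalled <- unique(epi$word[epi$phase == "recalled"])
  prof <- episodic_profile(pr, model, studied, recalled, participant_id = pid,
                           network_source = source)
  for (r in seq_len(nrow(prof))) {
    out[[length(out) + 1]] <- .effect_row(
      pid, "episodic", source,
      sprintf("centrality_%s", prof$status[r]), prof$mean_centrality[r],
      prof$n[r], NA_integer_)
    out[[length(out) + 1]] <- .effect_row(
      pid, "episodic", source,
      sprintf("cosine_to_retrieved_%s", prof$status[r]),
      prof$mean_cosine_to_retrieved[r], prof$n[r], NA_integer_)
  }
  pa <- paired_associate_effect(model, par_tr, participant_id = pid,
                                network_source = source)
  out[[length(out) + 1]] <- .effect_row(pid, "paired_associates", source,
                                        pa$statistic, pa$value,
                                        pa$n_retrieved, pa$n_comparison)
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, network construction (individual, aggregate,
#' common), macroscopic statistics, node measures, behavioural linkage and
#' reliability into one deterministic run. With a fixed config and seed the
#' emitted CSVs are byte-identical across runs.
#'
#' Outputs written to `out_dir`:
#' \describe{
#'   \item{table2.csv}{Per-participant macroscopic statistics of the full and
#'     common networks, with per-group mean rows appended.}
#'   \item{effects.csv}{Every behavioural statistic (fluency
#'     retrieved-vs-nonretrieved centrality, lag-1..3 mean cosine, episodic
#'     status profiles, paired-associate similarity effect) under both the
#'     individual and the aggregate network.}
#'   \item{effects_comparison.csv}{Task-level means under individual vs
#'     aggregate networks and their difference.}
#'   \item{reliability.csv}{Per-participant repeat-encounter consistency and
#'     repeat-association profile, plus the pooled aggregate profile.}
#'   \item{network_correlations.csv}{Cross-network correlation summaries of
#'     PageRank and cosine structure over the shared nodes.}
#'   \item{provenance.json}{Config, seed and session versions.}
#' }
#'
#' @param config A [pipeline_config()] object (or YAML path understood by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with all result data frames and the networks.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("data", {
    if (config$simulate) {
      simulate_cohort(n_per_group = config$n_per_group,
                      n_unique_cues = config$n_unique_cues,
                      n_repeat_cues = config$n_repeat_cues,
                      young = config$young, old = config$old,
                      behavior = config$behavior, letter = config$letter,
                      seed = config$seed)
    } else {
      p <- config$paths
      list(participants = load_participants(p$participants),
           associations = load_associations(p$associations),
           fluency = load_fluency(p$fluency),
           episodic = load_episodic(p$episodic),
           paired = load_paired(p$paired),
           category_words = canonicalize_words(readLines(p$category_list,
                                                         encoding = "UTF-8")))
    }
  })
  participants <- dat$participants
  ids <- participants$participant_id

  nets <- stage("build", {
    by_pid <- split(dat$associations, dat$associations$participant_id)[ids]
    ind <- lapply(ids, function(pid) {
      build_individual_network(by_pid[[pid]],
                               include_repeats = config$include_repeats,
                               group = participants$group[participants$participant_id == pid])
    })
    names(ind) <- ids
    agg <- build_aggregate_network(dat$associations,
                                   include_repeats = config$include_repeats)
    common <- common_subnetworks(ind)
    names(common) <- ids
    list(individual = ind, aggregate = agg, common = common)
  })

  table2 <- stage("stats", {
    full <- do.call(rbind, lapply(nets$individual, macro_stats))
    comm <- do.call(rbind, lapply(nets$common, macro_stats))
    names(comm) <- paste0("common_", names(comm))
    tab <- cbind(
      participant_id = ids,
      age = participants$age,
      group = participants$group,
      full[c("n_nodes", "mean_degree", "clustering", "path_length")],
      comm[c("common_n_nodes", "common_mean_degree", "common_clustering",
             "common_path_length")]
    )
    rownames(tab) <- NULL
    full$group <- participants$group
    gs <- group_summary(full, groups = c("young", "old"))
    mean_rows <- data.frame(
      participant_id = paste0("mean_", gs$group), age = NA_integer_,
      group = gs$group, n_nodes = gs$n_nodes, mean_degree = gs$mean_degree,
      clustering = gs$clustering, path_length = gs$path_length,
      common_n_nodes = NA_real_, common_mean_degree = NA_real_,
      common_clustering = NA_real_, common_path_length = NA_real_,
      stringsAsFactors = FALSE
    )
    rbind(tab, mean_rows)
  })

  shared <- Reduce(intersect, lapply(nets$individual,
                                     function(g) igraph::V(g)$name))

  measures <- stage("measures", {
    behav_words <- unique(c(dat$fluency$word, dat$episodic$word,
                            dat$paired$cue, dat$paired$target,
                            dat$category_words))
    one <- function(net) {
      nodes <- igraph::V(net)$name
      pr <- pagerank(net, damping = config$damping)
      need <- unique(c(intersect(behav_words, nodes),
                       intersect(shared, nodes),
                       .letter_candidates(nodes, character(0), config$letter,
                                          "task_letter")))
      model <- if (length(nodes) <= 2000) {
        walk_similarity(net, alpha = config$alpha,
                        use_ppmi = config$use_ppmi)
      } else {
        walk_similarity(net, alpha = config$alpha, use_ppmi = config$use_ppmi,
                        rows = need)
      }
      list(pr = pr, model = model)
    }
    m <- lapply(nets$individual, one)
    m$aggregate <- one(nets$aggregate)
    m
  })

  effects <- stage("link", {
    rows <- lapply(ids, function(pid) {
      flu <- dat$fluency[dat$fluency$participant_id == pid, , drop = FALSE]
      epi <- dat$episodic[dat$episodic$participant_id == pid, , drop = FALSE]
      par_tr <- dat$paired[dat$paired$participant_id == pid, , drop = FALSE]
      rbind(
        .effects_for_source(pid, igraph::V(nets$individual[[pid]])$name,
                            measures[[pid]]$pr, measures[[pid]]$model,
                            flu, epi, par_tr, dat$category_words,
                            config$letter_rule, "individual"),
        .effects_for_source(pid, igraph::V(nets$aggregate)$name,
                            measures$aggregate$pr, measures$aggregate$model,
                            flu, epi, par_tr, dat$category_words,
                            config$letter_rule, "aggregate")
      )
    })
    do.call(rbind, rows)
  })

  comparison <- stage("compare", {
    keep <- effects$statistic %in% c("centrality_retrieved_minus_nonretrieved",
                                     "cosine_recalled_minus_unrecalled")
    compare_individual_vs_aggregate(
      effects[keep & effects$network_source == "individual", , drop = FALSE],
      effects[keep & effects$network_source == "aggregate", , drop = FALSE])
  })

  reliability <- stage("reliability", {
    rows <- lapply(ids, function(pid) {
      rec <- dat$associations[dat$associations$participant_id == pid, ,
                              drop = FALSE]
      cons <- if (any(rec$is_repeat)) {
        repeated_cue_consistency(rec, direction = config$consistency_direction)
      } else {
        NA_real_
      }
      prof <- repeat_association_profile(rec)
      data.frame(participant_id = pid, repeat_consistency = as.numeric(cons),
                 pct_pairs_repeated = prof$pct_pairs_repeated,
                 max_pair_count = prof$max_pair_count,
                 n_distinct_pairs = prof$n_distinct_pairs,
                 stringsAsFactors = FALSE)
    })
    agg_prof <- repeat_association_profile(dat$associations)
    rows[[length(rows) + 1]] <- data.frame(
      participant_id = "aggregate", repeat_consistency = NA_real_,
      pct_pairs_repeated = agg_prof$pct_pairs_repeated,
      max_pair_count = agg_prof$max_pair_count,
      n_distinct_pairs = agg_prof$n_distinct_pairs, stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })

  netcor <- stage("netcor", {
    pr_meas <- lapply(measures[ids], function(m) m$pr)
    pr_meas$aggregate <- measures$aggregate$pr
    shared_agg <- intersect(shared, igraph::V(nets$aggregate)$name)
    pr_cor <- cross_network_measure_correlation(pr_meas, shared_agg,
                                                type = "vector")
    cos_meas <- lapply(measures[ids], function(m) m$model)
    cos_meas$aggregate <- measures$aggregate$model
    cos_cor <- cross_network_measure_correlation(cos_meas, shared_agg,
                                                 type = "cosine",
                                                 seed = config$seed)
    data.frame(
      measure = c("pagerank", "cosine"),
      mean_individual_aggregate = c(pr_cor$mean_individual_aggregate,
                                    cos_cor$mean_individual_aggregate),
      mean_individual_individual = c(pr_cor$mean_individual_individual,
                                     cos_cor$mean_individual_individual),
      n_shared_nodes = length(shared_agg),
      subsample_se = c(pr_cor$subsample_se, cos_cor$subsample_se),
      stringsAsFactors = FALSE
    )
  })

  stage("write", {
    wr <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                          row.names = FALSE, na = "")
    wr(table2, "table2.csv")
    wr(effects, "effects.csv")
    wr(comparison, "effects_comparison.csv")
    wr(reliability, "reliability.csv")
    wr(netcor, "network_correlations.csv")
    prov <- list(
      config = .config_as_list(config),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("assocnet")),
      r_version = R.version.string
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  })

  invisible(list(table2 = table2, effects = effects, comparison = comparison,
                 reliability = reliability, network_correlations = netcor,
                 networks = nets, measures = measures, data = dat))
}

#' @keywords internal
.config_as_list <- function(config) {
  out <- unclass(config)
  for (f in c("young", "old", "behavior")) out[[f]] <- unclass(out[[f]])
  out
}
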