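#' Default synthetic study configuration
#'
#' A reduced-scale emulation of a large risk-behaviour survey:
#' `n_subjects` subjects
#' in 4 planted clusters; a core of informative binary features with
#' light missingness plus a block of junk features missing 55-97% of
#' their values (removed by curation) and a few duplicated columns
#' (removed by the correlation filter); 8 multi-valued features; and four
#' binary targets whose per-cluster positive probabilities concentrate
#' the positives in overlapping subsets of the planted clusters.
#'
#' @param n_subjects total subjects (default 800).
#' @param seed integer seed.
#' @return a [survey_config()]; the junk/duplicate columns are appended
#'   by [generate_study_table()].
#' @export
default_study_config <- function(n_subjects = 800, seed = 1L) {
  survey_config(
    n_subjects = n_subjects, n_features = 56, n_clusters = 4,
    profile_lo = 0.15, profile_hi = 0.85,
    missing_rates = rep(c(0.02, 0.1, 0.2, 0.3), length.out = 56),
    skip_rate = 0.02, n_multivalued = 8, multivalued_levels = c(3, 3, 4, 4, 3, 3, 4, 3),
    target_specs = list(
      hiv       = c(0.70, 0.45, 0.08, 0.05),
      idu       = c(0.10, 0.65, 0.55, 0.08),
      homeless  = c(0.55, 0.15, 0.70, 0.45),
      insurance = c(0.15, 0.55, 0.10, 0.70)),
    seed = seed)
}

#' Generate the default synthetic study table
#'
#' [generate_survey()] under a [default_study_config()], augmented with
#' 40 junk features missing 55-97% of their values and 4 duplicated
#' columns, so that curation has realistic work to do.
#'
#' @param config a [survey_config()] (default [default_study_config()]).
#' @return a `survey_table`.
#' @export
generate_study_table <- function(config = default_study_config()) {
  tab <- generate_survey(config)
  old <- local_rng(config$seed + 77L)
  on.exit(restore_rng(old))
  n <- length(tab$subject_ids)
  for (j in seq_len(40)) {
    rate <- runif(1, 0.55, 0.97)
    v <- ifelse(runif(n) < 0.5, "yes", "no")
    v[runif(n) < rate] <- ""
    tab$data[[sprintf("junk%02d", j)]] <- v
  }
  # near-duplicates of informative columns (to be caught by the filter)
  for (j in 1:4) {
    src <- tab$data[[sprintf("q%03d", j)]]
    tab$data[[sprintf("dup%02d", j)]] <- src
  }
  tab
}

#' Run the full survey-mining pipeline
#'
#' For each target: curate the table, select feature sets by step-forward
#' AUC search (requested sizes plus the full post-curation pool), subset
#' the positive subjects, infer four graphs per feature set (minimum-k
#' kNN, sparsest-connected MB, glasso and CT), cluster each graph with
#' Louvain, Leiden, and NBR-Clust under VAT and integrity, score every
#' partition with the five validity indices in feature space, rank all
#' candidates jointly per target, and profile the winning clustering
#' (with small-cluster suppression). A stage failure aborts that target
#' only and is recorded.
#'
#' @param table a `survey_table` containing the target columns.
#' @param targets character vector of target feature names.
#' @param feature_sizes sizes for the step-forward search (default
#'   c(15, 20)); the full feature pool is always added.
#' @param seed master seed; per-target seeds are derived from it.
#' @param min_complete_fraction,corr_threshold,blacklist curation
#'   parameters (see [curate_survey()]).
#' @param min_cluster_size suppression threshold for profiles.
#' @param out_dir optional directory: when given, all intermediates
#'   (curation report, feature sets, GraphML graphs, partition CSVs,
#'   score CSV, rank JSON, profile CSV) are written beneath it.
#' @return object of class `psn_pipeline`: list with `per_target`
#'   (winner id, rank result, scorecards, winner partition + graph +
#'   profiles, feature sets, errors), `curation`, `seed`.
#' @export
run_pipeline <- function(table, targets, feature_sizes = c(15, 20), seed = 1L,
                         min_complete_fraction = 0.6, corr_threshold = 0.8,
                         blacklist = character(0), min_cluster_size = 10,
                         out_dir = NULL) {
  stopifnot(inherits(table, "survey_table"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  curation <- curate_survey(table, min_complete_fraction, corr_threshold,
                            blacklist = blacklist, protect = targets)
  if (!is.null(out_dir))
    write_curation_report(curation, file.path(out_dir, "curation_report.json"))
  X_all <- curation$matrix
  missing_targets <- setdiff(targets, colnames(X_all))
  if (length(missing_targets))
    stop("targets not present after curation: ",
         paste(missing_targets, collapse = ", "))
  feature_pool <- setdiff(colnames(X_all), targets)

  per_target <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    tseed <- (as.integer(seed) + 1009L * ti) %% 2147483647L
    res <- tryCatch(
      run_one_target(X_all, tg, feature_pool, feature_sizes, tseed,
                     min_cluster_size, out_dir),
      error = function(e) list(error = conditionMessage(e)))
    per_target[[tg]] <- res
  }
  structure(list(per_target = per_target, curation = curation,
                 targets = targets, seed = seed),
            class = "psn_pipeline")
}

run_one_target <- function(X_all, tg, feature_pool, feature_sizes, tseed,
                           min_cluster_size, out_dir) {
  y <- X_all[, tg]
  Xf <- X_all[, feature_pool, drop = FALSE]
  sizes <- sort(unique(c(feature_sizes[feature_sizes < length(feature_pool)],
                         length(feature_pool))))
  fsets <- step_forward_select(Xf, y, sizes, seed = tseed, target_name = tg)
  X_pos <- subset_positive(cbind(Xf, X_all[, tg, drop = FALSE]), tg)

  scorecards <- NULL
  partitions <- list()
  graphs <- list()
  skipped <- character(0)
  for (fs in fsets) {
    Xs <- X_pos[, fs$ordered_features, drop = FALSE]
    gset <- list(
      knn = min_k_connected(Xs),
      mb = sparsest_connected(Xs, "mb"),
      glasso = sparsest_connected(Xs, "glasso"),
      ct = sparsest_connected(Xs, "ct"))
    for (gm in names(gset)) {
      g <- gset[[gm]]
      graphs[[paste(gm, fs$size, sep = "_")]] <- g
      for (cm in c("louvain", "leiden", "nbr_vat", "nbr_integrity")) {
        id <- paste(gm, cm, fs$size, sep = "_")
        part <- tryCatch(cluster_graph(g, cm, seed = tseed),
                         error = function(e) NULL)
        if (is.null(part)) { skipped <- c(skipped, id); next }
        k <- part$n_clusters
        if (k < 2 || k > length(part$labels) - 1) { skipped <- c(skipped, id); next }
        row <- tryCatch(suppressWarnings(score_clustering(Xs, part, id)),
                        error = function(e) NULL)
        if (is.null(row) || anyNA(row[-1]) ||
            any(!is.finite(as.numeric(row[-1])))) {
          skipped <- c(skipped, id); next
        }
        partitions[[id]] <- part
        scorecards <- rbind(scorecards, row)
      }
    }
  }
  if (is.null(scorecards) || nrow(scorecards) < 2)
    stop("fewer than 2 scorable clusterings for target ", tg)
  ranking <- rank_clusterings(scorecards)
  win_id <- ranking$winner
  win_size <- sub(".*_", "", win_id)
  win_graph_id <- paste(sub("_.*", "", win_id), win_size, sep = "_")
  win_part <- partitions[[win_id]]
  X_win <- X_pos[, fsets[[win_size]]$ordered_features, drop = FALSE]
  profiles <- profile_clusters(X_win, win_part, min_size = min_cluster_size)

  if (!is.null(out_dir)) {
    tdir <- file.path(out_dir, tg)
    dir.create(tdir, showWarnings = FALSE)
    for (s in names(fsets))
      write_feature_set(fsets[[s]], file.path(tdir, paste0("features_", s, ".json")))
    for (gid in names(graphs))
      export_annotated_graph(
        graphs[[gid]],
        setNames(rep(0L, nrow(X_pos)), rownames(X_pos)),
        file.path(tdir, paste0("graph_", gid, ".graphml")))
    for (pid in names(partitions))
      write_partition(partitions[[pid]], file.path(tdir, paste0("partition_", pid, ".csv")))
    write.csv(scorecards, file.path(tdir, "scores.csv"), row.names = FALSE)
    jsonlite::write_json(list(winner = win_id, points = as.list(ranking$points),
                              tiebreak_log = ranking$tiebreak_log),
                         file.path(tdir, "rank.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    write_profiles_csv(profiles, file.path(tdir, "winner_profiles.csv"))
    export_annotated_graph(graphs[[win_graph_id]], win_part,
                           file.path(tdir, "winner_graph.graphml"))
  }
  list(target = tg, winner = win_id, ranking = ranking,
       scorecards = scorecards, winner_partition = win_part,
       winner_graph = graphs[[win_graph_id]], profiles = profiles,
       feature_sets = fsets, n_positive = nrow(X_pos), skipped = skipped,
       seed = tseed)
}

#' @export
print.psn_pipeline <- function(x, ...) {
  cat("psn_pipeline over", length(x$targets), "target(s), seed", x$seed, "\n")
  for (tg in names(x$per_target)) {
    r <- x$per_target[[tg]]
    if (!is.null(r$error)) {
      cat(sprintf("  %-12s FAILED: %s\n", tg, r$error))
    } else {
      cat(sprintf("  %-12s n+=%d winner=%s (%d clusters, %d suppressed)\n",
                  tg, r$n_positive, r$winner, r$winner_partition$n_clusters,
                  sum(r$profiles$suppressed)))
    }
  }
  invisible(x)
}

#' @export
summary.psn_pipeline <- function(object, ...) {
  for (tg in names(object$per_target)) {
    r <- object$per_target[[tg]]
    cat("==", tg, "==\n")
    if (!is.null(r$error)) { cat("  error:", r$error, "\n"); next }
    cat("  positives:", r$n_positive, "\n")
    print(r$ranking)
    print(r$profiles)
  }
  invisible(object)
}
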