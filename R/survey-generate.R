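#' Configuration for the synthetic survey generator
#'
#' Describes a subjects-by-features survey with planted subject clusters.
#' Each cluster has its own Bernoulli response profile over the binary
#' features, its own categorical distribution for each multi-valued
#' feature, and its own positive-probability for each binary target
#' variable, so every downstream stage (curation, feature selection,
#' graph inference, clustering) has recoverable ground truth.
#'
#' @param n_subjects total number of subjects.
#' @param n_features number of binary (yes/no) survey features.
#' @param n_clusters number of planted subject clusters.
#' @param cluster_sizes integer vector summing to `n_subjects`; defaults to
#'   an (almost) equal split.
#' @param cluster_profiles `n_clusters` x `n_features` matrix of
#'   probabilities of a "yes" response; defaults to profiles drawn once
#'   from \{`profile_lo`, `profile_hi`\} using `seed`.
#' @param profile_lo,profile_hi the two response probabilities used when
#'   `cluster_profiles` is auto-generated.
#' @param missing_rates per-feature probability in \[0,1) that a cell is
#'   recorded as missing (empty token); recycled to `n_features`.
#' @param skip_rate probability that an observed cell is recorded as
#'   "skipped" rather than yes/no (skipped cells count as observed for the
#'   missingness filter, and are mapped to "no" during curation).
#' @param n_multivalued number of additional categorical features with
#'   3-10 levels; their per-cluster level distributions are generated from
#'   `seed`.
#' @param multivalued_levels number of levels for each multi-valued
#'   feature; recycled to `n_multivalued`.
#' @param target_specs named list; each element is a length-`n_clusters`
#'   vector of per-cluster probabilities that the target is positive.
#' @param seed integer; fully determines the generated table.
#' @return an object of class `survey_config`.
#' @export
survey_config <- function(n_subjects, n_features, n_clusters,
                          cluster_sizes = NULL, cluster_profiles = NULL,
                          profile_lo = 0.15, profile_hi = 0.85,
                          missing_rates = 0, skip_rate = 0.02,
                          n_multivalued = 0, multivalued_levels = 3,
                          target_specs = list(), seed = 1L) {
  if (n_subjects < 1 || n_features < 1 || n_clusters < 1)
    stop("n_subjects, n_features and n_clusters must be positive")
  if (is.null(cluster_sizes)) {
    cluster_sizes <- rep(n_subjects %/% n_clusters, n_clusters)
    rem <- n_subjects - sum(cluster_sizes)
    if (rem > 0) cluster_sizes[seq_len(rem)] <- cluster_sizes[seq_len(rem)] + 1L
  }
  if (any(cluster_sizes < 1)) stop("all cluster sizes must be positive")
  if (sum(cluster_sizes) != n_subjects)
    stop("cluster sizes must sum to n_subjects")
  missing_rates <- rep_len(missing_rates, n_features)
  if (any(missing_rates < 0 | missing_rates >= 1))
    stop("missing_rates must lie in [0, 1)")
  if (skip_rate < 0 || skip_rate >= 1) stop("skip_rate must lie in [0, 1)")
  if (is.null(cluster_profiles)) {
    rng <- local_rng(seed + 1000L)
    cluster_profiles <- matrix(
      sample(c(profile_lo, profile_hi), n_clusters * n_features, replace = TRUE),
      nrow = n_clusters)
    restore_rng(rng)
  }
  cluster_profiles <- as.matrix(cluster_profiles)
  if (!all(dim(cluster_profiles) == c(n_clusters, n_features)))
    stop("cluster_profiles must be n_clusters x n_features")
  if (any(cluster_profiles < 0 | cluster_profiles > 1))
    stop("cluster_profiles must lie in [0, 1]")
  for (nm in names(target_specs)) {
    p <- target_specs[[nm]]
    if (length(p) != n_clusters || any(p < 0 | p > 1))
      stop("target_specs[['", nm, "']] must be ", n_clusters,
           " probabilities in [0, 1]")
  }
  n_multivalued <- as.integer(n_multivalued)
  multivalued_levels <- rep_len(as.integer(multivalued_levels),
                                max(n_multivalued, 1L))[seq_len(max(n_multivalued, 0L))]
  if (n_multivalued > 0 && any(multivalued_levels < 3 | multivalued_levels > 10))
    stop("multi-valued features must have 3 to 10 levels")
  structure(list(
    n_subjects = as.integer(n_subjects), n_features = as.integer(n_features),
    n_clusters = as.integer(n_clusters), cluster_sizes = as.integer(cluster_sizes),
    cluster_profiles = cluster_profiles, missing_rates = missing_rates,
    skip_rate = skip_rate, n_multivalued = n_multivalued,
    multivalued_levels = multivalued_levels,
    target_specs = target_specs, seed = as.integer(seed)),
    class = "survey_config")
}

# Run code under a temporary RNG state; callers pair with restore_rng().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Generate a synthetic survey table with planted subject clusters
#'
#' Draws a subjects-by-features table of categorical survey responses from
#' a [survey_config()]. Binary features take values "yes"/"no" with a
#' small "skipped" contamination; missingness is applied independently per
#' cell (missing completely at random) as the empty token `""`.
#' Multi-valued features are drawn from per-cluster categorical
#' distributions so that one-hot encoding retains cluster signal. Target
#' variables are complete yes/no columns drawn per-cluster Bernoulli.
#'
#' @param config a [survey_config()].
#' @return an object of class `survey_table`: a list with `data` (a
#'   character data.frame, subjects in rows), `subject_ids`,
#'   `ground_truth` (named integer vector of planted cluster labels,
#'   starting at 1), `multivalued` and `targets` (column-name vectors).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  old <- local_rng(config$seed)
  on.exit(restore_rng(old))
  n <- config$n_subjects
  labels <- rep(seq_len(config$n_clusters), times = config$cluster_sizes)
  ids <- sprintf("S%04d", seq_len(n))
  cols <- list()

  for (f in seq_len(config$n_features)) {
    p <- config$cluster_profiles[labels, f]
    v <- ifelse(runif(n) < p, "yes", "no")
    sk <- runif(n) < config$skip_rate
    v[sk] <- "skipped"
    miss <- runif(n) < config$missing_rates[f]
    v[miss] <- ""
    cols[[sprintf("q%03d", f)]] <- v
  }

  multivalued <- character(0)
  if (config$n_multivalued > 0) {
    for (m in seq_len(config$n_multivalued)) {
      L <- config$multivalued_levels[m]
      lv <- paste0("level", seq_len(L))
      # one categorical distribution per cluster, concentrated on a
      # cluster-specific preferred level
      probs <- matrix(0.5 / (L - 1), config$n_clusters, L)
      pref <- sample.int(L, config$n_clusters, replace = TRUE)
      probs[cbind(seq_len(config$n_clusters), pref)] <- 0.5
      v <- vapply(seq_len(n), function(i)
        sample(lv, 1L, prob = probs[labels[i], ]), character(1))
      nm <- sprintf("cat%02d", m)
      multivalued <- c(multivalued, nm)
      cols[[nm]] <- v
    }
  }

  targets <- names(config$target_specs)
  for (nm in targets) {
    p <- config$target_specs[[nm]][labels]
    cols[[nm]] <- ifelse(runif(n) < p, "yes", "no")
  }

  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  rownames(df) <- ids
  structure(list(data = df, subject_ids = ids,
                 ground_truth = setNames(labels, ids),
                 multivalued = multivalued, targets = targets),
            class = "survey_table")
}

#' @export
print.survey_table <- function(x, ...) {
  cat("survey_table:", length(x$subject_ids), "subjects x",
      ncol(x$data), "features\n")
  if (length(x$targets)) cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  if (!is.null(x$ground_truth))
    cat("  planted clusters:", length(unique(x$ground_truth)), "\n")
  invisible(x)
}

#' Write / read a survey table as CSV
#'
#' One row per subject, a leading `subject_id` column, then one column per
#' feature with literal tokens `yes`/`no`/`skipped` and `""` for missing.
#' Ground-truth labels, when present, are written alongside as
#' `<path>.labels.csv` with columns `subject_id,cluster`.
#'
#' @param table a `survey_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(table, path) {
  stopifnot(inherits(table, "survey_table"))
  out <- cbind(subject_id = table$subject_ids, table$data)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  if (!is.null(table$ground_truth)) {
    lab <- data.frame(subject_id = names(table$ground_truth),
                      cluster = unname(table$ground_truth))
    write.csv(lab, paste0(path, ".labels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_survey_csv
#' @param targets,multivalued optional column-name vectors restored on read.
#' @export
read_survey_csv <- function(path, targets = character(0),
                            multivalued = character(0)) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                 check.names = FALSE)
  ids <- df$subject_id
  df <- df[, setdiff(names(df), "subject_id"), drop = FALSE]
  df[is.na(df)] <- ""
  rownames(df) <- ids
  gt <- NULL
  labp <- paste0(path, ".labels.csv")
  if (file.exists(labp)) {
    lab <- read.csv(labp, stringsAsFactors = FALSE)
    gt <- setNames(as.integer(lab$cluster), lab$subject_id)[ids]
  }
  structure(list(data = df, subject_ids = ids, ground_truth = gt,
                 multivalued = multivalued, targets = targets),
            class = "survey_table")
}
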