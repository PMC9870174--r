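MISSING_TOKEN <- ""

is_missing_tok <- function(v) is.na(v) | v == MISSING_TOKEN

#' Drop features with too much missing data
#'
#' Retains exactly the features whose fraction of non-missing cells is at
#' least `min_complete_fraction` (default 0.6, i.e. features missing 40%
#' or more of their values are removed). "skipped" counts as observed.
#'
#' @param table a `survey_table`.
#' @param min_complete_fraction required non-missing fraction in (0, 1].
#' @return the pruned `survey_table`, with a `dropped_sparse` attribute
#'   naming the removed features.
#' @export
drop_sparse_features <- function(table, min_complete_fraction = 0.6) {
  stopifnot(inherits(table, "survey_table"))
  if (min_complete_fraction <= 0 || min_complete_fraction > 1)
    stop("min_complete_fraction must lie in (0, 1]")
  frac <- vapply(table$data, function(v) mean(!is_missing_tok(v)), numeric(1))
  keep <- frac >= min_complete_fraction
  if (!any(keep)) stop("all features dropped by the missingness filter")
  dropped <- names(table$data)[!keep]
  table$data <- table$data[, keep, drop = FALSE]
  table$multivalued <- intersect(table$multivalued, names(table$data))
  table$targets <- intersect(table$targets, names(table$data))
  attr(table, "dropped_sparse") <- dropped
  table
}

#' One-hot encode multi-valued features
#'
#' Each categorical feature with three or more observed levels (or any
#' feature listed in `table$multivalued`) is replaced by one binary
#' yes/no column per observed level, named `"<feature>: <level>"`.
#' Binary yes/no/skipped columns pass through unchanged. A missing source
#' value stays missing in every derived column; otherwise exactly one
#' derived column per source feature is "yes". Single-level columns pass
#' through as constants and are recorded in the `onehot_log` attribute.
#'
#' @param table a `survey_table`.
#' @return the expanded `survey_table` with a `provenance` attribute
#'   mapping derived columns to (source feature, level).
#' @export
one_hot_encode <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  binary_tokens <- c("yes", "no", "skipped")
  out <- list()
  prov <- list()
  log <- character(0)
  for (nm in names(table$data)) {
    v <- table$data[[nm]]
    obs <- unique(v[!is_missing_tok(v)])
    categorical <- nm %in% table$multivalued || length(setdiff(obs, binary_tokens)) > 0
    if (!categorical) {
      out[[nm]] <- v
      next
    }
    if (length(obs) < 2) {
      out[[nm]] <- v
      log <- c(log, paste0(nm, ": single observed level, passed through"))
      next
    }
    for (lv in sort(obs)) {
      col <- ifelse(is_missing_tok(v), MISSING_TOKEN, ifelse(v == lv, "yes", "no"))
      cn <- paste0(nm, ": ", lv)
      out[[cn]] <- col
      prov[[cn]] <- c(source = nm, level = lv)
    }
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE, optional = TRUE)
  rownames(df) <- table$subject_ids
  table$data <- df
  table$multivalued <- character(0)
  attr(table, "provenance") <- prov
  attr(table, "onehot_log") <- log
  table
}

#' Convert skipped and other non-yes answers to "no"
#'
#' Maps every binary survey column to 0/1: "yes" becomes 1 and every
#' other token (no, skipped, residual missing) becomes 0, completing the
#' matrix.
#'
#' @param table a `survey_table` whose columns are binary
#'   (yes/no/skipped/missing) after one-hot encoding.
#' @return a numeric subjects x features matrix with entries in \{0, 1\},
#'   rownames = subject ids.
#' @export
skipped_to_no <- function(table) {
  stopifnot(inherits(table, "survey_table"))
  m <- vapply(table$data, function(v) as.numeric(v == "yes"), numeric(nrow(table$data)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(table$data))
  dimnames(m) <- list(table$subject_ids, names(table$data))
  m
}

#' Prune highly correlated features
#'
#' Greedily removes features until no retained pair has absolute Pearson
#' correlation (on the 0/1 encoding this is the phi coefficient) above
#' `threshold`. At each step the offending feature with the larger mean
#' absolute correlation to all other retained features is dropped (ties
#' broken by dropping the lexicographically later name). Zero-variance
#' features are excluded from the correlation computation and retained,
#' with a warning.
#'
#' @param matrix numeric subjects x features matrix.
#' @param threshold correlation threshold in (0, 1); default 0.8.
#' @param protect feature names that are never dropped (e.g. target
#'   variables).
#' @return the filtered matrix, with attribute `dropped_correlated`: a
#'   data.frame of (feature, partner, correlation) for each removal.
#' @export
correlation_filter <- function(matrix, threshold = 0.8, protect = character(0)) {
  if (ncol(matrix) < 2) stop("correlation filter needs at least 2 features")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  sds <- apply(matrix, 2, sd)
  zerovar <- colnames(matrix)[sds == 0]
  if (length(zerovar))
    warning("zero-variance features retained, excluded from correlation: ",
            paste(zerovar, collapse = ", "))
  active <- setdiff(colnames(matrix), zerovar)
  dropped <- data.frame(feature = character(0), partner = character(0),
                        correlation = numeric(0))
  if (length(active) >= 2) {
    cm <- abs(cor(matrix[, active, drop = FALSE]))
    diag(cm) <- 0
    repeat {
      mx <- max(cm)
      if (mx <= threshold) break
      idx <- which(cm == mx, arr.ind = TRUE)[1, ]
      a <- rownames(cm)[idx[1]]; b <- colnames(cm)[idx[2]]
      cand <- setdiff(c(a, b), protect)
      if (length(cand) == 0) { # both protected; cannot resolve this pair
        cm[a, b] <- cm[b, a] <- 0
        next
      }
      if (length(cand) == 2) {
        ma <- mean(cm[a, ]); mb <- mean(cm[b, ])
        drop_f <- if (ma > mb) a else if (mb > ma) b else max(a, b)
      } else drop_f <- cand
      partner <- setdiff(c(a, b), drop_f)
      dropped <- rbind(dropped, data.frame(feature = drop_f, partner = partner,
                                           correlation = mx))
      keep <- setdiff(rownames(cm), drop_f)
      cm <- cm[keep, keep, drop = FALSE]
      if (length(keep) < 2) break
    }
    active <- rownames(cm)
  }
  keep_cols <- colnames(matrix)[colnames(matrix) %in% c(active, zerovar)]
  out <- matrix[, keep_cols, drop = FALSE]
  attr(out, "dropped_correlated") <- dropped
  out
}

#' Curate a raw survey table into a complete binary feature matrix
#'
#' Runs the full curation chain: blacklist removal, missingness pruning
#' ([drop_sparse_features()]), one-hot encoding of multi-valued features
#' ([one_hot_encode()]), mapping of skipped/other answers to "no"
#' ([skipped_to_no()]), and the pairwise correlation filter
#' ([correlation_filter()]).
#'
#' @param table a `survey_table`.
#' @param min_complete_fraction see [drop_sparse_features()].
#' @param corr_threshold see [correlation_filter()].
#' @param blacklist metadata-like columns removed up front.
#' @param protect columns never dropped by the correlation filter
#'   (defaults to the table's target columns).
#' @return object of class `survey_curation`: list with `matrix` (the
#'   complete 0/1 feature matrix), `report` (dropped features and
#'   reasons), `ground_truth` and `targets` carried over from the table.
#' @export
curate_survey <- function(table, min_complete_fraction = 0.6,
                          corr_threshold = 0.8, blacklist = character(0),
                          protect = table$targets) {
  stopifnot(inherits(table, "survey_table"))
  table$data <- table$data[, setdiff(names(table$data), blacklist), drop = FALSE]
  t1 <- drop_sparse_features(table, min_complete_fraction)
  t2 <- one_hot_encode(t1)
  m <- skipped_to_no(t2)
  stopifnot(all(m %in% c(0, 1)), !anyNA(m))
  mf <- correlation_filter(m, corr_threshold, protect = protect)
  report <- list(
    blacklisted = blacklist,
    dropped_sparse = attr(t1, "dropped_sparse"),
    onehot_log = attr(t2, "onehot_log"),
    provenance = attr(t2, "provenance"),
    dropped_correlated = attr(mf, "dropped_correlated"))
  structure(list(matrix = mf, report = report,
                 ground_truth = table$ground_truth,
                 targets = intersect(table$targets, colnames(mf))),
            class = "survey_curation")
}

#' @export
print.survey_curation <- function(x, ...) {
  cat("survey_curation:", nrow(x$matrix), "subjects x", ncol(x$matrix),
      "binary features\n")
  cat("  dropped sparse:", length(x$report$dropped_sparse),
      "| dropped correlated:", nrow(x$report$dropped_correlated), "\n")
  invisible(x)
}

#' Write the curation report as JSON
#'
#' @param curation a `survey_curation`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(curation, path) {
  stopifnot(inherits(curation, "survey_curation"))
  jsonlite::write_json(curation$report, path, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Wrap a 0/1 matrix back into a survey table
#'
#' Utility for re-running the curation chain on its own output (0 maps to
#' "no", 1 to "yes"); used to check that curation is idempotent.
#'
#' @param matrix numeric 0/1 subjects x features matrix with rownames.
#' @param targets optional target column names.
#' @return a `survey_table`.
#' @export
as_survey_table <- function(matrix, targets = character(0)) {
  df <- as.data.frame(ifelse(matrix == 1, "yes", "no"),
                      stringsAsFactors = FALSE, optional = TRUE)
  rownames(df) <- rownames(matrix)
  structure(list(data = df, subject_ids = rownames(matrix),
                 ground_truth = NULL, multivalued = character(0),
                 targets = targets),
            class = "survey_table")
}
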