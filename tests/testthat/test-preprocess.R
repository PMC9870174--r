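make_table <- function(cols, multivalued = character(0), targets = character(0)) {
  df <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  ids <- sprintf("S%03d", seq_len(nrow(df)))
  rownames(df) <- ids
  structure(list(data = df, subject_ids = ids, ground_truth = NULL,
                 multivalued = multivalued, targets = targets),
            class = "survey_table")
}

test_that("missingness filter retains exactly the sufficiently complete features", {
  set.seed(1)
  n <- 100
  miss <- c(0, 0.1, 0.25, 0.39, 0.41, 0.5, 0.7, 0.9, 0.99, 0.3)
  cols <- lapply(seq_along(miss), function(i) {
    v <- rep("yes", n)
    v[seq_len(round(miss[i] * n))] <- ""
    v
  })
  names(cols) <- sprintf("f%02d", seq_along(miss))
  tab <- make_table(cols)
  out <- drop_sparse_features(tab, 0.6)
  kept_oracle <- names(cols)[sapply(cols, function(v) mean(v != "") >= 0.6)]
  expect_identical(names(out$data), kept_oracle)
  expect_true("f01" %in% names(out$data))   # complete feature retained
  expect_false("f09" %in% names(out$data))  # 99% missing dropped
  expect_equal(nrow(out$data), n)
  all_missing <- make_table(list(a = rep("", 5)))
  expect_error(drop_sparse_features(all_missing, 0.6), "dropped")
})

test_that("one-hot encoding expands categorical features and keeps binary ones", {
  tab <- make_table(list(
    age = c("18-30", "31-45", "46+", "31-45", ""),
    smoke = c("yes", "no", "skipped", "yes", "no")))
  out <- one_hot_encode(tab)
  expect_setequal(names(out$data),
                  c("age: 18-30", "age: 31-45", "age: 46+", "smoke"))
  # exactly one derived column is yes per observed source value
  derived <- out$data[, startsWith(names(out$data), "age")]
  observed <- tab$data$age != ""
  expect_true(all(rowSums(derived[observed, ] == "yes") == 1))
  expect_true(all(derived[!observed, ] == ""))
  expect_identical(out$data$smoke, tab$data$smoke)
})

test_that("one-hot output size equals the sum of level counts plus pass-throughs", {
  set.seed(7)
  n <- 60
  levels_per <- c(3, 3, 4, 5, 3, 4, 2, 6, 3, 4, 3, 3)  # 12 multi-valued
  cols <- list()
  for (i in seq_along(levels_per))
    cols[[sprintf("mv%02d", i)]] <-
      sample(paste0("l", seq_len(levels_per[i])), n, replace = TRUE)
  for (i in 1:36)
    cols[[sprintf("bin%02d", i)]] <- sample(c("yes", "no"), n, replace = TRUE)
  tab <- make_table(cols, multivalued = sprintf("mv%02d", seq_along(levels_per)))
  out <- one_hot_encode(tab)
  expect_equal(ncol(out$data), sum(levels_per) + 36)
})

test_that("every non-yes token maps to 0", {
  tab <- make_table(list(q = c("yes", "no", "skipped", "")))
  m <- skipped_to_no(tab)
  expect_equal(unname(m[, "q"]), c(1, 0, 0, 0))
  expect_true(all(m %in% c(0, 1)))
})

test_that("correlation filter removes one of each highly correlated pair", {
  set.seed(3)
  x <- matrix(rbinom(400, 1, 0.5), 100, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  x <- cbind(x, a_copy = x[, "a"])  # r = 1 with a
  out <- correlation_filter(x, 0.8)
  expect_equal(ncol(out), 4)
  expect_true(xor("a" %in% colnames(out), "a_copy" %in% colnames(out)))
  cm <- abs(cor(out))
  diag(cm) <- 0
  expect_lte(max(cm), 0.8)
})

test_that("a single engineered 0.9 correlation removes exactly one feature", {
  set.seed(11)
  n <- 2000
  f1 <- rbinom(n, 1, 0.5)
  f2 <- ifelse(runif(n) < 0.95, f1, 1 - f1)  # |r| ~ 0.9
  x <- cbind(f1 = f1, f2 = f2,
             f3 = rbinom(n, 1, 0.5), f4 = rbinom(n, 1, 0.4),
             f5 = rbinom(n, 1, 0.6))
  stopifnot(abs(cor(f1, f2)) > 0.85)
  out <- correlation_filter(x, 0.8)
  expect_equal(ncol(out), 4)
  dropped <- attr(out, "dropped_correlated")
  expect_equal(nrow(dropped), 1)
  expect_true(dropped$feature %in% c("f1", "f2"))
  expect_true(dropped$partner %in% c("f1", "f2"))
  cm <- abs(cor(out)); diag(cm) <- 0
  expect_lte(max(cm), 0.8)
})

test_that("zero-variance features are retained with a warning", {
  x <- cbind(a = c(1, 1, 1, 1), b = c(0, 1, 0, 1), c = c(1, 0, 1, 0))
  expect_warning(out <- correlation_filter(x, 0.8), "zero-variance")
  expect_true("a" %in% colnames(out))
})

test_that("protected columns survive the correlation filter", {
  set.seed(5)
  t_col <- rbinom(500, 1, 0.5)
  near <- ifelse(runif(500) < 0.97, t_col, 1 - t_col)
  x <- cbind(hiv = t_col, proxy = near, other = rbinom(500, 1, 0.5))
  out <- correlation_filter(x, 0.8, protect = "hiv")
  expect_true("hiv" %in% colnames(out))
  expect_false("proxy" %in% colnames(out))
})

test_that("curation is idempotent and yields a complete binary matrix", {
  cfg <- survey_config(150, 20, 3, n_multivalued = 3,
                       missing_rates = rep(c(0.05, 0.5), 10), skip_rate = 0.05,
                       seed = 21)
  tab <- generate_survey(cfg)
  cur <- curate_survey(tab)
  m <- cur$matrix
  expect_true(all(m %in% c(0, 1)))
  expect_false(anyNA(m))
  again <- curate_survey(as_survey_table(m))
  expect_equal(dim(again$matrix), dim(m))
  expect_equal(unname(again$matrix), unname(m))
})
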