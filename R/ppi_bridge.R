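# Downstream validation by protein-protein interaction (PPI) score
# regression: interacting proteins tend to co-aggregate on heating and thus
# show similar melting curves (thermal proximity co-aggregation), so a
# decision tree fed pair features built from two proteins' melting profiles
# can regress interaction confidence scores.  Translated panels are judged
# by whether they support this regression as well as measured panels do.

#' Validate a table of PPI records
#'
#' @param records A data frame with columns `protein_a`, `protein_b`,
#'   `score` (scores in `[0, 1]`, no self pairs, unordered pairs unique).
#' @return The records as a tibble.
#' @export
ppi_records <- function(records) {
  req <- c("protein_a", "protein_b", "score")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort_cycletsa("PPI records need columns protein_a, protein_b, score.",
                   "cycletsa_format_error")
  }
  records <- tibble::as_tibble(records[req])
  if (any(records$protein_a == records$protein_b)) {
    abort_cycletsa("Self pairs (protein_a == protein_b) are not allowed.",
                   "cycletsa_integrity_error")
  }
  if (!is.numeric(records$score) || any(!is.finite(records$score)) ||
      any(records$score < 0 | records$score > 1)) {
    abort_cycletsa("PPI scores must be finite values in [0, 1].",
                   "cycletsa_integrity_error")
  }
  key <- paste(pmin(records$protein_a, records$protein_b),
               pmax(records$protein_a, records$protein_b))
  if (anyDuplicated(key)) {
    abort_cycletsa("Duplicate unordered protein pairs in PPI records.",
                   "cycletsa_integrity_error")
  }
  records
}

#' Build symmetric pair features from a melting panel
#'
#' For each retained record the feature vector concatenates the two
#' profiles in lexicographic order (so swapping the pair changes nothing),
#' the per-temperature absolute differences, and the Euclidean distance
#' between the curves: 2w + w + 1 values for a w-temperature grid (31 for
#' the default ten-point grid).  Records referencing a protein absent from
#' the panel are dropped and counted.
#'
#' @param panel A `cetsa_panel`.
#' @param records PPI records (see [ppi_records()]).
#' @return A list: `features` (matrix), `records` (retained rows),
#'   `n_dropped`.
#' @export
build_pair_features <- function(panel, records) {
  stopifnot(inherits(panel, "cetsa_panel"))
  records <- ppi_records(records)
  acc <- panel_accessions(panel)
  keep <- records$protein_a %in% acc & records$protein_b %in% acc
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    abort_cycletsa("No PPI record has both proteins in the panel.",
                   "cycletsa_data_error")
  }
  w <- ncol(panel$values)
  feats <- matrix(NA_real_, nrow = nrow(records), ncol = 3L * w + 1L)
  for (r in seq_len(nrow(records))) {
    u <- panel$values[records$protein_a[r], ]
    v <- panel$values[records$protein_b[r], ]
    if (vec_less(v, u)) { tmp <- u; u <- v; v <- tmp }
    d <- abs(u - v)
    feats[r, ] <- c(u, v, d, sqrt(sum(d^2)))
  }
  labels <- grid_labels(panel$grid)
  colnames(feats) <- c(paste0("lo_", labels), paste0("hi_", labels),
                       paste0("absdiff_", labels), "euclid_dist")
  list(features = feats, records = records, n_dropped = n_dropped)
}

#' Cross-validation fold assignment
#'
#' @param n Number of samples.
#' @param folds Number of folds (default 5, i.e. a 4:1 train:test ratio per
#'   fold).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`.
#' @export
cv_folds <- function(n, folds = 5L, seed = 1L) {
  if (!is_count(folds, min = 2L)) {
    abort_cycletsa("`folds` must be an integer >= 2.",
                   "cycletsa_argument_error")
  }
  if (n < folds) {
    abort_cycletsa(sprintf("Need at least %d samples for %d folds.", folds,
                           folds),
                   "cycletsa_data_error")
  }
  withr::with_seed(check_seed(seed), sample(rep(seq_len(folds),
                                                length.out = n)))
}

tree_control <- function(min_leaf = 1L, maxdepth = 30L) {
  rpart::rpart.control(minsplit = 2L * min_leaf, minbucket = min_leaf,
                       cp = 0, maxdepth = maxdepth, xval = 0L)
}

#' Decision-tree PPI score regression under k-fold cross-validation
#'
#' Fits a fully grown regression tree on each training fold and predicts
#' the held-out fold, so every sample receives exactly one out-of-fold
#' prediction; the pooled MAE summarises performance.  Deterministic given
#' the fold assignment.
#'
#' @param features Numeric feature matrix.
#' @param scores PPI scores in `[0, 1]`.
#' @param folds Number of folds, or an integer vector of precomputed fold
#'   ids (one per sample).
#' @param seed Seed for the fold assignment (ignored when `folds` is a
#'   vector).
#' @param min_leaf Minimum samples per leaf (default 1: fully grown).
#' @param maxdepth Maximum tree depth.
#' @return A list: `predictions` (out-of-fold), `fold` (assignment), `mae`.
#' @export
cv_tree_regression <- function(features, scores, folds = 5L, seed = 1L,
                               min_leaf = 1L, maxdepth = 30L) {
  features <- as.matrix(features)
  if (nrow(features) != length(scores)) {
    abort_cycletsa("`features` rows and `scores` length differ.",
                   "cycletsa_shape_error")
  }
  fold <- if (length(folds) == 1L) {
    cv_folds(length(scores), folds, seed)
  } else {
    if (length(folds) != length(scores)) {
      abort_cycletsa("Fold vector length must match the sample count.",
                     "cycletsa_argument_error")
    }
    as.integer(folds)
  }
  df <- data.frame(score = scores, features)
  preds <- rep(NA_real_, length(scores))
  for (k in sort(unique(fold))) {
    fit <- rpart::rpart(score ~ ., data = df[fold != k, , drop = FALSE],
                        method = "anova",
                        control = tree_control(min_leaf, maxdepth))
    preds[fold == k] <- stats::predict(fit, df[fold == k, , drop = FALSE])
  }
  list(predictions = preds, fold = fold, mae = mae(scores, preds))
}

score_histogram <- function(x, breaks) {
  graphics_free <- table(cut(clip01(x), breaks = breaks,
                             include.lowest = TRUE))
  as.integer(graphics_free)
}

#' Compare experimental and translated panels as PPI feature sources
#'
#' Builds pair features from both panels for the same records, applies
#' identical cross-validation folds to both, and reports both out-of-fold
#' MAEs, their difference, and binned histograms of the ground-truth and
#' predicted score distributions.
#'
#' @param panel_experimental,panel_translated Two `cetsa_panel` objects
#'   covering the same proteins (e.g. the measured panel and its
#'   model-translated counterpart).
#' @param records PPI records; rows whose proteins are missing from either
#'   panel are dropped.
#' @param folds,seed,min_leaf,maxdepth Passed to [cv_tree_regression()].
#' @param bins Number of equal-width score histogram bins on `[0, 1]`.
#' @return A list: `mae` (tibble with one row per source plus the absolute
#'   difference as an attribute is avoided -- the difference is its own
#'   column), `histogram` (tibble of bin edges and counts), `fold`,
#'   `n_records`.
#' @export
compare_feature_sources <- function(panel_experimental, panel_translated,
                                    records, folds = 5L, seed = 1L,
                                    min_leaf = 1L, maxdepth = 30L,
                                    bins = 10L) {
  fe <- build_pair_features(panel_experimental, records)
  # restrict to records available in both panels, in identical order
  ft <- build_pair_features(panel_translated, fe$records)
  fe <- build_pair_features(panel_experimental, ft$records)
  scores <- fe$records$score
  fold <- cv_folds(length(scores), folds, seed)
  cv_exp <- cv_tree_regression(fe$features, scores, folds = fold,
                               min_leaf = min_leaf, maxdepth = maxdepth)
  cv_tr <- cv_tree_regression(ft$features, scores, folds = fold,
                              min_leaf = min_leaf, maxdepth = maxdepth)
  breaks <- seq(0, 1, length.out = bins + 1L)
  histogram <- tibble::tibble(
    bin_left = breaks[-length(breaks)], bin_right = breaks[-1L],
    count_truth = score_histogram(scores, breaks),
    count_pred_experimental = score_histogram(cv_exp$predictions, breaks),
    count_pred_translated = score_histogram(cv_tr$predictions, breaks))
  mae_tbl <- tibble::tibble(
    source = c("experimental", "translated"),
    mae = c(cv_exp$mae, cv_tr$mae),
    mae_difference = abs(cv_exp$mae - cv_tr$mae),
    n = length(scores))
  list(mae = mae_tbl, histogram = histogram, fold = fold,
       n_records = length(scores),
       predictions = tibble::tibble(score = scores,
                                    experimental = cv_exp$predictions,
                                    translated = cv_tr$predictions))
}

#' Simulate PPI scores driven by melting-curve similarity
#'
#' Emulates thermal proximity co-aggregation: random protein pairs receive
#' an interaction score that decays with the Euclidean distance between
#' their melting profiles (scaled by the median pair distance), plus
#' truncated Gaussian noise.
#'
#' @param panel A `cetsa_panel`.
#' @param n_pairs Number of distinct unordered pairs to draw.
#' @param noise_sd Additive noise sd on the score scale.
#' @param seed Integer seed.
#' @return A PPI record tibble (`protein_a`, `protein_b`, `score`).
#' @export
simulate_ppi_scores <- function(panel, n_pairs = 1000L, noise_sd = 0.05,
                                seed = 1L) {
  stopifnot(inherits(panel, "cetsa_panel"))
  acc <- panel_accessions(panel)
  max_pairs <- choose(length(acc), 2)
  if (n_pairs > max_pairs) {
    abort_cycletsa(sprintf("Only %d distinct pairs available.", max_pairs),
                   "cycletsa_argument_error")
  }
  withr::with_seed(check_seed(seed), {
    picked <- sample(max_pairs, n_pairs)
    # map linear indices to (i < j) pairs
    ij <- t(vapply(picked, function(p) {
      i <- 1L
      while (p > length(acc) - i) {
        p <- p - (length(acc) - i)
        i <- i + 1L
      }
      c(i, i + p)
    }, integer(2)))
    d <- sqrt(rowSums((panel$values[ij[, 1L], , drop = FALSE] -
                         panel$values[ij[, 2L], , drop = FALSE])^2))
    tau <- stats::median(d)
    if (tau == 0) tau <- 1
    score <- clip01(exp(-(d / tau)^2) + stats::rnorm(n_pairs, 0, noise_sd))
    tibble::tibble(protein_a = acc[ij[, 1L]], protein_b = acc[ij[, 2L]],
                   score = score)
  })
}
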