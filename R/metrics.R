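# Regression evaluation metrics and the all-pairs transfer report.
#
# Note the MAPE convention: the default keeps the squared numerator,
# 100/n * sum(|(y - y')^2 / y|), which is how the quantity is defined for
# this model family; `mode = "conventional"` gives the textbook
# 100/n * sum(|y - y'| / |y|).

check_lengths <- function(y, y_pred) {
  if (!is.numeric(y) || !is.numeric(y_pred) || length(y) != length(y_pred) ||
      length(y) < 1L) {
    abort_cycletsa("`y` and `y_pred` must be numeric vectors of equal length >= 1.",
                   "cycletsa_shape_error")
  }
}

#' Mean squared error
#' @param y True values.
#' @param y_pred Predicted values.
#' @return Mean of squared residuals.
#' @export
mse <- function(y, y_pred) {
  check_lengths(y, y_pred)
  mean((y - y_pred)^2)
}

#' Mean absolute error
#' @inheritParams mse
#' @return Mean of absolute residuals.
#' @export
mae <- function(y, y_pred) {
  check_lengths(y, y_pred)
  mean(abs(y - y_pred))
}

#' Mean absolute percentage error
#'
#' @inheritParams mse
#' @param mode `"squared"` (default; squared numerator, see above) or
#'   `"conventional"`.
#' @param zero_action What to do when a true value is exactly zero:
#'   `"error"` (default) or `"drop"` (exclude those elements, used when
#'   pooling clipped synthetic data).
#' @return Percentage error (already multiplied by 100).
#' @export
mape <- function(y, y_pred, mode = c("squared", "conventional"),
                 zero_action = c("error", "drop")) {
  mode <- match.arg(mode)
  zero_action <- match.arg(zero_action)
  check_lengths(y, y_pred)
  zero <- y == 0
  if (any(zero)) {
    if (zero_action == "error") {
      abort_cycletsa(
        sprintf("True value is zero at index %d; MAPE is undefined there.",
                which(zero)[1L]),
        "cycletsa_division_error")
    }
    y_pred <- y_pred[!zero]
    y <- y[!zero]
    if (length(y) == 0L) {
      abort_cycletsa("All true values are zero; MAPE is undefined.",
                     "cycletsa_division_error")
    }
  }
  num <- switch(mode, squared = (y - y_pred)^2, conventional = abs(y - y_pred))
  100 * mean(abs(num / y))
}

#' Coefficient of determination
#'
#' `1 - sum((y - y')^2) / sum((y - mean(y))^2)`.
#'
#' @inheritParams mse
#' @return R-squared (at most 1; can be negative).
#' @export
r2 <- function(y, y_pred) {
  check_lengths(y, y_pred)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    abort_cycletsa("`y` has zero variance; R-squared is undefined.",
                   "cycletsa_degenerate_input_error")
  }
  1 - sum((y - y_pred)^2) / tss
}

#' Pearson correlation coefficient
#' @inheritParams mse
#' @return Correlation in `[-1, 1]`.
#' @export
pcc <- function(y, y_pred) {
  check_lengths(y, y_pred)
  if (stats::sd(y) == 0 || stats::sd(y_pred) == 0) {
    abort_cycletsa("Zero variance input; correlation is undefined.",
                   "cycletsa_degenerate_input_error")
  }
  stats::cor(y, y_pred)
}

#' All five metrics for one prediction
#'
#' @inheritParams mape
#' @return A one-row tibble with `mse`, `mape_pct`, `mae`, `r2`, `pcc`, `n`.
#' @export
metric_report <- function(y, y_pred, mode = "squared",
                          zero_action = "error") {
  tibble::tibble(mse = mse(y, y_pred),
                 mape_pct = mape(y, y_pred, mode, zero_action),
                 mae = mae(y, y_pred),
                 r2 = r2(y, y_pred),
                 pcc = pcc(y, y_pred),
                 n = length(y))
}

#' Evaluate a bundle over every ordered cell-line pair
#'
#' For each ordered pair (source, target), the source cell line's held-out
#' profiles are translated to the target's feature space and compared with
#' the target's measured profiles, with residuals pooled over all proteins
#' and temperatures (`aggregation = "per_protein"` instead averages
#' per-curve metrics).
#'
#' @param bundle A trained `cycle_bundle`.
#' @param multipanel A `cetsa_multipanel` covering the bundle's cell lines.
#' @param part Split part to evaluate (default `"test"`; `NULL` for all
#'   common proteins).
#' @param mape_mode MAPE convention, see [mape()].
#' @param aggregation `"pooled"` (default) or `"per_protein"`.
#' @return A tibble with one row per ordered pair: `transfer` (e.g.
#'   `"A->B"`), `source`, `target`, `mse`, `mape_pct`, `mae`, `r2`, `pcc`,
#'   `n`.
#' @export
evaluate_transfer <- function(bundle, multipanel, part = "test",
                              mape_mode = "squared",
                              aggregation = c("pooled", "per_protein")) {
  stopifnot(inherits(bundle, "cycle_bundle"),
            inherits(multipanel, "cetsa_multipanel"))
  aggregation <- match.arg(aggregation)
  if (!setequal(bundle$cell_lines, multipanel$cell_lines)) {
    abort_cycletsa("Bundle and multipanel cell lines differ.",
                   "cycletsa_configuration_error")
  }
  acc <- if (is.null(part)) multipanel$common_index
         else split_accessions(multipanel, part)
  cls <- bundle$cell_lines
  rows <- list()
  for (src in cls) {
    X <- panel_matrix(multipanel, src, acc)
    for (tgt in cls) {
      truth <- panel_matrix(multipanel, tgt, acc)
      pred <- translate(bundle, src, tgt, X)
      rep_row <- if (aggregation == "pooled") {
        metric_report(as.vector(truth), as.vector(pred),
                      mode = mape_mode, zero_action = "drop")
      } else {
        per <- lapply(seq_len(nrow(truth)), function(r) {
          metric_report(truth[r, ], pred[r, ], mode = mape_mode,
                        zero_action = "drop")
        })
        per <- do.call(rbind, per)
        tibble::tibble(mse = mean(per$mse), mape_pct = mean(per$mape_pct),
                       mae = mean(per$mae), r2 = mean(per$r2),
                       pcc = mean(per$pcc), n = nrow(truth))
      }
      rows[[length(rows) + 1L]] <-
        tibble::tibble(transfer = paste0(src, "->", tgt),
                       source = src, target = tgt, rep_row)
    }
  }
  do.call(rbind, rows)
}
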