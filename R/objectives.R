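# Training objective: three loss components combined with fixed coefficients.
#
# For cell lines i, j in 1..n with feature batches C_i (aligned by protein)
# and translation maps F(i,j) = decoder_j o encoder_i:
#   prediction loss   L1 = sum_{i,j} MSE(F(i,j)(C_i), C_j) / n
#   cycle loss        L2 = sum_{i,j} MSE(F(j,i)(F(i,j)(C_i)), C_i) / n
#   latent loss       L3 = sum_{k} sum_{i} MSE(Z_i, Z_k) / n^2
#   total             L  = alpha1 L1 + alpha2 L2 + alpha3 L3
# Both double sums run over all ordered pairs including i = j, and MSE is the
# per-element mean over the batch-by-feature block.  The 1/n normalisation of
# L1 and L2 is deliberate (n^2 pair terms divided by n); `normalization =
# "n2"` rescales to a per-pair mean, which only rescales alpha1 and alpha2.

#' Loss component weights
#'
#' @param alpha1,alpha2,alpha3 Non-negative weights of the prediction,
#'   cycle-consistency and latent-regularization losses; defaults 1, 0.01, 1.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha1 = 1, alpha2 = 0.01, alpha3 = 1) {
  for (a in list(alpha1, alpha2, alpha3)) {
    if (!is_number(a) || a < 0) {
      abort_cycletsa("Loss weights must be non-negative numbers.",
                     "cycletsa_argument_error")
    }
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3),
            class = "loss_weights")
}

mean_sq <- function(a, b) {
  if (!identical(dim(as.matrix(a)), dim(as.matrix(b)))) {
    abort_cycletsa("Mismatched shapes in MSE.", "cycletsa_shape_error")
  }
  mean((a - b)^2)
}

check_pair_coverage <- function(pairwise, n, what) {
  ok <- is.list(pairwise) && length(pairwise) == n &&
    all(vapply(pairwise, function(row) is.list(row) && length(row) == n,
               logical(1)))
  if (!ok) {
    abort_cycletsa(
      sprintf("`%s` must cover all %d x %d ordered cell-line pairs.", what,
              n, n),
      "cycletsa_coverage_error")
  }
}

loss_norm <- function(n, normalization) {
  switch(normalization, n = n, n2 = n^2)
}

#' Prediction loss over all ordered cell-line pairs
#'
#' @param true_panels List of n feature batches C_i (matrices aligned by
#'   protein).
#' @param translated Nested list: `translated[[i]][[j]]` is F(i,j)(C_i),
#'   covering all ordered pairs including i = j.
#' @param normalization `"n"` (default, as defined above) or `"n2"`.
#' @return The scalar prediction loss.
#' @export
prediction_loss <- function(true_panels, translated,
                            normalization = c("n", "n2")) {
  normalization <- match.arg(normalization)
  n <- length(true_panels)
  check_pair_coverage(translated, n, "translated")
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + mean_sq(translated[[i]][[j]], true_panels[[j]])
    }
  }
  total / loss_norm(n, normalization)
}

#' Cycle-consistency loss over all ordered cell-line pairs
#'
#' @param true_panels List of n feature batches C_i.
#' @param reconstructed Nested list: `reconstructed[[i]][[j]]` is
#'   F(j,i)(F(i,j)(C_i)).
#' @inheritParams prediction_loss
#' @return The scalar cycle-consistency loss.
#' @export
cycle_loss <- function(true_panels, reconstructed,
                       normalization = c("n", "n2")) {
  normalization <- match.arg(normalization)
  n <- length(true_panels)
  check_pair_coverage(reconstructed, n, "reconstructed")
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      total <- total + mean_sq(reconstructed[[i]][[j]], true_panels[[i]])
    }
  }
  total / loss_norm(n, normalization)
}

#' Latent-space regularization loss
#'
#' Mean squared difference between the latent batches of every ordered pair
#' of cell lines (including the zero diagonal), divided by n^2.
#'
#' @param latents List of n latent matrices Z_i of identical shape, aligned
#'   by protein.
#' @return The scalar latent regularization loss.
#' @export
latent_loss <- function(latents) {
  n <- length(latents)
  total <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      total <- total + mean_sq(latents[[i]], latents[[k]])
    }
  }
  total / n^2
}

#' Combine loss components into the weighted total
#'
#' @param l1,l2,l3 Finite loss components.
#' @param weights A [loss_weights()].
#' @param n_cell_lines,batch_size Optional bookkeeping counts carried in the
#'   breakdown.
#' @return A `loss_breakdown` with fields `l1`, `l2`, `l3`, `total`.
#' @export
total_loss <- function(l1, l2, l3, weights = loss_weights(),
                       n_cell_lines = NA_integer_, batch_size = NA_integer_) {
  stopifnot(inherits(weights, "loss_weights"))
  for (l in list(l1, l2, l3)) {
    if (!is_number(l)) {
      abort_cycletsa("Loss components must be finite numbers.",
                     "cycletsa_argument_error")
    }
  }
  structure(list(l1 = l1, l2 = l2, l3 = l3,
                 total = weights$alpha1 * l1 + weights$alpha2 * l2 +
                   weights$alpha3 * l3,
                 n_cell_lines = n_cell_lines, batch_size = batch_size),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.6g (l1 %.6g, l2 %.6g, l3 %.6g)\n",
              x$total, x$l1, x$l2, x$l3))
  invisible(x)
}
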