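# Independent brute-force oracle: per-element double loops over ordered
# cell-line pairs, written without reusing the package's vectorised code.
oracle_mse <- function(a, b) {
  s <- 0
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) {
    s <- s + (a[r, c] - b[r, c])^2
  }
  s / (nrow(a) * ncol(a))
}
oracle_l1 <- function(truth, translated, norm_n) {
  n <- length(truth); s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + oracle_mse(translated[[i]][[j]], truth[[j]])
  s / norm_n
}
oracle_l2 <- function(truth, reconstructed, norm_n) {
  n <- length(truth); s <- 0
  for (i in 1:n) for (j in 1:n) s <- s + oracle_mse(reconstructed[[i]][[j]], truth[[i]])
  s / norm_n
}
oracle_l3 <- function(latents) {
  n <- length(latents); s <- 0
  for (k in 1:n) for (i in 1:n) s <- s + oracle_mse(latents[[i]], latents[[k]])
  s / n^2
}

test_that("hand-computed loss examples reproduce exactly", {
  # n = 2, one protein, scalar features
  truth <- list(matrix(1), matrix(2))
  translated <- list(list(matrix(1.1), matrix(2.5)),
                     list(matrix(0.5), matrix(2.2)))
  expect_equal(prediction_loss(truth, translated),
               (0.01 + 0.25 + 0.25 + 0.04) / 2)
  expect_equal(prediction_loss(truth, translated), 0.275)

  # perfect translations give zero
  perfect <- list(list(matrix(1), matrix(2)), list(matrix(1), matrix(2)))
  expect_equal(prediction_loss(truth, perfect), 0)

  # n = 1: plain autoencoder reconstruction error
  expect_equal(prediction_loss(list(matrix(c(1, 2))),
                               list(list(matrix(c(1.1, 2.3))))),
               mean(c(0.01, 0.09)))

  # cycle loss: n = 1, residual 0.1 on one protein
  expect_equal(cycle_loss(list(matrix(1)), list(list(matrix(1.1)))), 0.01,
               tolerance = 1e-12)

  # latent loss: Z1 = 0, Z2 = 2 -> (0 + 4 + 4 + 0) / 4 = 2
  expect_equal(latent_loss(list(matrix(0), matrix(2))), 2)
  expect_equal(latent_loss(list(matrix(5), matrix(5))), 0)

  # weighted total with the default coefficients (1, 0.01, 1)
  bd <- total_loss(0.275, 0.01, 2)
  expect_equal(bd$total, 2.2751)
  expect_equal(total_loss(0, 0, 0)$total, 0)
  expect_equal(total_loss(0.4, 9, 7, loss_weights(1, 0, 0))$total, 0.4)
})

test_that("losses match the brute-force oracle on random inputs", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      n <- sample(1:4, 1)
      b <- sample(1:8, 1)
      d <- sample(1:5, 1)
      truth <- lapply(1:n, function(i) matrix(rnorm(b * d), b, d))
      translated <- lapply(1:n, function(i) {
        lapply(1:n, function(j) matrix(rnorm(b * d), b, d))
      })
      latents <- lapply(1:n, function(i) matrix(rnorm(b * 3), b, 3))
      expect_equal(prediction_loss(truth, translated),
                   oracle_l1(truth, translated, n), tolerance = 1e-10)
      expect_equal(prediction_loss(truth, translated, normalization = "n2"),
                   oracle_l1(truth, translated, n^2), tolerance = 1e-10)
      expect_equal(cycle_loss(truth, translated),
                   oracle_l2(truth, translated, n), tolerance = 1e-10)
      expect_equal(latent_loss(latents), oracle_l3(latents),
                   tolerance = 1e-10)
    }
  })
})

test_that("losses are permutation-invariant and symmetric as required", {
  withr::with_seed(33, {
    truth <- lapply(1:3, function(i) matrix(rnorm(12), 4, 3))
    rec <- lapply(1:3, function(i) lapply(1:3, function(j) matrix(rnorm(12), 4, 3)))
    perm <- sample(4)
    truth_p <- lapply(truth, function(m) m[perm, , drop = FALSE])
    rec_p <- lapply(rec, function(row) {
      lapply(row, function(m) m[perm, , drop = FALSE])
    })
    expect_equal(cycle_loss(truth, rec), cycle_loss(truth_p, rec_p))

    latents <- lapply(1:3, function(i) matrix(rnorm(8), 4, 2))
    expect_equal(latent_loss(latents), latent_loss(rev(latents)))
  })
})

test_that("loss coverage and shape errors are raised", {
  truth <- list(matrix(1), matrix(2))
  expect_error(prediction_loss(truth, list(list(matrix(1)))),
               class = "cycletsa_coverage_error")
  expect_error(cycle_loss(truth, list(list(matrix(1)), list(matrix(1)))),
               class = "cycletsa_coverage_error")
  expect_error(latent_loss(list(matrix(0, 2, 2), matrix(0, 3, 2))),
               class = "cycletsa_shape_error")
})

test_that("analytic gradients match finite differences on a tiny bundle", {
  b <- tiny_bundle(n = 2, seed = 3)
  Xl <- withr::with_seed(9, list(matrix(runif(8 * 4), 8),
                                 matrix(runif(8 * 4), 8)))
  w <- loss_weights()
  pass <- cycletsa:::cycle_pass(b, Xl, w, "n", training = FALSE,
                                with_grads = TRUE)
  loss_of <- function(bb) {
    cycletsa:::cycle_pass(bb, Xl, w, "n", FALSE, FALSE)$breakdown$total
  }
  eps <- 1e-6
  withr::with_seed(17, {
    for (mod in c("encoders", "decoders")) {
      for (i in 1:2) {
        for (l in seq_along(b[[mod]][[i]])) {
          analytic <- if (mod == "encoders") pass$g_enc[[i]][[l]]
                      else pass$g_dec[[i]][[l]]
          for (trial in 1:3) {
            r <- sample(length(b[[mod]][[i]][[l]]$W), 1)
            up <- b; up[[mod]][[i]][[l]]$W[r] <- up[[mod]][[i]][[l]]$W[r] + eps
            dn <- b; dn[[mod]][[i]][[l]]$W[r] <- dn[[mod]][[i]][[l]]$W[r] - eps
            fd <- (loss_of(up) - loss_of(dn)) / (2 * eps)
            expect_equal(analytic$W[r], fd, tolerance = 1e-4)
          }
          # one bias entry per layer too
          r <- sample(length(b[[mod]][[i]][[l]]$b), 1)
          up <- b; up[[mod]][[i]][[l]]$b[r] <- up[[mod]][[i]][[l]]$b[r] + eps
          dn <- b; dn[[mod]][[i]][[l]]$b[r] <- dn[[mod]][[i]][[l]]$b[r] - eps
          fd <- (loss_of(up) - loss_of(dn)) / (2 * eps)
          expect_equal(analytic$b[r], fd, tolerance = 1e-4)
        }
      }
    }
  })
})
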