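test_that("parameter counts match hand enumeration and brute force", {
  # toy spec 2 -> 3 -> 1 with bias: (2*3+3) + (3*1+1) = 13
  toy <- cycletsa:::new_layer_stack(list(layer_spec(2, 3), layer_spec(3, 1)),
                                    "encoder")
  expect_equal(count_parameters(toy, include_bias = TRUE), 13)
  expect_equal(count_parameters(toy, include_bias = FALSE), 9)

  # property: count equals enumeration of every stored weight entry
  withr::with_seed(11, {
    for (rep in 1:50) {
      dims <- sample(1:7, sample(2:4, 1) + 1, replace = TRUE)
      spec <- cycletsa:::new_layer_stack(
        lapply(seq_len(length(dims) - 1), function(i) {
          layer_spec(dims[i], dims[i + 1])
        }), "encoder")
      params <- cycletsa:::init_stack(spec)
      n_all <- length(unlist(params))
      n_w <- sum(vapply(params, function(l) length(l$W), numeric(1)))
      expect_equal(count_parameters(spec, include_bias = TRUE), n_all)
      expect_equal(count_parameters(spec, include_bias = FALSE), n_w)
    }
  })
})

test_that("default architecture reproduces the published accounting", {
  expect_identical(count_parameters(encoder_spec(), include_bias = TRUE),
                   2761000)
  expect_identical(count_parameters(decoder_spec(), include_bias = FALSE),
                   2755000)
  expect_identical(count_flops(encoder_spec(), flops_per_mac = 2), 5510000)
  # the decoder figure follows the other convention: 1 FLOP/MAC + bias adds
  expect_identical(count_flops(decoder_spec(), flops_per_mac = 1,
                               include_bias_adds = TRUE), 2756010)
  # algebraic identity: 1 FLOP/MAC without bias adds equals the weight count
  expect_identical(count_flops(encoder_spec(), 1),
                   count_parameters(encoder_spec(), include_bias = FALSE))
  toy <- cycletsa:::new_layer_stack(list(layer_spec(2, 3)), "encoder")
  expect_identical(count_flops(toy, 2), 12)
})

test_that("cyclic scheme halves and quarters the pairwise module budget", {
  mc <- scheme_module_counts(5)
  expect_equal(mc$cyclic, 10)     # n encoders + n decoders
  expect_equal(mc$pairwise, 40)   # n(n-1) of each
  expect_equal(mc$reduction_pct, 75)
  expect_equal(scheme_module_counts(3)$reduction_pct, 50)
})

test_that("bundles are seeded, distinct per cell line, and shape-checked", {
  b1 <- tiny_bundle(n = 3, seed = 5)
  b2 <- tiny_bundle(n = 3, seed = 5)
  expect_identical(b1$encoders, b2$encoders)
  expect_identical(b1$decoders, b2$decoders)
  b3 <- tiny_bundle(n = 3, seed = 6)
  expect_false(identical(b1$encoders, b3$encoders))
  # same architecture, different parameters across cell lines
  expect_false(identical(b1$encoders[[1]], b1$encoders[[2]]))

  expect_length(b1$encoders, 3)
  expect_length(b1$decoders, 3)

  # n = 1 degenerates to a plain autoencoder
  solo <- build_bundle("A", encoder_spec(4, 3, 5, 0),
                       decoder_spec(5, 3, 4, 0), seed = 1)
  x <- matrix(runif(8), 2, 4)
  expect_equal(translate(solo, "A", "A", x),
               decode(solo, "A", encode(solo, "A", x)))

  # chained dimension mismatch is rejected
  expect_error(build_bundle(c("A", "B"), encoder_spec(4, 3, 5, 0),
                            decoder_spec(6, 3, 4, 0)),
               class = "cycletsa_spec_error")
})

test_that("forward passes are deterministic in evaluation mode and finite", {
  b <- tiny_bundle()
  x <- matrix(runif(12, max = 5), 3, 4)
  z1 <- encode(b, "A", x)
  z2 <- encode(b, "A", x)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(3L, 5L))
  expect_true(all(is.finite(z1)))
  expect_true(all(z1 >= 0))  # latent layer carries ReLU
  y <- decode(b, "B", z1)
  expect_equal(dim(y), c(3L, 4L))
  expect_identical(translate(b, "A", "B", x), decode(b, "B", encode(b, "A", x)))

  # default widths: 10 -> 5000 -> 10
  bd <- build_bundle(c("A", "B"), encoder_spec(), decoder_spec(), seed = 1)
  x10 <- matrix(runif(10), 1, 10)
  z <- encode(bd, "A", x10)
  expect_equal(ncol(z), 5000L)
  expect_equal(ncol(decode(bd, "B", z)), 10L)

  expect_error(encode(b, "A", matrix(0, 2, 3)), class = "cycletsa_shape_error")
  expect_error(encode(b, "Z", x), class = "cycletsa_configuration_error")
})

test_that("zero-parameter bundles map any input to zero", {
  b <- constant_bundle(tiny_bundle())
  x <- matrix(runif(12), 3, 4)
  expect_equal(encode(b, "A", x), matrix(0, 3, 5))
  expect_equal(decode(b, "B", matrix(1, 3, 5)), matrix(0, 3, 4))
})

test_that("training-mode dropout is stochastic, evaluation mode is not", {
  enc <- encoder_spec(4, 8, 5, dropout = 0.5)
  dec <- decoder_spec(5, 8, 4, dropout = 0.5)
  b <- build_bundle("A", enc, dec, seed = 2)
  x <- matrix(runif(20, max = 3), 5, 4)
  set.seed(1)
  t1 <- encode(b, "A", x, training = TRUE)
  t2 <- encode(b, "A", x, training = TRUE)
  expect_false(identical(t1, t2))
  expect_identical(encode(b, "A", x), encode(b, "A", x))
})

test_that("checkpoints round-trip and reject incompatible files", {
  b <- tiny_bundle(n = 2, seed = 7)
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_bundle(b, path)
  b2 <- load_bundle(path)
  x <- matrix(runif(8), 2, 4)
  expect_identical(encode(b, "A", x), encode(b2, "A", x))
  expect_identical(count_parameters(b2$encoder_spec),
                   count_parameters(b$encoder_spec))
  expect_identical(b2$cell_lines, b$cell_lines)
  expect_identical(b2$seed, b$seed)

  saveRDS(list(not = "a checkpoint"), path)
  expect_error(load_bundle(path), class = "cycletsa_checkpoint_error")

  # latent_dim tampering is caught
  payload <- list(schema = 1L, package = "cycletsa", bundle = unclass(b))
  payload$bundle$latent_dim <- 999L
  saveRDS(payload, path)
  expect_error(load_bundle(path), class = "cycletsa_checkpoint_error")
})
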