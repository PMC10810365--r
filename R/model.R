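# Cyclic multi-autoencoder architecture: n encoders map each cell line's
# ten-point melting features into one shared latent space, n decoders map
# latent vectors back to any cell line.  Encoders (and decoders) share an
# architecture but never parameters.  All layers are fully connected; hidden
# layers carry ReLU and (in training mode) inverted dropout; the encoder
# output layer carries ReLU (latents are non-negative) and the decoder output
# layer is affine with no activation, so predicted abundances are unbounded.

#' Fully connected layer specification
#'
#' @param in_dim,out_dim Positive integer dimensions.
#' @param activation `"relu"` or `"none"`.
#' @param dropout Dropout rate in `[0, 1)` applied after the activation in
#'   training mode only.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(in_dim, out_dim, activation = c("relu", "none"),
                       dropout = 0) {
  activation <- match.arg(activation)
  if (!is_count(in_dim) || !is_count(out_dim)) {
    abort_cycletsa("Layer dimensions must be positive integers.",
                   "cycletsa_spec_error")
  }
  if (!is_number(dropout) || dropout < 0 || dropout >= 1) {
    abort_cycletsa("`dropout` must lie in [0, 1).", "cycletsa_spec_error")
  }
  structure(list(in_dim = as.integer(in_dim), out_dim = as.integer(out_dim),
                 activation = activation, dropout = dropout),
            class = "layer_spec")
}

new_layer_stack <- function(layers, role) {
  for (i in seq_along(layers)[-1L]) {
    if (layers[[i]]$in_dim != layers[[i - 1L]]$out_dim) {
      abort_cycletsa(
        sprintf("Layer %d input dim (%d) does not chain with layer %d output dim (%d).",
                i, layers[[i]]$in_dim, i - 1L, layers[[i - 1L]]$out_dim),
        "cycletsa_spec_error")
    }
  }
  structure(layers, class = "layer_stack", role = role)
}

#' Encoder architecture specification
#'
#' Default is the full-scale architecture 10 -> 500 -> 500 -> 5000 with ReLU
#' on every layer and dropout 0.3 after each hidden layer (never after the
#' output layer).
#'
#' @param input_dim Feature width (number of temperatures, default 10).
#' @param hidden Integer vector of hidden-layer widths (default `c(500, 500)`).
#' @param latent_dim Latent width (default 5000).
#' @param dropout Hidden-layer dropout rate (default 0.3).
#' @return A `layer_stack`.
#' @export
encoder_spec <- function(input_dim = 10L, hidden = c(500L, 500L),
                         latent_dim = 5000L, dropout = 0.3) {
  dims <- c(input_dim, hidden, latent_dim)
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    final <- i == length(dims) - 1L
    layer_spec(dims[i], dims[i + 1L], activation = "relu",
               dropout = if (final) 0 else dropout)
  })
  new_layer_stack(layers, role = "encoder")
}

#' Decoder architecture specification
#'
#' Default mirrors the encoder: 5000 -> 500 -> 500 -> 10, ReLU plus dropout
#' on the hidden layers, and an affine output layer with no activation.
#'
#' @param latent_dim Latent width (default 5000).
#' @param hidden Integer vector of hidden-layer widths (default `c(500, 500)`).
#' @param output_dim Feature width (default 10).
#' @param dropout Hidden-layer dropout rate (default 0.3).
#' @return A `layer_stack`.
#' @export
decoder_spec <- function(latent_dim = 5000L, hidden = c(500L, 500L),
                         output_dim = 10L, dropout = 0.3) {
  dims <- c(latent_dim, hidden, output_dim)
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    final <- i == length(dims) - 1L
    layer_spec(dims[i], dims[i + 1L],
               activation = if (final) "none" else "relu",
               dropout = if (final) 0 else dropout)
  })
  new_layer_stack(layers, role = "decoder")
}

stack_input_dim <- function(spec) spec[[1L]]$in_dim
stack_output_dim <- function(spec) spec[[length(spec)]]$out_dim

#' Count trainable parameters of a layer stack
#'
#' @param spec A `layer_stack`.
#' @param include_bias Count bias terms as well as weights.
#' @return Integer parameter count: `sum(in * out)` plus, with biases,
#'   `sum(out)`.
#' @export
#' @examples
#' count_parameters(encoder_spec())                       # 2,761,000
#' count_parameters(decoder_spec(), include_bias = FALSE) # 2,755,000
count_parameters <- function(spec, include_bias = TRUE) {
  stopifnot(inherits(spec, "layer_stack"))
  w <- sum(vapply(spec, function(l) as.numeric(l$in_dim) * l$out_dim,
                  numeric(1)))
  b <- sum(vapply(spec, function(l) as.numeric(l$out_dim), numeric(1)))
  w + if (include_bias) b else 0
}

#' Count forward-pass FLOPs of a layer stack
#'
#' Both common conventions are exposed: `flops_per_mac = 2` counts a
#' multiply-accumulate as two operations; `flops_per_mac = 1` counts it as
#' one (in which case, without bias adds, the count equals the weight count).
#'
#' @param spec A `layer_stack`.
#' @param flops_per_mac 1 or 2.
#' @param include_bias_adds Add one operation per bias term.
#' @return Numeric FLOP count for one sample.
#' @export
#' @examples
#' count_flops(encoder_spec(), flops_per_mac = 2)  # 5,510,000
count_flops <- function(spec, flops_per_mac = 2, include_bias_adds = FALSE) {
  stopifnot(inherits(spec, "layer_stack"))
  if (!flops_per_mac %in% c(1, 2)) {
    abort_cycletsa("`flops_per_mac` must be 1 or 2.", "cycletsa_argument_error")
  }
  macs <- count_parameters(spec, include_bias = FALSE)
  bias <- count_parameters(spec, include_bias = TRUE) - macs
  flops_per_mac * macs + if (include_bias_adds) bias else 0
}

# Fan-in scaled uniform initialization (U(-1/sqrt(fan_in), 1/sqrt(fan_in)))
# drawn from the current RNG stream.
init_stack <- function(spec) {
  lapply(spec, function(l) {
    bound <- 1 / sqrt(l$in_dim)
    list(W = matrix(stats::runif(l$in_dim * l$out_dim, -bound, bound),
                    nrow = l$in_dim, ncol = l$out_dim),
         b = stats::runif(l$out_dim, -bound, bound))
  })
}

#' Build a cyclic autoencoder bundle
#'
#' Creates one encoder and one decoder per cell line, all sharing the given
#' architectures but initialized with distinct parameters drawn
#' deterministically from `seed`.
#'
#' @param cell_lines Character vector of cell-line names (n >= 1; n = 1
#'   degenerates to a plain autoencoder).
#' @param encoder,decoder `layer_stack` specifications; the encoder output
#'   width must equal the decoder input width (the latent dimensionality).
#' @param seed Integer seed for parameter initialization.
#' @return A `cycle_bundle`.
#' @export
build_bundle <- function(cell_lines, encoder = encoder_spec(),
                         decoder = decoder_spec(), seed = 1L) {
  if (!is.character(cell_lines) || length(cell_lines) < 1L ||
      anyDuplicated(cell_lines)) {
    abort_cycletsa("`cell_lines` must be distinct names.",
                   "cycletsa_argument_error")
  }
  if (stack_output_dim(encoder) != stack_input_dim(decoder)) {
    abort_cycletsa(
      sprintf("Encoder output dim (%d) must equal decoder input dim (%d).",
              stack_output_dim(encoder), stack_input_dim(decoder)),
      "cycletsa_spec_error")
  }
  if (stack_input_dim(encoder) != stack_output_dim(decoder)) {
    abort_cycletsa(
      sprintf("Encoder input dim (%d) must equal decoder output dim (%d).",
              stack_input_dim(encoder), stack_output_dim(decoder)),
      "cycletsa_spec_error")
  }
  seed <- check_seed(seed)
  params <- withr::with_seed(seed, {
    list(encoders = lapply(cell_lines, function(cl) init_stack(encoder)),
         decoders = lapply(cell_lines, function(cl) init_stack(decoder)))
  })
  names(params$encoders) <- cell_lines
  names(params$decoders) <- cell_lines
  structure(list(cell_lines = cell_lines,
                 encoder_spec = encoder, decoder_spec = decoder,
                 encoders = params$encoders, decoders = params$decoders,
                 latent_dim = stack_output_dim(encoder), seed = seed),
            class = "cycle_bundle")
}

#' @export
print.cycle_bundle <- function(x, ...) {
  cat(sprintf(
    "<cycle_bundle> %d cell lines (%s): %d encoders + %d decoders, latent dim %d\n",
    length(x$cell_lines), paste(x$cell_lines, collapse = ", "),
    length(x$encoders), length(x$decoders), x$latent_dim))
  cat(sprintf("  encoder: %s params | decoder: %s params (incl. bias)\n",
              format(count_parameters(x$encoder_spec), big.mark = ","),
              format(count_parameters(x$decoder_spec), big.mark = ",")))
  invisible(x)
}

resolve_cell_line <- function(bundle, which) {
  if (is.character(which)) {
    i <- match(which, bundle$cell_lines)
    if (is.na(i)) {
      abort_cycletsa(sprintf("Unknown cell line '%s' (bundle has: %s).",
                             which, paste(bundle$cell_lines, collapse = ", ")),
                     "cycletsa_configuration_error")
    }
    i
  } else {
    if (!is_count(which) || which > length(bundle$cell_lines)) {
      abort_cycletsa("Cell-line index out of range.",
                     "cycletsa_configuration_error")
    }
    as.integer(which)
  }
}

# Forward pass through one layer stack. In training mode, inverted dropout
# masks are drawn from the current RNG stream and kept in the cache for the
# backward pass.
forward_stack <- function(params, spec, X, training = FALSE,
                          keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(spec)) else NULL
  A <- X
  for (l in seq_along(spec)) {
    lay <- spec[[l]]
    S <- A %*% params[[l]]$W
    S <- sweep(S, 2L, params[[l]]$b, "+")
    H <- if (lay$activation == "relu") pmax(S, 0) else S
    mask <- NULL
    if (training && lay$dropout > 0) {
      keep <- 1 - lay$dropout
      mask <- matrix((stats::runif(length(H)) < keep) / keep, nrow = nrow(H))
      H <- H * mask
    }
    if (keep_cache) cache[[l]] <- list(A = A, S = S, mask = mask)
    A <- H
  }
  if (keep_cache) list(out = A, cache = cache) else A
}

# Backward pass; returns the gradient w.r.t. the stack input plus per-layer
# parameter gradients.
backward_stack <- function(params, spec, cache, d_out) {
  grads <- vector("list", length(spec))
  d <- d_out
  for (l in rev(seq_along(spec))) {
    lay <- spec[[l]]
    cc <- cache[[l]]
    if (!is.null(cc$mask)) d <- d * cc$mask
    if (lay$activation == "relu") d <- d * (cc$S > 0)
    grads[[l]] <- list(W = crossprod(cc$A, d), b = colSums(d))
    d <- tcrossprod(d, params[[l]]$W)
  }
  list(d_in = d, grads = grads)
}

check_width <- function(X, expected, what) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != expected) {
    abort_cycletsa(sprintf("%s expects width %d, got %d.", what, expected,
                           ncol(X)),
                   "cycletsa_shape_error")
  }
  X
}

#' Encode a feature batch into the shared latent space
#'
#' @param bundle A `cycle_bundle`.
#' @param source Cell-line name or index whose encoder to use.
#' @param features Numeric matrix, batch x input width.
#' @param training Training mode (dropout active, stochastic); evaluation
#'   mode (default) is deterministic.
#' @return Latent matrix, batch x latent width.
#' @export
encode <- function(bundle, source, features, training = FALSE) {
  stopifnot(inherits(bundle, "cycle_bundle"))
  i <- resolve_cell_line(bundle, source)
  X <- check_width(features, stack_input_dim(bundle$encoder_spec), "encode()")
  forward_stack(bundle$encoders[[i]], bundle$encoder_spec, X,
                training = training)
}

#' Decode latent vectors into one cell line's feature space
#'
#' @param bundle A `cycle_bundle`.
#' @param target Cell-line name or index whose decoder to use.
#' @param latent Numeric matrix, batch x latent width.
#' @param training Training mode (dropout active).
#' @return Feature matrix, batch x output width (unbounded; the output layer
#'   has no activation).
#' @export
decode <- function(bundle, target, latent, training = FALSE) {
  stopifnot(inherits(bundle, "cycle_bundle"))
  j <- resolve_cell_line(bundle, target)
  Z <- check_width(latent, stack_input_dim(bundle$decoder_spec), "decode()")
  forward_stack(bundle$decoders[[j]], bundle$decoder_spec, Z,
                training = training)
}

#' Translate features from one cell line to another
#'
#' The translation map F(i,j) is the composition of encoder i and decoder j;
#' `translate(bundle, i, i, x)` is the i-th autoencoder's reconstruction.
#'
#' @param bundle A `cycle_bundle`.
#' @param source,target Cell-line names or indices.
#' @param features Numeric matrix, batch x input width.
#' @param training Training mode.
#' @return Feature matrix in the target cell line's space.
#' @export
translate <- function(bundle, source, target, features, training = FALSE) {
  decode(bundle, target, encode(bundle, source, features, training = training),
         training = training)
}

#' Module counts of the cyclic vs. pairwise translation schemes
#'
#' The cyclic scheme needs n encoders + n decoders; direct pairwise
#' translation between all ordered cell-line pairs needs n(n-1) of each.
#'
#' @param n_cell_lines Number of cell lines.
#' @return A list with `cyclic` (= 2n), `pairwise` (= 2n(n-1)) and
#'   `reduction_pct`, the percentage of parameters saved when every module
#'   shares one architecture (100 * (1 - cyclic / pairwise)).
#' @export
#' @examples
#' scheme_module_counts(5)$reduction_pct  # 75
scheme_module_counts <- function(n_cell_lines) {
  stopifnot(is_count(n_cell_lines, min = 2L))
  n <- as.numeric(n_cell_lines)
  cyclic <- 2 * n
  pairwise <- 2 * n * (n - 1)
  list(cyclic = cyclic, pairwise = pairwise,
       reduction_pct = 100 * (1 - cyclic / pairwise))
}

CHECKPOINT_SCHEMA <- 1L

#' Save / load a model bundle checkpoint
#'
#' The checkpoint is a single-file container (R serialization) holding a
#' schema version, the architecture description, cell-line names, the init
#' seed and the raw parameter arrays; [load_bundle()] validates the schema
#' and the dimensional consistency of the stored parameters.
#'
#' @param bundle A `cycle_bundle`.
#' @param path Checkpoint file path.
#' @return `save_bundle()` returns `path` invisibly; `load_bundle()` returns
#'   the restored `cycle_bundle`.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "cycle_bundle"))
  payload <- list(schema = CHECKPOINT_SCHEMA, package = "cycletsa",
                  bundle = unclass(bundle))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort_cycletsa(sprintf("Cannot read checkpoint %s: %s", path,
                           conditionMessage(e)), "cycletsa_checkpoint_error")
  })
  if (!is.list(payload) || !identical(payload$package, "cycletsa") ||
      !identical(payload$schema, CHECKPOINT_SCHEMA)) {
    abort_cycletsa(
      sprintf("Not a cycletsa checkpoint (expected schema %d).",
              CHECKPOINT_SCHEMA),
      "cycletsa_checkpoint_error")
  }
  b <- payload$bundle
  for (s in c("encoder_spec", "decoder_spec")) {
    b[[s]] <- new_layer_stack(lapply(b[[s]], function(l) {
      class(l) <- "layer_spec"; l
    }), role = sub("_spec", "", s))
  }
  if (!identical(b$latent_dim, stack_output_dim(b$encoder_spec))) {
    abort_cycletsa("Checkpoint latent_dim does not match its encoder spec.",
                   "cycletsa_checkpoint_error")
  }
  ok <- all(vapply(seq_along(b$cell_lines), function(i) {
    all(vapply(seq_along(b$encoder_spec), function(l) {
      identical(dim(b$encoders[[i]][[l]]$W),
                c(b$encoder_spec[[l]]$in_dim, b$encoder_spec[[l]]$out_dim))
    }, logical(1))) &&
    all(vapply(seq_along(b$decoder_spec), function(l) {
      identical(dim(b$decoders[[i]][[l]]$W),
                c(b$decoder_spec[[l]]$in_dim, b$decoder_spec[[l]]$out_dim))
    }, logical(1)))
  }, logical(1)))
  if (!ok) {
    abort_cycletsa("Checkpoint parameter shapes do not match its specs.",
                   "cycletsa_checkpoint_error")
  }
  structure(b, class = "cycle_bundle")
}
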