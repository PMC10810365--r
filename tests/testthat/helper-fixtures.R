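# Shared fixtures, built in code at test time.

# A tiny panel with hand-written values.
tiny_panel <- function(cell_line = "A", accessions = c("P1", "P2", "P3")) {
  vals <- matrix(seq(0.1, by = 0.01, length.out = length(accessions) * 10),
                 nrow = length(accessions), byrow = TRUE,
                 dimnames = list(accessions, NULL))
  cell_line_panel(cell_line, vals)
}

# Panel with given accession set and deterministic values.
panel_with <- function(cell_line, accessions, seed = 1) {
  vals <- withr::with_seed(seed, matrix(runif(length(accessions) * 10),
                                        nrow = length(accessions),
                                        dimnames = list(accessions, NULL)))
  cell_line_panel(cell_line, vals)
}

# Desk-scale architecture used for trained-model tests.
desk_specs <- function(hidden = c(64L, 64L), latent = 128L, dropout = 0.3) {
  list(enc = encoder_spec(hidden = hidden, latent_dim = latent,
                          dropout = dropout),
       dec = decoder_spec(latent_dim = latent, hidden = hidden,
                          dropout = dropout))
}

# Tiny dropout-free bundle for analytic checks.
tiny_bundle <- function(n = 2, seed = 3) {
  enc <- encoder_spec(input_dim = 4L, hidden = 3L, latent_dim = 5L,
                      dropout = 0)
  dec <- decoder_spec(latent_dim = 5L, hidden = 3L, output_dim = 4L,
                      dropout = 0)
  build_bundle(LETTERS[seq_len(n)], enc, dec, seed = seed)
}

# TRUE if self-prediction MSE is lowest per source in a transfer matrix.
self_dominant <- function(transfer) {
  all(vapply(unique(transfer$source), function(src) {
    self <- transfer$mse[transfer$source == src & transfer$target == src]
    all(self <= transfer$mse[transfer$source == src & transfer$target != src])
  }, logical(1)))
}

# Set every parameter of a bundle to a constant (default zero).
constant_bundle <- function(bundle, value = 0) {
  for (mod in c("encoders", "decoders")) {
    for (i in seq_along(bundle[[mod]])) {
      for (l in seq_along(bundle[[mod]][[i]])) {
        bundle[[mod]][[i]][[l]]$W[] <- value
        bundle[[mod]][[i]][[l]]$b[] <- value
      }
    }
  }
  bundle
}
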