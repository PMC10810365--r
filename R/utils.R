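# Internal helpers shared across modules.

abort_cycletsa <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "cycletsa_error"), ...)
}

`%||%` <- rlang::`%||%`

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == trunc(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_seed <- function(seed) {
  if (!is_count(seed, min = 0L)) {
    abort_cycletsa("`seed` must be a single non-negative integer.",
                   "cycletsa_argument_error")
  }
  as.integer(seed %% .Machine$integer.max)
}

# Deterministic lexicographic sort independent of the session locale.
sort_accessions <- function(x) sort(x, method = "radix")

clip01 <- function(x) pmin(pmax(x, 0), 1)

# TRUE if numeric vector a precedes b lexicographically (strict).
vec_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  if (length(i) == 0L) FALSE else d[i[1L]] < 0
}
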