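#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic counter scheme used everywhere the package needs several
#' independent RNG streams from one user-supplied seed: liquid `k` of an
#' ensemble, weight-trial `k` of an experiment, and so on. `derive_seed(s, 0)`
#' is `s` itself, so a one-liquid ensemble reproduces the single liquid built
#' directly from the master seed.
#'
#' @param seed master seed (integer-like scalar).
#' @param k counter, a non-negative integer (0 returns `seed` unchanged
#'   modulo the 31-bit wrap).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), length(k) == 1L, k >= 0)
  as.integer((as.double(seed) + as.double(k) * 100003) %% 2147483647)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# if seed is NULL, run in the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Polynomial rolling hash (two co-prime moduli) of a character scalar,
# returned as 16 hex digits. Fingerprint only, not cryptographic; avoids a
# digest dependency. Exact in doubles: intermediate products stay < 2^53.
config_fingerprint <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483647
    h2 <- (h2 * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

stop_liquidens <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "liquidens_error")))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}
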