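#' Per-run secrets and randomness source
#'
#' Every pipeline run owns one `run_secrets` object holding the 16-byte
#' secret salt used for pseudonymization and defining where random draws
#' come from. In `"production"` mode the salt is freshly generated from a
#' cryptographically secure source ([openssl::rand_bytes()]), draws are
#' non-seedable, and the salt is never written anywhere — no key list
#' exists, so pseudonym tokens are one-way. In `"test"` mode the caller
#' supplies a seed (and optionally a salt) so that a whole run is
#' bit-reproducible.
#'
#' @param mode `"production"` or `"test"`.
#' @param seed Integer seed; required in test mode, forbidden in
#'   production mode.
#' @param salt Raw vector of exactly 16 bytes; optional in test mode
#'   (defaults to 16 zero bytes), forbidden in production mode.
#' @return A `run_secrets` object.
#' @export
run_secrets <- function(mode = c("production", "test"), seed = NULL, salt = NULL) {
  mode <- match.arg(mode)
  if (mode == "production") {
    if (!is.null(seed) || !is.null(salt))
      stop_swapdata("seed and salt may only be injected in test mode",
                    "swapdata_config_error")
    salt <- openssl::rand_bytes(16L)
  } else {
    if (is.null(seed))
      stop_swapdata("test mode requires a seed", "swapdata_config_error")
    if (is.null(salt)) salt <- as.raw(rep(0L, 16L))
    set.seed(as.integer(seed))
  }
  if (!is.raw(salt) || length(salt) != 16L)
    stop_swapdata("salt must be exactly 16 bytes", "swapdata_config_error")
  structure(list(mode = mode, salt = salt), class = "run_secrets")
}

#' @export
print.run_secrets <- function(x, ...) {
  # The salt is deliberately never printed.
  cat(sprintf("<run_secrets: mode=%s, salt=16 bytes (not shown)>\n", x$mode))
  invisible(x)
}

# Uniform 32-bit integers (as doubles in [0, 2^32)) from the secure source.
rand_uint32 <- function(n) {
  b <- as.integer(openssl::rand_bytes(4L * n))
  dim(b) <- c(4L, n)
  b[1L, ] * 16777216 + b[2L, ] * 65536 + b[3L, ] * 256 + b[4L, ]
}

# n uniform integers in 1..k. Test mode uses the seeded R RNG; production
# mode uses rejection sampling on secure 32-bit words (no modulo bias).
draw_int <- function(secrets, n, k) {
  stopifnot(inherits(secrets, "run_secrets"), k >= 1)
  if (n == 0L) return(integer(0))
  if (secrets$mode == "test") return(sample.int(k, n, replace = TRUE))
  limit <- floor(2^32 / k) * k
  out <- numeric(0)
  while (length(out) < n) {
    u <- rand_uint32(max(n - length(out), 64L))
    out <- c(out, u[u < limit])
  }
  as.integer(out[seq_len(n)] %% k) + 1L
}

# A uniform random permutation of 1..n (Fisher-Yates equivalent: in
# production mode rows are ordered by 64-bit secure uniforms).
rand_perm <- function(secrets, n) {
  if (n <= 1L) return(seq_len(n))
  if (secrets$mode == "test") return(sample.int(n))
  order(rand_uint32(n) * 2^32 + rand_uint32(n))
}

# k distinct indices drawn uniformly from 1..n.
rand_take <- function(secrets, n, k) {
  if (k == 0L) return(integer(0))
  if (secrets$mode == "test") return(sample.int(n, k))
  rand_perm(secrets, n)[seq_len(k)]
}
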