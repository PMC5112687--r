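# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Round half away from zero (display convention for published percentages;
# base round() is half-to-even and gives 50/719 -> 6.9, not 7.0).
round_half_out <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(a, b) 100 * a / b

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL leaves the stream untouched.
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-stream derivation from a master seed: every stochastic
# stage k of a run gets seed derive_seed(master, k), keeping independent
# stages reproducible individually. Kept inside 32-bit integer range.
derive_seed <- function(master, k) {
  as.integer((as.double(master) %% 2147483647 * 48271 + k * 1009) %% 2147483647)
}

stop_rds <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "rds_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Polynomial rolling hash of a character vector, for provenance stamps.
# Not cryptographic; only needs to detect config drift between outputs.
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
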