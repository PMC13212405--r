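# Internal helpers shared across modules.

# Channels a station series always carries, in canonical order.
STATION_CHANNELS <- c("CO", "NO", "NO2", "NOX", "O3", "SO2", "PM",
                      "TEMP", "RH", "WS")

# Derive a child seed from a master seed and an integer tag so that each
# stochastic component owns an independent stream. Kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Evaluate `expr` under `set.seed(seed)` while preserving the caller's RNG
# stream, so seeded primitives have no side effect on surrounding code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Register, in the calling function, restoration of the caller-of-caller's
# RNG state on exit. Lets seeded operations (which set.seed internally)
# leave the surrounding RNG stream untouched.
local_rng <- function(envir = parent.frame()) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  restore <- if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(base::on.exit, list(restore, add = TRUE), envir = envir)
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
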