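# Internal helpers shared across modules.

# Deterministic substream seeds: one master seed, per-unit streams derived by
# counter so that generating a subset of units never shifts the draws of the
# others. Kept below 2^31 - 1 for set.seed().
substream_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) * 16807 + 1) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(master, ..., code) {
  withr::with_seed(substream_seed(master, ...), code)
}

# index assignment (not pmin/pmax) so matrix dims survive
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Run `code` with the global RNG state restored afterwards; `code` may call
# set.seed() freely (cheap per-unit substreams without withr overhead).
with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

stop_params <- function(msg, ...) {
  abort(msg, class = "manipusel_error_params", ...)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop_params(sprintf("`%s` must be a single number in [%s, %s].",
                        name, format(min), format(max)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop_params(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

euclid <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

cheby <- function(x1, y1, x2, y2) pmax(abs(x2 - x1), abs(y2 - y1))
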