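# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All generator functions use this so that each
# one consumes its own stream derived from the master seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic integer mixer (Lehmer steps modulo 2^31 - 1). Used to derive
# keyed sub-seeds, e.g. a subscriber-day key for tie-breaking, so that
# re-running one subscriber never reshuffles another's draws. All products
# stay below 2^53 and are therefore exact in doubles.
mix_key <- function(...) {
  m <- 2147483647
  a <- 48271
  h <- 17
  for (v in list(...)) {
    if (is.character(v)) v <- sum(utf8ToInt(v) * seq_along(utf8ToInt(v)))
    v <- abs(as.numeric(v)) %% m
    h <- (a * ((h + v) %% m)) %% m
    h <- (a * h) %% m
  }
  as.integer(h)
}

# Offsets giving each generator its own stream under a shared master seed.
stream_seed <- function(seed, stream) {
  offsets <- c(districts = 11L, flows = 23L, diaries = 37L, rasters = 53L,
               plan = 71L, national = 89L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  mix_key(seed, offsets[[stream]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}
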