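# Internal helpers shared across modules.

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.  All seeded package entry points go through this.
withSeed <- function(seed, expr) {
  if (length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item sub-seed from a master seed, kept inside 32-bit range.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647)
}

stopIfNot <- function(ok, msg) {
  if (!ok) stop(msg, call. = FALSE)
  invisible(TRUE)
}
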