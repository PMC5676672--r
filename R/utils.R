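## Internal helpers shared across modules.

## Evaluate `code` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so simulation calls never perturb user randomness.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Error with a condition class so callers can distinguish configuration
## problems from numeric failures.
configError <- function(msg) {
  stop(errorCondition(msg, class = c("bioradar_config_error", "error")))
}

stopIfNot <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
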