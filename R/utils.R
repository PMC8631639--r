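# Internal helpers: scoped RNG and shared validation.

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Seed offsets keeping the fabrication / split / CV RNG streams apart while
# derived from one base seed (all results stay < 2^31).
.SEED_SPLIT <- 1000003L
.SEED_CV <- 2000003L

stopIfNotCohort <- function(x, arg = "table") {
  if (!is(x, "CNACohort"))
    stop(sprintf("'%s' must be a CNACohort", arg), call. = FALSE)
  invisible(x)
}

# Mean with an empty-input guard used by correlation summaries.
meanOrNA <- function(x) if (length(x)) mean(x) else NA_real_
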