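`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls do not perturb the
# session RNG stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Configuration errors get their own condition class so the command-line
# wrapper can map them to a distinct exit code.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("tilkill_config_error", "error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# standard error of the mean; NA (not 0/NaN) for n < 2
std_error <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
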