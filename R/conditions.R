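# Structured error conditions.  Three classes, all inheriting retag_error:
#   retag_usage_error  -- caller mistake (bad arguments, unknown column)
#   retag_data_error   -- input data violate an invariant
#   retag_domain_error -- mathematically undefined request (e.g. N = 0)
# The CLI maps usage -> exit 2 and data/domain -> exit 3.

retagStop <- function(msg, class, call = sys.call(-2)) {
  stop(structure(
    class = c(class, "retag_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stopUsage <- function(...) retagStop(paste0(...), "retag_usage_error")

stopData <- function(...) retagStop(paste0(...), "retag_data_error")

stopDomain <- function(...) retagStop(paste0(...), "retag_domain_error")

# Deterministic 32-bit FNV-1a string hash, kept exact in doubles.
# Used to derive per-animal RNG seeds and config fingerprints.
hashString <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` with a private RNG stream seeded from `seed`, restoring
# the caller's RNG state afterwards so simulation never perturbs user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
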