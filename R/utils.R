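# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
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

# Derive a per-stage seed from a single pipeline seed so that adding a stage
# never perturbs another stage's random stream. Offsets are fixed per stage
# name; results stay below 2^31 - 1.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(
    modularity = 101L, nulls = 211L, communities = 307L,
    landscape = 401L, robustness = 503L, pipeline = 601L
  )
  off <- offsets[[stage]]
  if (is.null(off)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1009L + off
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(is.finite(m)) &&
    all(m >= 0) && all(m == round(m))
}
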