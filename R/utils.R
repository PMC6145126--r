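#' @import methods
#' @importFrom stats cor pt rnorm runif sd setNames
#' @importFrom utils read.table write.table head
NULL

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# stream afterwards.  All stochastic entry points route through this so that
# identical (config, seed) yields identical output regardless of ambient state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.assertFraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

# Canonical (sorted) gene-pair key, used wherever unordered pairs are stored.
.pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
}
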