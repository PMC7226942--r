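#' @import methods
#' @importFrom stats cor median phyper quantile rbinom rnorm runif sd setNames
#'   wilcox.test rexp
#' @importFrom utils read.table write.table head modifyList
NULL

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
withSeed <- function(seed, expr) {
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Derive a stream-specific child seed from a master seed (keeps values < 2^31).
childSeed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Canonical key for an undirected pair of names.
pairKey <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
}

# Deterministic JSON writer used for all pipeline artifacts.
writeJSONArtifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}
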