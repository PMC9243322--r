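# Internal numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax of a logit matrix (n x C), numerically stabilised.
softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# One-hot matrix (n x C) from 1-based integer labels.
oneHot <- function(labels, numClasses) {
  m <- matrix(0, length(labels), numClasses)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators and trainers are reproducible without
# clobbering the session stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Stable checksum of a (possibly nested) list of numeric arrays; used to
# assert the trunk-freeze contract during transfer learning.
paramChecksum <- function(params) {
  v <- unlist(params, use.names = FALSE)
  if (is.null(v)) return(0)
  sum(v * seq_along(v) %% 97) + sum(v^2)
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
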