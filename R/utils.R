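# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' @useDynLib ecoassembly, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom ape read.tree
NULL

# Derive a reproducible sub-seed from a master seed and a character key.
# Keeps per-pair / per-stage random streams independent of execution order.
# Result stays inside the 32-bit integer range.
.derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 131 + ch) %% 2147480000
  }
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480000)
}

# Run `expr` under a local RNG state seeded with `seed` (NULL = leave RNG alone).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
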