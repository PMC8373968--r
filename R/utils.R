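# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a label
#'
#' Every stochastic stage of the simulator draws from its own named
#' substream so that, e.g., adding a dataset never shifts the sampling of
#' an existing one. The hash is a plain polynomial rolling hash over the
#' label, mixed with the master seed; all arithmetic stays below 2^53 so
#' it is exact in doubles and the result fits a 32-bit integer.
#'
#' @param seed master integer seed.
#' @param label character scalar naming the substream.
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(length(label) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483587
  s <- ((as.numeric(seed) %% 2147483587) * 48271) %% 2147483587
  as.integer((h + s) %% 2147483587)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of an arbitrary R object via its serialization (tools::md5sum is
# file-based, so serialize to a tempfile first).
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 2 for stable serialization across R >= 3.5 sessions
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# Geometric mean of strictly positive values.
geo_mean <- function(x) exp(mean(log(x)))
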