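#' Derive a deterministic sub-seed from a master seed and a key
#'
#' Stochastic stages of the simulator draw from independent substreams so that
#' results do not depend on iteration order. Each stage derives its own seed by
#' hashing a string key (for example `"site1/realise/species_12"`) together
#' with the master seed. The hash is a 31-ary polynomial rolling hash over the
#' key's bytes, mixed with the master seed by a Knuth multiplicative step, and
#' reduced modulo 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric key parts; concatenated with "/".
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "site", 3)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1L)), collapse = "/")
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- seed %% m
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% m
  # final avalanche so nearby master seeds decorrelate
  h <- (h * 48271) %% m
  as.integer(h)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. NULL seed means "use current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
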