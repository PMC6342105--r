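#' @keywords internal
#' @importFrom splines bs
#' @importFrom stats predict
"_PACKAGE"

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# FNV-1a hash of a serialized R object, as 8 hex digits; used to stamp the
# effective configuration into output file headers.
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(h, b)
    # 32-bit FNV prime multiply, kept in double precision via modular split
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# Mix a user seed with a call-site salt so that different generators called
# with the same seed do not consume identical uniform streams (which would
# correlate, e.g., catchment positions with presence draws).
mix_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  ((abs(as.numeric(seed)) + salt) * 48271) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
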