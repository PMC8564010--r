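#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards (the idiom of simulate() methods).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic ladder of child seeds: draws `n` independent 31-bit seeds
## from a stream keyed by `seed`, so consumer r always sees the same child
## seed regardless of execution order.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## FNV-1a 32-bit hash of a character scalar; used to stamp config hashes
## into artifacts without a digest dependency.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte (b < 256); done in doubles to stay
    ## within the 32-bit range without bitwXor's integer coercion
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    ## 32-bit modular multiply by 16777619
    h <- (h * 16777619) %% 4294967296
  }
  ## h can exceed .Machine$integer.max; format as two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Clamp the linear predictor so plogis() stays numerically inside (0,1).
## |eta| > 36 already underflows the complementary probability.
clamp_eta <- function(eta, limit = 36, warn = TRUE) {
  n_out <- sum(abs(eta) > limit)
  if (n_out > 0 && warn) {
    warning(sprintf(
      "%d linear-predictor value(s) exceeded |eta| = %g and were clamped",
      n_out, limit), call. = FALSE)
  }
  pmin(pmax(eta, -limit), limit)
}

stop_validation <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
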