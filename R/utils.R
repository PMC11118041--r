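# Internal helpers shared across modules.

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' Saves and restores `.Random.seed` so seeded generation inside the package
#' never perturbs the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Trapezoidal integral of y sampled at uniform spacing dt.
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) stop("trapz() needs at least 2 samples")
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used to stamp a configuration fingerprint into study outputs.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor affects only the low byte (b < 256); done in doubles to stay
    # within 32 bits without bitwXor's integer-range limit
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, split into
    # 16-bit halves so every intermediate stays exactly representable
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonnegative && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
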