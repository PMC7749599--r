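# Internal helpers: seeding, logging, small numerics.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically expand one top-level seed into n per-unit seeds (< 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Stage logging to stderr; suppress with options(cpcmorph.quiet = TRUE).
cpc_log <- function(fmt, ...) {
  if (!isTRUE(getOption("cpcmorph.quiet", FALSE))) {
    message(sprintf(paste0("[cpcmorph] ", fmt), ...))
  }
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
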