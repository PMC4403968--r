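#' @importFrom stats coef lm lm.fit optim plogis qlogis rnorm sd setNames var sigma
#' @importFrom methods is new slot validObject
#' @importFrom utils read.csv read.table write.csv packageVersion
NULL

## Seed plumbing ------------------------------------------------------------
##
## All stochastic generators take one integer master seed; sub-streams are
## derived deterministically so that adding a stage never shifts the draws of
## another.  Derived seeds stay inside the 31-bit range R accepts.

deriveSeed <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k))
    for (ki in as.double(k)) {
      h <- (h * 48271 + ki + 1) %% 2147483647
    }
  }
  as.integer(h)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  expr
}

stopValidation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopValidation("'%s' must be a single finite number", name)
  }
  invisible(x)
}

## Sentinel used in parameter maps for voxels outside the mask or with an
## invalid fit.
mapSentinel <- function() NA_real_
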