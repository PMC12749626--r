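#' @keywords internal
#' @useDynLib miniscifunnel, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate expr with a locally-set RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic substream derivation: one user-facing seed fans out to named
# component seeds (split/train/conformers/synth, ...) so components are
# independently reproducible.  Kept below 2^31 - 1.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647L)
}

clip01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "miniscifunnel_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) stop_mf(class, fmt, ...)
  invisible(TRUE)
}
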