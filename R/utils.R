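#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a reproducible child seed from a base seed and integer tags.
# Multiplicative congruential mixing keeps everything inside 32-bit range so
# set.seed() accepts it; the per-tag streams mean that e.g. adding electrodes
# to a simulation does not perturb the trains already generated.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.double(t) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` with a local RNG state: seeds with `seed`, restores the
# caller's .Random.seed afterwards so library calls never disturb user code.
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}
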