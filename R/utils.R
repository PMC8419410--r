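#' @keywords internal
"_PACKAGE"

# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

#' Derive a child RNG seed from a master seed
#'
#' One master seed is expanded into independent per-component seeds by
#' seeding R's RNG with the master seed and drawing the k-th of a block of
#' integers.  Sub-simulations (tree, counts, timelines, ...) are therefore
#' independently reproducible from `(seed, component index)`.
#'
#' @param seed master integer seed.
#' @param k component index (1-based).
#' @return an integer seed below 2^31.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k), k >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  sample.int(2147483646L, as.integer(k))[as.integer(k)]
}

# validate a probability-like scalar
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}
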