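`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

#' Derive a stream of reproducible child seeds from one master seed
#'
#' R's RNG seeds are 32-bit; child seeds are kept in `[1, 2^31 - 1]` so they
#' can be passed back to [set.seed()].
#'
#' @param seed master seed (integer).
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(2147483646L, n, replace = FALSE)
}
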