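#' @useDynLib rna2d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Round a percentage half away from zero
#'
#' Computes `100 * count / total` and rounds to one decimal with ties going
#' away from zero (the convention used in printed classification tables;
#' base R's `round()` rounds half to even).
#'
#' @param count numerator count.
#' @param total denominator count.
#' @param digits decimal places (default 1).
#' @return numeric percentage.
#' @export
#' @examples
#' percentage(44913, 46316)  # 97.0
percentage <- function(count, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  round_half_up(100 * count / total, digits)
}

#' @rdname percentage
#' @param x numeric vector to round.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
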