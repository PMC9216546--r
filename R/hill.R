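#' Hill-type rate parameters
#'
#' Bundle and validate the parameters of a Hill rate law
#' \eqn{f(x) = \lambda x^n / (K^n + x^n)}. Positive Hill coefficients `n`
#' describe activation (f increases from 0 to `lam`), negative coefficients
#' describe repression (f decreases from `lam` to 0), written in the
#' algebraically equivalent form \eqn{\lambda K^{|n|}/(K^{|n|} + x^{|n|})}
#' so that the function is defined at `x = 0`. At `n = 0` the common limit
#' `lam / 2` of both branches is used, which keeps sweeps across `n = 0`
#' continuous.
#'
#' @param lam Maximal rate \eqn{\lambda} (molecules per unit time), `>= 0`.
#' @param n Hill coefficient; any real number, including negative values.
#' @param K Half-maximal abundance (molecules), `> 0`.
#'
#' @return An object of class `hill_params`.
#' @examples
#' hill_params(80, 2, 40)
#' @export
hill_params <- function(lam, n, K) {
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0)
    abort("`lam` must be a single non-negative number.")
  if (!is.numeric(n) || length(n) != 1 || is.na(n))
    abort("`n` must be a single number.")
  if (!is.numeric(K) || length(K) != 1 || is.na(K) || K <= 0)
    abort("`K` must be a single positive number.")
  structure(list(lam = as.numeric(lam), n = as.numeric(n), K = as.numeric(K)),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> lam = %g, n = %g, K = %g\n", x$lam, x$n, x$K))
  invisible(x)
}

#' Hill rate function
#'
#' Turn [hill_params()] into a vectorized rate function over non-negative
#' abundances. `f(0) = 0` for `n > 0`, `f(0) = lam` for `n < 0` (the
#' repressor-absent limit), and `f == lam / 2` everywhere for `n = 0`.
#'
#' @param params A `hill_params` object, or `lam` when the three parameters
#'   are given separately.
#' @param n,K Hill coefficient and half-max abundance when `params` is the
#'   numeric `lam`.
#'
#' @return A function mapping abundance vectors to rates in `[0, lam]`.
#' @examples
#' f <- hill_rate(hill_params(80, 2, 40))
#' f(40) # half-maximum: 40
#' @export
hill_rate <- function(params, n = NULL, K = NULL) {
  if (!inherits(params, "hill_params")) params <- hill_params(params, n, K)
  lam <- params$lam
  nn <- params$n
  KK <- params$K
  function(x) hill_eval(x, lam, nn, KK)
}

# vectorized evaluation shared by the rate machinery
hill_eval <- function(x, lam, n, K) {
  if (n == 0) return(rep(lam / 2, length(x)))
  out <- numeric(length(x))
  if (n > 0) {
    pos <- x > 0
    xn <- x[pos]^n
    out[pos] <- lam * xn / (K^n + xn)
  } else {
    m <- -n
    out[x <= 0] <- lam
    pos <- x > 0
    Km <- K^m
    out[pos] <- lam * Km / (Km + x[pos]^m)
  }
  out
}
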