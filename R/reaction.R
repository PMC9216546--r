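# Symbolic rate laws -------------------------------------------------------
#
# Propensities are restricted to the rate families actually needed for
# three-component gene-network motifs: constant, linear (first-order),
# Hill, Hill + constant, Hill + linear, and mass-action dimer. Keeping the
# rate laws symbolic (rather than opaque closures) lets the same definition
# drive the compiled simulator, the truncated master-equation oracle, and
# plain-text serialization.

rate_types <- c(constant = 1L, linear = 2L, hill = 3L,
                hill_const = 4L, hill_linear = 5L, dimer = 6L)

#' Rate-law constructors
#'
#' Build a symbolic propensity for use in [reaction()]. Species are referred
#' to by name and resolved against the system's species list.
#'
#' * `rate_constant(k)`: propensity `k`.
#' * `rate_linear(k, species)`: `k * x`, e.g. first-order degradation
#'   `x / tau` via `rate_linear(1 / tau, "x3")`.
#' * `rate_hill(lam, n, K, species)`: Hill law, see [hill_rate()].
#' * `rate_hill_const(lam, n, K, species, c)`: Hill plus basal rate `c`.
#' * `rate_hill_linear(lam, n, K, species, c, linear_species)`: Hill on one
#'   species plus `c * x` of another.
#' * `rate_dimer(gamma, species)`: mass-action dimerization
#'   `gamma * x * (x - 1)`, zero at `x < 2`.
#'
#' @param k,lam,n,K,c,gamma Numeric rate-law parameters.
#' @param species,linear_species Species name the law depends on.
#' @return A `rate_law` object.
#' @name rate_laws
NULL

new_rate <- function(type, params, species = character()) {
  structure(list(type = type, params = params, species = species),
            class = "rate_law")
}

#' @rdname rate_laws
#' @export
rate_constant <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  new_rate("constant", list(k = k))
}

#' @rdname rate_laws
#' @export
rate_linear <- function(k, species) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  new_rate("linear", list(k = k), species = species)
}

#' @rdname rate_laws
#' @export
rate_hill <- function(lam, n, K, species) {
  p <- hill_params(lam, n, K)
  new_rate("hill", list(lam = p$lam, n = p$n, K = p$K), species = species)
}

#' @rdname rate_laws
#' @export
rate_hill_const <- function(lam, n, K, species, c) {
  p <- hill_params(lam, n, K)
  stopifnot(is.numeric(c), length(c) == 1, c >= 0)
  new_rate("hill_const", list(lam = p$lam, n = p$n, K = p$K, c = c),
           species = species)
}

#' @rdname rate_laws
#' @export
rate_hill_linear <- function(lam, n, K, species, c, linear_species) {
  p <- hill_params(lam, n, K)
  stopifnot(is.numeric(c), length(c) == 1, c >= 0)
  new_rate("hill_linear", list(lam = p$lam, n = p$n, K = p$K, c = c),
           species = c(species, linear_species))
}

#' @rdname rate_laws
#' @export
rate_dimer <- function(gamma, species) {
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma >= 0)
  new_rate("dimer", list(gamma = gamma), species = species)
}

#' @export
print.rate_law <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  sp <- if (length(x$species)) paste0(" on ", paste(x$species, collapse = ", ")) else ""
  cat(sprintf("<rate_law:%s>%s (%s)\n", x$type, sp, ps))
  invisible(x)
}

#' Define a reaction
#'
#' A reaction is a stoichiometric change applied at a state-dependent rate.
#' The built-in rate laws all vanish on states from which firing would drive
#' a species negative (e.g. first-order and dimer degradation are zero at
#' 0 and at 0/1 molecules respectively), so trajectories stay non-negative.
#'
#' @param stoich Named integer vector of abundance changes (names are species;
#'   omitted species are unchanged), e.g. `c(x3 = +1)`.
#' @param rate A `rate_law` from [rate_laws].
#' @return A `reaction` object.
#' @examples
#' reaction(c(x3 = 1), rate_hill(80, 2, 40, "x2"))
#' @export
reaction <- function(stoich, rate) {
  if (is.null(names(stoich)) || any(names(stoich) == ""))
    abort("`stoich` must be a named integer vector.")
  if (!inherits(rate, "rate_law")) abort("`rate` must be a rate_law object.")
  stoich <- vapply(stoich, function(v) {
    if (v != round(v)) abort("stoichiometric changes must be integers.")
    as.integer(v)
  }, integer(1))
  structure(list(stoich = stoich, rate = rate), class = "reaction")
}

# Vectorized propensity of one rate law over a state matrix (rows = states,
# columns = species, resolved by name).
eval_rate <- function(rate, X, species_names) {
  col <- function(nm) X[, match(nm, species_names), drop = TRUE]
  p <- rate$params
  switch(rate$type,
    constant = rep(p$k, nrow(X)),
    linear = p$k * col(rate$species[1]),
    hill = hill_eval(col(rate$species[1]), p$lam, p$n, p$K),
    hill_const = hill_eval(col(rate$species[1]), p$lam, p$n, p$K) + p$c,
    hill_linear = hill_eval(col(rate$species[1]), p$lam, p$n, p$K) +
      p$c * col(rate$species[2]),
    dimer = {
      x <- col(rate$species[1])
      p$gamma * x * (x - 1)
    },
    abort(paste0("unknown rate type: ", rate$type))
  )
}

# Encode reactions for the compiled simulator: par row = (p1,p2,p3,i,p5,j).
encode_reactions <- function(system) {
  rs <- system$reactions
  S <- length(system$species)
  R <- length(rs)
  stoich <- matrix(0L, R, S)
  type <- integer(R)
  par <- matrix(0, R, 6)
  for (k in seq_len(R)) {
    st <- rs[[k]]$stoich
    stoich[k, match(names(st), system$species)] <- st
    rate <- rs[[k]]$rate
    type[k] <- rate_types[[rate$type]]
    p <- rate$params
    idx <- match(rate$species, system$species)
    par[k, ] <- switch(rate$type,
      constant = c(p$k, 0, 0, 1, 0, 1),
      linear = c(p$k, 0, 0, idx[1], 0, 1),
      hill = c(p$lam, p$n, p$K, idx[1], 0, 1),
      hill_const = c(p$lam, p$n, p$K, idx[1], p$c, 1),
      hill_linear = c(p$lam, p$n, p$K, idx[1], p$c, idx[2]),
      dimer = c(p$gamma, 0, 0, idx[1], 0, 1)
    )
  }
  list(stoich = stoich, type = type, par = par,
       speed = vapply(rs, function(r) r$speed %||% 1, numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
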