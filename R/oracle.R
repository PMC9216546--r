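# Brute-force stationary solver for small truncated systems -----------------
#
# The chemical master equation is solved exactly on a truncated rectangular
# state space: the sparse generator is assembled with reactions that would
# leave the box switched off (reflecting convention, which keeps the
# generator a proper rate matrix), and the stationary probability vector is
# obtained from a sparse linear solve of the balance equations with one
# redundant row replaced by the normalization constraint. This is a test
# oracle for small systems, not a scalable solver.

#' Exact stationary distribution of a truncated system
#'
#' @param system A [reaction_system()].
#' @param bounds Named (or system-ordered) integer vector of per-species
#'   maximum counts; the truncated box is the product of `0:bounds`.
#' @param max_states Guard on the truncated state-space size.
#' @return A `stationary_distribution`: probability array over the box
#'   (dimensions in species order), `bounds`, and `leaked_mass`, the total
#'   probability on boundary states, which must be small for the truncation
#'   to be trusted.
#' @examples
#' sys <- reaction_system(
#'   c("x2", "x3"),
#'   list(reaction(c(x3 = 1), rate_constant(5)),
#'        reaction(c(x3 = -1), rate_linear(1, "x3"))),
#'   lifetimes = c(x2 = NA, x3 = 1)
#' )
#' sd <- solve_stationary(sys, c(x2 = 0, x3 = 40))
#' @export
solve_stationary <- function(system, bounds, max_states = 1.2e6) {
  S <- length(system$species)
  if (!is.null(names(bounds))) bounds <- bounds[system$species]
  bounds <- as.integer(bounds)
  if (length(bounds) != S || any(is.na(bounds)) || any(bounds < 0))
    abort("`bounds` must give a non-negative maximum for every species.")
  dims <- bounds + 1L
  n <- prod(dims)
  if (n > max_states)
    abort(sprintf("truncated state space has %d states (limit %d).", n,
                  as.integer(max_states)))

  # state grid, one row per state, linear index = 1 + sum x_s * stride_s
  strides <- cumprod(c(1L, head(dims, -1L)))
  X <- matrix(0L, n, S)
  for (s in seq_len(S)) {
    X[, s] <- as.integer(((seq_len(n) - 1L) %/% strides[s]) %% dims[s])
  }
  colnames(X) <- system$species

  A <- propensity_matrix(system, X) # n x R propensities
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (k in seq_along(system$reactions)) {
    d <- rep(0L, S)
    st <- system$reactions[[k]]$stoich
    d[match(names(st), system$species)] <- st
    target_ok <- rep(TRUE, n)
    shift <- 0L
    for (s in seq_len(S)) {
      xs <- X[, s] + d[s]
      target_ok <- target_ok & xs >= 0L & xs <= bounds[s]
      shift <- shift + d[s] * strides[s]
    }
    act <- which(target_ok & A[, k] > 0)
    if (!length(act)) next
    tgt <- act + shift
    # out-flux (diagonal) and in-flux (off-diagonal), generator convention
    # dP/dt = Q P with Q[to, from]
    ii <- c(ii, act, tgt)
    jj <- c(jj, act, act)
    xx <- c(xx, -A[act, k], A[act, k])
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  # Solve Q pi = 0 by anchoring one reference state at probability 1 and
  # normalizing afterwards: drop the reference row (the balance equations
  # are redundant) and move its column to the right-hand side. This keeps
  # the system lattice-sparse; appending a dense normalization row instead
  # causes catastrophic fill-in during the sparse LU.
  # anchor near the deterministic rate-balance point, a high-probability state
  xref <- pmin(pmax(round(rate_balance_state(system)), 0L), bounds)
  ref <- 1L + sum(as.integer(xref) * strides)
  Qc <- methods::as(Q, "CsparseMatrix")
  b <- -as.numeric(Qc[, ref])[-ref]
  Asys <- Qc[-ref, -ref]
  pi_rest <- tryCatch(
    as.numeric(Matrix::solve(Asys, b)),
    error = function(e) abort(paste0("stationary solve failed (singular or ",
                                     "ill-conditioned generator): ",
                                     conditionMessage(e)))
  )
  pi_hat <- append(pi_rest, 1, after = ref - 1L)
  pi_hat[pi_hat < 0] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  boundary <- rep(FALSE, n)
  for (s in seq_len(S)) if (bounds[s] > 0) boundary <- boundary | X[, s] == bounds[s]
  prob <- array(pi_hat, dim = dims)
  structure(list(species = system$species, bounds = bounds, prob = prob,
                 leaked_mass = sum(pi_hat[boundary]),
                 observed = system$observed, Q = Q, states = X),
            class = "stationary_distribution")
}

#' @export
print.stationary_distribution <- function(x, ...) {
  cat(sprintf("<stationary_distribution> %s states, leaked mass %.3g\n",
              format(prod(x$bounds + 1L), big.mark = ","), x$leaked_mass))
  invisible(x)
}

#' Exact joint distribution of the observed pair from an oracle solve
#'
#' Marginalizes the truncated stationary distribution over the unobserved
#' species.
#'
#' @param sd A `stationary_distribution` from [solve_stationary()].
#' @param trim Drop the outermost all-below-`trim` probability states so the
#'   support matches what a finite sample would plausibly cover (default
#'   keeps everything).
#' @return A `joint_distribution` with `n_source_samples = 0`.
#' @export
oracle_joint <- function(sd, trim = 0) {
  idx <- match(sd$observed, sd$species)
  P <- apply(sd$prob, idx, sum)
  x2 <- 0:(dim(P)[1] - 1L)
  x3 <- 0:(dim(P)[2] - 1L)
  if (trim > 0) {
    keep2 <- which(rowSums(P) > trim)
    keep3 <- which(colSums(P) > trim)
    r2 <- min(keep2):max(keep2)
    r3 <- min(keep3):max(keep3)
    P <- P[r2, r3, drop = FALSE]
    x2 <- x2[r2]
    x3 <- x3[r3]
  }
  joint_distribution(x2, x3, P, n_source_samples = 0)
}

#' Exact stationary marginal of one species from an oracle solve
#'
#' @param sd A `stationary_distribution`.
#' @param species Species name.
#' @return Tibble with columns `state` and `p`.
#' @export
oracle_marginal <- function(sd, species) {
  idx <- match(species, sd$species)
  if (is.na(idx)) abort("unknown species.")
  p <- apply(sd$prob, idx, sum)
  tibble(state = 0:(length(p) - 1L), p = p)
}

#' Exact stationary moments of functions of the state
#'
#' @param sd A `stationary_distribution`.
#' @param fns Named list of functions of the state matrix columns, e.g.
#'   `list(x3 = function(X) X[, "x3"])`.
#' @return Named numeric vector of expectations.
#' @export
oracle_moments <- function(sd, fns) {
  p <- as.vector(sd$prob)
  vapply(fns, function(f) sum(f(sd$states) * p), numeric(1))
}
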