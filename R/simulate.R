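# Exact stochastic simulation (Doob-Gillespie) ------------------------------

#' Simulate an exact stochastic trajectory
#'
#' Runs the standard Doob-Gillespie algorithm: exponentially distributed
#' waiting times with the total propensity as rate, reactions chosen with
#' probability proportional to their propensity. Statistically exact and
#' reproducible for a fixed seed.
#'
#' @param system A [reaction_system()].
#' @param t_end End time (> 0).
#' @param initial_state Integer state vector (defaults to the deterministic
#'   rate-balance fixed point, rounded).
#' @param seed Integer seed; when `NULL` the current RNG state is used.
#' @param max_events Safety cap on the number of recorded events.
#' @return A tibble with columns `time` and one column per species, one row
#'   per event (plus the initial state). Attributes: `absorbed` (all
#'   propensities vanished before `t_end`), `truncated` (event cap hit).
#' @examples
#' sys <- example_system("noise_enhancing")
#' tr <- simulate_trajectory(sys, t_end = 5, seed = 1)
#' @export
simulate_trajectory <- function(system, t_end, initial_state = NULL,
                                seed = NULL, max_events = 5e6) {
  stopifnot(t_end > 0)
  x0 <- prepare_initial_state(system, initial_state)
  enc <- encode_reactions(system)
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_trajectory_cpp(x0, enc$stoich, enc$type, enc$par, enc$speed,
                            t_end, max_events)
  out <- as_tibble(as.data.frame(res$state))
  names(out) <- system$species
  out <- bind_cols(tibble(time = as.numeric(res$time)), out)
  attr(out, "absorbed") <- res$absorbed
  attr(out, "truncated") <- res$truncated
  attr(out, "t_end") <- res$t_end
  out
}

#' Draw stationary snapshots of the observed pair
#'
#' Simulates one long exact trajectory, discards a burn-in, then records the
#' observed pair every `interval` time units. With spacing of several times
#' the slowest lifetime, successive snapshots are approximately independent
#' draws from the stationary distribution; [snapshot_autocorrelation()] is
#' the diagnostic. All information about the unobserved species is
#' discarded.
#'
#' @param system A [reaction_system()].
#' @param n_samples Number of snapshots `N >= 1`.
#' @param burn_in Burn-in time before the first snapshot; default 50 times
#'   the slowest declared lifetime.
#' @param interval Time between snapshots; default 10 times the slowest
#'   declared lifetime.
#' @param seed Integer seed recorded in the metadata.
#' @param initial_state Optional integer state vector.
#' @return A `snapshot_ensemble`: tibble with integer columns `x2`, `x3`
#'   (named after the observed pair) and a `meta` attribute (seed, burn-in,
#'   interval, system name, source).
#' @examples
#' sys <- example_system("noise_enhancing")
#' snaps <- sample_snapshots(sys, 500, seed = 1)
#' @export
sample_snapshots <- function(system, n_samples, burn_in = NULL,
                             interval = NULL, seed = NULL,
                             initial_state = NULL) {
  if (n_samples < 1) abort("`n_samples` must be at least 1.")
  tau_max <- slowest_lifetime(system)
  burn_in <- burn_in %||% (50 * tau_max)
  interval <- interval %||% (10 * tau_max)
  stopifnot(burn_in >= 0, interval > 0)
  x0 <- prepare_initial_state(system, initial_state)
  enc <- encode_reactions(system)
  obs <- match(system$observed, system$species)
  if (!is.null(seed)) set.seed(seed)
  res <- ssa_snapshots_cpp(x0, enc$stoich, enc$type, enc$par, enc$speed,
                           burn_in, interval, as.integer(n_samples),
                           obs[1], obs[2])
  new_snapshot_ensemble(
    res$samples[, 1], res$samples[, 2],
    meta = list(seed = seed, burn_in = burn_in, interval = interval,
                system = system$name, source = "ssa",
                absorbed = res$absorbed, n = as.integer(n_samples))
  )
}

#' Construct a snapshot ensemble from paired abundances
#'
#' @param x2,x3 Non-negative integer vectors of equal length (regulator and
#'   regulated abundances, one entry per sampled cell/realization).
#' @param meta Optional metadata list (seed, provenance, ...).
#' @return A `snapshot_ensemble` tibble.
#' @examples
#' snapshot_ensemble(c(1, 1, 3, 3), c(2, 2, 4, 4))
#' @export
snapshot_ensemble <- function(x2, x3, meta = list()) {
  if (length(x2) != length(x3)) abort("`x2` and `x3` must have equal length.")
  if (any(x2 != round(x2)) || any(x3 != round(x3)))
    abort("snapshot abundances must be integers.")
  new_snapshot_ensemble(x2, x3, meta)
}

new_snapshot_ensemble <- function(x2, x3, meta = list()) {
  out <- tibble(x2 = as.integer(x2), x3 = as.integer(x3))
  if (any(out$x2 < 0) || any(out$x3 < 0))
    abort("snapshot abundances must be non-negative integers.")
  attr(out, "meta") <- meta
  class(out) <- c("snapshot_ensemble", class(out))
  out
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<snapshot_ensemble> N = %d (%s%s)\n", nrow(x),
              m$source %||% "unknown source",
              if (!is.null(m$system)) paste0(", system ", m$system) else ""))
  NextMethod()
}

slowest_lifetime <- function(system) {
  lt <- system$lifetimes
  if (all(is.na(lt))) return(1)
  max(lt, na.rm = TRUE)
}

prepare_initial_state <- function(system, initial_state) {
  if (is.null(initial_state)) return(rate_balance_state(system))
  if (length(initial_state) != length(system$species))
    abort("`initial_state` must have one entry per species.")
  if (any(initial_state < 0) || any(initial_state != round(initial_state)))
    abort("`initial_state` must be non-negative integers.")
  as.integer(initial_state)
}

#' Lag-k autocorrelation of successive snapshots
#'
#' Diagnostic for the approximate independence of snapshots drawn from one
#' trajectory: values near zero indicate the spacing is large enough.
#'
#' @param samples A `snapshot_ensemble`.
#' @param lag Positive integer lag.
#' @return Tibble with one row per observed coordinate and its lag-`lag`
#'   autocorrelation.
#' @export
snapshot_autocorrelation <- function(samples, lag = 1) {
  stopifnot(lag >= 1, nrow(samples) > lag)
  ac <- function(v) {
    n <- length(v)
    a <- v[seq_len(n - lag)]
    b <- v[seq_len(n - lag) + lag]
    if (var(a) == 0 || var(b) == 0) return(NA_real_)
    cov(a, b) / sqrt(var(a) * var(b))
  }
  tibble(coordinate = names(samples),
         lag = lag,
         autocorrelation = vapply(samples, ac, numeric(1)))
}

# snapshot i/o ---------------------------------------------------------------

#' Write or read a snapshot ensemble
#'
#' Snapshots are stored as a two-column (`x2`, `x3`) tab-separated text file
#' with a header, plus a YAML metadata sidecar (`<path>.meta.yml`) holding
#' seed, burn-in, interval and provenance.
#'
#' @param samples A `snapshot_ensemble`.
#' @param path File path for the TSV table.
#' @return `read_snapshots()` returns the ensemble; `write_snapshots()`
#'   returns `path` invisibly.
#' @export
write_snapshots <- function(samples, path) {
  write.table(as.data.frame(samples[, c("x2", "x3")]), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- attr(samples, "meta") %||% list()
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  meta_path <- paste0(path, ".meta.yml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  new_snapshot_ensemble(d$x2, d$x3, meta = meta)
}
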