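#' Define a reaction system
#'
#' A reaction system couples an ordered species list with a set of
#' [reaction()]s and designates the observed pair of species (by default
#' `x2`, the regulator, and `x3`, the regulated component). Only the observed
#' pair enters the inference; all other species are latent.
#'
#' @param species Character vector of species names.
#' @param reactions List of [reaction()] objects.
#' @param observed Length-2 character vector naming the observed pair
#'   (regulator first).
#' @param lifetimes Optional named numeric vector of mean lifetimes used to
#'   pick default burn-in and snapshot spacing; inferred from first-order
#'   degradation reactions when omitted.
#' @param name Optional label carried through metadata.
#' @return A `reaction_system` object.
#' @seealso [example_system()] for the built-in three-component motifs.
#' @export
reaction_system <- function(species, reactions, observed = c("x2", "x3"),
                            lifetimes = NULL, name = NULL) {
  if (anyDuplicated(species)) abort("species names must be unique.")
  if (!all(vapply(reactions, inherits, logical(1), "reaction")))
    abort("`reactions` must be a list of reaction objects.")
  for (r in reactions) {
    unknown <- setdiff(c(names(r$stoich), r$rate$species), species)
    if (length(unknown))
      abort(paste0("reaction references unknown species: ",
                   paste(unknown, collapse = ", ")))
  }
  if (length(observed) != 2 || anyDuplicated(observed) ||
      !all(observed %in% species))
    abort("`observed` must name two distinct species of the system.")
  if (is.null(lifetimes)) {
    lifetimes <- infer_lifetimes(species, reactions)
  }
  structure(list(species = species, reactions = reactions,
                 observed = observed, lifetimes = lifetimes,
                 name = name %||% "custom"),
            class = "reaction_system")
}

# mean lifetime 1/k from first-order self-degradation reactions
infer_lifetimes <- function(species, reactions) {
  lt <- setNames(rep(NA_real_, length(species)), species)
  for (r in reactions) {
    st <- r$stoich
    if (length(st) == 1 && st < 0 && r$rate$type == "linear" &&
        identical(r$rate$species[1], names(st)) && r$rate$params$k > 0) {
      sp <- names(st)
      k <- r$rate$params$k * (r$speed %||% 1)
      lt[sp] <- 1 / k
    }
  }
  lt
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("<reaction_system> %s: %d species (%s), %d reactions; observed pair (%s)\n",
              x$name, length(x$species), paste(x$species, collapse = ", "),
              length(x$reactions), paste(x$observed, collapse = ", ")))
  for (r in x$reactions) {
    st <- paste(sprintf("%s%+d", names(r$stoich), r$stoich), collapse = ", ")
    ps <- paste(names(r$rate$params), signif(unlist(r$rate$params), 4),
                sep = "=", collapse = ", ")
    sp <- if (length(r$rate$species))
      paste0("(", paste(r$rate$species, collapse = ","), ")") else ""
    spd <- if (!is.null(r$speed) && r$speed != 1)
      sprintf(" x speed %g", r$speed) else ""
    cat(sprintf("  [%s]  rate %s%s {%s}%s\n", st, r$rate$type, sp, ps, spd))
  }
  invisible(x)
}

#' Evaluate all propensities on a matrix of states
#'
#' @param system A [reaction_system()].
#' @param X Integer matrix of states (rows = states, columns = species in
#'   system order) or a single state vector.
#' @return Numeric matrix, rows = states, columns = reactions.
#' @export
propensity_matrix <- function(system, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  out <- vapply(system$reactions, function(r) {
    eval_rate(r$rate, X, system$species) * (r$speed %||% 1)
  }, numeric(nrow(X)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(X))
  out
}

#' Degradation specification for the observed downstream component
#'
#' Describes how the regulated component is degraded, which fixes the
#' right-hand side of the flux-balance equations. Two built-ins cover the
#' supported cases: first-order decay (`x / tau3`, one molecule per event)
#' and mass-action dimer decay (`gamma * x * (x - 1)`, two molecules per
#' event). When `scale_known = FALSE` the recovered rate is interpreted as
#' `tau3 * f(x2)` (shape identified, scale not).
#'
#' @param kind `"linear"` or `"dimeric"`.
#' @param tau3 Mean lifetime for first-order decay (default 1).
#' @param gamma Dimer rate constant (default 2).
#' @param scale_known Is the degradation scale known? Affects reporting only.
#' @return A `degradation_spec` with fields `kind`, `step` (molecules removed
#'   per event), `g` (propensity function of the downstream abundance), and
#'   the parameters.
#' @export
degradation_spec <- function(kind = c("linear", "dimeric"), tau3 = 1,
                             gamma = 2, scale_known = TRUE) {
  kind <- match.arg(kind)
  if (kind == "linear") {
    stopifnot(tau3 > 0)
    g <- function(x) ifelse(x >= 1, x / tau3, 0)
    step <- 1L
  } else {
    stopifnot(gamma > 0)
    g <- function(x) ifelse(x >= 2, gamma * x * (x - 1), 0)
    step <- 2L
  }
  structure(list(kind = kind, step = step, g = g, tau3 = tau3, gamma = gamma,
                 scale_known = scale_known),
            class = "degradation_spec")
}

#' Built-in three-component example motifs
#'
#' Construct the four three-component feedback motifs used as test beds.
#' All share the conserved downstream part: production of `x3` at the Hill
#' rate `f(x2) = lam * x2^n / (K^n + x2^n)` with `lam = 80, n = 2, K = 40`,
#' and degradation `x3 / tau3` with `tau3 = 1` (or the dimer variant
#' `gamma * x3 * (x3 - 1)` with `gamma = 2`, removing two molecules per
#' event). They differ in the upstream `x1`, `x2` dynamics:
#'
#' * `bistable`: `f1(x2) = Hill(50, 6, 37)(x2) + 15`, `f2(x1) = x1`,
#'   `tau1 = tau2 = 1`.
#' * `oscillating`: `f1(x3) = Hill(50000, -10, 0.1)(x3)`,
#'   `f2(x1) = Hill(80, 1, 100)(x1)`, `tau1 = tau2 = 1`.
#' * `noise_controlling`: `f1(x3) = 50 * x3`,
#'   `f2(x1) = Hill(3000, -10, 10)(x1)`, `tau1 = 50`, `tau2 = 1`.
#' * `noise_enhancing`: `f1 = 5`,
#'   `f2(x1, x3) = Hill(25, 4, 50)(x3) + 8 * x1`, `tau1 = tau2 = 1`.
#'
#' @param name Motif name.
#' @param degradation `"linear"` or `"dimeric"` decay of `x3`.
#' @param overrides Named list overriding declared parameters:
#'   `f3_lam`, `f3_n`, `f3_K` (downstream Hill), `tau1`, `tau2`, `tau3`,
#'   `gamma`, upstream parameters where the motif has them (`f1_lam`,
#'   `f1_n`, `f1_K`, `f1_c`, `f2_lam`, `f2_n`, `f2_K`, `f2_c`; overriding a
#'   parameter the named motif does not use is an error), and `x2_speed`.
#'   `x2_speed` multiplies both the production and
#'   degradation propensity of `x2`, modulating its timescale (effective
#'   lifetime `tau2 / x2_speed`) without changing its stationary conditional
#'   distribution, which is how the relative-timescale sweeps are run.
#' @return A [reaction_system()] with three species `x1, x2, x3` and observed
#'   pair `(x2, x3)`.
#' @examples
#' example_system("noise_enhancing")
#' example_system("noise_enhancing", "dimeric", overrides = list(gamma = 2))
#' @export
example_system <- function(name = c("noise_enhancing", "bistable",
                                    "oscillating", "noise_controlling"),
                           degradation = c("linear", "dimeric"),
                           overrides = list()) {
  if (is.character(name) && length(name) == 1 &&
      !name %in% c("noise_enhancing", "bistable", "oscillating",
                   "noise_controlling"))
    abort(paste0("unknown system '", name, "'; valid names: noise_enhancing, ",
                 "bistable, oscillating, noise_controlling"))
  name <- match.arg(name)
  degradation <- match.arg(degradation)
  # printed upstream parameters per motif; only these slots may be overridden
  up_defaults <- switch(name,
    bistable = list(f1_lam = 50, f1_n = 6, f1_K = 37, f1_c = 15, f2_lam = 1),
    oscillating = list(f1_lam = 50000, f1_n = -10, f1_K = 0.1,
                       f2_lam = 80, f2_n = 1, f2_K = 100),
    noise_controlling = list(f1_lam = 50, f2_lam = 3000, f2_n = -10,
                             f2_K = 10),
    noise_enhancing = list(f1_lam = 5, f2_lam = 25, f2_n = 4, f2_K = 50,
                           f2_c = 8)
  )
  allowed <- c("f3_lam", "f3_n", "f3_K", "tau1", "tau2", "tau3", "gamma",
               "x2_speed", names(up_defaults))
  bad <- setdiff(names(overrides), allowed)
  if (length(bad))
    abort(paste0("unknown override(s) for motif '", name, "': ",
                 paste(bad, collapse = ", "), "; declared parameters: ",
                 paste(allowed, collapse = ", ")))
  ov <- modifyList(c(list(f3_lam = 80, f3_n = 2, f3_K = 40, tau1 = NULL,
                          tau2 = 1, tau3 = 1, gamma = 2, x2_speed = 1),
                     up_defaults),
                   overrides)
  tau1 <- ov$tau1 %||% if (name == "noise_controlling") 50 else 1

  upstream <- switch(name,
    bistable = list(
      reaction(c(x1 = 1L), rate_hill_const(ov$f1_lam, ov$f1_n, ov$f1_K,
                                           "x2", ov$f1_c)),
      reaction(c(x2 = 1L), rate_linear(ov$f2_lam, "x1"))
    ),
    oscillating = list(
      reaction(c(x1 = 1L), rate_hill(ov$f1_lam, ov$f1_n, ov$f1_K, "x3")),
      reaction(c(x2 = 1L), rate_hill(ov$f2_lam, ov$f2_n, ov$f2_K, "x1"))
    ),
    noise_controlling = list(
      reaction(c(x1 = 1L), rate_linear(ov$f1_lam, "x3")),
      reaction(c(x2 = 1L), rate_hill(ov$f2_lam, ov$f2_n, ov$f2_K, "x1"))
    ),
    noise_enhancing = list(
      reaction(c(x1 = 1L), rate_constant(ov$f1_lam)),
      reaction(c(x2 = 1L), rate_hill_linear(ov$f2_lam, ov$f2_n, ov$f2_K,
                                            "x3", ov$f2_c, "x1"))
    )
  )
  deaths <- list(
    reaction(c(x1 = -1L), rate_linear(1 / tau1, "x1")),
    reaction(c(x2 = -1L), rate_linear(1 / ov$tau2, "x2"))
  )
  x3_birth <- reaction(c(x3 = 1L), rate_hill(ov$f3_lam, ov$f3_n, ov$f3_K, "x2"))
  x3_death <- if (degradation == "linear") {
    reaction(c(x3 = -1L), rate_linear(1 / ov$tau3, "x3"))
  } else {
    reaction(c(x3 = -2L), rate_dimer(ov$gamma, "x3"))
  }
  reactions <- c(upstream[1], deaths[1], upstream[2], deaths[2],
                 list(x3_birth, x3_death))
  if (ov$x2_speed != 1) {
    reactions[[3]]$speed <- ov$x2_speed
    reactions[[4]]$speed <- ov$x2_speed
  }
  lifetimes <- c(x1 = tau1, x2 = ov$tau2 / ov$x2_speed,
                 x3 = if (degradation == "linear") ov$tau3 else NA_real_)
  sys <- reaction_system(c("x1", "x2", "x3"), reactions,
                         observed = c("x2", "x3"), lifetimes = lifetimes,
                         name = paste0(name,
                                       if (degradation == "dimeric") "_dimeric" else ""))
  sys$degradation <- degradation_spec(degradation, tau3 = ov$tau3,
                                      gamma = ov$gamma)
  sys$true_rate <- hill_rate(hill_params(ov$f3_lam, ov$f3_n, ov$f3_K))
  sys$params <- ov[c("f3_lam", "f3_n", "f3_K", "tau2", "tau3", "gamma",
                     "x2_speed", names(up_defaults))]
  sys$params$tau1 <- tau1
  sys
}

# deterministic rate-balance fixed point (damped iteration), used as the
# default SSA initial state to shorten burn-in
rate_balance_state <- function(system, iterations = 400) {
  S <- length(system$species)
  x <- rep(10, S)
  for (it in seq_len(iterations)) {
    X <- matrix(pmax(x, 0), nrow = 1)
    colnames(X) <- NULL
    a <- propensity_matrix(system, X)[1, ]
    target <- x
    for (s in seq_len(S)) {
      prod_rate <- 0
      deg_lin <- 0
      deg_dimer <- 0
      for (k in seq_along(system$reactions)) {
        d <- system$reactions[[k]]$stoich
        ds <- d[match(system$species[s], names(d))]
        if (is.na(ds) || ds == 0) next
        if (ds > 0) prod_rate <- prod_rate + ds * a[k]
        else {
          r <- system$reactions[[k]]
          if (r$rate$type == "dimer") deg_dimer <- deg_dimer +
              r$rate$params$gamma * (r$speed %||% 1) * abs(ds)
          else if (r$rate$type == "linear") deg_lin <- deg_lin +
              r$rate$params$k * (r$speed %||% 1) * abs(ds)
        }
      }
      if (deg_dimer > 0 && prod_rate > 0) {
        target[s] <- (1 + sqrt(1 + 4 * prod_rate / deg_dimer)) / 2
      } else if (deg_lin > 0) {
        target[s] <- prod_rate / deg_lin
      }
    }
    x <- 0.8 * x + 0.2 * target
  }
  pmax(0L, as.integer(round(x)))
}

#' Write or read a system definition as a plain-text config
#'
#' Systems serialize to a YAML key-value file: species, observed pair, and
#' one entry per reaction with its stoichiometry and symbolic rate law.
#'
#' @param system A [reaction_system()].
#' @param path File path.
#' @return `read_system_config()` returns the reconstructed system;
#'   `write_system_config()` returns `path` invisibly.
#' @export
write_system_config <- function(system, path) {
  enc <- list(
    name = system$name,
    species = as.list(system$species),
    observed = as.list(system$observed),
    lifetimes = as.list(system$lifetimes),
    reactions = lapply(system$reactions, function(r) {
      list(stoich = as.list(r$stoich), type = r$rate$type,
           params = r$rate$params,
           species = as.list(r$rate$species),
           speed = r$speed %||% 1)
    })
  )
  yaml::write_yaml(enc, path)
  invisible(path)
}

#' @rdname write_system_config
#' @export
read_system_config <- function(path) {
  enc <- yaml::read_yaml(path)
  reactions <- lapply(enc$reactions, function(r) {
    sp <- unlist(r$species)
    rate <- switch(r$type,
      constant = rate_constant(r$params$k),
      linear = rate_linear(r$params$k, sp[1]),
      hill = rate_hill(r$params$lam, r$params$n, r$params$K, sp[1]),
      hill_const = rate_hill_const(r$params$lam, r$params$n, r$params$K,
                                   sp[1], r$params$c),
      hill_linear = rate_hill_linear(r$params$lam, r$params$n, r$params$K,
                                     sp[1], r$params$c, sp[2]),
      dimer = rate_dimer(r$params$gamma, sp[1]),
      abort(paste0("unknown rate type in config: ", r$type))
    )
    rx <- reaction(unlist(r$stoich), rate)
    if (!is.null(r$speed) && r$speed != 1) rx$speed <- r$speed
    rx
  })
  lt <- unlist(enc$lifetimes)
  reaction_system(unlist(enc$species), reactions,
                  observed = unlist(enc$observed),
                  lifetimes = lt, name = enc$name)
}
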