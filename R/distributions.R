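# Joint distributions over the observed pair --------------------------------

#' Construct a joint distribution over the observed pair
#'
#' Probabilities are stored on the full integer rectangle spanned by the
#' supports (explicit zeros inside the hull), so that downstream balance
#' matrices have well-defined columns for interior states that happen never
#' to be observed.
#'
#' @param x2,x3 Sorted contiguous integer supports.
#' @param prob Matrix of probabilities (or counts; normalized internally),
#'   rows indexed by `x2`, columns by `x3`.
#' @param n_source_samples Number of samples behind the estimate (0 for an
#'   exact, oracle-derived distribution).
#' @return A `joint_distribution`.
#' @export
joint_distribution <- function(x2, x3, prob, n_source_samples = 0) {
  x2 <- as.integer(x2)
  x3 <- as.integer(x3)
  if (any(diff(x2) != 1L) || any(diff(x3) != 1L))
    abort("supports must be contiguous integer ranges.")
  if (any(x2 < 0) || any(x3 < 0)) abort("supports must be non-negative.")
  prob <- as.matrix(prob)
  dimnames(prob) <- NULL
  if (nrow(prob) != length(x2) || ncol(prob) != length(x3))
    abort("`prob` must be length(x2) x length(x3).")
  if (any(prob < 0)) abort("probabilities must be non-negative.")
  tot <- sum(prob)
  if (tot <= 0) abort("total probability mass must be positive.")
  structure(list(x2 = x2, x3 = x3, prob = prob / tot,
                 n_source_samples = as.integer(n_source_samples)),
            class = "joint_distribution")
}

#' @export
print.joint_distribution <- function(x, ...) {
  cat(sprintf("<joint_distribution> x2 in [%d, %d], x3 in [%d, %d]%s\n",
              min(x$x2), max(x$x2), min(x$x3), max(x$x3),
              if (x$n_source_samples > 0)
                sprintf(" (from N = %d samples)", x$n_source_samples)
              else " (exact)"))
  invisible(x)
}

#' @export
tidy.joint_distribution <- function(x, ...) {
  tibble(x2 = rep(x$x2, times = length(x$x3)),
         x3 = rep(x$x3, each = length(x$x2)),
         p = as.vector(x$prob))
}

#' Empirical joint distribution of a snapshot ensemble
#'
#' `prob[j, i] = count(x2 = j, x3 = i) / N` over the observed ranges.
#'
#' @param samples A `snapshot_ensemble` (or tibble with `x2`, `x3`).
#' @return A `joint_distribution`.
#' @examples
#' e <- snapshot_ensemble(c(1, 1, 3, 3), c(2, 2, 4, 4))
#' empirical_joint(e)
#' @export
empirical_joint <- function(samples) {
  if (nrow(samples) < 1) abort("empty snapshot ensemble.")
  x2_lv <- seq(min(samples$x2), max(samples$x2))
  x3_lv <- seq(min(samples$x3), max(samples$x3))
  counts <- table(factor(samples$x2, levels = x2_lv),
                  factor(samples$x3, levels = x3_lv))
  joint_distribution(x2_lv, x3_lv, unclass(counts),
                     n_source_samples = nrow(samples))
}

#' Marginal distribution of one coordinate
#'
#' @param joint A `joint_distribution`.
#' @param axis `"x2"` or `"x3"`.
#' @return Tibble with the state column (`x2` or `x3`) and probability `p`.
#' @export
marginal <- function(joint, axis = c("x2", "x3")) {
  axis <- match.arg(axis)
  v <- marginal_vec(joint, axis)
  out <- tibble(state = joint[[axis]], p = v)
  names(out)[1] <- axis
  out
}

marginal_vec <- function(joint, axis) {
  if (axis == "x2") rowSums(joint$prob) else colSums(joint$prob)
}

#' Conditional mean of one coordinate given the other
#'
#' The naive baseline of rate inference: in the limit of very slow upstream
#' fluctuations, `<x3 | x2> / tau3` identifies the production rate directly;
#' for faster regulators it flattens and no longer tracks the rate.
#' States never observed are absent from the table (not imputed).
#'
#' @param x A `snapshot_ensemble` or `joint_distribution`.
#' @param of Coordinate to average (default `"x3"`).
#' @param given Conditioning coordinate (default `"x2"`).
#' @return Tibble with the conditioning state, the conditional `mean`, and
#'   the probability `p` of the conditioning state.
#' @export
conditional_mean <- function(x, of = "x3", given = "x2") {
  stopifnot(of %in% c("x2", "x3"), given %in% c("x2", "x3"), of != given)
  if (inherits(x, "joint_distribution")) {
    P <- if (given == "x2") x$prob else t(x$prob)
    g_states <- x[[given]]
    o_states <- x[[of]]
    pg <- rowSums(P)
    keep <- pg > 0
    m <- as.vector(P[keep, , drop = FALSE] %*% o_states) / unname(pg[keep])
    out <- tibble(state = g_states[keep], mean = m, p = unname(pg[keep]))
  } else {
    out <- as_tibble(x) |>
      group_by(.data[[given]]) |>
      summarise(mean = mean(.data[[of]]), n = n(), .groups = "drop") |>
      mutate(p = .data$n / sum(.data$n)) |>
      select(state = all_of(given), mean, p)
  }
  names(out)[1] <- given
  out
}

#' Draw independent samples from a joint distribution
#'
#' Resamples `(x2, x3)` pairs i.i.d. from a (typically exact, oracle-derived)
#' joint distribution.
#'
#' @param joint A `joint_distribution`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A `snapshot_ensemble`.
#' @export
sample_joint <- function(joint, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- as.vector(joint$prob)
  idx <- sample.int(length(p), n, replace = TRUE, prob = p)
  j <- (idx - 1L) %% length(joint$x2) + 1L
  i <- (idx - 1L) %/% length(joint$x2) + 1L
  new_snapshot_ensemble(joint$x2[j], joint$x3[i],
                        meta = list(seed = seed, source = "resample",
                                    n = as.integer(n)))
}

#' Total-variation distance between two joint distributions
#'
#' @param a,b `joint_distribution` objects (supports may differ).
#' @return Numeric in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  da <- tidy(a)
  db <- tidy(b)
  m <- full_join(da, db, by = c("x2", "x3"), suffix = c("_a", "_b")) |>
    mutate(p_a = coalesce(.data$p_a, 0), p_b = coalesce(.data$p_b, 0))
  sum(abs(m$p_a - m$p_b)) / 2
}

# joint i/o ------------------------------------------------------------------

#' Write or read a joint distribution table
#'
#' Three-column tab-separated text `(x2, x3, value)`; the third column is
#' named `prob` or `count`, marking which it holds. Zero cells inside the
#' support hull are written explicitly so the file round-trips exactly.
#'
#' @param joint A `joint_distribution`.
#' @param path File path.
#' @param what Write probabilities or (rescaled) counts; counts require a
#'   sample-backed joint.
#' @return `read_joint()` returns a `joint_distribution`; `write_joint()`
#'   returns `path` invisibly.
#' @export
write_joint <- function(joint, path, what = c("prob", "count")) {
  what <- match.arg(what)
  d <- tidy(joint)
  if (what == "count") {
    if (joint$n_source_samples < 1)
      abort("counts requested but the joint is not sample-backed.")
    d$count <- round(d$p * joint$n_source_samples)
    d$p <- NULL
  } else {
    names(d)[3] <- "prob"
  }
  write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_joint
#' @export
read_joint <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  val_col <- intersect(c("prob", "count"), names(d))
  if (length(val_col) != 1)
    abort("joint table must have a `prob` or `count` column.")
  x2_lv <- seq(min(d$x2), max(d$x2))
  x3_lv <- seq(min(d$x3), max(d$x3))
  prob <- matrix(0, length(x2_lv), length(x3_lv))
  prob[cbind(match(d$x2, x2_lv), match(d$x3, x3_lv))] <- d[[val_col]]
  n_src <- if (val_col == "count") sum(d[[val_col]]) else 0
  joint_distribution(x2_lv, x3_lv, prob, n_source_samples = n_src)
}

#' @export
autoplot.joint_distribution <- function(object, ...) {
  d <- tidy(object) |> filter(.data$p > 0)
  ggplot2::ggplot(d, ggplot2::aes(.data$x2, .data$x3, fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "P(x2, x3)") +
    ggplot2::labs(x = "x2 (regulator)", y = "x3 (regulated)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.snapshot_ensemble <- function(object, ...) {
  autoplot(empirical_joint(object), ...)
}
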