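#!/usr/bin/env Rscript

# Command-line driver for the snapshot-based rate-inference pipeline.
#
# Usage:
#   Rscript scripts/ratesnap.R simulate --system noise_enhancing --n 100000 \
#       --seed 1 --out snaps.tsv
#   Rscript scripts/ratesnap.R corrupt --in snaps.tsv --kind additive \
#       --sigma-abs 3 --seed 2 --out noisy.tsv
#   Rscript scripts/ratesnap.R infer --in snaps.tsv --degradation linear \
#       --tau3 1 --cv --monotone none --seed 3 --out estimate.tsv
#   Rscript scripts/ratesnap.R evaluate --estimate estimate.tsv \
#       --lam 80 --hill-n 2 --K 40 --samples snaps.tsv --out metrics.tsv
#   Rscript scripts/ratesnap.R sweep --config experiment.yml \
#       --param n_samples --values 1000,10000 --out sweep.tsv
#
# Tables are tab-separated; simulate/corrupt/infer write a `.meta.yml`
# sidecar next to the main output with the run metadata.

suppressMessages({
  library(ratesnap)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
subcommand <- if (length(args)) args[[1]] else ""
rest <- args[-1]

usage_stop <- function() {
  stop("usage: ratesnap.R {simulate|corrupt|infer|evaluate|sweep} [options]",
       call. = FALSE)
}

parse <- function(opt_list) {
  parse_args(OptionParser(option_list = opt_list), args = rest)
}

write_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
}

run_simulate <- function() {
  o <- parse(list(
    make_option("--system", type = "character", default = "noise_enhancing"),
    make_option("--degradation", type = "character", default = "linear"),
    make_option("--n", type = "integer", default = 100000L),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", type = "character", default = "snapshots.tsv")))
  sys <- example_system(o$system, o$degradation)
  s <- sample_snapshots(sys, o$n, seed = o$seed)
  write_snapshots(s, o$out)
  message(sprintf("wrote %d snapshots of %s to %s", nrow(s), o$system, o$out))
}

run_corrupt <- function() {
  o <- parse(list(
    make_option("--in", type = "character", dest = "input"),
    make_option("--kind", type = "character",
                help = "additive | relative | undercount"),
    make_option("--sigma-abs", type = "double", default = NA,
                dest = "sigma_abs"),
    make_option("--sigma-rel", type = "double", default = NA,
                dest = "sigma_rel"),
    make_option("--p", type = "double", default = NA),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", type = "character", default = "corrupted.tsv")))
  s <- read_snapshots(o$input)
  out <- switch(o$kind,
    additive = apply_additive(s, o$sigma_abs, seed = o$seed),
    relative = apply_relative(s, o$sigma_rel, seed = o$seed),
    undercount = apply_undercount(s, o$p, seed = o$seed),
    stop("unknown --kind: ", o$kind, call. = FALSE))
  write_snapshots(out, o$out)
  message(sprintf("wrote %d corrupted snapshots to %s", nrow(out), o$out))
}

run_infer <- function() {
  o <- parse(list(
    make_option("--in", type = "character", dest = "input",
                help = "snapshot table (x2, x3) or joint table (x2, x3, prob|count)"),
    make_option("--degradation", type = "character", default = "linear"),
    make_option("--tau3", type = "double", default = 1),
    make_option("--gamma", type = "double", default = 2),
    make_option("--epsilon", type = "double", default = NA),
    make_option("--cv", action = "store_true", default = FALSE),
    make_option("--no-cv", action = "store_false", dest = "cv"),
    make_option("--monotone", type = "character", default = "none",
                help = "none | up | down"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", type = "character", default = "estimate.tsv")))
  header <- strsplit(readLines(o$input, n = 1), "\t")[[1]]
  is_joint <- any(c("prob", "count") %in% header)
  deg <- degradation_spec(o$degradation, tau3 = o$tau3, gamma = o$gamma)
  constraint <- switch(o$monotone, none = "none", up = "increasing",
                       down = "decreasing",
                       stop("unknown --monotone: ", o$monotone, call. = FALSE))
  epsilon <- if (is.na(o$epsilon)) NULL else o$epsilon
  if (o$cv) {
    if (is_joint)
      stop("--cv needs snapshot input (held-out split).", call. = FALSE)
    s <- read_snapshots(o$input)
    est <- infer_rate_cv(s, deg, epsilon = epsilon, split_seed = o$seed,
                         constraint = constraint)
  } else {
    joint <- if (is_joint) read_joint(o$input)
             else empirical_joint(read_snapshots(o$input))
    est <- infer_rate(assemble_balance_system(joint, deg), epsilon = epsilon,
                      constraint = constraint)
  }
  write.table(as.data.frame(est$estimate[, c("x2", "f", "reliable")]),
              o$out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sidecar(o$out, list(
    input = o$input, degradation = o$degradation, tau3 = o$tau3,
    gamma = o$gamma, epsilon = est$epsilon, model = est$model,
    constraint = constraint, cv = o$cv, seed = o$seed,
    n_samples = est$n, scale_known = est$scale_known,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("ratesnap"))))
  message(sprintf("wrote %d-state %s-model estimate to %s",
                  nrow(est$estimate), est$model, o$out))
}

run_evaluate <- function() {
  o <- parse(list(
    make_option("--estimate", type = "character"),
    make_option("--lam", type = "double", default = 80),
    make_option("--hill-n", type = "double", default = 2, dest = "hill_n"),
    make_option("--K", type = "double", default = 40),
    make_option("--marginal", type = "character", default = NA,
                help = "optional x2-marginal table (x2, p) for the error weights"),
    make_option("--samples", type = "character", default = NA,
                help = "optional snapshot table; enables the importance I"),
    make_option("--out", type = "character", default = "metrics.tsv")))
  est_tab <- read.table(o$estimate, header = TRUE, sep = "\t")
  truth <- hill_params(o$lam, o$hill_n, o$K)
  p_x2 <- if (!is.na(o$marginal)) {
    m <- read.table(o$marginal, header = TRUE, sep = "\t")
    p <- m$p[match(est_tab$x2, m$x2)]
    ifelse(is.na(p), 0, p)
  } else {
    stop("--marginal (x2, p table) is required for the error weights.",
         call. = FALSE)
  }
  err <- inference_error(est_tab[, c("x2", "f")], truth, p_x2 = p_x2)
  I <- NA_real_
  n <- NA_integer_
  if (!is.na(o$samples)) {
    s <- read_snapshots(o$samples)
    # nearest-neighbour lookup so samples outside the estimate support work
    f_fun <- function(x) {
      est_tab$f[vapply(x, function(v) which.min(abs(est_tab$x2 - v)),
                       integer(1))]
    }
    I <- importance(s, f_fun)$I
    n <- nrow(s)
  }
  write.table(data.frame(E = err$E, I = I, N = n), o$out, sep = "\t",
              quote = FALSE, row.names = FALSE)
  message(sprintf("E = %.4g, I = %.4g, N = %s", err$E, I, n))
}

run_sweep <- function() {
  o <- parse(list(
    make_option("--config", type = "character",
                help = "experiment configuration (YAML)"),
    make_option("--param", type = "character"),
    make_option("--values", type = "character",
                help = "comma-separated values"),
    make_option("--out", type = "character", default = "sweep.tsv")))
  cfg <- read_experiment_config(o$config)
  values <- strsplit(o$values, ",")[[1]]
  values <- if (!anyNA(suppressWarnings(as.numeric(values))))
    as.numeric(values) else values
  res <- sweep_experiment(cfg, o$param, values)
  write.table(as.data.frame(res), o$out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  message(sprintf("wrote %d sweep cells to %s", nrow(res), o$out))
}

switch(subcommand,
       simulate = run_simulate(),
       corrupt = run_corrupt(),
       infer = run_infer(),
       evaluate = run_evaluate(),
       sweep = run_sweep(),
       usage_stop())
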