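#' @useDynLib enerfeas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

default_q_grid <- function(n = 500, lo = 1, hi = 100) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# theta-dependent automatic grid: [0.5 Q_c, 50 d'N0], log-spaced.
auto_q_grid <- function(net, n = 200) {
  qc <- critical_supply(net)
  hi <- 50 * sum(net$d * net$N0)
  lo <- max(0.5 * qc, 1e-6 * hi)
  exp(seq(log(lo), log(hi), length.out = n))
}

write_table_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(paste0("# ", k, ": ", meta[[k]]), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Single-network analysis run
#'
#' Computes the initialization/maturation probability curve of one network
#' over a supply grid, its critical and optimal supply, and writes the
#' curve table, a regime summary and a manifest to \code{out_dir}.
#'
#' @param net an \code{energetic_network}.
#' @param out_dir output directory (created if needed).
#' @param Q supply grid; default 500 log-spaced points on [1, 100].
#' @param samples Monte Carlo samples per evaluation where needed.
#' @param seed RNG seed recorded in the manifest.
#' @return invisibly, a list with \code{curve} and \code{regimes}.
#' @export
run_single <- function(net, out_dir, Q = default_q_grid(),
                       samples = 2e4, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  curve <- probability_curve(net, Q, samples = samples)
  regimes <- optimal_supply(curve, net, refine = net$S == 2)
  meta <- list(mode = "single", network = net$id, seed = seed,
               samples = samples,
               Q_c = regimes$Q_c, Q_opt = regimes$Q_opt)
  write_table_with_meta(as.data.frame(curve),
                        file.path(out_dir, "curve.csv"), meta)
  yaml::write_yaml(meta, file.path(out_dir, "manifest.yml"))
  invisible(list(curve = curve, regimes = regimes))
}

#' Ensemble analysis run
#'
#' Generates a seeded ensemble, evaluates full-community probability
#' curves by rejection classification (fast, vectorized), aggregates them
#' by logit-space FDA, and writes per-replicate curves plus the FDA
#' summary tables.
#'
#' @param config a \code{generator_config}.
#' @param out_dir output directory.
#' @param Q supply grid.
#' @param samples rejection samples per (replicate, Q).
#' @return invisibly, list with \code{curves}, \code{fda_init},
#'   \code{fda_mat}.
#' @export
run_ensemble <- function(config, out_dir, Q = default_q_grid(100),
                         samples = 4000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nets <- generate_ensemble(config)
  curves <- lapply(nets, function(net)
    probability_curve(net, Q, method = "rejection", samples = samples))
  fda_init <- fda_aggregate(curves, value = "p_init")
  fda_mat <- fda_aggregate(curves, value = "p_mat")
  meta <- list(mode = "ensemble", S = config$S,
               replicates = config$replicates, seed = config$seed,
               samples = samples)
  for (r in seq_along(curves))
    write_table_with_meta(as.data.frame(curves[[r]]),
                          file.path(out_dir, sprintf("curve_rep%03d.csv", r)),
                          c(meta, list(replicate = r)))
  write_table_with_meta(as.data.frame(fda_init),
                        file.path(out_dir, "fda_init.csv"), meta)
  write_table_with_meta(as.data.frame(fda_mat),
                        file.path(out_dir, "fda_mat.csv"), meta)
  yaml::write_yaml(c(meta, list(
    child_seeds = attr(nets, "manifest")$child_seeds)),
    file.path(out_dir, "manifest.yml"))
  invisible(list(curves = curves, fda_init = fda_init, fda_mat = fda_mat))
}

#' Feasibility-partition analysis run
#'
#' Enumerates all candidate communities of one network, evaluates their
#' partition probabilities over a supply grid by Monte Carlo
#' classification, and writes the per-community table, the per-size
#' maturation summaries and the average-diversity curve.
#'
#' @param net an \code{energetic_network} with \code{S <= 8} (budget guard:
#'   2^S communities per grid point).
#' @param out_dir output directory.
#' @param Q supply grid.
#' @param samples classification samples per grid point.
#' @param seed RNG seed.
#' @return invisibly, list with \code{partitions} (long table),
#'   \code{by_size}, \code{diversity}.
#' @export
run_partitions <- function(net, out_dir, Q = default_q_grid(60),
                           samples = 2e4, seed = 1L) {
  if (net$S > 8)
    stop("partition runs limited to S <= 8 (", 2^net$S,
         " communities x ", length(Q), " grid points requested)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  tabs <- lapply(Q, function(q) {
    pp <- partition_probabilities(net, q, n = samples)
    pp$Q <- q
    pp
  })
  long <- do.call(rbind, tabs)
  by_size <- do.call(rbind, lapply(tabs, function(pp) {
    agg <- stats::aggregate(cbind(p_init, p_mat) ~ D, data = pp, FUN = mean)
    agg$Q <- pp$Q[1]
    agg
  }))
  div <- data.frame(Q = Q, D = vapply(tabs, function(pp)
    suppressWarnings(average_diversity(net, pp$Q[1], partition = pp)), 0))
  meta <- list(mode = "partitions", network = net$id, S = net$S,
               seed = seed, samples = samples)
  write_table_with_meta(long, file.path(out_dir, "partitions.csv"), meta)
  write_table_with_meta(by_size, file.path(out_dir, "by_size.csv"), meta)
  write_table_with_meta(div, file.path(out_dir, "diversity.csv"), meta)
  yaml::write_yaml(meta, file.path(out_dir, "manifest.yml"))
  invisible(list(partitions = long, by_size = by_size, diversity = div))
}
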