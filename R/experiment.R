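#' Configure an in-silico benchmarking experiment
#'
#' Describes one of the standard simulation designs used to benchmark the
#' replicate statistics on known ground truth:
#' \describe{
#'   \item{`"perfect"`}{pairs of disjoint equal-depth draws from one pool —
#'     faithful replicates by construction.}
#'   \item{`"duplication"`}{one draw compared against an exact copy of
#'     itself.}
#'   \item{`"depth_sweep"`}{perfect-replicate pairs at a grid of per-lane
#'     depths.}
#'   \item{`"unequal_split"`}{perfect-replicate pairs with a fixed total
#'     read count split unevenly between the lanes.}
#'   \item{`"contamination"`}{the second lane of each pair mixes reads from
#'     the main pool and a contaminant pool at a grid of fractions.}
#' }
#'
#' @param experiment one of the designs above.
#' @param depth per-lane reads for `"perfect"`, `"duplication"` and
#'   `"contamination"` (default 5e6).
#' @param depths per-lane depth grid for `"depth_sweep"`
#'   (default `c(0.5, 1, 2, 5, 10) * 1e6`).
#' @param total total reads per pair for `"unequal_split"` (default 1e7).
#' @param split_fracs first-lane share of `total` for `"unequal_split"`
#'   (default `c(.1, .3, .5, .7, .9)`, i.e. splits 1:9 through 9:1).
#' @param fractions contaminant fractions for `"contamination"`
#'   (default `c(0, .05, .1, .25, .5, .75, 1)`).
#' @param replicates independent realizations per condition (default 200).
#' @param seed master integer seed; every realization gets a deterministic
#'   sub-seed so the whole report is reproducible bit for bit.
#' @param statistics statistics to evaluate per realization, a subset of
#'   `c("sere", "pearson_r", "kappa")`.
#' @param pool optional [pool_counts()] to draw from; a synthetic pool is
#'   generated from the master seed when omitted.
#' @param contaminant_pool optional contaminant [pool_counts()]; when
#'   omitted for `"contamination"`, an independent synthetic pool (a
#'   genuinely different abundance profile) is generated.
#' @param n_bins,pool_size,sdlog,expressed_frac parameters forwarded to
#'   [make_synthetic_pool()] when pools are generated.
#' @return a validated list of class `sere_experiment_config`.
#' @seealso [run_experiment()]
#' @export
experiment_config <- function(experiment = c("perfect", "duplication",
                                             "depth_sweep", "unequal_split",
                                             "contamination"),
                              depth = 5e6,
                              depths = c(0.5, 1, 2, 5, 10) * 1e6,
                              total = 1e7,
                              split_fracs = c(.1, .3, .5, .7, .9),
                              fractions = c(0, .05, .1, .25, .5, .75, 1),
                              replicates = 200L,
                              seed = 1L,
                              statistics = c("sere", "pearson_r", "kappa"),
                              pool = NULL, contaminant_pool = NULL,
                              n_bins = 222097, pool_size = 22.9e6,
                              sdlog = 2.4, expressed_frac = 0.4) {
  experiment <- match.arg(experiment)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (depth <= 0 || total <= 0) stop("depths must be positive", call. = FALSE)
  if (any(split_fracs <= 0) || any(split_fracs >= 1))
    stop("`split_fracs` must lie strictly between 0 and 1", call. = FALSE)
  if (any(fractions < 0) || any(fractions > 1))
    stop("`fractions` must lie in [0, 1]", call. = FALSE)
  if (!is.null(pool)) stopifnot(inherits(pool, "pool_counts"))
  if (!is.null(contaminant_pool))
    stopifnot(inherits(contaminant_pool, "pool_counts"))
  structure(list(experiment = experiment, depth = depth, depths = depths,
                 total = total, split_fracs = split_fracs,
                 fractions = fractions, replicates = as.integer(replicates),
                 seed = as.integer(seed), statistics = statistics,
                 pool = pool, contaminant_pool = contaminant_pool,
                 n_bins = n_bins, pool_size = pool_size, sdlog = sdlog,
                 expressed_frac = expressed_frac),
            class = "sere_experiment_config")
}

#' Run a simulation experiment
#'
#' Executes the configured number of independent realizations per condition,
#' evaluates the requested statistics on each simulated lane pair (SERE with
#' singleton exclusion; Pearson r on log RPKM with a pseudo-count; Cohen's
#' kappa on the standard RPKM bins), and summarizes them as means and
#' empirical 0.5%/99.5% quantiles per condition.
#'
#' @param config a [experiment_config()].
#' @return an object of class `sere_sim_report` with elements `experiment`,
#'   `parameters`, `statistic_values` (one row per condition x realization),
#'   and `summary` (mean and empirical 99% range per condition and
#'   statistic).
#' @examples
#' cfg <- experiment_config("perfect", depth = 2e4, replicates = 5,
#'                          n_bins = 2000, pool_size = 2e5, seed = 7)
#' rep <- run_experiment(cfg)
#' rep$summary
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "sere_experiment_config"))
  pool <- config$pool
  if (is.null(pool))
    pool <- make_synthetic_pool(n_bins = config$n_bins,
                                pool_size = config$pool_size,
                                sdlog = config$sdlog,
                                expressed_frac = config$expressed_frac,
                                seed = derive_seed(config$seed, 0L))
  contaminant <- config$contaminant_pool
  if (config$experiment == "contamination" && is.null(contaminant))
    contaminant <- make_synthetic_pool(n_bins = length(pool$totals),
                                       pool_size = pool$pool_size,
                                       sdlog = config$sdlog,
                                       expressed_frac = config$expressed_frac,
                                       seed = derive_seed(config$seed, 1L))

  conditions <- switch(config$experiment,
    perfect = , duplication = config$depth,
    depth_sweep = config$depths,
    unequal_split = config$split_fracs,
    contamination = config$fractions)
  cond_name <- switch(config$experiment,
    perfect = , duplication = , depth_sweep = "depth",
    unequal_split = "split_frac",
    contamination = "fraction")

  rows <- vector("list", length(conditions) * config$replicates)
  idx <- 0L
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    for (r in seq_len(config$replicates)) {
      idx <- idx + 1L
      set.seed(derive_seed(config$seed, idx + 1L))
      m <- .simulate_pair(config$experiment, cond, config, pool, contaminant)
      vals <- .pair_statistics(m, config$statistics)
      rows[[idx]] <- c(stats::setNames(cond, cond_name),
                       replicate = r, vals)
    }
  }
  values <- as.data.frame(do.call(rbind, rows))
  summ <- do.call(rbind, lapply(split(values, values[[cond_name]]),
    function(d) {
      do.call(rbind, lapply(config$statistics, function(s) {
        v <- d[[s]]
        data.frame(condition = d[[cond_name]][1L], statistic = s,
                   mean = mean(v),
                   q005 = unname(stats::quantile(v, 0.005, type = 7)),
                   q995 = unname(stats::quantile(v, 0.995, type = 7)))
      }))
    }))
  rownames(summ) <- NULL
  structure(list(experiment = config$experiment,
                 parameters = list(conditions = conditions,
                                   condition = cond_name,
                                   replicates = config$replicates,
                                   seed = config$seed,
                                   statistics = config$statistics,
                                   pool_size = pool$pool_size,
                                   n_bins = length(pool$totals)),
                 statistic_values = values,
                 summary = summ),
            class = "sere_sim_report")
}

# One simulated lane pair for the given design and condition value.
.simulate_pair <- function(experiment, cond, config, pool, contaminant) {
  switch(experiment,
    perfect = split_perfect_replicates(pool, c(cond, cond)),
    depth_sweep = split_perfect_replicates(pool, c(cond, cond)),
    unequal_split = split_perfect_replicates(
      pool, c(round(cond * config$total),
              config$total - round(cond * config$total))),
    duplication = {
      lane <- draw_sample(pool, cond)
      count_matrix(cbind(lane1 = lane, lane2 = lane),
                   bin_ids = pool$bin_ids)
    },
    contamination = {
      lane1 <- draw_sample(pool, config$depth)
      rest <- pool_counts(pool$totals - lane1, bin_ids = pool$bin_ids)
      lane2 <- contaminate(rest, contaminant, config$depth, cond)
      count_matrix(cbind(lane1 = lane1, lane2 = lane2),
                   bin_ids = pool$bin_ids)
    })
}

.pair_statistics <- function(m, statistics) {
  out <- numeric(0)
  if ("sere" %in% statistics)
    out <- c(out, sere = sere_statistic(m, ci_level = NULL)$sere)
  if ("pearson_r" %in% statistics)
    out <- c(out, pearson_r = pearson_log_rpkm(m))
  if ("kappa" %in% statistics)
    out <- c(out, kappa = kappa_statistic(m))
  out
}

#' @export
print.sere_sim_report <- function(x, ...) {
  cat(sprintf("sere_sim_report: '%s' experiment, %d realizations per condition, seed %d\n",
              x$experiment, x$parameters$replicates, x$parameters$seed))
  cat(sprintf("pool: %s reads over %d bins\n",
              format(x$parameters$pool_size, big.mark = ","),
              x$parameters$n_bins))
  print(transform(x$summary, mean = round(mean, 4), q005 = round(q005, 4),
                  q995 = round(q995, 4)), row.names = FALSE)
  invisible(x)
}

#' Write a simulation report as TSV
#'
#' Writes the per-realization statistic values to `path` and, when
#' `summary_path` is given, the condition-level summary (mean and empirical
#' 0.5%/99.5% quantiles) next to it.
#'
#' @param report a `sere_sim_report` from [run_experiment()].
#' @param path output TSV for the per-realization table.
#' @param summary_path optional output TSV for the summary table.
#' @return `path`, invisibly.
#' @export
write_simulation_report <- function(report, path, summary_path = NULL) {
  stopifnot(inherits(report, "sere_sim_report"))
  utils::write.table(report$statistic_values, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.table(report$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a simulation report
#'
#' Diagnostic plot of per-condition means with the empirical 99% band, one
#' panel per statistic.
#'
#' @param x a `sere_sim_report`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sere_sim_report <- function(x, ...) {
  stats_used <- x$parameters$statistics
  old <- graphics::par(mfrow = c(1, length(stats_used)))
  on.exit(graphics::par(old))
  for (s in stats_used) {
    d <- x$summary[x$summary$statistic == s, ]
    graphics::plot(d$condition, d$mean, type = "b", pch = 19,
                   ylim = range(d$q005, d$q995),
                   xlab = x$parameters$condition, ylab = s,
                   main = sprintf("%s (%s)", s, x$experiment), ...)
    graphics::arrows(d$condition, d$q005, d$condition, d$q995,
                     angle = 90, code = 3, length = 0.03,
                     col = "grey40")
  }
  invisible(x)
}
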