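#' Read pools for in-silico experiments
#'
#' A pool holds the per-bin totals of a universal set of mapped reads from
#' which simulated lanes are drawn. Drawing reads without replacement from a
#' pool of counted reads is exactly a multivariate hypergeometric draw on
#' the per-bin totals, so no read-level files are needed.
#'
#' @param totals non-negative integer vector of reads available per bin.
#' @param bin_ids unique bin identifiers; defaults to `names(totals)` or
#'   generated ids.
#' @return an object of class `pool_counts` with elements `bin_ids`,
#'   `totals`, and `pool_size`.
#' @export
pool_counts <- function(totals, bin_ids = names(totals)) {
  totals <- as.numeric(totals)
  if (any(!is.finite(totals)) || any(totals < 0) ||
      any(totals != round(totals)))
    stop("pool totals must be non-negative integers", call. = FALSE)
  if (sum(totals) <= 0) stop("pool is empty", call. = FALSE)
  if (is.null(bin_ids)) bin_ids <- sprintf("bin%06d", seq_along(totals))
  if (length(bin_ids) != length(totals) || anyDuplicated(bin_ids))
    stop("`bin_ids` must be unique and parallel to `totals`", call. = FALSE)
  structure(list(bin_ids = as.character(bin_ids), totals = totals,
                 pool_size = sum(totals)),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts: %s reads over %d bins (%d with reads)\n",
              format(x$pool_size, big.mark = ","), length(x$totals),
              sum(x$totals > 0)))
  invisible(x)
}

#' Synthetic universal read pool
#'
#' Generates a pool emulating a deeply skewed exon-level count profile: a
#' fraction `expressed_frac` of bins carries log-normal abundances, the rest
#' is unexpressed, and `pool_size` reads are allocated multinomially. With
#' the defaults a 5.5-million-read subsample shows roughly 55% of observed
#' bins at a count of 10 or less and a maximum count of order 1e5, matching
#' the regime of real exon tables at that depth.
#'
#' @param n_bins number of bins (default 222097, a genome-wide merged-exon
#'   count).
#' @param pool_size total reads in the pool (default 2.29e7).
#' @param meanlog,sdlog log-normal abundance parameters (defaults 0 and
#'   2.4; `meanlog` is immaterial up to scale).
#' @param expressed_frac fraction of bins with nonzero abundance
#'   (default 0.4).
#' @param abundance optional vector of relative bin abundances; when given
#'   it overrides the log-normal model, so several pools of distinct reads
#'   can share one underlying expression profile.
#' @param seed optional integer seed; given the same seed the pool is
#'   reproduced exactly.
#' @return a [pool_counts()] object.
#' @examples
#' p <- make_synthetic_pool(n_bins = 1000, pool_size = 1e5, seed = 1)
#' identical(p, make_synthetic_pool(n_bins = 1000, pool_size = 1e5, seed = 1))
#' @export
make_synthetic_pool <- function(n_bins = 222097, pool_size = 22.9e6,
                                meanlog = 0, sdlog = 2.4,
                                expressed_frac = 0.4, abundance = NULL,
                                seed = NULL) {
  if (n_bins < 1 || pool_size < 1)
    stop("`n_bins` and `pool_size` must be at least 1", call. = FALSE)
  if (sdlog < 0 || expressed_frac <= 0 || expressed_frac > 1)
    stop("invalid skew parameters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(abundance)) {
    abundance <- stats::rlnorm(n_bins, meanlog = meanlog, sdlog = sdlog)
    if (expressed_frac < 1)
      abundance <- abundance * stats::rbinom(n_bins, 1L, expressed_frac)
  } else {
    if (length(abundance) != n_bins || any(abundance < 0))
      stop("`abundance` must be non-negative with one entry per bin",
           call. = FALSE)
  }
  if (sum(abundance) <= 0) abundance[1L] <- 1  # degenerate tiny case
  totals <- as.numeric(stats::rmultinom(1L, size = pool_size,
                                        prob = abundance))
  pool_counts(totals, bin_ids = sprintf("bin%06d", seq_len(n_bins)))
}

#' Pool the reads of selected lanes
#'
#' Combines the counts of the selected lanes of an empirical table into a
#' universal pool (per-bin totals add across lanes).
#'
#' @param x a [count_matrix()].
#' @param lanes lane ids to combine; default all lanes.
#' @return a [pool_counts()] object over the matrix's bins.
#' @export
pool_from_lanes <- function(x, lanes = lane_ids(x)) {
  stopifnot(inherits(x, "count_matrix"))
  x <- select_lanes(x, lanes)
  pool_counts(rowSums(x$counts), bin_ids = bin_ids(x))
}

# Exact multivariate hypergeometric draw of k reads from per-bin totals,
# via binary splitting: the draw allocated to a group of bins splits
# between its two halves as a univariate hypergeometric, recursively down
# to single bins. All levels are vectorized rhyper calls, so the cost is
# O(n_bins) regardless of k.
rmvhyper <- function(totals, k) {
  n <- length(totals)
  k <- as.numeric(k)
  if (k == 0) return(integer(n))
  if (k > sum(totals))
    stop("cannot draw ", format(k, scientific = FALSE),
         " reads without replacement from a pool of ",
         format(sum(totals), scientific = FALSE), call. = FALSE)
  depth <- ceiling(log2(max(n, 2)))
  tot <- c(as.numeric(totals), numeric(2L^depth - n))
  sums <- vector("list", depth + 1L)
  sums[[depth + 1L]] <- tot
  for (d in depth:1) {
    s <- sums[[d + 1L]]
    sums[[d]] <- s[seq.int(1L, length(s), 2L)] + s[seq.int(2L, length(s), 2L)]
  }
  kk <- k
  for (d in seq_len(depth)) {
    s <- sums[[d + 1L]]
    left <- s[seq.int(1L, length(s), 2L)]
    right <- s[seq.int(2L, length(s), 2L)]
    xl <- numeric(length(left))
    todo <- which(kk > 0)
    if (length(todo)) {
      kt <- kk[todo]; lt <- left[todo]; rt <- right[todo]
      xt <- numeric(length(todo))
      rnd <- which(lt > 0 & rt > 0)
      if (length(rnd))
        xt[rnd] <- stats::rhyper(length(rnd), lt[rnd], rt[rnd], kt[rnd])
      xt[rt == 0] <- kt[rt == 0]  # right half empty: everything goes left
      xl[todo] <- xt
    }
    kk2 <- numeric(2L * length(left))
    kk2[seq.int(1L, length(kk2), 2L)] <- xl
    kk2[seq.int(2L, length(kk2), 2L)] <- kk - xl
    kk <- kk2
  }
  as.integer(kk[seq_len(n)])
}

#' Draw a simulated lane from a pool
#'
#' Without replacement (the default, mirroring random splitting of real
#' reads) the counts follow the multivariate hypergeometric distribution on
#' the pool totals; with replacement they are multinomial on the pool
#' proportions (pure-Poisson theory mode). The drawn counts always sum to
#' `n_reads` exactly.
#'
#' @param pool a [pool_counts()].
#' @param n_reads number of reads to draw.
#' @param seed optional integer seed.
#' @param replacement draw with replacement (default `FALSE`).
#' @return integer vector of counts, parallel to `pool$bin_ids`.
#' @examples
#' p <- pool_counts(c(a = 5, b = 0, c = 10, d = 3, e = 7))
#' sum(draw_sample(p, 8, seed = 1))  # 8
#' @export
draw_sample <- function(pool, n_reads, seed = NULL, replacement = FALSE) {
  stopifnot(inherits(pool, "pool_counts"))
  if (n_reads < 0) stop("`n_reads` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (replacement) {
    as.integer(stats::rmultinom(1L, size = n_reads,
                                prob = pool$totals / pool$pool_size))
  } else {
    if (n_reads > pool$pool_size)
      stop("cannot draw ", format(n_reads, scientific = FALSE),
           " reads without replacement from a pool of ",
           format(pool$pool_size, scientific = FALSE), call. = FALSE)
    rmvhyper(pool$totals, n_reads)
  }
}

#' Split a pool into perfect in-silico replicates
#'
#' Sequential draws without replacement from the shrinking pool: the lanes
#' are disjoint subsets of the pool's reads and differ from each other only
#' by the stochasticity of the sampling, i.e., they are perfect replicates
#' affected by Poisson-type variation only. Unequal `sizes` emulate
#' multiplexed samples with different yields.
#'
#' @param pool a [pool_counts()].
#' @param sizes vector of per-lane read counts; their sum must not exceed
#'   the pool size (ignored in independent mode, where each lane only needs
#'   to fit the pool on its own).
#' @param seed optional integer seed.
#' @param disjoint draw the lanes sequentially without replacement from the
#'   shrinking pool (default); if `FALSE`, lanes are independent draws from
#'   the full pool.
#' @return a [count_matrix()] with the pool's bins and one lane per size.
#' @examples
#' p <- make_synthetic_pool(n_bins = 500, pool_size = 5e4, seed = 1)
#' m <- split_perfect_replicates(p, c(1e4, 1e4), seed = 2)
#' lane_totals(m)
#' @export
split_perfect_replicates <- function(pool, sizes, seed = NULL,
                                     disjoint = TRUE) {
  stopifnot(inherits(pool, "pool_counts"))
  sizes <- as.numeric(sizes)
  if (length(sizes) < 1L || any(sizes < 0))
    stop("`sizes` must be non-negative read counts", call. = FALSE)
  if (disjoint && sum(sizes) > pool$pool_size)
    stop("requested lanes exceed the pool size", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(pool$totals)
  counts <- matrix(0L, n, length(sizes),
                   dimnames = list(pool$bin_ids,
                                   sprintf("lane%d", seq_along(sizes))))
  remaining <- pool$totals
  for (j in seq_along(sizes)) {
    lane <- rmvhyper(if (disjoint) remaining else pool$totals, sizes[j])
    if (disjoint) remaining <- remaining - lane
    counts[, j] <- lane
  }
  count_matrix(counts)
}

#' Contaminate a simulated lane with reads from another pool
#'
#' Builds one lane of `n_reads` in which a fraction of the reads originates
#' from a contaminant pool: `round(fraction * n_reads)` reads are drawn from
#' `pool_contaminant` and the remainder from `pool_main` (both without
#' replacement), so the total is preserved exactly.
#'
#' @param pool_main,pool_contaminant [pool_counts()] objects over the same
#'   bins.
#' @param n_reads lane size.
#' @param fraction contaminant fraction in \[0, 1\].
#' @param seed optional integer seed.
#' @return integer vector of counts, parallel to the pools' bins.
#' @export
contaminate <- function(pool_main, pool_contaminant, n_reads, fraction,
                        seed = NULL) {
  stopifnot(inherits(pool_main, "pool_counts"),
            inherits(pool_contaminant, "pool_counts"))
  if (length(pool_main$totals) != length(pool_contaminant$totals))
    stop("pools must cover the same bins", call. = FALSE)
  if (fraction < 0 || fraction > 1)
    stop("`fraction` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_cont <- round(fraction * n_reads)
  n_main <- n_reads - n_cont
  draw_sample(pool_main, n_main) + draw_sample(pool_contaminant, n_cont)
}

# Deterministic per-realization seed derivation from one master seed, kept
# below 2^31 so downstream set.seed() always accepts it.
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483587 * 48271 + i * 16807) %%
               2147483587) + 1L
}
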