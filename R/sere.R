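#' Expected counts under the technical-replicate (Poisson) model
#'
#' If the lanes are simple technical replicates, the count of bin i in lane
#' j is Poisson with mean proportional to both the bin abundance and the
#' lane depth; the maximum-likelihood estimate of that mean from the table
#' margins is \deqn{\hat y_{ij} = E_i L_j / T,} where \eqn{E_i} is the bin
#' total, \eqn{L_j} the lane total and \eqn{T} the grand total. Row sums of
#' the result equal \eqn{E_i} and column sums equal \eqn{L_j}.
#'
#' @param x a [count_matrix()], normally already stripped of all-zero bins
#'   (see [drop_uninformative_bins()]).
#' @return a numeric matrix of the same shape as `x$counts`.
#' @examples
#' m <- count_matrix(rbind(c(10, 6), c(4, 8)))
#' expected_counts(m)  # rows (8, 8) and (6, 6)
#' @export
expected_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  tot <- grand_total(x)
  if (tot <= 0)
    stop("cannot compute expected counts: grand total is 0", call. = FALSE)
  outer(bin_totals(x), lane_totals(x)) / tot
}

#' Per-bin Poisson overdispersion
#'
#' The per-bin dispersion compares the observed squared deviation from the
#' replicate-model expectation with the Poisson variance:
#' \deqn{s_i^2 = \frac{1}{M-1} \sum_j \frac{(y_{ij} - \hat y_{ij})^2}{\hat y_{ij}},}
#' with \eqn{M-1} degrees of freedom per bin because the deviations sum to
#' zero within each bin. A value of 1 is what pure Poisson sampling noise
#' produces; 0 means the lanes agree exactly; values above 1 indicate excess
#' (biological or technical) variation. A singleton bin (\eqn{E_i = 1})
#' always yields \eqn{s_i^2 = 1} when lane totals are equal.
#'
#' @param x a [count_matrix()] with at least 2 lanes, no all-zero bins and
#'   no empty lanes.
#' @return a named non-negative numeric vector, one entry per bin.
#' @examples
#' m <- count_matrix(rbind(c(10, 6), c(4, 8)))
#' bin_dispersions(m)  # 1 and 4/3
#' @export
bin_dispersions <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (n_lanes(x) < 2L)
    stop("at least 2 lanes are required", call. = FALSE)
  L <- lane_totals(x)
  if (any(L == 0))
    stop("lane '", lane_ids(x)[L == 0][1L],
         "' has zero total reads; empty lanes signal an upstream error",
         call. = FALSE)
  if (any(bin_totals(x) == 0))
    stop("matrix contains all-zero bins; apply drop_uninformative_bins() first",
         call. = FALSE)
  yhat <- expected_counts(x)
  rowSums((x$counts - yhat)^2 / yhat) / (n_lanes(x) - 1L)
}

#' Simple Error Ratio Estimate (SERE)
#'
#' Aggregates the per-bin dispersions ([bin_dispersions()]) into a single
#' quality statistic: \eqn{s^2} is the mean of \eqn{s_i^2} over the retained
#' bins and \eqn{SERE = s = \sqrt{s^2}}. SERE is 1 for faithful replicates
#' (Poisson sampling noise only), 0 for a dataset compared against an exact
#' copy of itself (duplication / extreme underdispersion), and grows above 1
#' with genuine global differences between the lanes (overdispersion).
#'
#' All-zero bins are always excluded. Because singletons contribute exactly
#' 1 regardless of sample similarity, bins with \eqn{E_i = 1} are also
#' excluded by default; with `exclude_singletons = TRUE` the retained bin
#' set, its margins, and the divisor of the average all refer to the
#' non-singleton informative bins, so appending singleton bins to a matrix
#' leaves the statistic exactly unchanged.
#'
#' @param x a [count_matrix()] with M >= 2 lanes, raw integer counts.
#' @param exclude_singletons drop bins with a total count of 1 across the
#'   compared lanes (default `TRUE`).
#' @param ci_level confidence level for the reported interval
#'   (default 0.99); set to `NULL` to skip the interval.
#' @param ci_mode interval construction, see [sere_confidence_interval()].
#' @return an object of class `sere_result` with elements
#'   `per_bin_dispersion`, `n_used`, `n_singletons_excluded`, `m_lanes`,
#'   `s_squared`, `sere`, `dof` (\eqn{\nu = n_{used}(M-1)}), `ci_level`,
#'   `ci_lower`, `ci_upper`, `ci_mode`.
#' @examples
#' m <- count_matrix(rbind(c(10, 6), c(4, 8)))
#' res <- sere_statistic(m)
#' res$sere  # sqrt(7/6)
#' @references The per-bin ratio is the classical Pearson overdispersion
#'   measure for Poisson models (McCullagh & Nelder, Generalized Linear
#'   Models).
#' @export
sere_statistic <- function(x, exclude_singletons = TRUE, ci_level = 0.99,
                           ci_mode = c("noncentral", "null")) {
  stopifnot(inherits(x, "count_matrix"))
  ci_mode <- match.arg(ci_mode)
  if (n_lanes(x) < 2L)
    stop("SERE requires at least 2 lanes", call. = FALSE)
  L0 <- lane_totals(x)
  if (any(L0 == 0))
    stop("lane '", lane_ids(x)[L0 == 0][1L],
         "' has zero total reads; empty lanes signal an upstream error",
         call. = FALSE)
  x <- drop_uninformative_bins(x)
  n_singletons <- sum(singleton_mask(x))
  n_excluded <- 0L
  if (exclude_singletons && n_singletons > 0L) {
    keep <- !singleton_mask(x)
    x <- count_matrix(x$counts[keep, , drop = FALSE],
                      bin_ids = bin_ids(x)[keep], lane_ids = lane_ids(x),
                      bin_lengths = if (is.null(x$bin_lengths)) NULL else
                        x$bin_lengths[keep])
    n_excluded <- n_singletons
  }
  if (n_bins(x) == 0L)
    stop("no informative bins remain after filtering; nothing to compare",
         call. = FALSE)
  if (any(lane_totals(x) == 0))
    stop("a lane has no reads left after filtering; lanes are not comparable",
         call. = FALSE)
  disp <- bin_dispersions(x)
  s2 <- mean(disp)
  dof <- n_bins(x) * (n_lanes(x) - 1L)
  res <- structure(list(per_bin_dispersion = disp,
                        n_used = n_bins(x),
                        n_singletons_excluded = n_excluded,
                        m_lanes = n_lanes(x),
                        s_squared = s2,
                        sere = sqrt(s2),
                        dof = dof,
                        ci_level = NA_real_,
                        ci_lower = NA_real_,
                        ci_upper = NA_real_,
                        ci_mode = ci_mode),
                   class = "sere_result")
  if (!is.null(ci_level)) {
    ci <- sere_confidence_interval(res, level = ci_level, mode = ci_mode)
    res$ci_level <- ci_level
    res$ci_lower <- ci[[1L]]
    res$ci_upper <- ci[[2L]]
  }
  res
}

#' Confidence interval for SERE
#'
#' Under the null hypothesis of faithful replication,
#' \eqn{\nu s^2} with \eqn{\nu = n_{used}(M-1)} follows a chi-squared
#' distribution with \eqn{\nu} degrees of freedom; under global differences
#' it is noncentral chi-squared with noncentrality
#' \eqn{\lambda = \sum_j L_j^2 (p_{ij} - \bar p_i)^2} accumulated over bins,
#' where \eqn{p_{ij}} is the true fraction of bin i within lane j and
#' \eqn{\bar p_i} its pooled value.
#'
#' Two constructions are available:
#' \describe{
#'   \item{`"noncentral"`}{test inversion on \eqn{\lambda}: the bounds are
#'     the values of \eqn{\lambda \ge 0} at which the observed \eqn{\nu s^2}
#'     sits at the outer quantiles of \eqn{\chi^2(\nu, \lambda)}, mapped to
#'     the SERE scale via \eqn{s = \sqrt{(\nu+\lambda)/\nu}} (from
#'     \eqn{E[\chi^2(\nu,\lambda)] = \nu+\lambda}). Because \eqn{\lambda} is
#'     floored at 0 this interval never falls below 1; it quantifies the
#'     overdispersion component and is not informative for underdispersed
#'     data (use the `"null"` mode there).}
#'   \item{`"null"`}{the scaled chi-square interval obtained by treating
#'     \eqn{s^2} as a dispersion factor \eqn{\phi} with
#'     \eqn{\nu s^2/\phi \sim \chi^2_\nu}; it always brackets the point
#'     estimate and shrinks at rate \eqn{O(\nu^{-1/2})}.}
#' }
#'
#' @param result a `sere_result` from [sere_statistic()].
#' @param level confidence level in (0, 1), default 0.99.
#' @param mode `"noncentral"` (default) or `"null"`.
#' @return a named numeric vector `c(lower, upper)` on the SERE scale.
#' @examples
#' res <- sere_statistic(count_matrix(rbind(c(10, 6), c(4, 8))))
#' sere_confidence_interval(res, level = 0.99, mode = "null")
#' @export
sere_confidence_interval <- function(result, level = 0.99,
                                     mode = c("noncentral", "null")) {
  stopifnot(inherits(result, "sere_result"))
  mode <- match.arg(mode)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be a probability strictly between 0 and 1",
         call. = FALSE)
  nu <- result$dof
  if (nu < 1)
    stop("confidence interval needs at least 1 degree of freedom",
         call. = FALSE)
  alpha <- 1 - level
  X <- nu * result$s_squared
  if (mode == "null") {
    lower <- sqrt(X / stats::qchisq(1 - alpha / 2, df = nu))
    upper <- sqrt(X / stats::qchisq(alpha / 2, df = nu))
    return(c(lower = lower, upper = upper))
  }
  lam_hi <- .invert_ncp(X, nu, alpha / 2)
  lam_lo <- .invert_ncp(X, nu, 1 - alpha / 2)
  c(lower = sqrt((nu + lam_lo) / nu), upper = sqrt((nu + lam_hi) / nu))
}

# Solve pchisq(X, nu, ncp = lambda) = target for lambda >= 0 (the CDF is
# strictly decreasing in lambda); returns 0 when even lambda = 0 puts X in
# the left tail below `target`. Beyond lambda ~ 1e4 the noncentral CDF in R
# loses precision, so the large-noncentrality regime uses the normal limit
# of chi-square(nu, lambda) (mean nu + lambda, variance 2(nu + 2 lambda)),
# where the two agree to well within the interval width.
.invert_ncp <- function(X, nu, target) {
  if (X - nu > 1e4) {
    z <- stats::qnorm(target)
    lam <- max(X - nu, 0)
    for (i in 1:100) {
      new <- max(X - nu - z * sqrt(2 * (nu + 2 * lam)), 0)
      if (abs(new - lam) < 1e-9 * max(1, lam)) break
      lam <- new
    }
    return(lam)
  }
  if (stats::pchisq(X, df = nu, ncp = 0) <= target) return(0)
  hi <- max(X - nu, 1)
  for (i in 1:200) {
    if (stats::pchisq(X, df = nu, ncp = hi) <= target) break
    hi <- hi * 2
  }
  stats::uniroot(function(l) stats::pchisq(X, df = nu, ncp = l) - target,
                 lower = 0, upper = hi,
                 tol = 1e-9 * max(1, hi))$root
}

#' @export
print.sere_result <- function(x, ...) {
  cat(sprintf("SERE = %.3f  (s^2 = %.4f, %d bins used, %d singleton%s excluded, M = %d lanes, dof = %d)\n",
              x$sere, x$s_squared, x$n_used, x$n_singletons_excluded,
              if (x$n_singletons_excluded == 1L) "" else "s",
              x$m_lanes, x$dof))
  if (!is.na(x$ci_level))
    cat(sprintf("%d%% CI (%s mode): [%.3f, %.3f]\n",
                round(100 * x$ci_level), x$ci_mode, x$ci_lower, x$ci_upper))
  flag <- sere_flag(x$sere)
  if (nzchar(flag)) cat("note:", flag, "\n")
  invisible(x)
}

# Advisory interpretation labels; heuristics, never hard failures.
sere_flag <- function(s) {
  if (s < 0.9) "underdispersion (possible duplication)"
  else if (s > 1.1) "overdispersion (global difference)"
  else ""
}
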