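#' RPKM transform
#'
#' Reads per kilobase of bin model per million mapped reads:
#' \deqn{RPKM_i = (y_i + c) \cdot 10^9 / (len_i \cdot L),}
#' with pseudo-count \eqn{c} (default 1 read, so that zero counts stay on
#' the log scale), bin length in base pairs and lane total \eqn{L}.
#'
#' @param counts integer vector of raw counts for one lane.
#' @param lengths positive bin lengths in base pairs. There is no implicit
#'   default: for simulated data without lengths pass
#'   `lengths = rep(1, length(counts))` (unit-length mode; values are then
#'   reads-per-million times 1000).
#' @param lane_total total mapped reads in the lane, > 0.
#' @param pseudo_count reads added to every bin before normalizing
#'   (default 1; use 0 for the Kappa binning so the zero category stays
#'   reachable).
#' @return numeric vector of RPKM values.
#' @examples
#' rpkm_transform(0, lengths = 1000, lane_total = 1e6)   # 1
#' rpkm_transform(9, lengths = 500, lane_total = 1e6)    # 20
#' @export
rpkm_transform <- function(counts, lengths = NULL, lane_total,
                           pseudo_count = 1) {
  if (is.null(lengths))
    stop("bin lengths are required for RPKM; for length-free data pass ",
         "`lengths = rep(1, length(counts))` to use unit-length mode",
         call. = FALSE)
  if (any(lengths <= 0)) stop("bin lengths must be positive", call. = FALSE)
  if (length(lane_total) != 1L || lane_total <= 0)
    stop("`lane_total` must be a single positive number", call. = FALSE)
  (counts + pseudo_count) * 1e9 / (lengths * lane_total)
}

.lengths_or_unit <- function(x) {
  if (is.null(x$bin_lengths)) rep(1, n_bins(x)) else x$bin_lengths
}

#' Pearson correlation between two lanes on a transformed scale
#'
#' The most common replicate check in the RNA-Seq literature: Pearson's
#' product-moment correlation of the two lanes after a variance-compressing
#' transform. Bins with zero counts in both lanes are excluded first. The
#' value of r is invariant to the logarithm base and any affine rescaling of
#' the transformed values.
#'
#' @param x a [count_matrix()] with exactly 2 lanes.
#' @param transform `"log-rpkm-pseudo"` (default; log RPKM with a
#'   pseudo-count of one read, unit lengths when the matrix has none),
#'   `"log-count-pseudo"` (log of count + pseudo), or `"sqrt-count"` (the
#'   variance-stabilizing transform for Poisson data).
#' @param pseudo_count pseudo-count for the log transforms, default 1.
#' @param log_base base of the logarithm (reporting only; r is unaffected).
#' @return the correlation, a number in \[-1, 1\].
#' @export
pearson_log_rpkm <- function(x,
                             transform = c("log-rpkm-pseudo",
                                           "log-count-pseudo",
                                           "sqrt-count"),
                             pseudo_count = 1, log_base = 10) {
  stopifnot(inherits(x, "count_matrix"))
  transform <- match.arg(transform)
  if (n_lanes(x) != 2L)
    stop("Pearson comparison is defined for exactly 2 lanes", call. = FALSE)
  x <- drop_uninformative_bins(x)
  if (n_bins(x) < 2L)
    stop("need at least 2 informative bins for a correlation", call. = FALSE)
  L <- lane_totals(x)
  tr <- switch(transform,
    "log-rpkm-pseudo" = {
      len <- .lengths_or_unit(x)
      cbind(log(rpkm_transform(x$counts[, 1L], len, L[1L], pseudo_count),
                base = log_base),
            log(rpkm_transform(x$counts[, 2L], len, L[2L], pseudo_count),
                base = log_base))
    },
    "log-count-pseudo" = log(x$counts + pseudo_count, base = log_base),
    "sqrt-count" = sqrt(x$counts))
  if (stats::sd(tr[, 1L]) == 0 || stats::sd(tr[, 2L]) == 0)
    stop("correlation undefined: a transformed lane has zero variance",
         call. = FALSE)
  stats::cor(tr[, 1L], tr[, 2L])
}

#' RPKM bin schemes for the Kappa statistic
#'
#' A bin scheme maps every non-negative RPKM value to exactly one of K
#' ordered categories. The convention is half-open intervals: category 1 is
#' `[0, e1]`, category k is `(e[k-1], e[k]]`, and category K is
#' `(e[K-1], Inf)`. With the default edges the first category is exactly
#' \{0\} and the printed labels follow the customary 9-bin RPKM scheme
#' (0, 1-10, 11-20, 21-40, 41-80, 80-160, 161-320, 321-1000, >1000), with
#' the touching bounds resolved as half-open intervals.
#'
#' @param edges strictly increasing numeric thresholds (K-1 of them).
#' @param labels optional K category labels; generated when omitted.
#' @return an object of class `bin_scheme` with elements `edges`, `labels`,
#'   and `k`.
#' @examples
#' assign_bins(c(0, 10, 10.5, 1e6), rpkm_bin_scheme())  # 1 2 3 9
#' @export
bin_scheme <- function(edges, labels = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 1L || is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be strictly increasing", call. = FALSE)
  k <- length(edges) + 1L
  if (is.null(labels)) {
    labels <- c(sprintf("<=%g", edges[1L]),
                sprintf("(%g,%g]", edges[-length(edges)], edges[-1L]),
                sprintf(">%g", edges[length(edges)]))
  }
  if (length(labels) != k)
    stop("`labels` must have one entry per category (", k, ")",
         call. = FALSE)
  structure(list(edges = edges, labels = as.character(labels), k = k),
            class = "bin_scheme")
}

#' @rdname bin_scheme
#' @export
rpkm_bin_scheme <- function() {
  bin_scheme(edges = c(0, 10, 20, 40, 80, 160, 320, 1000),
             labels = c("0", "1-10", "11-20", "21-40", "41-80", "80-160",
                        "161-320", "321-1000", ">1000"))
}

#' Assign RPKM values to scheme categories
#'
#' @param rpkm non-negative numeric vector.
#' @param scheme a [bin_scheme()].
#' @return integer vector of category indices in `1:scheme$k`.
#' @export
assign_bins <- function(rpkm, scheme = rpkm_bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (any(rpkm < 0)) stop("RPKM values must be non-negative", call. = FALSE)
  findInterval(rpkm, scheme$edges, left.open = TRUE) + 1L
}

#' Cross-tabulate two category vectors
#'
#' Builds the K x K agreement table for the Kappa statistic: cell (a, b)
#' counts the bins whose category is a in the first lane and b in the
#' second, so agreeing bins accumulate on the diagonal.
#'
#' @param categories_a,categories_b equal-length integer vectors of category
#'   indices in `1:k`.
#' @param k number of categories.
#' @return a `k x k` integer matrix of class `contingency_table`.
#' @export
contingency_table <- function(categories_a, categories_b, k) {
  if (length(categories_a) != length(categories_b))
    stop("category vectors must have equal length", call. = FALSE)
  a <- as.integer(categories_a); b <- as.integer(categories_b)
  if (length(a) && (min(a, b) < 1L || max(a, b) > k))
    stop("category index out of range 1..", k, call. = FALSE)
  tab <- matrix(tabulate((b - 1L) * k + a, nbins = k * k), k, k)
  structure(tab, class = c("contingency_table", "matrix"))
}

#' Cohen's simple Kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o} the diagonal fraction and chance agreement
#' \eqn{p_e = \sum_k r_k c_k / n^2} from the marginals.
#'
#' @param table a square count matrix (rows: lane-A category, columns:
#'   lane-B category), e.g. from [contingency_table()].
#' @return the kappa value in \[-1, 1\].
#' @examples
#' cohens_kappa(matrix(c(6, 2, 2, 0), 2, byrow = TRUE))  # -0.25
#' @export
cohens_kappa <- function(table) {
  tab <- unclass(as.matrix(table))
  n <- sum(tab)
  if (n <= 0) stop("empty contingency table", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1)
    stop("kappa undefined: all mass in a single category (p_e = 1)",
         call. = FALSE)
  (po - pe) / (1 - pe)
}

#' Linearly weighted Kappa
#'
#' Weighted agreement where disagreement grows with the distance from the
#' diagonal, \eqn{w_{ab} = |a-b|/(K-1)}:
#' \eqn{\kappa_w = 1 - \sum w_{ab} O_{ab} / \sum w_{ab} E_{ab}} with
#' expected cell counts \eqn{E_{ab} = r_a c_b / n}. For K = 2 the weights
#' collapse to 0/1 and \eqn{\kappa_w} equals the simple kappa.
#'
#' @inheritParams cohens_kappa
#' @param weights weighting scheme; only `"linear"` is provided.
#' @return the weighted kappa value in \[-1, 1\].
#' @export
weighted_kappa <- function(table, weights = "linear") {
  weights <- match.arg(weights)
  tab <- unclass(as.matrix(table))
  k <- nrow(tab)
  n <- sum(tab)
  if (n <= 0) stop("empty contingency table", call. = FALSE)
  w <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  e <- outer(rowSums(tab), colSums(tab)) / n
  denom <- sum(w * e)
  if (denom <= 0)
    stop("weighted kappa undefined: all mass in a single category",
         call. = FALSE)
  1 - sum(w * tab) / denom
}

#' Kappa agreement between two lanes of a count matrix
#'
#' Convenience wrapper reproducing the standard concordance workflow: drop
#' all-zero bins, normalize each lane to RPKM (no pseudo-count, so that the
#' zero category is reachable; unit lengths when the matrix carries none),
#' assign the scheme categories, cross-tabulate, and compute the (optionally
#' linearly weighted) kappa.
#'
#' @param x a [count_matrix()] with exactly 2 lanes.
#' @param scheme a [bin_scheme()]; default [rpkm_bin_scheme()].
#' @param weighted use [weighted_kappa()] instead of [cohens_kappa()].
#' @param pseudo_count pseudo-count for the RPKM transform, default 0.
#' @return the kappa value.
#' @export
kappa_statistic <- function(x, scheme = rpkm_bin_scheme(), weighted = FALSE,
                            pseudo_count = 0) {
  stopifnot(inherits(x, "count_matrix"))
  if (n_lanes(x) != 2L)
    stop("Kappa comparison is defined for exactly 2 lanes", call. = FALSE)
  x <- drop_uninformative_bins(x)
  if (n_bins(x) == 0L) stop("no informative bins to compare", call. = FALSE)
  len <- .lengths_or_unit(x)
  L <- lane_totals(x)
  ca <- assign_bins(rpkm_transform(x$counts[, 1L], len, L[1L], pseudo_count),
                    scheme)
  cb <- assign_bins(rpkm_transform(x$counts[, 2L], len, L[2L], pseudo_count),
                    scheme)
  tab <- contingency_table(ca, cb, scheme$k)
  if (weighted) weighted_kappa(tab) else cohens_kappa(tab)
}

#' Write a contingency table as TSV
#'
#' @param table a [contingency_table()].
#' @param path output file path.
#' @param labels optional category labels for header and first column.
#' @return `path`, invisibly.
#' @export
write_contingency_table <- function(table, path, labels = NULL) {
  tab <- unclass(as.matrix(table))
  if (is.null(labels)) labels <- sprintf("cat%d", seq_len(nrow(tab)))
  df <- data.frame(category = labels, tab, check.names = FALSE)
  names(df)[-1L] <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
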