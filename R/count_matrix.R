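#' Bin-by-lane read count matrix
#'
#' Container for raw RNA-Seq read counts aggregated over bins (exons, genes,
#' or any other counting unit) across sequencing lanes. All statistics in
#' this package operate on raw integer counts; normalized values (RPKM,
#' CPM, ...) are rejected because the underlying Poisson sampling model
#' applies to raw counts only.
#'
#' @param counts numeric matrix of non-negative integer counts, bins in rows
#'   and lanes in columns. Values must be whole numbers; they are stored as
#'   integers.
#' @param bin_ids character vector of unique bin identifiers, one per row.
#'   Defaults to the row names of `counts`.
#' @param lane_ids character vector of unique lane identifiers, one per
#'   column. Defaults to the column names of `counts`.
#' @param bin_lengths optional vector of positive bin lengths in base pairs,
#'   parallel to `bin_ids`; required only for RPKM-based comparators.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with `bin_ids` as row names and `lane_ids` as column
#'   names) and `bin_lengths` (numeric or `NULL`).
#' @examples
#' m <- count_matrix(rbind(a = c(10, 6), b = c(4, 8)),
#'                   lane_ids = c("lane1", "lane2"))
#' grand_total(m)
#' @seealso [read_count_table()], [sere_statistic()]
#' @export
count_matrix <- function(counts, bin_ids = rownames(counts),
                         lane_ids = colnames(counts), bin_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(bin_ids)) bin_ids <- sprintf("bin%d", seq_len(nrow(counts)))
  if (is.null(lane_ids)) lane_ids <- sprintf("lane%d", seq_len(ncol(counts)))
  bin_ids <- as.character(bin_ids)
  lane_ids <- as.character(lane_ids)
  if (length(bin_ids) != nrow(counts))
    stop("`bin_ids` must have one entry per row of `counts`", call. = FALSE)
  if (length(lane_ids) != ncol(counts))
    stop("`lane_ids` must have one entry per column of `counts`", call. = FALSE)
  if (anyDuplicated(bin_ids))
    stop("duplicate bin id: '", bin_ids[duplicated(bin_ids)][1L], "'",
         call. = FALSE)
  if (anyDuplicated(lane_ids))
    stop("duplicate lane id: '", lane_ids[duplicated(lane_ids)][1L], "'",
         call. = FALSE)
  .check_counts(counts, bin_ids, lane_ids)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(bin_ids, lane_ids)
  if (!is.null(bin_lengths)) {
    bin_lengths <- as.numeric(bin_lengths)
    if (length(bin_lengths) != nrow(counts))
      stop("`bin_lengths` must be parallel to `bin_ids`", call. = FALSE)
    if (any(!is.finite(bin_lengths)) || any(bin_lengths <= 0))
      stop("`bin_lengths` must be positive", call. = FALSE)
    names(bin_lengths) <- bin_ids
  }
  structure(list(counts = counts, bin_lengths = bin_lengths),
            class = "count_matrix")
}

# Validate raw counts, reporting the first offending cell by bin and lane id.
.check_counts <- function(counts, bin_ids, lane_ids) {
  if (!is.numeric(counts))
    stop("counts must be numeric", call. = FALSE)
  bad <- !is.finite(counts) | counts < 0 | counts != round(counts)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid count '%s' for bin '%s' in lane '%s' (counts must be non-negative integers)",
                 format(counts[idx[1L], idx[2L]]),
                 bin_ids[idx[1L]], lane_ids[idx[2L]]), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d bins x %d lanes, %s reads total%s\n",
              n_bins(x), n_lanes(x), format(grand_total(x), big.mark = ","),
              if (is.null(x$bin_lengths)) "" else ", with bin lengths"))
  cat("lanes:", paste(utils::head(lane_ids(x), 8), collapse = ", "),
      if (n_lanes(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Count matrix accessors
#'
#' Marginal totals and dimensions of a [count_matrix()]: per-lane totals
#' \eqn{L_j = \sum_i y_{ij}}, per-bin totals \eqn{E_i = \sum_j y_{ij}}, grand
#' total \eqn{T}, and the numbers of bins (N) and lanes (M). Totals are
#' returned as doubles so that downstream products do not overflow.
#'
#' @param x a `count_matrix`.
#' @return `lane_totals()` and `bin_totals()` return named numeric vectors;
#'   `grand_total()`, `n_bins()`, and `n_lanes()` return single numbers;
#'   `lane_ids()` and `bin_ids()` return character vectors.
#' @examples
#' m <- count_matrix(rbind(c(1, 0), c(5, 7)))
#' sum(lane_totals(m)) == grand_total(m)
#' @name count_matrix-accessors
NULL

#' @rdname count_matrix-accessors
#' @export
lane_totals <- function(x) colSums(x$counts)

#' @rdname count_matrix-accessors
#' @export
bin_totals <- function(x) rowSums(x$counts)

#' @rdname count_matrix-accessors
#' @export
grand_total <- function(x) sum(as.numeric(x$counts))

#' @rdname count_matrix-accessors
#' @export
n_bins <- function(x) nrow(x$counts)

#' @rdname count_matrix-accessors
#' @export
n_lanes <- function(x) ncol(x$counts)

#' @rdname count_matrix-accessors
#' @export
lane_ids <- function(x) colnames(x$counts)

#' @rdname count_matrix-accessors
#' @export
bin_ids <- function(x) rownames(x$counts)

#' Subset lanes of a count matrix
#'
#' Returns the column subset of the matrix in the requested order, leaving
#' the bin set untouched. Used, e.g., to restrict a multi-lane table to the
#' technical replicates of one sample before a pairwise comparison.
#'
#' @param x a [count_matrix()].
#' @param lanes character vector of lane ids to keep, in the desired order.
#' @return a `count_matrix` with the requested lanes.
#' @examples
#' m <- count_matrix(cbind(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
#' n_lanes(select_lanes(m, c("c", "a")))
#' @export
select_lanes <- function(x, lanes) {
  lanes <- as.character(lanes)
  missing <- setdiff(lanes, lane_ids(x))
  if (length(missing))
    stop("unknown lane id: '", missing[1L], "'", call. = FALSE)
  if (length(lanes) < 1L)
    stop("at least one lane must be selected", call. = FALSE)
  count_matrix(x$counts[, lanes, drop = FALSE],
               bin_ids = bin_ids(x), lane_ids = lanes,
               bin_lengths = x$bin_lengths)
}

#' Drop bins with no reads in any compared lane
#'
#' A bin whose count is zero in every lane of the comparison carries no
#' information about replicate agreement and is excluded before computing
#' SERE, Pearson's r, or Kappa. Lane totals are unaffected.
#'
#' @param x a [count_matrix()].
#' @return a `count_matrix` containing exactly the bins with
#'   \eqn{E_i > 0}; possibly zero bins.
#' @examples
#' m <- count_matrix(rbind(c(0, 0), c(1, 0), c(5, 7)))
#' n_bins(drop_uninformative_bins(m))  # 2
#' @export
drop_uninformative_bins <- function(x) {
  keep <- bin_totals(x) > 0
  if (all(keep)) return(x)
  count_matrix(x$counts[keep, , drop = FALSE],
               bin_ids = bin_ids(x)[keep], lane_ids = lane_ids(x),
               bin_lengths = if (is.null(x$bin_lengths)) NULL else
                 x$bin_lengths[keep])
}

#' Flag singleton bins
#'
#' A singleton is a bin covered by exactly one read across all compared
#' lanes (\eqn{E_i = 1}). For a singleton the per-bin dispersion equals 1
#' regardless of whether the lanes agree, so singletons pull the aggregate
#' SERE towards 1 and are excluded from the average by default.
#'
#' @param x a [count_matrix()].
#' @return a named logical vector over bins, `TRUE` where \eqn{E_i = 1}.
#' @examples
#' m <- count_matrix(rbind(c(1, 0), c(0, 1), c(1, 1), c(2, 0)))
#' singleton_mask(m)
#' @export
singleton_mask <- function(x) bin_totals(x) == 1
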