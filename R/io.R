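#' Read a tab-separated count table
#'
#' Parses a master read-count file: UTF-8, tab-delimited, header row
#' required. The first column holds the bin identifier; an optional column
#' named `length` holds bin lengths in base pairs; every remaining column
#' (or those named in `lane_columns`) is a lane of non-negative integer
#' counts. `length` is the single reserved non-lane column name.
#'
#' @param path path to the TSV file.
#' @param lane_columns optional character vector naming the count columns to
#'   load (in that order); by default all non-reserved columns are used.
#' @return a [count_matrix()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("bin_id\tlane1\tlane2", "ex1\t10\t6", "ex2\t4\t8"), f)
#' read_count_table(f)
#' @export
read_count_table <- function(path, lane_columns = NULL) {
  if (!file.exists(path))
    stop("count table not found: '", path, "'", call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L)
    stop("count table needs a bin-id column and at least one count column",
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate bin id in '", path, "': '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  other <- names(df)[-1L]
  lengths <- NULL
  if ("length" %in% other) {
    lengths <- df[["length"]]
    other <- setdiff(other, "length")
  }
  if (is.null(lane_columns)) lane_columns <- other
  missing <- setdiff(lane_columns, names(df))
  if (length(missing))
    stop("lane column '", missing[1L], "' not present in '", path, "'",
         call. = FALSE)
  if (length(lane_columns) < 2L)
    stop("fewer than 2 lane columns selected; a count table must provide at least two lanes",
         call. = FALSE)
  counts <- matrix(0L, nrow(df), length(lane_columns),
                   dimnames = list(ids, lane_columns))
  for (col in lane_columns) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.finite(vn))
      if (length(bad))
        stop(sprintf("malformed count '%s' for bin '%s' in column '%s' of '%s'",
                     v[bad[1L]], ids[bad[1L]], col, path), call. = FALSE)
      v <- vn
    }
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("invalid count '%s' for bin '%s' in column '%s' of '%s' (counts must be non-negative integers)",
                   format(v[bad[1L]]), ids[bad[1L]], col, path), call. = FALSE)
    counts[, col] <- as.integer(v)
  }
  count_matrix(counts, bin_ids = ids, lane_ids = lane_columns,
               bin_lengths = lengths)
}

#' Write a count matrix as a tab-separated table
#'
#' Inverse of [read_count_table()]: writes a header row, the bin-id column
#' (named `bin_id`), a `length` column when bin lengths are present, and one
#' column per lane. Reading the file back reproduces the matrix exactly.
#'
#' @param x a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  header <- c("bin_id",
              if (!is.null(x$bin_lengths)) "length",
              lane_ids(x))
  cols <- list(bin_ids(x))
  if (!is.null(x$bin_lengths))
    cols <- c(cols, list(format(x$bin_lengths, trim = TRUE,
                                scientific = FALSE)))
  for (j in seq_len(n_lanes(x))) cols <- c(cols, list(x$counts[, j]))
  lines <- c(paste(header, collapse = "\t"),
             if (n_bins(x) > 0) do.call(paste, c(cols, sep = "\t")))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
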