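#' Pairwise SERE matrix
#'
#' Computes the SERE statistic for every pair of lanes. Zero-bin and (if
#' requested) singleton filtering are re-applied within each pair, matching
#' the pairwise definition of the statistic; the multi-lane statistic from
#' [sere_statistic()] instead filters over the full lane set. The diagonal
#' is 0 by convention (a lane compared with itself is a duplication).
#'
#' @param x a [count_matrix()] with M >= 2 lanes.
#' @param exclude_singletons passed to [sere_statistic()].
#' @return an object of class `sere_matrix`: a symmetric numeric matrix of
#'   pairwise SERE values with lane ids as dimnames.
#' @examples
#' m <- count_matrix(cbind(a = c(10, 4), b = c(6, 8), c = c(10, 4)))
#' pairwise_sere(m)["a", "c"]  # 0: identical columns
#' @export
pairwise_sere <- function(x, exclude_singletons = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  m <- n_lanes(x)
  if (m < 2L) stop("pairwise SERE requires at least 2 lanes", call. = FALSE)
  ids <- lane_ids(x)
  vals <- matrix(0, m, m, dimnames = list(ids, ids))
  for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
    s <- sere_statistic(select_lanes(x, ids[c(a, b)]),
                        exclude_singletons = exclude_singletons,
                        ci_level = NULL)$sere
    vals[a, b] <- vals[b, a] <- s
  }
  structure(vals, class = c("sere_matrix", "matrix"))
}

#' @export
print.sere_matrix <- function(x, ...) {
  cat("pairwise SERE matrix (", nrow(x), " lanes):\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Write a pairwise SERE matrix as TSV
#'
#' @param x a `sere_matrix` from [pairwise_sere()].
#' @param path output file path; lane ids appear as the header row and the
#'   first column.
#' @return `path`, invisibly.
#' @export
write_sere_matrix <- function(x, path) {
  df <- data.frame(lane = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cluster lanes by excess dispersion
#'
#' Hierarchical clustering of lanes with the pairwise SERE matrix as the
#' dissimilarity: duplicated lanes merge at height 0, technical replicates
#' near 1, and globally different samples at larger heights, so the tree
#' reads as a map of excess dispersion. Average linkage is the default; all
#' three classical monotone linkages are available.
#'
#' @param x a [count_matrix()] with M >= 3 lanes.
#' @param linkage agglomeration method for [stats::hclust()].
#' @param exclude_singletons passed to [pairwise_sere()].
#' @return an object of class [stats::hclust].
#' @seealso [sere_newick()] for Newick export.
#' @export
sere_cluster <- function(x, linkage = c("average", "single", "complete"),
                         exclude_singletons = TRUE) {
  linkage <- match.arg(linkage)
  if (n_lanes(x) < 3L)
    stop("clustering requires at least 3 lanes", call. = FALSE)
  d <- stats::as.dist(unclass(pairwise_sere(
    x, exclude_singletons = exclude_singletons)))
  stats::hclust(d, method = linkage)
}

#' Export a lane dendrogram as Newick text
#'
#' @param tree an [stats::hclust] object, e.g. from [sere_cluster()].
#' @param path optional file path; when given the tree is written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
sere_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  txt <- ape::write.tree(ape::as.phylo(tree))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
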