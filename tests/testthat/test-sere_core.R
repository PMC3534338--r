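test_that("expected counts follow the margin product and preserve margins", {
  m <- count_matrix(rbind(c(10, 6), c(4, 8)))
  yhat <- expected_counts(m)
  expect_equal(unname(yhat), rbind(c(8, 8), c(6, 6)))
  set.seed(21)
  for (rep in 1:10) {
    mm <- count_matrix(rand_count_matrix(6, 3))
    yh <- expected_counts(mm)
    expect_equal(unname(rowSums(yh)), unname(bin_totals(mm)))
    expect_equal(unname(colSums(yh)), unname(lane_totals(mm)))
  }
  # equal lane totals split each bin evenly
  m2 <- count_matrix(rbind(c(3, 1), c(1, 3)))
  expect_equal(unname(expected_counts(m2)[, 1]),
               unname(bin_totals(m2)) / 2)
  # duplicated lane: margins force yhat = y
  dup <- count_matrix(cbind(a = c(2, 5), b = c(2, 5)))
  expect_equal(unname(expected_counts(dup)), unname(dup$counts) * 1.0)
  expect_error(expected_counts(count_matrix(matrix(0L, 2, 2))),
               "grand total is 0")
})

test_that("per-bin dispersions match hand values and contract cases", {
  m <- count_matrix(rbind(c(10, 6), c(4, 8)))
  expect_equal(unname(bin_dispersions(m)), c(1, 4 / 3))
  # singleton with equal lane totals is exactly 1
  s <- count_matrix(rbind(c(1, 0), c(3, 4)))
  expect_equal(unname(bin_dispersions(s))[1], 1)
  # duplicated lanes give zero everywhere
  dup <- count_matrix(cbind(a = c(2, 5, 1), b = c(2, 5, 1)))
  expect_equal(unname(bin_dispersions(dup)), c(0, 0, 0))
  expect_error(bin_dispersions(count_matrix(rbind(c(0, 0), c(1, 2)))),
               "all-zero bins")
  expect_error(bin_dispersions(count_matrix(rbind(c(1, 0), c(2, 0)))),
               "zero total reads")
})

test_that("the aggregate statistic matches the hand-evaluated example", {
  m <- count_matrix(rbind(c(10, 6), c(4, 8)))
  res <- sere_statistic(m)
  expect_equal(res$s_squared, 7 / 6)
  expect_equal(res$sere, sqrt(7 / 6))
  expect_equal(res$n_used, 2)
  expect_equal(res$dof, 2)
  expect_equal(res$s_squared, mean(res$per_bin_dispersion))
})

test_that("duplication gives SERE exactly 0 and singletons are neutral", {
  lane <- c(5L, 0L, 3L, 1L, 10L)
  dup <- count_matrix(cbind(a = lane, b = lane))
  expect_identical(sere_statistic(dup)$sere, 0)
  base <- count_matrix(rbind(c(10, 6), c(4, 8)))
  with_singletons <- count_matrix(rbind(c(10, 6), c(4, 8),
                                        c(1, 0), c(0, 1)))
  r1 <- sere_statistic(base)
  r2 <- sere_statistic(with_singletons)
  expect_identical(r1$sere, r2$sere)
  expect_equal(r2$n_singletons_excluded, 2)
  # with exclusion off the singletons do enter the average
  r3 <- sere_statistic(with_singletons, exclude_singletons = FALSE)
  expect_equal(r3$n_used, 4)
  expect_false(identical(r3$sere, r1$sere))
})

test_that("degenerate inputs are rejected", {
  expect_error(sere_statistic(count_matrix(matrix(1L, 2, 1))), "2 lanes")
  expect_error(sere_statistic(count_matrix(rbind(c(1, 0), c(2, 0)))),
               "zero total reads")
  only_singletons <- count_matrix(rbind(c(1, 0), c(0, 1)))
  expect_error(sere_statistic(only_singletons), "no informative bins")
  res <- sere_statistic(count_matrix(rbind(c(10, 6), c(4, 8))))
  expect_error(sere_confidence_interval(res, level = 1.2), "probability")
  expect_error(sere_confidence_interval(res, level = 0), "probability")
})

test_that("null-mode intervals bracket the estimate and shrink with dof", {
  set.seed(31)
  for (rep in 1:15) {
    m <- count_matrix(rand_count_matrix(6, 3))
    res <- sere_statistic(m, ci_level = 0.99, ci_mode = "null")
    expect_lte(res$ci_lower, res$sere)
    expect_gte(res$ci_upper, res$sere)
  }
  # width scales like dof^(-1/2): compare N and 100N replicated designs
  block <- matrix(rep(c(10L, 6L, 4L, 8L), 5), ncol = 2, byrow = TRUE)
  small <- sere_statistic(count_matrix(block), ci_mode = "null")
  big <- sere_statistic(count_matrix(block[rep(1:10, 100), ]),
                        ci_mode = "null")
  ratio <- (small$ci_upper - small$ci_lower) /
    (big$ci_upper - big$ci_lower)
  # small-dof intervals are relatively wider than the asymptotic rate
  expect_gt(ratio, 7)
  expect_lt(ratio, 16)
})

test_that("noncentral intervals quantify the overdispersion component", {
  # strongly overdispersed pair: interval sits above 1 and under the
  # noncentral inversion both bounds map through (nu + lambda)/nu
  m <- count_matrix(rbind(c(100, 10), c(10, 100), c(50, 60)))
  res <- sere_statistic(m, ci_mode = "noncentral")
  expect_gt(res$sere, 1)
  expect_gte(res$ci_lower, 1)
  expect_lt(res$ci_lower, res$sere)
  expect_gt(res$ci_upper, res$sere)
  # the inversion is consistent: at the bounds the observed nu*s^2 sits at
  # the outer tail probabilities
  nu <- res$dof
  X <- nu * res$s_squared
  lam_hi <- nu * res$ci_upper^2 - nu
  expect_equal(pchisq(X, df = nu, ncp = lam_hi), 0.005, tolerance = 1e-6)
  # null data: lower bound collapses to 1 (lambda floored at zero)
  dup <- count_matrix(cbind(a = c(5L, 9L), b = c(5L, 9L)))
  resd <- sere_statistic(dup, ci_mode = "noncentral")
  expect_identical(resd$ci_lower, 1)
})

test_that("pairwise SERE is symmetric with zero diagonal and permutes", {
  m <- count_matrix(cbind(a = c(10L, 4L, 0L), b = c(6L, 8L, 2L),
                          c = c(10L, 4L, 0L)))
  pw <- pairwise_sere(m)
  expect_equal(unclass(pw), t(unclass(pw)))
  expect_equal(unname(diag(pw)), c(0, 0, 0))
  expect_identical(pw["a", "c"], 0)      # identical columns
  perm <- select_lanes(m, c("b", "c", "a"))
  pw2 <- pairwise_sere(perm)
  expect_equal(unclass(pw2), unclass(pw)[c("b", "c", "a"), c("b", "c", "a")])
  # per-pair filtering: pairwise value equals the dedicated 2-lane call
  expect_equal(pw["a", "b"],
               sere_statistic(select_lanes(m, c("a", "b")))$sere)
})

test_that("clustering merges duplicates at height zero and exports Newick", {
  m <- count_matrix(cbind(a = c(10L, 4L, 7L), b = c(6L, 8L, 2L),
                          c = c(10L, 4L, 7L)))
  tree <- sere_cluster(m)
  expect_s3_class(tree, "hclust")
  expect_equal(min(tree$height), 0)
  expect_false(is.unsorted(tree$height))   # monotone agglomeration
  nwk <- sere_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c"))
  f <- tempfile(fileext = ".nwk")
  sere_newick(tree, f)
  expect_equal(readLines(f), nwk)
  expect_error(sere_cluster(select_lanes(m, c("a", "b"))), "at least 3")
})

test_that("two-group pools cluster by group with near-unit within heights", {
  set.seed(41)
  poolA <- make_synthetic_pool(n_bins = 20000, pool_size = 4e6, seed = 51)
  poolB <- make_synthetic_pool(n_bins = 20000, pool_size = 4e6, seed = 52)
  a <- split_perfect_replicates(poolA, c(1e6, 1e6), seed = 53)
  b <- split_perfect_replicates(poolB, c(1e6, 1e6), seed = 54)
  m <- count_matrix(cbind(a1 = a$counts[, 1], a2 = a$counts[, 2],
                          b1 = b$counts[, 1], b2 = b$counts[, 2]))
  tree <- sere_cluster(m)
  merges <- tree$height
  # two within-group merges near 1, final between-group merge well above
  expect_true(all(abs(sort(merges)[1:2] - 1) < 0.05))
  expect_gt(max(merges), 1.2)
  # the first two merges join the true pairs
  first_pairs <- apply(tree$merge, 1, function(r) all(r < 0))
  groups <- list(sort(tree$labels[-tree$merge[1, ]]),
                 sort(tree$labels[-tree$merge[2, ]]))
  expect_true(all(first_pairs[1:2]))
  expect_setequal(vapply(groups, paste, "", collapse = "+"),
                  c("a1+a2", "b1+b2"))
})

test_that("sere matrix TSV export round-trips lane ids and values", {
  m <- count_matrix(cbind(a = c(10L, 4L), b = c(6L, 8L), c = c(9L, 5L)))
  pw <- pairwise_sere(m)
  f <- tempfile(fileext = ".tsv")
  write_sere_matrix(pw, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(back$lane, c("a", "b", "c"))
  expect_equal(unname(as.matrix(back[, -1])), unname(unclass(pw)))
})
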