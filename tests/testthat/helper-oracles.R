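# Independent, loop-based reference implementations used to cross-check the
# vectorized package code. Deliberately literal and slow.

oracle_sere <- function(counts, exclude_singletons = TRUE) {
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) keep[i] <- sum(counts[i, ]) > 0
  counts <- counts[keep, , drop = FALSE]
  if (exclude_singletons) {
    keep <- logical(nrow(counts))
    for (i in seq_len(nrow(counts))) keep[i] <- sum(counts[i, ]) != 1
    counts <- counts[keep, , drop = FALSE]
  }
  N <- nrow(counts); M <- ncol(counts)
  if (N == 0) return(NA_real_)
  L <- numeric(M)
  for (j in seq_len(M)) for (i in seq_len(N)) L[j] <- L[j] + counts[i, j]
  if (any(L == 0)) return(NA_real_)
  total <- sum(L)
  acc <- 0
  for (i in seq_len(N)) {
    Ei <- sum(counts[i, ])
    si2 <- 0
    for (j in seq_len(M)) {
      yhat <- Ei * L[j] / total
      si2 <- si2 + (counts[i, j] - yhat)^2 / yhat
    }
    acc <- acc + si2 / (M - 1)
  }
  sqrt(acc / N)
}

oracle_kappa <- function(tab) {
  n <- sum(tab)
  k <- nrow(tab)
  po <- 0
  for (i in seq_len(k)) po <- po + tab[i, i] / n
  pe <- 0
  for (i in seq_len(k)) {
    ri <- sum(tab[i, ]); ci <- sum(tab[, i])
    pe <- pe + (ri * ci) / n^2
  }
  (po - pe) / (1 - pe)
}

oracle_weighted_kappa <- function(tab) {
  n <- sum(tab)
  k <- nrow(tab)
  num <- den <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    w <- abs(a - b) / (k - 1)
    num <- num + w * tab[a, b]
    den <- den + w * sum(tab[a, ]) * sum(tab[, b]) / n
  }
  1 - num / den
}

# Random small count matrix; rejection-samples until both lanes have reads
# and at least one non-singleton informative bin remains.
rand_count_matrix <- function(n, m, max_count = 5L) {
  repeat {
    counts <- matrix(sample(0:max_count, n * m, replace = TRUE), n, m)
    L_ok <- all(colSums(counts) > 0)
    informative <- rowSums(counts) > 1
    if (L_ok && any(informative) &&
        all(colSums(counts[informative, , drop = FALSE]) > 0))
      return(counts)
  }
}

tmp_count_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
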