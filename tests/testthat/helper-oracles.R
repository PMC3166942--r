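# Independent brute-force oracles, deliberately written as plain double loops
# and closed-form sums so they share no code path with the package internals.

# random expression matrix with unique ids and a given missing fraction
rand_expr <- function(n_rows, n_cols, miss_frac = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_rows * n_cols, mean = 5, sd = 2), n_rows, n_cols,
              dimnames = list(sprintf("r%03d", seq_len(n_rows)),
                              sprintf("s%02d", seq_len(n_cols))))
  if (miss_frac > 0) {
    # never blank out a full row
    for (i in seq_len(n_rows)) {
      na_j <- which(runif(n_cols) < miss_frac)
      if (length(na_j) >= n_cols) na_j <- na_j[-1]
      m[i, na_j] <- NA
    }
  }
  m
}

# fewest-missing trim by explicit per-group loops
oracle_trim <- function(m, groups) {
  keep <- character(0)
  for (g in unique(groups[rownames(m)])) {
    ids <- rownames(m)[groups[rownames(m)] == g]
    miss <- sapply(ids, function(i) sum(is.na(m[i, ])))
    keep <- c(keep, ids[miss == min(miss)])
  }
  m[rownames(m) %in% keep, , drop = FALSE]
}

oracle_score <- function(x, method) {
  x_ok <- x[!is.na(x)]
  switch(method,
    MaxMean = ,
    MinMean = mean(x_ok),
    absMaxMean = ,
    absMinMean = mean(abs(x_ok)),
    maxRowVariance = if (length(x_ok) < 2) NA_real_ else {
      mu <- mean(x_ok)
      sum((x_ok - mu)^2) / (length(x_ok) - 1)
    })
}

# admissible representative rows of a (trimmed) group submatrix: extreme
# score, then highest-mean among exact ties; a random draw may pick any of
# the returned ids
oracle_representative_set <- function(sub, method) {
  scores <- sapply(rownames(sub), function(i) oracle_score(sub[i, ], method))
  minimise <- method %in% c("MinMean", "absMinMean")
  scores[is.na(scores)] <- if (minimise) Inf else -Inf
  extreme <- if (minimise) min(scores) else max(scores)
  cand <- names(scores)[scores == extreme]
  if (length(cand) > 1) {
    means <- sapply(cand, function(i) mean(sub[i, ], na.rm = TRUE))
    cand <- cand[means == max(means)]
  }
  cand
}

# Pearson correlation over complete pairs, from the raw sum formulas
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

oracle_adjacency <- function(sub, beta = 1) {
  n <- nrow(sub)
  a <- matrix(1, n, n, dimnames = list(rownames(sub), rownames(sub)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        a[i, j] <- ((1 + oracle_pearson(sub[i, ], sub[j, ])) / 2)^beta
      }
    }
  }
  a
}

oracle_connectivity <- function(a) {
  k <- numeric(nrow(a))
  names(k) <- rownames(a)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (i != j) k[i] <- k[i] + a[i, j]
    }
  }
  k
}

oracle_hub <- function(sub, beta = 1) {
  k <- oracle_connectivity(oracle_adjacency(sub, beta))
  names(k)[which(k == max(k))[1]]   # first maximal row
}

# upper-tail hypergeometric by enumerating draws grouped by overlap count
oracle_hyper_p <- function(k, K, M, N) {
  js <- seq(from = k, to = min(K, M))
  if (k > min(K, M)) return(0)
  sum(choose(M, js) * choose(N - M, K - js)) / choose(N, K)
}

# literal enumeration of every C(N, K) draw (tiny N only)
oracle_hyper_combn <- function(k, K, M, N) {
  if (K == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, K)
  hits <- 0
  for (c in seq_len(ncol(draws))) {
    if (sum(draws[, c] <= M) >= k) hits <- hits + 1
  }
  hits / ncol(draws)
}
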