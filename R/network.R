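# Signed weighted correlation networks and connectivity.
#
# The adjacency between two rows x_i, x_j is a_ij = ((1 + cor(x_i, x_j)) / 2)^beta
# with Pearson correlation on pairwise-complete observations. The signed form
# keeps track of correlation direction: r = -1 maps to adjacency 0, r = 1 to
# adjacency 1, r = 0 to 2^-beta. beta ("soft threshold") defaults to 1, which
# is appropriate when few rows make up a group.

#' Signed weighted correlation network adjacency
#'
#' Computes the signed adjacency matrix `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta`
#' between the rows of a numeric matrix, using Pearson correlation over
#' pairwise-complete samples. Adjacencies lie in `[0, 1]` and preserve the
#' sign of the underlying correlation: perfectly anti-correlated rows get
#' adjacency 0, perfectly correlated rows get adjacency 1.
#'
#' @param m Numeric matrix (rows = variables, columns = samples) with at least
#'   two rows. Every row must have positive variance and every pair of rows
#'   must share at least three non-missing samples.
#' @param beta Positive soft-thresholding power; default 1.
#' @return Symmetric numeric matrix of adjacencies with unit diagonal and a
#'   `"beta"` attribute.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
#' signed_adjacency(m)        # a~b: 1, a~c: 0
#' @export
signed_adjacency <- function(m, beta = 1) {
  stopifnot(is.matrix(m), is.numeric(beta), length(beta) == 1, beta > 0)
  if (nrow(m) < 2) stop("need at least 2 rows to build a network")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  bad <- which(is.na(sds) | sds == 0)
  if (length(bad) > 0) {
    stop("zero-variance row(s), correlation undefined: ",
         paste(rownames(m)[bad], collapse = ", "))
  }
  obs <- (!is.na(m)) * 1
  overlap <- tcrossprod(obs)
  low <- which(overlap < 3 & upper.tri(overlap), arr.ind = TRUE)
  if (nrow(low) > 0) {
    stop(sprintf("rows '%s' and '%s' share fewer than 3 non-missing samples",
                 rownames(m)[low[1, 1]], rownames(m)[low[1, 2]]))
  }
  r <- stats::cor(t(m), use = "pairwise.complete.obs")
  if (anyNA(r)) {
    idx <- which(is.na(r), arr.ind = TRUE)[1, ]
    stop(sprintf("correlation undefined for rows '%s' and '%s'",
                 rownames(m)[idx[1]], rownames(m)[idx[2]]))
  }
  a <- ((1 + r) / 2)^beta
  a[a < 0] <- 0       # guard against r slightly outside [-1, 1]
  a[a > 1] <- 1
  diag(a) <- 1
  attr(a, "beta") <- beta
  a
}

#' Connectivity of each node in a network
#'
#' Node connectivity `k_i` is the sum of connection weights between node `i`
#' and all other nodes; the diagonal is excluded. Highly connected ("hub")
#' rows tend to be strongly positively correlated with the rest of their
#' group.
#'
#' @param adj Adjacency matrix as produced by [signed_adjacency()].
#' @return Named numeric vector of connectivities, `0 <= k_i <= n - 1`.
#' @export
connectivity <- function(adj) {
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  rowSums(adj) - diag(adj)
}

#' Most highly connected row of a group
#'
#' Builds the signed adjacency between the rows and returns the identifier of
#' the row with the highest connectivity. When several rows attain the
#' maximum, the first such row (in input order) is chosen.
#'
#' @param m Numeric matrix with at least 3 rows (connectivity-based selection
#'   is only meaningful with at least 3 variables).
#' @param beta Soft-thresholding power.
#' @return The rowname of the hub row.
#' @export
hub_row <- function(m, beta = 1) {
  if (nrow(m) < 3) {
    stop("connectivity-based selection requires at least 3 rows")
  }
  k <- connectivity(signed_adjacency(m, beta = beta))
  rownames(m)[which.max(k)]   # which.max returns the first maximum: tie rule
}

#' Whole-network connectivity of every row
#'
#' Computes, for each row of a (typically collapsed) matrix, its connectivity
#' against all other rows of the matrix, i.e. how correlated that gene is with
#' the rest of the network. The computation is blocked over rows so that the
#' full correlation matrix of a large network is never held in memory at once.
#'
#' @param m Numeric matrix; rows with zero variance are excluded with a
#'   warning (their correlations are undefined).
#' @param beta Soft-thresholding power.
#' @param block_size Number of rows correlated against the matrix per block.
#' @return Named numeric vector of connectivities over the retained rows.
#' @export
whole_network_connectivity <- function(m, beta = 1, block_size = 1000) {
  stopifnot(is.matrix(m), beta > 0, block_size >= 1)
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  sds <- apply(m, 1, stats::sd, na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning(sum(drop), " zero-variance row(s) excluded from connectivity: ",
            paste(utils::head(rownames(m)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
    m <- m[!drop, , drop = FALSE]
  }
  n <- nrow(m)
  if (n < 2) stop("need at least 2 rows with positive variance")
  tm <- t(m)
  k <- stats::setNames(numeric(n), rownames(m))
  for (start in seq(1, n, by = block_size)) {
    idx <- start:min(start + block_size - 1, n)
    r <- stats::cor(tm[, idx, drop = FALSE], tm, use = "pairwise.complete.obs")
    if (anyNA(r)) {
      stop("undefined pairwise correlation encountered; ",
           "check for rows with too few shared non-missing samples")
    }
    a <- ((1 + r) / 2)^beta
    a[a < 0] <- 0
    a[a > 1] <- 1
    # subtract each row's self-adjacency (exactly 1) rather than trusting
    # floating-point cor(x, x)
    k[idx] <- rowSums(a) - a[cbind(seq_along(idx), idx)]
  }
  k
}
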