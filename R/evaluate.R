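# Cross-dataset reproducibility of collapsing strategies.
#
# Two matrices collapsed to a shared set of group labels are compared by
# (1) the Spearman correlation of their per-row mean expressions and
# (2) the Spearman correlation of their whole-network connectivities, the
# latter computed on a signed weighted correlation network built per dataset
# after collapsing. Strategies are ranked by the average of each measure over
# all dataset pairs, and by how often each strategy attains the pair's
# highest correlation ("win" fraction).

#' Spearman correlation of ranked mean expression between two datasets
#'
#' Correlates the per-row means of two matrices that share an identical row
#' label sequence (use [intersect_on_groups()] first). Ranking the means and
#' correlating amounts to the Spearman correlation coefficient; ties receive
#' average ranks.
#'
#' @param a,b Numeric matrices (or `"collapse_result"`s) with identical
#'   rownames in identical order and at least 3 rows.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
ranked_mean_expression_correlation <- function(a, b) {
  a <- as_collapse_matrix(a)
  b <- as_collapse_matrix(b)
  check_aligned_rows(a, b)
  stats::cor(rowMeans(a, na.rm = TRUE), rowMeans(b, na.rm = TRUE),
             method = "spearman")
}

#' Spearman correlation of ranked connectivity between two datasets
#'
#' Builds a signed weighted correlation network within each matrix (same
#' `beta`), computes each row's whole-network connectivity, and returns the
#' Spearman correlation of the two connectivity vectors over the shared rows.
#' A significantly positive value indicates that the co-expression network of
#' the collapsed variables is robustly defined across the two datasets.
#'
#' @param a,b Numeric matrices (or `"collapse_result"`s) with identical
#'   rownames in identical order and at least 3 rows.
#' @param beta Soft-thresholding power.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
ranked_connectivity_correlation <- function(a, b, beta = 1) {
  a <- as_collapse_matrix(a)
  b <- as_collapse_matrix(b)
  check_aligned_rows(a, b)
  ka <- whole_network_connectivity(a, beta = beta)
  kb <- whole_network_connectivity(b, beta = beta)
  shared <- intersect(names(ka), names(kb))
  if (length(shared) < 3) {
    stop("fewer than 3 shared rows with defined connectivity")
  }
  stats::cor(ka[shared], kb[shared], method = "spearman")
}

check_aligned_rows <- function(a, b) {
  if (nrow(a) < 3 || nrow(b) < 3) stop("need at least 3 shared rows")
  if (!identical(rownames(a), rownames(b))) {
    stop("matrices must share an identical row label sequence; ",
         "use intersect_on_groups() first")
  }
  invisible(TRUE)
}

#' Compare collapsing strategies across dataset pairs
#'
#' For every unordered pair of datasets and every strategy: collapse both
#' datasets, restrict them to their shared groups, and compute the ranked
#' mean-expression and ranked-connectivity Spearman correlations. Results are
#' aggregated per strategy into means, standard errors (sample SD / sqrt(number
#' of pairs)), and win fractions — the share of pairs in which the strategy
#' attains the pair's highest correlation, with exact ties splitting the win
#' equally among the tied strategies.
#'
#' The pseudo-strategy `"none"` evaluates the uncollapsed matrices,
#' intersected on raw row identifiers, as a no-collapse baseline.
#'
#' @param datasets List of at least two datasets, each a list with elements
#'   `mat` (numeric matrix) and `groups` (named character vector).
#' @param strategies Character vector of strategy names (see
#'   [strategy_config()]), optionally including `"none"`.
#' @param beta Soft-thresholding power used both for connectivity-based
#'   collapsing and for the post-collapse networks.
#' @param seed Seed passed to each collapse (random tie-breaks).
#' @param tie_tol Two correlations within `tie_tol` of the pair's maximum are
#'   treated as tied for the win.
#' @return A data.frame with one row per strategy: `strategy`, `n_pairs`,
#'   `expr_cor_mean`, `expr_cor_se`, `conn_cor_mean`, `conn_cor_se`,
#'   `expr_win`, `conn_win`.
#' @export
compare_strategies <- function(datasets,
                               strategies = c("1.max", "2.var", "3.kMax",
                                              "4.kVar"),
                               beta = 1, seed = 0L, tie_tol = 1e-12) {
  stopifnot(length(datasets) >= 2, length(strategies) >= 1)
  for (d in datasets) {
    stopifnot(is.list(d), is.matrix(d$mat))
  }
  # collapse each dataset once per strategy
  collapsed <- lapply(strategies, function(s) {
    lapply(datasets, function(d) {
      if (s == "none") d$mat else
        collapse_by_strategy(d$mat, d$groups, strategy = s,
                             connectivity_power = beta, seed = seed)$matrix
    })
  })
  names(collapsed) <- strategies

  pairs <- utils::combn(length(datasets), 2)
  expr_cor <- conn_cor <- matrix(NA_real_, ncol(pairs), length(strategies),
                                 dimnames = list(NULL, strategies))
  kept <- logical(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    res <- tryCatch({
      for (s in strategies) {
        ab <- intersect_on_groups(collapsed[[s]][[i]], collapsed[[s]][[j]])
        expr_cor[p, s] <- ranked_mean_expression_correlation(ab$a, ab$b)
        conn_cor[p, s] <- ranked_connectivity_correlation(ab$a, ab$b,
                                                          beta = beta)
      }
      TRUE
    }, error = function(e) {
      warning("dataset pair (", i, ", ", j, ") skipped: ",
              conditionMessage(e))
      FALSE
    })
    kept[p] <- res
  }
  if (!any(kept)) stop("all dataset pairs were skipped")
  expr_cor <- expr_cor[kept, , drop = FALSE]
  conn_cor <- conn_cor[kept, , drop = FALSE]
  n_pairs <- sum(kept)

  win_frac <- function(cors) {
    w <- stats::setNames(numeric(length(strategies)), strategies)
    for (p in seq_len(nrow(cors))) {
      top <- which(cors[p, ] >= max(cors[p, ]) - tie_tol)
      w[top] <- w[top] + 1 / length(top)
    }
    w / nrow(cors)
  }
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_

  data.frame(
    strategy = strategies,
    n_pairs = n_pairs,
    expr_cor_mean = colMeans(expr_cor),
    expr_cor_se = apply(expr_cor, 2, se),
    conn_cor_mean = colMeans(conn_cor),
    conn_cor_se = apply(conn_cor, 2, se),
    expr_win = win_frac(expr_cor),
    conn_win = win_frac(conn_cor),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
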