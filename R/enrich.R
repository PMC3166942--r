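# Hypergeometric enrichment of user gene lists against reference collections.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` successes when drawing `K` items
#' without replacement from a universe of `N` items of which `M` are
#' successes, i.e. `P(X >= k)` for `X ~ Hypergeometric(N, M, K)`. This is the
#' enrichment p-value for an overlap of `k` genes between a user list of size
#' `K` and a reference list of size `M` drawn from a shared universe of `N`
#' genes. `k = 0` always gives exactly 1.
#'
#' @param k Observed overlap, `0 <= k <= min(K, M)`.
#' @param K User list size.
#' @param M Reference list size.
#' @param N Universe size, `N >= max(K, M)`.
#' @return The upper-tail p-value in `(0, 1]`.
#' @examples
#' hypergeometric_p(5, 5, 5, 10)   # 1 / choose(10, 5)
#' @export
hypergeometric_p <- function(k, K, M, N) {
  stopifnot(length(k) == length(K), length(K) == length(M),
            length(M) == length(N))
  if (any(k < 0 | K < 0 | M < 0 | N < 0 | k > pmin(K, M) | K > N | M > N)) {
    stop("require 0 <= k <= min(K, M) and K, M <= N")
  }
  stats::phyper(k - 1, M, N - M, K, lower.tail = FALSE)
}

#' Hypergeometric enrichment of gene lists against reference collections
#'
#' Tests every (user list, reference list) pair for overlap enrichment under
#' the hypergeometric distribution, with Bonferroni correction across all
#' pairs tested. Gene symbols are upper-cased and trimmed before matching,
#' and genes outside the universe are dropped (with a message reporting
#' counts), since an enrichment p-value is only meaningful relative to an
#' explicit background.
#'
#' @param user Named list of character vectors: the gene lists to test (e.g.
#'   groups produced by collapsing).
#' @param reference Named list of character vectors: the reference collections.
#' @param universe Character vector: the background gene set. Required — there
#'   is no safe default background.
#' @param alpha Significance threshold applied to the Bonferroni-corrected
#'   p-value; default 0.05.
#' @param out Optional path: the full record table is written there as TSV.
#' @param out_significant Optional path for the significant-only table.
#' @return A data.frame with one row per (user, reference) pair: `user_list`,
#'   `reference_list`, `overlap`, `user_size`, `ref_size`, `universe_size`,
#'   `p_value`, `p_bonferroni`, `significant`, `overlap_genes`
#'   (`|`-separated).
#' @export
enrich_lists <- function(user, reference, universe, alpha = 0.05,
                         out = NULL, out_significant = NULL) {
  stopifnot(is.list(user), is.list(reference), length(user) >= 1,
            length(reference) >= 1, alpha > 0, alpha <= 1)
  if (missing(universe) || is.null(universe) || length(universe) == 0) {
    stop("a background universe must be supplied")
  }
  if (is.null(names(user)) || is.null(names(reference)) ||
      anyDuplicated(names(user)) || anyDuplicated(names(reference))) {
    stop("user and reference collections must have unique list names")
  }
  norm <- function(x) unique(toupper(trimws(as.character(x))))
  universe <- norm(universe)
  harmonize <- function(lists, label) {
    lapply(stats::setNames(names(lists), names(lists)), function(nm) {
      g <- norm(lists[[nm]])
      keep <- g %in% universe
      if (!all(keep)) {
        message(label, " list '", nm, "': ", sum(!keep),
                " gene(s) outside the universe dropped")
      }
      g[keep]
    })
  }
  user <- harmonize(user, "user")
  reference <- harmonize(reference, "reference")
  if (all(lengths(user) == 0) || all(lengths(reference) == 0)) {
    stop("no genes from the lists are present in the universe")
  }

  N <- length(universe)
  n_tests <- length(user) * length(reference)
  rows <- list()
  for (u in names(user)) {
    for (r in names(reference)) {
      ov <- intersect(user[[u]], reference[[r]])
      p <- hypergeometric_p(length(ov), length(user[[u]]),
                            length(reference[[r]]), N)
      rows[[length(rows) + 1]] <- data.frame(
        user_list = u, reference_list = r, overlap = length(ov),
        user_size = length(user[[u]]), ref_size = length(reference[[r]]),
        universe_size = N, p_value = p,
        p_bonferroni = min(1, p * n_tests),
        significant = min(1, p * n_tests) < alpha,
        overlap_genes = paste(sort(ov), collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out_significant)) {
    utils::write.table(res[res$significant, , drop = FALSE], out_significant,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
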