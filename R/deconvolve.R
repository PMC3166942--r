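# Marker-based estimation of relative cell-type abundance.
#
# Markers are picked from pure cell-type profiles by fold-change enrichment,
# the marker rows of a mixture matrix are collapsed per cell type under any
# collapsing strategy, and each cell type's collapsed row is scaled so that
# its values sum to 1 across samples. The result estimates each type's
# relative abundance across samples only up to a per-type constant (like
# converting between temperature scales); accuracy is therefore scored by
# correlation with the known truth, which is scale invariant.

#' Select cell-type marker genes by fold-change enrichment
#'
#' For each gene and cell type, the fold change is
#' `(mean over the type's pure columns + pseudocount) /
#'  (mean over all other types' pure columns + pseudocount)`.
#' Each gene is assigned to the single type in which it is most enriched
#' (keeping marker lists disjoint), only genes with fold change > 1 qualify,
#' and the top `n` genes per type by descending fold change form the panel.
#'
#' @param pure Numeric matrix of pure profiles (rows = genes, columns = pure
#'   samples), on a linear intensity scale unless `log_base` is given.
#' @param col_types Character vector assigning each column of `pure` to a cell
#'   type (length `ncol(pure)`, or named by column).
#' @param n Number of markers requested per type; if fewer genes qualify the
#'   panel is truncated with a warning.
#' @param pseudocount Added to both means before the ratio to guard zeros;
#'   default 1 (appropriate for linear-scale intensities).
#' @param log_base If the data are on a log scale, the base (e.g. 2); values
#'   are unlogged before fold changes are computed.
#' @return An object of class `"marker_panel"`: a list with `markers` (named
#'   list, type -> character vector of marker ids, sorted by descending fold
#'   change) and `fold_changes` (named list of the matching fold changes).
#' @export
select_markers <- function(pure, col_types, n, pseudocount = 1,
                           log_base = NULL) {
  stopifnot(is.matrix(pure), !is.null(rownames(pure)))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer")
  }
  if (!is.null(names(col_types))) col_types <- col_types[colnames(pure)]
  col_types <- as.character(col_types)
  if (length(col_types) != ncol(pure)) {
    stop("col_types must assign a cell type to every column of pure")
  }
  types <- sort(unique(col_types))
  if (length(types) < 2) stop("need at least 2 cell types")
  if (!is.null(log_base)) pure <- log_base^pure

  fc <- sapply(types, function(t) {
    on <- rowMeans(pure[, col_types == t, drop = FALSE], na.rm = TRUE)
    off <- rowMeans(pure[, col_types != t, drop = FALSE], na.rm = TRUE)
    (on + pseudocount) / (off + pseudocount)
  })
  if (!is.matrix(fc)) {
    fc <- matrix(fc, nrow = 1, dimnames = list(rownames(pure), types))
  }
  best <- types[max.col(fc, ties.method = "first")]

  markers <- fold_changes <- stats::setNames(vector("list", length(types)),
                                             types)
  for (t in types) {
    cand <- which(best == t & fc[, t] > 1)
    cand <- cand[order(fc[cand, t], decreasing = TRUE)]
    if (length(cand) < n) {
      warning("cell type '", t, "': only ", length(cand),
              " marker(s) with fold change > 1 (requested ", n, ")")
    }
    take <- utils::head(cand, n)
    markers[[t]] <- rownames(pure)[take]
    fold_changes[[t]] <- stats::setNames(fc[take, t], rownames(pure)[take])
  }
  structure(list(markers = markers, fold_changes = fold_changes,
                 n_requested = as.integer(n)),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("Marker panel: ", length(x$markers), " cell type(s), ",
      x$n_requested, " marker(s) requested per type\n", sep = "")
  for (t in names(x$markers)) {
    fc <- x$fold_changes[[t]]
    cat(sprintf("  %s: %d markers (fold change %.2f .. %.2f)\n", t,
                length(x$markers[[t]]),
                if (length(fc)) max(fc) else NA, if (length(fc)) min(fc) else NA))
  }
  invisible(x)
}

# named character vector gene -> cell type from a panel
panel_groups <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  unlist(lapply(names(panel$markers), function(t) {
    stats::setNames(rep(t, length(panel$markers[[t]])), panel$markers[[t]])
  }))
}

#' Predict relative cell-type proportions from mixture expression
#'
#' Collapses the panel's marker rows of the mixture matrix per cell type under
#' the chosen strategy, then divides each cell type's collapsed row by its sum
#' across samples, so that the proportions of a single cell type sum to 1
#' across all samples. Markers absent from the mixture matrix are dropped with
#' a warning. Eigengene-based predictions (`"5.ME"`) may contain negative
#' values; they are scaled by their signed sum as-is and flagged via the
#' `"may_be_negative"` attribute.
#'
#' @param mixtures Numeric matrix of mixed-sample expression (rows = genes,
#'   columns = samples).
#' @param panel A `"marker_panel"` from [select_markers()].
#' @param strategy Strategy name (see [strategy_config()]) or a list with
#'   elements `method` and `connectivity_based`.
#' @param connectivity_power,seed Passed to [collapse_rows()].
#' @return Numeric matrix (cell types x samples) of relative proportions with
#'   attributes `scaling = "per_type_sum_one"` and `may_be_negative`.
#' @export
predict_proportions <- function(mixtures, panel, strategy = "3.kMax",
                                connectivity_power = 1, seed = 0L) {
  stopifnot(is.matrix(mixtures), !is.null(rownames(mixtures)))
  groups <- panel_groups(panel)
  present <- names(groups) %in% rownames(mixtures)
  if (!all(present)) {
    warning(sum(!present), " marker(s) absent from the mixture matrix dropped")
    groups <- groups[present]
  }
  if (length(groups) == 0) stop("no panel markers present in the mixtures")
  cfg <- if (is.character(strategy)) strategy_config(strategy) else strategy
  sub <- mixtures[rownames(mixtures) %in% names(groups), , drop = FALSE]
  res <- collapse_rows(sub, groups, method = cfg$method,
                       connectivity_based = isTRUE(cfg$connectivity_based),
                       connectivity_power = connectivity_power, seed = seed)
  p <- res$matrix
  rs <- rowSums(p)
  if (cfg$method != "ME" && any(rs <= 0)) {
    stop("non-positive collapsed row sum for cell type(s): ",
         paste(rownames(p)[rs <= 0], collapse = ", "))
  }
  if (any(rs == 0)) stop("zero collapsed row sum; proportions undefined")
  p <- p / rs
  attr(p, "scaling") <- "per_type_sum_one"
  attr(p, "may_be_negative") <- cfg$method == "ME"
  attr(p, "method") <- cfg$method
  p
}

#' Score predicted against true proportions
#'
#' Scales the truth by the same convention as the predictions (each cell
#' type's values sum to 1 across samples), then reports the Pearson
#' correlation pooled over all (cell type, sample) points and per cell type.
#'
#' @param pred Predicted proportion matrix (cell types x samples), as from
#'   [predict_proportions()].
#' @param truth True proportion matrix with the same cell types and samples
#'   (any per-type scale; it is renormalized).
#' @return List with `pooled` (scalar Pearson r) and `per_type` (named vector
#'   of per-type Pearson r).
#' @export
score_predictions <- function(pred, truth) {
  stopifnot(is.matrix(pred), is.matrix(truth))
  if (!setequal(rownames(pred), rownames(truth)) ||
      ncol(pred) != ncol(truth)) {
    stop("pred and truth must cover the same cell types and samples")
  }
  truth <- truth[rownames(pred), , drop = FALSE]
  if (!is.null(colnames(pred)) && !is.null(colnames(truth))) {
    if (!setequal(colnames(pred), colnames(truth))) {
      stop("pred and truth must cover the same samples")
    }
    truth <- truth[, colnames(pred), drop = FALSE]
  }
  rs <- rowSums(truth)
  if (any(rs == 0)) stop("truth has a zero-sum cell type row")
  truth <- truth / rs
  per_type <- vapply(rownames(pred), function(t) {
    stats::cor(pred[t, ], truth[t, ])
  }, numeric(1))
  list(pooled = stats::cor(as.vector(pred), as.vector(truth)),
       per_type = per_type)
}

#' Sweep panel size and strategy for deconvolution accuracy
#'
#' Re-selects markers for each requested panel size, predicts proportions
#' under each strategy, and scores the predictions, producing one row per
#' `(panel size, strategy)` combination. Used to assess how robust each
#' strategy is to the number of marker genes.
#'
#' @param mixtures,truth As in [predict_proportions()] / [score_predictions()].
#' @param pure,col_types Passed to [select_markers()].
#' @param counts Integer vector of panel sizes to test.
#' @param strategies Character vector of strategy names.
#' @param connectivity_power,seed Passed through.
#' @return A data.frame with columns `n_markers`, `strategy`, `pooled_r`,
#'   `mean_type_r`, `min_type_r`.
#' @export
marker_count_sweep <- function(mixtures, pure, col_types, truth, counts,
                               strategies = c("1.max", "3.kMax", "5.ME",
                                              "6.Avg"),
                               connectivity_power = 1, seed = 0L) {
  stopifnot(length(counts) >= 1)
  rows <- list()
  for (n in counts) {
    panel <- select_markers(pure, col_types, n)
    for (s in strategies) {
      pred <- predict_proportions(mixtures, panel, strategy = s,
                                  connectivity_power = connectivity_power,
                                  seed = seed)
      sc <- score_predictions(pred, truth)
      rows[[length(rows) + 1]] <- data.frame(
        n_markers = n, strategy = s, pooled_r = sc$pooled,
        mean_type_r = mean(sc$per_type), min_type_r = min(sc$per_type),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
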