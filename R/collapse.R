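# Core engine: collapse the rows of a numeric matrix into one row per group.
#
# Two families of methods are supported. Representative methods choose one
# existing row per group (by extreme row mean, mean absolute value, row
# variance, or network connectivity); the output row is then a bit-identical
# copy of the chosen input row. Composite methods compute a new row per group
# (column-wise average, first principal component / module eigengene, or a
# user-supplied aggregation function).

REPRESENTATIVE_METHODS <- c("MaxMean", "MinMean", "absMaxMean", "absMinMean",
                            "maxRowVariance")
COMPOSITE_METHODS <- c("ME", "average", "function")
ALL_METHODS <- c(REPRESENTATIVE_METHODS, COMPOSITE_METHODS)

#' Named collapsing strategies
#'
#' The six strategies used throughout the empirical analyses, as shorthand for
#' `(method, connectivity_based)` pairs:
#'
#' * `"1.max"`  — `MaxMean`, no connectivity-based collapsing
#' * `"2.var"`  — `maxRowVariance`, no connectivity-based collapsing
#' * `"3.kMax"` — `MaxMean` with connectivity-based collapsing (groups of 3+
#'   rows are collapsed to their most highly connected row; 2-row groups fall
#'   back to `MaxMean`)
#' * `"4.kVar"` — `maxRowVariance` with connectivity-based collapsing
#' * `"5.ME"`   — module eigengene (first principal component)
#' * `"6.Avg"`  — column-wise average
#'
#' @param strategy One of the names above.
#' @return List with elements `method` and `connectivity_based`, suitable for
#'   splicing into [collapse_rows()].
#' @export
strategy_config <- function(strategy) {
  presets <- list(
    "1.max"  = list(method = "MaxMean",        connectivity_based = FALSE),
    "2.var"  = list(method = "maxRowVariance", connectivity_based = FALSE),
    "3.kMax" = list(method = "MaxMean",        connectivity_based = TRUE),
    "4.kVar" = list(method = "maxRowVariance", connectivity_based = TRUE),
    "5.ME"   = list(method = "ME",             connectivity_based = FALSE),
    "6.Avg"  = list(method = "average",        connectivity_based = FALSE)
  )
  if (!strategy %in% names(presets)) {
    stop("unknown strategy '", strategy, "'; expected one of: ",
         paste(names(presets), collapse = ", "), ", none")
  }
  presets[[strategy]]
}

#' Keep only the rows with the fewest missing values per group
#'
#' Within each group, retains exactly the rows attaining that group's minimum
#' missing-value count. A group can never vanish: a singleton row is kept
#' whatever its missing count, and a complete matrix passes through unchanged.
#'
#' @param m Numeric matrix with rownames.
#' @param groups Named character vector mapping every row of `m` to a group.
#' @return The trimmed matrix (row order preserved).
#' @export
trim_fewest_missing <- function(m, groups) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  if (!all(rownames(m) %in% names(groups))) {
    stop("every row of the matrix must have a group assignment")
  }
  miss <- rowSums(is.na(m))
  grp <- as.character(groups[rownames(m)])
  min_by_group <- tapply(miss, grp, min)
  keep <- miss == min_by_group[grp]
  m[keep, , drop = FALSE]
}

#' Score rows for representative selection
#'
#' `MaxMean`/`MinMean` score each row by its mean over non-missing entries;
#' `absMaxMean`/`absMinMean` by the mean of absolute values; `maxRowVariance`
#' by the unbiased (n - 1) sample variance. A row with fewer than two
#' non-missing values has no defined variance; its score is `NA` and it loses
#' all comparisons under `maxRowVariance`.
#'
#' @param m Numeric matrix.
#' @param method One of `"MaxMean"`, `"MinMean"`, `"absMaxMean"`,
#'   `"absMinMean"`, `"maxRowVariance"`.
#' @return Numeric vector of scores, one per row.
#' @export
row_score <- function(m, method = REPRESENTATIVE_METHODS) {
  method <- match.arg(method)
  switch(method,
    MaxMean = ,
    MinMean = rowMeans(m, na.rm = TRUE),
    absMaxMean = ,
    absMinMean = rowMeans(abs(m), na.rm = TRUE),
    maxRowVariance = apply(m, 1, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) NA_real_ else stats::var(x)
    })
  )
}

# Representative selection within one group: extreme score, then highest mean,
# then a seeded uniform random draw among the remaining ties. Returns the
# index of the chosen row. Score ties are exact floating-point ties.
select_representative_idx <- function(sub, method) {
  score <- row_score(sub, method)
  minimise <- method %in% c("MinMean", "absMinMean")
  score[is.na(score)] <- if (minimise) Inf else -Inf
  extreme <- if (minimise) min(score) else max(score)
  cand <- which(score == extreme)
  if (length(cand) > 1) {
    mm <- rowMeans(sub[cand, , drop = FALSE], na.rm = TRUE)
    cand <- cand[mm == max(mm)]
  }
  if (length(cand) > 1) {
    cand <- cand[sample.int(length(cand), 1)]
  }
  cand
}

#' Choose one representative row from a group submatrix
#'
#' Applies the representative rule: extreme [row_score()] for the method,
#' ties broken by highest row mean, remaining ties broken uniformly at random
#' (seeded, so reproducible).
#'
#' @param sub Numeric matrix of candidate rows (with rownames).
#' @param method A representative method name.
#' @param seed Integer seed for the random tie-break.
#' @return The rowname of the selected row.
#' @export
select_representative <- function(sub, method = REPRESENTATIVE_METHODS,
                                  seed = 0L) {
  method <- match.arg(method)
  stopifnot(is.matrix(sub), nrow(sub) >= 1, !is.null(rownames(sub)))
  with_seed(seed, rownames(sub)[select_representative_idx(sub, method)])
}

#' Module eigengene of a group of rows
#'
#' Returns the first principal component of the group, computed as the first
#' right-singular vector (over samples) of the row-standardized submatrix.
#' The result has unit Euclidean norm and is sign-oriented so that its
#' correlation with the column-wise mean of the group rows is non-negative
#' (first PCs have arbitrary sign; downstream uses are correlation-based and
#' therefore sign-sensitive). Missing entries are imputed with their row's
#' mean before standardization. If every row is constant the eigengene is
#' undefined; an all-zero vector is returned with a warning.
#'
#' @param sub Numeric matrix (rows = group members, columns = samples).
#' @return Numeric vector of length `ncol(sub)`.
#' @export
module_eigengene <- function(sub) {
  stopifnot(is.matrix(sub), nrow(sub) >= 1)
  if (anyNA(sub)) {
    rm <- rowMeans(sub, na.rm = TRUE)
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- rm[idx[, 1]]
    message(nrow(idx), " missing value(s) imputed with row means for eigengene")
  }
  ctr <- sub - rowMeans(sub)
  sds <- sqrt(rowSums(ctr^2) / max(1, ncol(sub) - 1))
  ok <- sds > 0
  if (!any(ok)) {
    warning("all rows constant; module eigengene undefined, returning zeros")
    return(stats::setNames(numeric(ncol(sub)), colnames(sub)))
  }
  std <- ctr[ok, , drop = FALSE] / sds[ok]
  v <- svd(std, nu = 0, nv = 1)$v[, 1]
  # orient: non-negative correlation with the mean profile of the group
  mprof <- colMeans(sub)
  s <- sum(v * (mprof - mean(mprof)))
  if (s < 0) {
    v <- -v
  } else if (s == 0) {
    nz <- which(v != 0)
    if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
  }
  stats::setNames(v, colnames(sub))
}

#' Collapse the rows of a matrix into one row per group
#'
#' The workhorse of the package. Rows of `m` sharing a group label in
#' `groups` are reduced to a single output row per group. Rows absent from
#' `groups` (or mapped to a blank label) are dropped with a message. When
#' `select_fewest_missing = TRUE` (default), each group is first trimmed to
#' the rows with the fewest missing values.
#'
#' Representative methods select one existing row per group (see
#' [row_score()]); ties go to the highest row mean, then to a seeded random
#' draw. With `connectivity_based = TRUE`, groups of three or more (trimmed)
#' rows are instead collapsed to their most highly connected row in the
#' signed weighted correlation network ([hub_row()]); two-row groups fall back
#' to the configured representative method and singletons pass through.
#' Connectivity-based collapsing only applies to representative methods;
#' composite methods (`"ME"`, `"average"`, `"function"`) always aggregate
#' every group.
#'
#' @param m Numeric matrix with unique rownames and colnames.
#' @param groups Named character vector mapping row identifiers to group
#'   labels.
#' @param method Collapsing method: one of `"MaxMean"` (default), `"MinMean"`,
#'   `"absMaxMean"`, `"absMinMean"`, `"maxRowVariance"`, `"ME"`, `"average"`,
#'   `"function"`.
#' @param connectivity_based Collapse groups of 3+ rows to their network hub?
#' @param connectivity_power Soft-thresholding power `beta > 0` for the signed
#'   adjacency; default 1.
#' @param select_fewest_missing Trim each group to its fewest-missing rows
#'   first? Default `TRUE`.
#' @param method_function For `method = "function"`: a function mapping a
#'   group submatrix to a vector of length `ncol(m)` (e.g. `colMeans`).
#' @param seed Integer seed for random tie-breaks; recorded in the result.
#' @return An object of class `"collapse_result"`: a list with
#'   * `matrix` — collapsed matrix, one row per group, rows in sorted group
#'     order, row labels = group labels;
#'   * `group2row` — named character vector, group -> selected input row
#'     identifier, or a `"<ME>"`/`"<average>"`/`"<function>"` sentinel for
#'     composite rows;
#'   * `method`, `connectivity_based`, `connectivity_power`,
#'     `select_fewest_missing`, `seed` — the configuration used.
#' @examples
#' m <- rbind(p1 = c(5, 6, 7), p2 = c(1, 2, 3), p3 = c(2, 2, 2))
#' colnames(m) <- paste0("s", 1:3)
#' g <- c(p1 = "gA", p2 = "gA", p3 = "gB")
#' collapse_rows(m, g, method = "MaxMean")$group2row   # gA -> p1, gB -> p3
#' @export
collapse_rows <- function(m, groups,
                          method = c("MaxMean", "MinMean", "absMaxMean",
                                     "absMinMean", "maxRowVariance", "ME",
                                     "average", "function"),
                          connectivity_based = FALSE,
                          connectivity_power = 1,
                          select_fewest_missing = TRUE,
                          method_function = NULL,
                          seed = 0L) {
  method <- match.arg(method)
  stopifnot(is.matrix(m), !is.null(rownames(m)),
            is.numeric(connectivity_power), connectivity_power > 0)
  if (method == "function" && is.null(method_function)) {
    stop("method = \"function\" requires a method_function")
  }
  if (method != "function" && !is.null(method_function)) {
    stop("method_function is only used with method = \"function\"")
  }
  if (is.null(names(groups))) stop("groups must be a named vector")
  grp <- as.character(groups)
  grp[is.na(grp) | trimws(grp) == ""] <- NA_character_
  names(grp) <- names(groups)

  mapped <- rownames(m) %in% names(grp)[!is.na(grp)]
  if (!all(mapped)) {
    message(sum(!mapped),
            " row(s) without a (non-blank) group assignment dropped")
  }
  m <- m[mapped, , drop = FALSE]
  if (nrow(m) == 0) stop("no rows remain after group filtering")
  row_group <- grp[rownames(m)]

  if (select_fewest_missing) {
    m <- trim_fewest_missing(m, row_group)
    row_group <- row_group[rownames(m)]
  }

  labels <- sort(unique(row_group))
  out <- matrix(NA_real_, length(labels), ncol(m),
                dimnames = list(labels, colnames(m)))
  group2row <- stats::setNames(character(length(labels)), labels)

  with_seed(seed, {
    for (g in labels) {
      ids <- rownames(m)[row_group == g]         # input (file) row order
      sub <- m[ids, , drop = FALSE]
      if (method %in% COMPOSITE_METHODS) {
        out[g, ] <- switch(method,
          ME = module_eigengene(sub),
          average = colMeans(sub, na.rm = TRUE),
          "function" = {
            v <- method_function(sub)
            if (!is.numeric(v) || length(v) != ncol(sub)) {
              stop("method_function returned output of length ",
                   length(v), " (expected ", ncol(sub),
                   ") for group '", g, "'")
            }
            as.numeric(v)
          })
        group2row[g] <- paste0("<", method, ">")
      } else {
        chosen <- if (connectivity_based && nrow(sub) >= 3) {
          hub_row(sub, beta = connectivity_power)
        } else {
          ids[select_representative_idx(sub, method)]
        }
        out[g, ] <- m[chosen, ]
        group2row[g] <- chosen
      }
    }
  })

  structure(list(matrix = out, group2row = group2row, method = method,
                 connectivity_based = connectivity_based,
                 connectivity_power = connectivity_power,
                 select_fewest_missing = select_fewest_missing,
                 seed = as.integer(seed)),
            class = "collapse_result")
}

#' Collapse under a named strategy
#'
#' Convenience wrapper applying one of the six named strategies (see
#' [strategy_config()]) to [collapse_rows()].
#'
#' @param m,groups As in [collapse_rows()].
#' @param strategy Strategy name, e.g. `"1.max"` or `"3.kMax"`.
#' @param connectivity_power,seed As in [collapse_rows()].
#' @return A `"collapse_result"`.
#' @export
collapse_by_strategy <- function(m, groups, strategy = "1.max",
                                 connectivity_power = 1, seed = 0L) {
  cfg <- strategy_config(strategy)
  collapse_rows(m, groups, method = cfg$method,
                connectivity_based = cfg$connectivity_based,
                connectivity_power = connectivity_power, seed = seed)
}

#' @export
print.collapse_result <- function(x, ...) {
  cat("Collapsed matrix: ", nrow(x$matrix), " group(s) x ", ncol(x$matrix),
      " sample(s)\n", sep = "")
  cat("  method: ", x$method,
      if (x$connectivity_based)
        paste0(" + connectivity-based (beta = ", x$connectivity_power, ")"),
      "\n", sep = "")
  n_rep <- sum(!startsWith(x$group2row, "<"))
  cat("  representative rows: ", n_rep, "; composite rows: ",
      length(x$group2row) - n_rep, "\n", sep = "")
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so collapsing never perturbs a
# surrounding simulation.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  expr
}
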