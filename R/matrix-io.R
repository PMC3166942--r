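# Plain-text I/O for expression matrices, row->group maps and gene lists.
# All matrices are base numeric matrices with unique, non-empty rownames
# (variables: probes, genes, markers) and unique colnames (samples).

MISSING_TOKENS <- c("NA", "NaN", "")

#' Read an expression matrix from a delimited text file
#'
#' The file must have a header row of sample identifiers and a first column of
#' unique row identifiers. Missing values may be encoded as `NA`, `NaN`, or an
#' empty field. Rows whose values are entirely missing are dropped with a
#' warning, since no collapsing method can use them.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter, `"\t"` (default) or `","`.
#' @return A numeric matrix with rownames (row identifiers) and colnames
#'   (sample identifiers); missing cells are `NA`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' write_expression(m, f)
#' read_expression(f)
#' @seealso [write_expression()], [read_group_map()]
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("file does not exist: ", path)
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    stop("expected at least two columns (row identifier + one sample): ", path)
  }
  ids <- trimws(raw[[1]])
  if (any(ids == "")) {
    stop("empty row identifier at line(s) ",
         paste(which(ids == "") + 1L, collapse = ", "), " of ", path)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop("duplicate row identifier(s): ", paste(dup, collapse = ", "))
  }
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifier(s) in header of ", path)
  }
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- trimws(raw[[j + 1L]])
    miss <- v %in% MISSING_TOKENS | is.na(v)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!miss & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of %s",
                   v[bad[1]], ids[bad[1]], samples[j], path))
    }
    vals[, j] <- num
  }
  drop_all_missing_rows(vals)
}

drop_all_missing_rows <- function(m) {
  empty <- rowSums(!is.na(m)) == 0
  if (any(empty)) {
    warning(sum(empty), " row(s) with no non-missing values dropped: ",
            paste(utils::head(rownames(m)[empty], 5), collapse = ", "),
            if (sum(empty) > 5) ", ..." else "")
    m <- m[!empty, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("matrix has no retained rows")
  m
}

#' Write an expression matrix to a delimited text file
#'
#' Missing values are written as `NA`. The first column holds row identifiers
#' under the header `id`, so that [read_expression()] round-trips the file.
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, sep = "\t") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, na = "NA",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a row-to-group map
#'
#' Expects a two-column delimited file with a header line: row identifier,
#' group label. Rows with a blank or missing group label are excluded with a
#' message. A row identifier listed twice with conflicting groups is an error;
#' exact duplicate pairs are tolerated and de-duplicated.
#'
#' @param path Path to a two-column delimited file.
#' @param sep Field delimiter.
#' @return A named character vector: `names` are row identifiers, values are
#'   group labels.
#' @export
read_group_map <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected two columns (row_id, group): ", path)
  ids <- trimws(raw[[1]])
  grp <- trimws(raw[[2]])
  blank <- is.na(grp) | grp == ""
  if (any(blank)) {
    message(sum(blank), " row(s) with blank group label excluded from map")
    ids <- ids[!blank]
    grp <- grp[!blank]
  }
  keep <- !duplicated(paste(ids, grp, sep = "\r"))
  ids <- ids[keep]
  grp <- grp[keep]
  if (anyDuplicated(ids)) {
    bad <- unique(ids[duplicated(ids)])
    stop("conflicting group assignments for row(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(ids) == 0) stop("group map is empty after exclusions: ", path)
  stats::setNames(grp, ids)
}

#' Write a row-to-group map
#'
#' @param groups Named character vector (names = row identifiers, values =
#'   group labels).
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(groups, path, sep = "\t") {
  stopifnot(!is.null(names(groups)))
  df <- data.frame(row_id = names(groups), group = as.character(groups),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a one-column gene list
#'
#' One identifier per line, no header; blank lines are skipped.
#'
#' @param path Path to a text file.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[x != ""]
}

#' Read a collection of named gene lists
#'
#' Expects a two-column delimited file with header: gene identifier, list
#' name. Returns the collection as a named list of character vectors, the
#' format consumed by [enrich_lists()].
#'
#' @param path Path to a two-column delimited file.
#' @param sep Field delimiter.
#' @return Named list of character vectors.
#' @export
read_list_collection <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected two columns (gene, list): ", path)
  genes <- trimws(raw[[1]])
  lists <- trimws(raw[[2]])
  keep <- genes != "" & lists != ""
  split(genes[keep], lists[keep])
}

#' Restrict two collapsed matrices to their shared groups
#'
#' Mirrors the first step of every between-dataset comparison: take the subset
#' of groups (e.g. genes) in common and put both matrices in the same,
#' sorted row order.
#'
#' @param a,b Collapsed matrices (or [collapse_rows()] results), one row per
#'   group.
#' @return List with elements `a` and `b`: the two matrices restricted to the
#'   sorted intersection of their row labels, identically ordered.
#' @export
intersect_on_groups <- function(a, b) {
  a <- as_collapse_matrix(a)
  b <- as_collapse_matrix(b)
  shared <- sort(intersect(rownames(a), rownames(b)))
  if (length(shared) == 0) {
    stop("no group labels in common between the two matrices")
  }
  list(a = a[shared, , drop = FALSE], b = b[shared, , drop = FALSE])
}

as_collapse_matrix <- function(x) {
  if (inherits(x, "collapse_result")) x <- x$matrix
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  x
}
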