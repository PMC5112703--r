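#' Construct an expression matrix
#'
#' A thin wrapper around a numeric feature-by-sample matrix of log2
#' abundances that records what kind of feature the rows are (mature miRs or
#' mRNA microarray probes). Feature ids live in `rownames`, sample ids in
#' `colnames`.
#'
#' @param values Numeric matrix (features x samples) with rownames and
#'   colnames set.
#' @param feature_kind Either `"miR"` or `"mRNA-probe"`.
#' @return A matrix of class `expr_matrix` with a `feature_kind` attribute.
#' @export
expression_matrix <- function(values, feature_kind = c("miR", "mRNA-probe")) {
  feature_kind <- match.arg(feature_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values))) stop("feature ids must be set as rownames")
  if (is.null(colnames(values))) stop("sample ids must be set as colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids are not allowed")
  if (!all(is.finite(values))) stop("expression values must be finite")
  structure(values, feature_kind = feature_kind,
            class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d %s features x %d samples\n",
              nrow(x), attr(x, "feature_kind"), ncol(x)))
  invisible(x)
}

feature_kind <- function(m) attr(m, "feature_kind")

# rewrap a plain matrix, keeping the kind of a template expr_matrix
rewrap <- function(values, template) {
  expression_matrix(values, feature_kind = feature_kind(template))
}

#' Read an expression matrix from TSV
#'
#' Expects a header row, a first column of feature ids and one numeric
#' column per sample. Duplicate feature ids are disambiguated with a
#' suffix (with a warning); non-numeric cells are an error.
#'
#' @param path Path to a tab-separated file.
#' @param feature_kind `"miR"` or `"mRNA-probe"`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, feature_kind = c("miR", "mRNA-probe")) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty expression file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a feature column plus samples")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    warning("duplicate feature ids in ", path, "; suffix-disambiguating")
    ids <- make.unique(ids, sep = "_dup")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals),
                                     dimnames = list(ids, colnames(vals))))
  if (anyNA(storage) && !anyNA(vals))
    stop("non-numeric expression values in ", path)
  if (anyNA(storage)) stop("missing/non-numeric expression values in ", path)
  expression_matrix(storage, feature_kind)
}

#' Write an expression matrix to TSV
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), unclass(m),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
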