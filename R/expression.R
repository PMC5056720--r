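#' Coerce to a gene-by-condition expression matrix
#'
#' The clustering and concordance functions work on a numeric matrix with
#' unique gene identifiers as row names and ordered condition labels as
#' column names. Accepts such a matrix directly, or a data frame / tibble
#' whose first column holds gene identifiers.
#'
#' @param x Matrix or data frame.
#' @return Numeric matrix with rownames (genes) and colnames (conditions).
#' @export
as_expression_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- norm_symbol(x[[1]])
  } else {
    domain_error("expression data must be a matrix or data frame")
  }
  storage.mode(m) <- "double"
  if (is.null(rownames(m)) || any(rownames(m) == "")) {
    domain_error("expression matrix needs gene identifiers as row names")
  }
  if (anyDuplicated(rownames(m))) {
    domain_error("duplicate gene identifiers in expression matrix")
  }
  if (ncol(m) < 3) {
    domain_error("expression matrix needs >= 3 conditions (Pearson correlation)")
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("cond", seq_len(ncol(m)))
  m
}

#' Read a tab-delimited expression matrix
#'
#' First column: gene identifier; header row: condition labels.
#'
#' @param file Path to a TSV file.
#' @return Numeric matrix (see [as_expression_matrix()]).
#' @export
read_expression <- function(file) {
  df <- readr::read_tsv(file, col_types = readr::cols(), progress = FALSE,
                        name_repair = "minimal")
  as_expression_matrix(as.data.frame(df))
}

#' Write an expression matrix as TSV
#'
#' @param expr Matrix from [as_expression_matrix()].
#' @param file Output path.
#' @param id_col Name of the gene-identifier column in the header.
#' @return `file`, invisibly.
#' @export
write_expression <- function(expr, file, id_col = "gene") {
  df <- as.data.frame(expr)
  df <- cbind(stats::setNames(data.frame(rownames(expr)), id_col), df)
  readr::write_tsv(as_tibble(df), file, progress = FALSE)
  invisible(file)
}
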