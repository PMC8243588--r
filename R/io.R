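# Delimited-text I/O for expression matrices, trait tables and gene lists.

#' Read a gene x sample expression matrix from delimited text
#'
#' First column holds gene identifiers, header holds sample identifiers.
#' Duplicate gene ids are an error (all duplicates are listed).
#'
#' @param path file path.
#' @param sep field separator (tab by default; use "," for CSV).
#' @param scale scale tag to attach ("rpkm" or "log2").
#' @return numeric matrix with dimnames and a \code{scale} attribute.
#' @export
read_expression <- function(path, sep = "\t", scale = "rpkm") {
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) .stopf("read_expression: empty file '%s'", path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    .stopf("read_expression: duplicate gene ids: %s",
           paste(utils::head(dup, 10), collapse = ", "))
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  attr(X, "scale") <- scale
  X
}

#' Write an expression matrix as delimited text
#'
#' @param X gene x sample matrix.
#' @param path output path.
#' @param sep field separator.
#' @param digits significant digits for numeric output (default 6; NA for
#'   full precision).
#' @export
write_expression <- function(X, path, sep = "\t", digits = 6) {
  V <- as.matrix(X)
  if (!is.na(digits)) V <- signif(V, digits)
  df <- data.frame(gene_id = rownames(V), V, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample trait table
#'
#' The first column (or a \code{sample_id} column) supplies sample ids, which
#' become rownames.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data frame with sample ids as rownames.
#' @export
read_traits <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0) .stopf("read_traits: empty file '%s'", path)
  idcol <- if ("sample_id" %in% names(df)) "sample_id" else names(df)[1]
  ids <- as.character(df[[idcol]])
  if (anyDuplicated(ids)) .stopf("read_traits: duplicate sample ids")
  rownames(df) <- ids
  df
}

#' Check that expression and trait samples agree
#'
#' @param X gene x sample matrix.
#' @param traits trait data frame (rownames = sample ids).
#' @return invisibly TRUE; errors with the symmetric difference otherwise.
#' @export
check_sample_alignment <- function(X, traits) {
  a <- colnames(X); b <- rownames(traits)
  only_x <- setdiff(a, b); only_t <- setdiff(b, a)
  if (length(only_x) > 0 || length(only_t) > 0)
    .stopf("sample mismatch; only in expression: [%s]; only in traits: [%s]",
           paste(utils::head(only_x, 5), collapse = ", "),
           paste(utils::head(only_t, 5), collapse = ", "))
  invisible(TRUE)
}
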