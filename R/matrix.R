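#' Validate a NOGF count matrix
#'
#' The NOGF ("number of genes in a functional category") matrix holds
#' nonnegative integer gene counts, species as rows and categories as
#' columns, with unique dimnames.
#'
#' @param m matrix to validate.
#' @return the matrix (integer storage mode) invisibly on success.
#' @export
validate_function_matrix <- function(m) {
  if (!is.matrix(m)) stop("NOGF matrix must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("NOGF matrix needs species row names and category column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate species ids in NOGF matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate category ids in NOGF matrix")
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m))) {
    stop("NOGF counts must be nonnegative integers")
  }
  storage.mode(m) <- "integer"
  invisible(m)
}

#' Read / write a NOGF count matrix (TSV)
#'
#' On disk the matrix is stored categories-as-rows, species-as-columns (the
#' orientation of a category-per-line supplementary table); in memory the
#' package uses species-as-rows. Set `transpose = FALSE` if the file is
#' already species-as-rows.
#'
#' @param path TSV path; first column holds row ids, header holds column ids.
#' @param transpose whether the file is categories-as-rows (default TRUE).
#' @return integer matrix, species as rows, categories as columns.
#' @export
read_function_matrix <- function(path, transpose = TRUE) {
  x <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(x)
  if (transpose) m <- t(m)
  validate_function_matrix(m)
}

#' @rdname read_function_matrix
#' @param m NOGF matrix (species as rows).
#' @export
write_function_matrix <- function(m, path, transpose = TRUE) {
  validate_function_matrix(m)
  out <- if (transpose) t(m) else m
  df <- data.frame(id = rownames(out), out, check.names = FALSE)
  names(df)[1L] <- if (transpose) "category_id" else "species_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a functional hierarchy mapping (two-column TSV)
#'
#' Maps each third-level category to its second-level (upper) parent.
#' Returned as a named character vector: `hierarchy[category_id]` is the
#' upper category id. Custom gene sets may map to the reserved upper
#' category `"custom"`.
#'
#' @param path two-column TSV (category_id, upper_category_id) with header.
#' @return named character vector.
#' @export
read_hierarchy <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2L) stop("hierarchy file needs two columns (category_id, upper_category_id)")
  if (anyDuplicated(x[[1L]])) {
    stop("category mapped to more than one upper category: ",
         paste(unique(x[[1L]][duplicated(x[[1L]])]), collapse = ", "))
  }
  stats::setNames(as.character(x[[2L]]), as.character(x[[1L]]))
}

#' @rdname read_hierarchy
#' @param hierarchy named character vector (names = category ids).
#' @export
write_hierarchy <- function(hierarchy, path) {
  utils::write.table(
    data.frame(category_id = names(hierarchy),
               upper_category_id = unname(hierarchy)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
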