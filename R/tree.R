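#' Parse a Newick tree string
#'
#' Parses a single rooted Newick statement with branch lengths into an
#' `ape::phylo` object, after a validation pass that reports the character
#' position of structural problems (unbalanced parentheses, missing
#' terminating `;`) and rejects duplicate leaf labels.
#'
#' @param text Newick string terminated by `;`.
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  semi_at <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("newick parse error: unmatched ')' at position ", i)
    } else if (ch == ";") { semi_at <- i; break }
  }
  if (is.na(semi_at)) {
    stop("newick parse error: missing terminating ';' (end of input, position ",
         length(chars), ")")
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' at position ", semi_at)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse error: unreadable tree")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("newick parse error: duplicate leaf label(s): ",
         paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop("newick parse error: tree has no branch lengths")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    stop("newick parse error: branch lengths must be finite and >= 0")
  }
  tree
}

#' Read / write Newick files
#'
#' @param path path of a Newick file holding one tree.
#' @return `read_tree`: a `phylo` object.
#' @export
read_tree <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname read_tree
#' @param tree a `phylo` object.
#' @param digits significant digits for branch lengths on output.
#' @export
write_tree <- function(tree, path, digits = 12L) {
  writeLines(ape::write.tree(tree, digits = digits), path)
  invisible(path)
}
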