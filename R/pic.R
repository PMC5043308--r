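#' Phylogenetically independent contrasts (Felsenstein pruning)
#'
#' Transforms tip trait values into standardized independent contrasts on
#' a rooted binary tree. At each internal node with child values x1, x2
#' and (augmented) branch lengths v1, v2 the contrast is
#' `(x1 - x2) / sqrt(v1 + v2)`; the node is assigned the
#' precision-weighted value `(x1/v1 + x2/v2) / (1/v1 + 1/v2)` and its
#' parent branch is augmented by `v1 v2 / (v1 + v2)`.
#'
#' The sign of a contrast is arbitrary in theory; for reproducibility the
#' child taken as x1 is the one whose subtree contains the
#' lexicographically smallest tip label. When a contrast denominator
#' `v1 + v2` is exactly zero (two zero-length sister branches) a small
#' epsilon is substituted, with a warning.
#'
#' Polytomies are rejected; resolve them explicitly (e.g. with
#' [resolve_polytomies()]) if a zero-branch resolution is acceptable.
#'
#' @param tree rooted binary `phylo` tree with branch lengths >= 0.
#' @param trait named numeric vector, one value per tip label.
#' @param label optional variable label stored on the result.
#' @param eps regularization used only when a denominator is exactly 0.
#' @return object of class `contrast_set`: list with `contrasts` (named by
#'   internal node number, in increasing node order), `node_ids`, `label`.
#' @export
compute_contrasts <- function(tree, trait, label = NULL, eps = 1e-8) {
  n_tip <- ape::Ntip(tree)
  if (n_tip < 2L) stop("tree must have at least 2 tips")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0L) {
    stop("tip(s) without a trait value: ", paste(missing, collapse = ", "))
  }
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  if (any(lengths(kids) != 2L)) {
    bad <- names(kids)[lengths(kids) != 2L]
    stop("tree is not binary (polytomy or unbranched node at node ",
         paste(bad, collapse = ", "), ")")
  }
  # branch length of the edge above each node
  blen <- numeric(n_tip + tree$Nnode)
  blen[tree$edge[, 2L]] <- tree$edge.length
  root <- n_tip + 1L

  val <- numeric(n_tip + tree$Nnode)
  aug <- blen                      # augmented branch length above each node
  minlab <- character(n_tip + tree$Nnode)
  contrasts <- numeric(tree$Nnode)
  names(contrasts) <- as.character(root:(n_tip + tree$Nnode))
  warned <- FALSE

  # postorder over internal nodes (children before parents)
  po <- postorder_nodes(tree)
  for (u in po) {
    ch <- kids[[as.character(u)]]
    info <- lapply(ch, function(v) {
      if (v <= n_tip) list(x = unname(trait[tree$tip.label[v]]),
                           v = aug[v], lab = tree$tip.label[v])
      else list(x = val[v], v = aug[v], lab = minlab[v])
    })
    if (info[[2L]]$lab < info[[1L]]$lab) info <- info[c(2L, 1L)]
    v1 <- info[[1L]]$v; v2 <- info[[2L]]$v
    vsum <- v1 + v2
    if (vsum == 0) {
      if (!warned) {
        warning("zero contrast denominator regularized with eps = ", eps)
        warned <- TRUE
      }
      vsum <- eps
      v1 <- v1 + eps / 2; v2 <- v2 + eps / 2
    }
    contrasts[as.character(u)] <- (info[[1L]]$x - info[[2L]]$x) / sqrt(vsum)
    val[u] <- (info[[1L]]$x / v1 + info[[2L]]$x / v2) / (1 / v1 + 1 / v2)
    aug[u] <- blen[u] + v1 * v2 / vsum
    minlab[u] <- min(info[[1L]]$lab, info[[2L]]$lab)
  }
  contrasts <- contrasts[order(as.integer(names(contrasts)))]
  structure(list(contrasts = contrasts,
                 node_ids = as.integer(names(contrasts)),
                 label = label),
            class = "contrast_set")
}

# internal nodes in postorder (every child processed before its parent)
postorder_nodes <- function(tree) {
  n_tip <- ape::Ntip(tree)
  ord <- ape::reorder.phylo(tree, "postorder")
  unique(ord$edge[, 1L])
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("Independent contrasts",
      if (!is.null(x$label)) paste0(" for ", x$label), ": k = ",
      length(x$contrasts), "\n", sep = "")
  print(x$contrasts, ...)
  invisible(x)
}

#' Correlation of contrasts through the origin
#'
#' Contrasts have expectation zero, so their association is measured by a
#' no-intercept correlation: `r = sum(cx cy) / sqrt(sum(cx^2) sum(cy^2))`,
#' with a two-sided p-value from `t = r sqrt(k - 1) / sqrt(1 - r^2)` on
#' k - 1 df.
#'
#' @param cx,cy `contrast_set` objects (or bare numeric vectors) of equal
#'   length k >= 2.
#' @return list with `r`, `p`, `k`.
#' @export
corr_through_origin <- function(cx, cy) {
  x <- if (inherits(cx, "contrast_set")) cx$contrasts else as.numeric(cx)
  y <- if (inherits(cy, "contrast_set")) cy$contrasts else as.numeric(cy)
  k <- length(x)
  if (length(y) != k) stop("contrast sets differ in length")
  if (k < 2L) stop("need at least 2 contrasts")
  ssx <- sum(x^2); ssy <- sum(y^2)
  if (ssx == 0) stop("zero sum of squares in cx")
  if (ssy == 0) stop("zero sum of squares in cy")
  r <- sum(x * y) / sqrt(ssx * ssy)
  r <- max(-1, min(1, r))
  df <- k - 1L
  tt <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = df), k = k)
}

#' Resolve polytomies to a binary tree
#'
#' Arbitrarily resolves multifurcations by inserting zero-length branches
#' (wraps `ape::multi2di`). PIC results on such a resolution depend on the
#' arbitrary order; opt in deliberately.
#'
#' @param tree a `phylo` tree.
#' @return a binary `phylo` tree.
#' @export
resolve_polytomies <- function(tree) {
  out <- ape::multi2di(tree, random = FALSE)
  if (is.null(out$edge.length)) out$edge.length <- numeric(nrow(out$edge))
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}
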