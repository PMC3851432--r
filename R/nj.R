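# Neighbor joining with deterministic tie-breaking.
#
# Classical Q-criterion agglomeration (Saitou & Nei / Studier & Keppler).
# On an additive (tree-metric) distance matrix the generating topology and
# branch lengths are recovered exactly.  Ties in the Q matrix are broken
# by the lowest (row, column) index pair so results are reproducible, and
# negative branch lengths are clamped to zero with the deficit recorded.

#' Neighbor-joining tree from a distance matrix
#'
#' @param d symmetric numeric matrix with zero diagonal and at least three
#'   taxa (row/column names become tip labels), or a [stats::dist].
#' @return an unrooted [ape::phylo] tree.  The attribute
#'   `"clamped_deficit"` records the total negative branch length clamped
#'   to zero (0 for additive inputs).
#' @examples
#' d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4, 4,
#'             dimnames = list(letters[1:4], letters[1:4]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) abort("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) abort("distance matrix must have a zero diagonal")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  rownames(d) <- colnames(d) <- NULL

  # each active node carries a Newick fragment
  frags <- labels
  clamped <- 0
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped - x; 0 } else x
  }
  fmt <- function(x) sprintf("%.17g", x)

  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # lowest (i, j), i < j, among minimal entries
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]

    li <- clamp(0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(d[i, j] - (0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))))
    new_frag <- paste0("(", frags[i], ":", fmt(li), ",", frags[j], ":", fmt(lj), ")")

    du <- 0.5 * (d[i, -c(i, j)] + d[j, -c(i, j)] - d[i, j])
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    frags <- c(frags[-c(i, j)], new_frag)
  }

  # final three-taxon star: closed-form branch lengths
  la <- clamp(0.5 * (d[1, 2] + d[1, 3] - d[2, 3]))
  lb <- clamp(0.5 * (d[1, 2] + d[2, 3] - d[1, 3]))
  lc <- clamp(0.5 * (d[1, 3] + d[2, 3] - d[1, 2]))
  newick <- paste0("(", frags[1], ":", fmt(la), ",", frags[2], ":", fmt(lb),
                   ",", frags[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = newick)
  if (clamped > 0) {
    inform(sprintf("clamped %.6g of negative branch length to zero", clamped))
  }
  attr(tree, "clamped_deficit") <- clamped
  tree
}

#' Newick serialization
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] with a
#' guaranteed round trip of topology and branch lengths (to well beyond
#' 6 decimals) and an informative parse error on malformed text.
#'
#' @param tree an [ape::phylo] tree.
#' @param path optional file to write to; when `NULL` the Newick string is
#'   returned.
#' @return `write_newick()`: the Newick string (invisibly when writing to
#'   a file); `read_newick()`: an [ape::phylo].
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 10)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_newick
#' @param text Newick string (or a file path containing one).
#' @export
read_newick <- function(text) {
  tree <- if (file.exists(text)) {
    tryCatch(ape::read.tree(text), error = function(e) NULL)
  } else {
    # balance check first: ape can silently mis-parse unbalanced input
    chars <- strsplit(text, "")[[1]]
    depth <- cumsum((chars == "(") - (chars == ")"))
    if (any(depth < 0) || utils::tail(depth, 1) != 0) {
      abort(sprintf("malformed Newick: unbalanced parentheses at offset %d",
                    which(depth < 0)[1] %||% length(chars)))
    }
    tryCatch(suppressWarnings(ape::read.tree(text = text)),
             error = function(e) NULL)
  }
  if (is.null(tree)) abort("malformed Newick: parse failed")
  tree
}

#' Pairwise path lengths on a tree
#'
#' Tip-to-tip patristic distances, used to verify that neighbor joining
#' reproduces additive distance matrices exactly.
#'
#' @param tree an [ape::phylo].
#' @return symmetric matrix of path lengths with tip labels.
#' @export
tree_path_lengths <- function(tree) {
  ape::cophenetic.phylo(tree)
}
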