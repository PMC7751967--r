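# Neighbor joining (Saitou-Nei) on a percent-difference matrix, producing an
# unrooted tree in Newick form. Implemented here so that tie-breaking and
# negative-branch handling are explicit and deterministic; an independent
# reference implementation (ape::nj) serves as a cross-check in the tests,
# never as the code path.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative NJ with the Saitou-Nei Q criterion. When several
#' pairs minimize Q equally, the lexicographically smallest label pair is
#' joined (internal nodes are keyed by the smallest leaf label they
#' contain). Negative branch lengths are clamped to zero with a warning.
#'
#' @param d Symmetric numeric matrix with zero diagonal, non-negative
#'   entries and unique labels as dimnames; at least 3 leaves.
#' @return List of class `nj_tree` with `newick` (string) and `tree`
#'   (`ape::phylo`, unrooted).
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))), paste0("t", seq_len(nrow(d))))
  }
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (nrow(d) < 3) stop("need at least 3 leaves")

  labels <- rownames(d)
  nwk <- setNames(as.list(labels), labels) # label -> newick fragment
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) {
      clamped <<- TRUE
      0
    } else {
      x
    }
  }
  fmt <- function(x) sprintf("%.10g", x)

  while (nrow(d) > 3) {
    n <- nrow(d)
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(rownames(d)[ij]), collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]
    j <- pick[2]
    li <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    la <- rownames(d)[i]
    lb <- rownames(d)[j]
    new_label <- min(la, lb)
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[[la]], fmt(li), nwk[[lb]], fmt(lj))
    others <- setdiff(seq_len(n), c(i, j))
    dnew <- pmax((d[i, others] + d[j, others] - d[i, j]) / 2, 0)
    d <- d[others, others, drop = FALSE]
    d <- rbind(cbind(d, dnew), c(dnew, 0))
    rownames(d)[nrow(d)] <- colnames(d)[ncol(d)] <- new_label
    nwk[[la]] <- NULL
    nwk[[lb]] <- NULL
    nwk[[new_label]] <- new_nwk
  }

  lab <- rownames(d)
  # three-point formulas for the final star join
  l1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  l2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  l3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  newick <- sprintf(
    "(%s:%s,%s:%s,%s:%s);",
    nwk[[lab[1]]], fmt(l1), nwk[[lab[2]]], fmt(l2), nwk[[lab[3]]], fmt(l3)
  )
  if (clamped) warning("negative branch length(s) clamped to 0")
  structure(
    list(newick = newick, tree = ape::read.tree(text = newick)),
    class = "nj_tree"
  )
}

#' @export
print.nj_tree <- function(x, ...) {
  cat(sprintf(
    "<nj_tree> %d leaves; newick: %s\n",
    length(x$tree$tip.label),
    if (nchar(x$newick) > 70) paste0(substr(x$newick, 1, 67), "...") else x$newick
  ))
  invisible(x)
}

#' Write an NJ tree to a Newick file
#'
#' @param x An `nj_tree`.
#' @param path Output file.
#' @export
write_newick <- function(x, path) {
  writeLines(x$newick, path)
  invisible(path)
}

#' Leaf-to-leaf path lengths on a tree
#'
#' Convenience wrapper returning the cophenetic (path-length) matrix of the
#' reconstructed tree in input-distance units, used to verify additivity.
#'
#' @param x An `nj_tree` or `ape::phylo`.
#' @return Symmetric matrix of path lengths.
#' @export
tree_path_lengths <- function(x) {
  tree <- if (inherits(x, "nj_tree")) x$tree else x
  ape::cophenetic.phylo(tree)
}
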