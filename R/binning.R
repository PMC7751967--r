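# Epitope binning from pairwise sandwich-format competition data: normalize
# secondary responses, threshold into a boolean blocked matrix, group clones
# with identical blocking profiles into bins, and derive the competition
# network and sandwich-compatible reagent pairs.

#' Normalize a raw competition matrix
#'
#' `normalized[i, j] = raw[i, j] / expected[j]`: the secondary response of
#' clone j over immobilized clone i, as a fraction of clone j's expected
#' (uncompeted) response.
#'
#' @param raw Square matrix of secondary responses (RU), clone ids as
#'   dimnames.
#' @param expected Positive per-clone expected maximal responses (named or
#'   in column order).
#' @return Normalized matrix.
#' @export
normalize_competition <- function(raw, expected) {
  stopifnot(is.matrix(raw), nrow(raw) == ncol(raw))
  if (!is.null(names(expected)) && !is.null(colnames(raw))) {
    expected <- expected[colnames(raw)]
  }
  if (length(expected) != ncol(raw)) stop("expected length must match clone count")
  if (any(expected <= 0)) stop("expected responses must be positive")
  sweep(raw, 2, expected, "/")
}

#' Threshold normalized competition into a blocked matrix
#'
#' Clone j is blocked over clone i when its normalized secondary response is
#' strictly below `threshold`; the diagonal (self-competition) is forced
#' `TRUE`.
#'
#' @param normalized Normalized competition matrix.
#' @param threshold Blocking threshold on the fractional response (default
#'   0.2).
#' @return Logical matrix.
#' @export
call_blocked <- function(normalized, threshold = 0.2) {
  blocked <- normalized < threshold
  diag(blocked) <- TRUE
  blocked
}

symmetrize_or <- function(blocked) blocked | t(blocked)

#' Assign epitope bins from a blocked matrix
#'
#' A bin is a family of clones sharing an identical blocking profile: rows
#' of the (optionally OR-symmetrized) blocked matrix are compared exactly
#' and identical rows share a bin. Bins are labelled by their smallest
#' member id.
#'
#' @param blocked Square logical matrix, clone ids as dimnames.
#' @param symmetrize Symmetrize by logical OR before comparing rows
#'   (default `TRUE`; guards against capture-orientation artifacts).
#' @return List with `assignment` (bin label per clone, named) and `bins`
#'   (list of clone-id vectors). Bins partition the clone set.
#' @export
assign_bins <- function(blocked, symmetrize = TRUE) {
  if (!is.matrix(blocked) || nrow(blocked) != ncol(blocked)) {
    stop("blocked matrix must be square")
  }
  if (is.null(rownames(blocked))) {
    dimnames(blocked) <- list(
      paste0("clone_", seq_len(nrow(blocked))),
      paste0("clone_", seq_len(nrow(blocked)))
    )
  }
  b <- if (symmetrize) symmetrize_or(blocked) else blocked
  keys <- apply(b, 1, paste, collapse = "")
  ids <- rownames(b)
  bins <- split(ids, keys)
  labels <- vapply(bins, function(m) sort(m)[1], character(1))
  bins <- setNames(bins, labels)
  bins <- bins[order(names(bins))]
  assignment <- setNames(rep(names(bins), lengths(bins)), unlist(bins))[ids]
  list(assignment = assignment, bins = bins)
}

#' Competition network edge list
#'
#' Undirected edges between clones blocked in either direction
#' (self-edges excluded); the node set is every clone, including isolated
#' ones.
#'
#' @param blocked Square logical matrix.
#' @return List with `nodes` (clone ids) and `edges` (data.frame `from`,
#'   `to`, with `from < to`).
#' @export
build_network <- function(blocked) {
  b <- symmetrize_or(blocked)
  ids <- rownames(b) %||% paste0("clone_", seq_len(nrow(b)))
  pairs <- which(upper.tri(b) & b, arr.ind = TRUE)
  edges <- data.frame(
    from = ids[pairs[, 1]], to = ids[pairs[, 2]],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = ids, edges = edges)
}

#' Sandwich-compatible clone pairs
#'
#' Pairs with no competition in either direction: both can hold the drug at
#' the same time, the prerequisite for a capture/detect sandwich.
#'
#' @param blocked Square logical matrix.
#' @return data.frame `a`, `b` (ids, `a < b`); empty when every pair
#'   competes.
#' @export
sandwich_compatible_pairs <- function(blocked) {
  ids <- rownames(blocked) %||% paste0("clone_", seq_len(nrow(blocked)))
  free <- !blocked & !t(blocked)
  pairs <- which(upper.tri(free) & free, arr.ind = TRUE)
  out <- data.frame(
    a = ids[pairs[, 1]], b = ids[pairs[, 2]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
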